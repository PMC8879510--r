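## Independent reference implementations used only to cross-check the
## package. Deliberately brute force and self-contained: none of them
## call the code paths they verify.

oracleRevComp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

## Exhaustive window scan for GG...N18...NGG targets on both strands.
oracleScan <- function(seq, gene = "seq1") {
  n <- nchar(seq)
  out <- list()
  if (n >= 23) {
    for (s in seq.int(0L, n - 23L)) {
      win <- substr(seq, s + 1L, s + 23L)
      if (grepl("N", win, fixed = TRUE)) next
      for (strand in c("+", "-")) {
        cand <- if (strand == "+") win else oracleRevComp(win)
        if (substr(cand, 1, 2) == "GG" && substr(cand, 22, 23) == "GG") {
          out[[length(out) + 1]] <- data.frame(
            gene = gene, seq = cand, strand = strand, start = s,
            end = s + 23L, distance_to_cds_start = NA_integer_,
            rank = NA_integer_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(gene = character(0), seq = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0),
                      distance_to_cds_start = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  d <- do.call(rbind, out)
  d <- d[order(d$start, match(d$strand, c("+", "-"))), , drop = FALSE]
  rownames(d) <- NULL
  d
}

## Gotoh affine-gap global alignment score (match +1, mismatch -2,
## a gap of length k costs 5 + k). Score only, quadratic DP.
oracleAlignScore <- function(a, b, match = 1, mismatch = -2,
                             open = 5, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, na + 1, nb + 1)
  X <- matrix(NEG, na + 1, nb + 1)  # gap in b (a aligned to -)
  Y <- matrix(NEG, na + 1, nb + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(na)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(nb)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  max(M[na + 1, nb + 1], X[na + 1, nb + 1], Y[na + 1, nb + 1])
}

## Build a DuplexFragment for simulator tests from a forward-strand core
## and two end descriptions (side in "5p"/"3p"/"blunt"; ovSeq is the
## protruding strand's 5'->3' sequence).
makeTestFragment <- function(index, core, leftSide = "blunt",
                             leftSeq = "", rightSide = "blunt",
                             rightSeq = "") {
  fwdPrefix <- switch(leftSide, blunt = "", "5p" = leftSeq,
                      "3p" = oracleRevComp(leftSeq))
  fwdSuffix <- switch(rightSide, blunt = "", "3p" = rightSeq,
                      "5p" = oracleRevComp(rightSeq))
  fwd <- paste0(fwdPrefix, core, fwdSuffix)
  topStart <- if (leftSide == "5p") 0 else nchar(fwdPrefix)
  topEnd <- nchar(fwd) - if (rightSide == "5p") nchar(fwdSuffix) else 0
  botStart <- if (leftSide == "3p") 0 else nchar(fwdPrefix)
  botEnd <- nchar(fwd) - if (rightSide == "3p") nchar(fwdSuffix) else 0
  new("DuplexFragment", index = as.integer(index),
      topOligo = substr(fwd, topStart + 1, topEnd),
      bottomOligo = oracleRevComp(substr(fwd, botStart + 1, botEnd)),
      leftOverhang = list(seq = leftSeq, side = leftSide),
      rightOverhang = list(seq = rightSeq, side = rightSide),
      fwdSeq = fwd)
}

## Factorial enumeration of ligation products: every permutation of every
## non-empty subset, in every orientation vector. Returns the canonical
## multiset of products as sorted "topology|fragment-ids" strings.
oracleLigation <- function(frags) {
  n <- length(frags)
  endOf <- function(i, flip, which) {
    f <- frags[[i]]
    if (!flip) {
      if (which == "L") f@leftOverhang else f@rightOverhang
    } else {
      if (which == "L") f@rightOverhang else f@leftOverhang
    }
  }
  compat <- function(eR, eL) {
    eR$side != "blunt" && eR$side == eL$side &&
      eL$seq == oracleRevComp(eR$seq)
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (p in perms(v[-k])) out[[length(out) + 1]] <- c(v[k], p)
    out
  }
  keys <- character(0)
  subsets <- unlist(lapply(seq_len(n), function(k)
    utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
  for (sub in subsets) {
    for (ord in perms(sub)) {
      k <- length(ord)
      for (bits in 0:(2^k - 1)) {
        flips <- as.logical(bitwAnd(bits, 2^(seq_len(k) - 1)))
        ok <- TRUE
        if (k > 1) {
          for (j in seq_len(k - 1)) {
            if (!compat(endOf(ord[j], flips[j], "R"),
                        endOf(ord[j + 1], flips[j + 1], "L"))) {
              ok <- FALSE; break
            }
          }
        }
        if (!ok) next
        unused <- setdiff(seq_len(n), ord)
        circ <- compat(endOf(ord[k], flips[k], "R"),
                       endOf(ord[1], flips[1], "L"))
        if (circ) {
          keys <- c(keys, paste0("circular|",
                                 paste(sort(ord), collapse = ",")))
        }
        extendable <- FALSE
        for (u in unused) for (fl in c(FALSE, TRUE)) {
          if (compat(endOf(ord[k], flips[k], "R"), endOf(u, fl, "L")) ||
              compat(endOf(u, fl, "R"), endOf(ord[1], flips[1], "L"))) {
            extendable <- TRUE
          }
        }
        if (!extendable)
          keys <- c(keys, paste0("linear|",
                                 paste(sort(ord), collapse = ",")))
      }
    }
  }
  sort(unique(keys))
}

## Random valid 23-nt target: GG + 18 random + N + GG.
randomTarget <- function() {
  paste0("GG", paste(sample(c("A", "C", "G", "T"), 19, TRUE),
                     collapse = ""), "GG")
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}
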