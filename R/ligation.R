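## Exhaustive sticky-end ligation simulation.

## Oriented view of a fragment: flipping a duplex swaps its ends (the
## protruding strand's 5'->3' sequence and protrusion side are physical
## properties of the molecule and do not change).
orientedEnd <- function(frag, flipped, which) {
  if (!flipped) {
    if (which == "L") frag@leftOverhang else frag@rightOverhang
  } else {
    if (which == "L") frag@rightOverhang else frag@leftOverhang
  }
}

orientedFwdSeq <- function(frag, flipped) {
  if (flipped) revComp(frag@fwdSeq) else frag@fwdSeq
}

## Two sticky ends anneal iff they protrude on the same side (both 5' or
## both 3') and their single-stranded sequences are reverse complements.
## Blunt ends never ligate in this model.
endsCompatible <- function(endA, endB) {
  endA$side != "blunt" && endA$side == endB$side &&
    endB$seq == revComp(endA$seq)
}

chainSignature <- function(chain) {
  paste(vapply(chain, function(x)
    sprintf("%d%s", x$i, if (x$flip) "r" else "f"), character(1)),
    collapse = ",")
}

## Canonical key of a product, invariant under reading direction and (for
## circles) rotation. Flipping the whole chain reverses order and flips
## every fragment.
canonicalKey <- function(chain, circular) {
  flipChain <- lapply(rev(chain), function(x)
    list(i = x$i, flip = !x$flip))
  if (!circular) {
    min(chainSignature(chain), chainSignature(flipChain))
  } else {
    rots <- function(ch) {
      n <- length(ch)
      vapply(seq_len(n), function(k)
        chainSignature(ch[c(seq(k, n), if (k > 1) seq(1, k - 1))]),
        character(1))
    }
    min(c(rots(chain), rots(flipChain)))
  }
}

assembleSeq <- function(chain, frags) {
  pieces <- character(length(chain))
  for (k in seq_along(chain)) {
    s <- orientedFwdSeq(frags[[chain[[k]]$i]], chain[[k]]$flip)
    if (k > 1) {
      ov <- orientedEnd(frags[[chain[[k]]$i]], chain[[k]]$flip, "L")
      s <- substr(s, nchar(ov$seq) + 1L, nchar(s))
    }
    pieces[k] <- s
  }
  paste(pieces, collapse = "")
}

#' Simulate all ligation products of a fragment set
#'
#' Exhaustively joins duplex fragments (each usable at most once per
#' product, in either orientation) wherever sticky ends are Watson-Crick
#' complementary with matching protrusion sides. Blunt ends do not ligate.
#' All maximal products are returned: linear chains that cannot be
#' extended by any unused fragment, plus every possible circular closure.
#' The result is independent of the input order of the fragments.
#'
#' A correctly designed [splitTemplate()] output yields exactly one
#' product: the full-length linear template, with no circular species.
#'
#' @param frags List of [DuplexFragment-class] objects, or an
#'   [OligoSet-class].
#' @return \code{data.frame} with columns \code{topology}
#'   (\code{"linear"}/\code{"circular"}), \code{n_fragments},
#'   \code{length} (nt, forward strand), \code{fragments} (signature like
#'   \code{"1f,2f,3f"}; \code{r} marks a flipped fragment) and
#'   \code{sequence}. For circular products the sequence is reported from
#'   an arbitrary but deterministic opening point.
#' @export
simulateLigation <- function(frags) {
  if (is(frags, "OligoSet")) frags <- fragments(frags)
  stopifnot(length(frags) >= 1L,
            all(vapply(frags, is, logical(1), "DuplexFragment")))
  n <- length(frags)
  if (n > 8L) stop("exhaustive simulation limited to 8 fragments")

  products <- new.env(parent = emptyenv())
  addProduct <- function(chain, circular) {
    key <- canonicalKey(chain, circular)
    if (!is.null(products[[key]])) return(invisible())
    products[[key]] <- list(chain = chain, circular = circular)
  }

  canExtend <- function(end, used, side) {
    for (i in seq_len(n)) {
      if (used[i]) next
      for (fl in c(FALSE, TRUE)) {
        other <- orientedEnd(frags[[i]], fl,
                             if (side == "right") "L" else "R")
        if (side == "right" && endsCompatible(end, other)) return(TRUE)
        if (side == "left" && endsCompatible(other, end)) return(TRUE)
      }
    }
    FALSE
  }

  extend <- function(chain, used) {
    last <- chain[[length(chain)]]
    rightEnd <- orientedEnd(frags[[last$i]], last$flip, "R")
    leftEnd <- orientedEnd(frags[[chain[[1]]$i]], chain[[1]]$flip, "L")
    ## circular closure is always a product
    if (length(chain) >= 1L && endsCompatible(rightEnd, leftEnd) &&
        !(length(chain) == 1L && rightEnd$side == "blunt"))
      addProduct(chain, circular = TRUE)
    extended <- FALSE
    for (i in seq_len(n)) {
      if (used[i]) next
      for (fl in c(FALSE, TRUE)) {
        nextLeft <- orientedEnd(frags[[i]], fl, "L")
        if (endsCompatible(rightEnd, nextLeft)) {
          extended <- TRUE
          used2 <- used; used2[i] <- TRUE
          extend(c(chain, list(list(i = i, flip = fl))), used2)
        }
      }
    }
    ## maximal linear product: extendable at neither end
    if (!extended && !canExtend(leftEnd, used, "left"))
      addProduct(chain, circular = FALSE)
  }

  for (i in seq_len(n)) {
    used <- rep(FALSE, n); used[i] <- TRUE
    ## starting orientation: forward only -- the flipped chain is the
    ## same molecule and is collapsed by the canonical key anyway
    extend(list(list(i = i, flip = FALSE)), used)
    extend(list(list(i = i, flip = TRUE)), used)
  }

  keys <- ls(products)
  if (!length(keys))
    return(data.frame(topology = character(0), n_fragments = integer(0),
                      length = integer(0), fragments = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  rows <- lapply(keys, function(k) {
    p <- products[[k]]
    seqStr <- assembleSeq(p$chain, frags)
    if (p$circular) {
      ## close the circle: trim the terminal overlap with the first piece
      lastOv <- orientedEnd(frags[[p$chain[[1]]$i]], p$chain[[1]]$flip, "L")
      seqStr <- substr(seqStr, 1L, nchar(seqStr) - nchar(lastOv$seq))
    } else {
      ## a linear duplex has two equivalent readings; report the
      ## lexicographically larger strand so the text is independent of
      ## the fragment input order
      seqStr <- max(seqStr, revComp(seqStr))
    }
    data.frame(topology = if (p$circular) "circular" else "linear",
               n_fragments = length(p$chain),
               length = nchar(seqStr),
               fragments = chainSignature(p$chain),
               sequence = seqStr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$length, out$topology, out$sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
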