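## Template construction and six-oligo decomposition.

## T7 promoter prefix (transcription starts at the GG supplied by the
## target) and the constant 81-nt single-guide scaffold.
T7_PROMOTER <- "AATTTAATACGACTCACTATA"
SCAFFOLD81 <- paste0(
  "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGG",
  "CACCGAGTCGGTGCTTTTT")

#' Build the full gRNA transcription template for one target
#'
#' Assembles T7 promoter + spacer region + scaffold. By default the 3-nt
#' PAM is kept between spacer and scaffold, matching the published
#' template pattern (125 nt); \code{includePAM = FALSE} drops it (122 nt).
#' The template's first transcribed bases are the target's leading
#' \code{GG}, which is why targets are required to start with \code{GG}.
#'
#' @param target 23-nt target sequence (protospacer + PAM) or a
#'   single-hit [GuideTargetSet-class].
#' @param gene Gene identifier (defaults to the set's gene if a
#'   \code{GuideTargetSet} is given).
#' @param includePAM Keep the PAM in the transcribed spacer region.
#' @return A [GuideTemplate-class].
#' @export
#' @examples
#' tpl <- buildTemplate("GGATGTCCCTTGAGAACGGGAGG", gene = "gabbr1a")
#' nchar(templateSeq(tpl))  # 125
buildTemplate <- function(target, gene = "gene", includePAM = TRUE) {
  if (is(target, "GuideTargetSet")) {
    stopifnot(length(target) == 1L)
    gene <- target@gene
    target <- targetSeqs(target)
  }
  v <- validateTarget(target)
  if (!v$valid)
    stop("invalid target sequence (", paste(v$reasons, collapse = ", "),
         "): ", target)
  spacer <- if (includePAM) target else substr(target, 1, 20)
  new("GuideTemplate", gene = gene, targetSeq = target,
      seq = paste0(T7_PROMOTER, spacer, SCAFFOLD81),
      includePAM = includePAM)
}

## End of the target-dependent region on the template (0-based exclusive).
## The spacer occupies [21, 21+len); its first two bases (GG, fixed by the
## selection rule) and -- when the PAM is kept -- the final GG of the PAM
## are constant across targets, so only [23, 21+len-2) truly varies.
variableRegionEnd <- function(template) {
  if (template@includePAM) 21L + 23L - 2L else 21L + 20L
}

## Build one DuplexFragment from top-strand coverage [tS,tE) and
## bottom-strand coverage [bS,bE) on the template forward coordinate.
makeFragment <- function(template, index, tS, tE, bS, bE) {
  seq <- template
  sub <- function(s, e) if (e > s) substr(seq, s + 1L, e) else ""
  left <-
    if (tS < bS) list(seq = sub(tS, bS), side = "5p")
    else if (bS < tS) list(seq = revComp(sub(bS, tS)), side = "3p")
    else list(seq = "", side = "blunt")
  right <-
    if (tE > bE) list(seq = sub(bE, tE), side = "3p")
    else if (bE > tE) list(seq = revComp(sub(tE, bE)), side = "5p")
    else list(seq = "", side = "blunt")
  new("DuplexFragment", index = as.integer(index),
      topOligo = sub(tS, tE), bottomOligo = revComp(sub(bS, bE)),
      leftOverhang = left, rightOverhang = right,
      fwdSeq = sub(min(tS, bS), max(tE, bE)))
}

## Admissibility of the two junction overhangs (forward-strand sequences):
## distinct, non-palindromic, and not reverse complements of each other.
## These are the minimal conditions under which the three fragments join
## in exactly one order and cannot circularise.
overhangsAdmissible <- function(o1, o2) {
  o1 != o2 && o1 != revComp(o1) && o2 != revComp(o2) && o2 != revComp(o1)
}

#' Split a template into three sticky-ended duplex fragments
#'
#' Deterministically searches junction cut positions on both strands such
#' that: all six oligos are 38-46 nt; every target-dependent base falls in
#' fragment 1 (so only fragment 1's two oligos ever need resynthesis for a
#' new guide); the outer template ends are blunt; and the two junction
#' overhangs are pairwise distinct, non-self-complementary and not
#' complementary to each other, which forces a unique ligation order and
#' suppresses circular products. Among admissible splits the one with the
#' most balanced oligo lengths is chosen (ties resolved by scan order), so
#' the design is reproducible without any randomness.
#'
#' @param template A [GuideTemplate-class].
#' @param overhangLen Junction overhang length in nt (default 4;
#'   3 and 5 are supported).
#' @param oligoLenRange Allowed oligo length range (default \code{c(38, 46)}).
#' @return An [OligoSet-class].
#' @export
splitTemplate <- function(template, overhangLen = 4L,
                          oligoLenRange = c(38L, 46L)) {
  stopifnot(is(template, "GuideTemplate"))
  L <- as.integer(overhangLen)
  if (!L %in% 3:5)
    stop("overhangLen must be 3, 4 or 5")
  lo <- as.integer(oligoLenRange[1]); hi <- as.integer(oligoLenRange[2])
  seq <- template@seq
  n <- nchar(seq)
  vEnd <- variableRegionEnd(template)

  best <- NULL
  bestScore <- Inf
  ## junction k: top-strand cut tk, bottom-strand cut uk = tk +/- L
  for (t1 in seq.int(lo, hi)) for (d1 in c(-L, L)) {
    u1 <- t1 + d1
    if (u1 < lo || u1 > hi) next
    if (min(t1, u1) < vEnd) next            # keep variable bases in frag 1
    for (t2 in seq.int(n - hi, n - lo)) for (d2 in c(-L, L)) {
      u2 <- t2 + d2
      lens <- c(t1, t2 - t1, n - t2, u1, u2 - u1, n - u2)
      if (any(lens < lo | lens > hi)) next
      if (min(t2, u2) < max(t1, u1)) next   # junctions must not overlap
      o1 <- substr(seq, min(t1, u1) + 1L, max(t1, u1))
      o2 <- substr(seq, min(t2, u2) + 1L, max(t2, u2))
      if (!overhangsAdmissible(o1, o2)) next
      score <- stats::var(lens)
      if (score < bestScore - 1e-9) {
        bestScore <- score
        best <- c(t1 = t1, u1 = u1, t2 = t2, u2 = u2)
      }
    }
  }
  if (is.null(best))
    stop("no admissible split: no junction placement satisfies the ",
         "oligo-length, variable-region and overhang constraints; ",
         "try overhangLen 3 or 5")

  t1 <- best["t1"]; u1 <- best["u1"]; t2 <- best["t2"]; u2 <- best["u2"]
  frags <- list(
    makeFragment(seq, 1L, 0L, t1, 0L, u1),
    makeFragment(seq, 2L, t1, t2, u1, u2),
    makeFragment(seq, 3L, t2, n, u2, n)
  )
  tab <- do.call(rbind, lapply(frags, function(f) {
    data.frame(
      name = sprintf("F%d-%s", f@index, c("top", "bottom")),
      sequence = c(f@topOligo, f@bottomOligo),
      length = c(nchar(f@topOligo), nchar(f@bottomOligo)),
      fragment = f@index, strand = c("top", "bottom"),
      stringsAsFactors = FALSE)
  }))
  ## an oligo is target-variable iff it covers any variable position;
  ## by construction those are exactly fragment 1's two oligos
  spans <- rbind(c(0L, t1), c(t1, t2), c(t2, n),
                 c(0L, u1), c(u1, u2), c(u2, n))
  spans <- spans[c(1, 4, 2, 5, 3, 6), , drop = FALSE]
  tab$variable_per_target <- spans[, 1] < vEnd & spans[, 2] > 23L
  rownames(tab) <- NULL
  new("OligoSet", gene = template@gene, oligoTable = tab,
      fragments = frags, overhangLen = L, templateSeq = seq)
}

#' Compare two oligo designs
#'
#' Lists the oligos whose sequences differ between two designs produced by
#' [splitTemplate()] with identical parameters. For two guides this is
#' exactly the two fragment-1 oligos: the remaining fragments are shared
#' and never need resynthesis.
#'
#' @param setA,setB [OligoSet-class] objects.
#' @return \code{data.frame} with columns \code{name}, \code{fragment},
#'   \code{seq_a}, \code{seq_b}; zero rows when the designs are identical.
#' @export
diffOligos <- function(setA, setB) {
  stopifnot(is(setA, "OligoSet"), is(setB, "OligoSet"))
  if (setA@overhangLen != setB@overhangLen ||
      nchar(setA@templateSeq) != nchar(setB@templateSeq))
    stop("oligo sets were built with different parameters")
  a <- setA@oligoTable; b <- setB@oligoTable
  stopifnot(identical(a$name, b$name))
  differ <- a$sequence != b$sequence
  out <- data.frame(name = a$name[differ], fragment = a$fragment[differ],
                    seq_a = a$sequence[differ], seq_b = b$sequence[differ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
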