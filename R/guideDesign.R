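## Guide target scanning, ranking and masking.

#' Validate a candidate gRNA target sequence
#'
#' A valid target is a 23-nt DNA string over \code{A/C/G/T} that begins
#' with \code{GG} (required for efficient T7 transcription initiation) and
#' whose final three bases are the Cas9 PAM \code{NGG} (positions 22-23
#' fixed \code{GG}, position 21 free).
#'
#' @param seq A DNA string.
#' @return A list with elements \code{valid} (logical) and \code{reasons}
#'   (character vector of failure codes, empty when valid). Codes:
#'   \code{bad_alphabet}, \code{bad_length}, \code{no_gg_prefix},
#'   \code{no_ngg_suffix}.
#' @export
#' @examples
#' validateTarget("GGATGTCCCTTGAGAACGGGAGG")$valid
validateTarget <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  reasons <- character(0)
  if (!grepl("^[ACGT]*$", seq) || nchar(seq) == 0L)
    reasons <- c(reasons, "bad_alphabet")
  if (nchar(seq) != 23L)
    reasons <- c(reasons, "bad_length")
  if (substr(seq, 1, 2) != "GG")
    reasons <- c(reasons, "no_gg_prefix")
  if (nchar(seq) < 23L || substr(seq, 22, 23) != "GG")
    reasons <- c(reasons, "no_ngg_suffix")
  list(valid = length(reasons) == 0L, reasons = reasons)
}

#' Scan a sequence for gRNA targets on both strands
#'
#' Slides a 23-nt window over the forward strand (and, by default, the
#' reverse complement) and reports every window that passes
#' [validateTarget()]. Windows containing \code{N} are skipped, since the
#' PAM rule is undefined on \code{N}. Overlapping and nested hits are all
#' reported; hits are sorted by forward-strand start, \code{+} before
#' \code{-} at equal start.
#'
#' @param seq DNA string to scan (may contain \code{N}).
#' @param gene Identifier used to label hits.
#' @param bothStrands Scan the minus strand as well (default \code{TRUE}).
#' @return A [GuideTargetSet-class]. Sequences shorter than 23 nt yield an
#'   empty set (not an error). Minus-strand hits report \code{seq} in
#'   target-strand orientation; \code{start}/\code{end} are always 0-based
#'   half-open forward-strand coordinates.
#' @export
#' @examples
#' findTargets("GGATGTCCCTTGAGAACGGGAGGGTGTCGCTG", gene = "gabbr1a")
findTargets <- function(seq, gene = "seq1", bothStrands = TRUE) {
  stopifnot(isDNA(seq, allowN = TRUE))
  n <- nchar(seq)
  empty <- data.frame(gene = character(0), seq = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0),
                      distance_to_cds_start = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  if (n < 23L)
    return(new("GuideTargetSet", gene = gene, hits = empty))
  starts <- 0:(n - 23L)
  wins <- substring(seq, starts + 1L, starts + 23L)
  ok <- !grepl("N", wins, fixed = TRUE)
  hitPlus <- ok & substr(wins, 1, 2) == "GG" & substr(wins, 22, 23) == "GG"
  rows <- list()
  if (any(hitPlus)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, seq = wins[hitPlus], strand = "+",
      start = starts[hitPlus], end = starts[hitPlus] + 23L,
      distance_to_cds_start = NA_integer_, rank = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (bothStrands) {
    rcwins <- revComp(wins[ok])
    hitMinus <- substr(rcwins, 1, 2) == "GG" &
      substr(rcwins, 22, 23) == "GG"
    if (any(hitMinus)) {
      st <- starts[ok][hitMinus]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, seq = rcwins[hitMinus], strand = "-",
        start = st, end = st + 23L,
        distance_to_cds_start = NA_integer_, rank = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(hits)) {
    ord <- order(hits$start, match(hits$strand, c("+", "-")))
    hits <- hits[ord, , drop = FALSE]
    rownames(hits) <- NULL
  }
  new("GuideTargetSet", gene = gene, hits = hits)
}

#' Rank targets by proximity to the coding-sequence start
#'
#' Indels near the N-terminus of the coding sequence are most likely to
#' produce premature terminations, so candidates are ordered by absolute
#' distance between the hit's forward-strand start and \code{cdsStart}.
#' Ties are broken \code{+} strand first, then lower start coordinate.
#'
#' @param targets A [GuideTargetSet-class].
#' @param cdsStart 0-based forward-strand coordinate of the CDS start.
#' @return The set with \code{distance_to_cds_start} and \code{rank}
#'   filled in and hits reordered by rank.
#' @export
rankTargets <- function(targets, cdsStart) {
  stopifnot(is(targets, "GuideTargetSet"),
            is.numeric(cdsStart), length(cdsStart) == 1L, cdsStart >= 0)
  h <- targets@hits
  if (nrow(h) == 0L) return(targets)
  h$distance_to_cds_start <- abs(h$start - as.integer(cdsStart))
  ord <- order(h$distance_to_cds_start,
               match(h$strand, c("+", "-")), h$start)
  h <- h[ord, , drop = FALSE]
  h$rank <- seq_len(nrow(h))
  rownames(h) <- NULL
  new("GuideTargetSet", gene = targets@gene, hits = h)
}

#' Remove targets overlapping known variant positions
#'
#' A sequence variant inside the protospacer or PAM can abolish guide
#' binding, so any hit whose interval \code{[start, end)} intersects a
#' user-supplied variant position is dropped. Positions are 0-based
#' forward-strand coordinates; the half-open end is exclusive, so a
#' variant exactly at \code{end} does not remove the hit.
#'
#' @param targets A [GuideTargetSet-class].
#' @param variantPositions Integer vector of 0-based positions.
#' @return The filtered [GuideTargetSet-class].
#' @export
maskVariants <- function(targets, variantPositions) {
  stopifnot(is(targets, "GuideTargetSet"), is.numeric(variantPositions))
  h <- targets@hits
  if (nrow(h) == 0L || length(variantPositions) == 0L) return(targets)
  vp <- as.integer(variantPositions)
  keep <- vapply(seq_len(nrow(h)), function(i) {
    !any(vp >= h$start[i] & vp < h$end[i])
  }, logical(1))
  h <- h[keep, , drop = FALSE]
  rownames(h) <- NULL
  new("GuideTargetSet", gene = targets@gene, hits = h)
}
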