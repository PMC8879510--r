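## Indel calling and classification from Sanger-resolved alleles.

## Alignment scoring used throughout: match +1, mismatch -2, and an
## affine gap of length k costs 5 + k (gap opening 5, extension 1).
ALN_MATCH <- 1
ALN_MISMATCH <- -2
ALN_GAP_OPEN <- 5
ALN_GAP_EXT <- 1

#' Globally align a mutant allele to its wild-type sequence
#'
#' Needleman-Wunsch global alignment with affine gap penalties (match +1,
#' mismatch -2, gap open -5, gap extension -1 per gapped position),
#' computed with [Biostrings::pairwiseAlignment()].
#'
#' @param wtSeq Wild-type DNA sequence.
#' @param alleleSeq Mutant allele DNA sequence.
#' @return List with \code{wt} and \code{allele} (aligned strings with
#'   \code{-} for gaps) and \code{score}.
#' @seealso [callEvent()]
#' @export
alignAllele <- function(wtSeq, alleleSeq) {
  stopifnot(isDNA(wtSeq), isDNA(alleleSeq))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = ALN_MATCH, mismatch = ALN_MISMATCH, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = alleleSeq, subject = wtSeq, type = "global",
    substitutionMatrix = mat,
    gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
  list(wt = as.character(Biostrings::subject(aln)),
       allele = as.character(Biostrings::pattern(aln)),
       score = Biostrings::score(aln))
}

#' Classify a net indel change
#'
#' Pure classification rule: the class is \code{complex} when both a
#' deletion and an insertion component are present, otherwise named after
#' the single component (or \code{none}); an event shifts the reading
#' frame iff its net length change is not a multiple of 3.
#'
#' @param netChange Signed net change in nt.
#' @param hasDel,hasIns Whether the allele carries deletion / insertion
#'   components.
#' @return List with \code{mutation_class} and \code{frameshift}.
#' @export
#' @examples
#' classifyNet(-33, hasDel = TRUE, hasIns = FALSE)  # in-frame deletion
classifyNet <- function(netChange, hasDel, hasIns) {
  stopifnot(length(netChange) == 1L, is.logical(hasDel), is.logical(hasIns))
  netChange <- as.integer(netChange)
  cls <- if (hasDel && hasIns) "complex"
         else if (hasDel) "deletion"
         else if (hasIns) "insertion"
         else "none"
  list(mutation_class = cls,
       frameshift = netChange %% 3L != 0L && cls != "none")
}

## Canonical label: net change first, component breakdown parenthesised
## only for complex events. "0" for the null event.
formatLabel <- function(net, del, ins) {
  fmt <- function(x) if (x > 0) sprintf("+%d", x)
                     else if (x < 0) sprintf("%d", x) else "0"
  if (del > 0 && ins > 0)
    sprintf("%s (-%d, +%d)", fmt(net), del, ins)
  else fmt(net)
}

#' Parse a canonical mutation label
#'
#' Inverts the label grammar used in founder-screen tables: a signed net
#' change, optionally followed by a parenthesised \code{(-deleted,
#' +inserted)} component breakdown for complex events, e.g. \code{"-8"},
#' \code{"+1"}, \code{"+2 (-5, +7)"} or \code{"0"}.
#'
#' @param label Label string.
#' @return List with \code{net}, \code{del}, \code{ins},
#'   \code{mutation_class} and \code{frameshift}.
#' @export
parseLabel <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, !is.na(label))
  m <- regmatches(label,
    regexec("^([+-]?[0-9]+)(?: \\(-([0-9]+), \\+([0-9]+)\\))?$", label))[[1]]
  if (length(m) == 0L) stop("unparseable mutation label: '", label, "'")
  net <- as.integer(m[2])
  if (m[3] != "") {
    del <- as.integer(m[3]); ins <- as.integer(m[4])
    if (ins - del != net)
      stop("label components inconsistent with net change: '", label, "'")
  } else if (net < 0L) {
    del <- -net; ins <- 0L
  } else if (net > 0L) {
    del <- 0L; ins <- net
  } else {
    del <- 0L; ins <- 0L
  }
  cl <- classifyNet(net, del > 0L, ins > 0L)
  list(net = net, del = del, ins = ins,
       mutation_class = cl$mutation_class, frameshift = cl$frameshift)
}

labelIsValid <- function(label) {
  !inherits(try(parseLabel(label), silent = TRUE), "try-error")
}

#' Call the mutation event of one allele
#'
#' Extracts the single edit region of a Sanger-resolved allele: the
#' longest common prefix and suffix with the wild type are trimmed and the
#' remaining wild-type bases form the deletion component while the
#' remaining allele bases form the insertion component. This is exactly
#' how founder-screen tables annotate alleles (e.g. \code{"-8"},
#' \code{"+2 (-5, +7)"}): one event per allele, placed directly after the
#' longest common prefix. Equal-length alleles are block substitutions at
#' the sequence level and are reported position-wise in a side channel
#' with class \code{none}, since indel screens record only
#' length-changing events. The model assumes one edit region per allele
#' (the Sanger-genotyping situation); alleles carrying several widely
#' separated edits are summarised as a single spanning event.
#'
#' @param wtSeq Wild-type DNA sequence.
#' @param alleleSeq Mutant allele DNA sequence.
#' @param gene Gene identifier stored in the event.
#' @return A [MutationEvent-class].
#' @export
#' @examples
#' ev <- callEvent("CCTCCTCTCCCCGAATCTACACCCACT",
#'                 "CCTCCCCGAATCTACACCCACT", gene = "tmem183a")
#' eventLabel(ev)  # "-5"
callEvent <- function(wtSeq, alleleSeq, gene = "gene") {
  stopifnot(isDNA(wtSeq), isDNA(alleleSeq))
  noDel <- data.frame(position = integer(0), length = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  noIns <- data.frame(position = integer(0), seq = character(0),
                      stringsAsFactors = FALSE)
  noSub <- data.frame(position = integer(0), wt = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
  if (wtSeq == alleleSeq)
    return(new("MutationEvent", gene = gene, deletions = noDel,
               insertions = noIns, substitutions = noSub,
               netChange = 0L, mutationClass = "none",
               frameshift = FALSE, label = "0"))

  net <- nchar(alleleSeq) - nchar(wtSeq)
  if (net == 0L) {
    ## equal length: at the sequence level this is a (block) substitution,
    ## not an indel; report position-wise mismatches in the side channel
    w <- strsplit(wtSeq, "")[[1]]
    a <- strsplit(alleleSeq, "")[[1]]
    mm <- which(w != a)
    subs <- data.frame(position = mm - 1L, wt = w[mm], alt = a[mm],
                       stringsAsFactors = FALSE)
    return(new("MutationEvent", gene = gene, deletions = noDel,
               insertions = noIns, substitutions = subs,
               netChange = 0L, mutationClass = "none",
               frameshift = FALSE, label = "0"))
  }

  p <- commonPrefixLen(wtSeq, alleleSeq)
  s <- commonSuffixLen(wtSeq, alleleSeq)
  maxTrim <- min(nchar(wtSeq), nchar(alleleSeq)) - p
  if (s > maxTrim) s <- maxTrim
  delSeq <- substr(wtSeq, p + 1L, nchar(wtSeq) - s)
  insSeq <- substr(alleleSeq, p + 1L, nchar(alleleSeq) - s)
  dels <- if (nchar(delSeq) > 0)
    data.frame(position = p, length = nchar(delSeq), seq = delSeq,
               stringsAsFactors = FALSE) else noDel
  inss <- if (nchar(insSeq) > 0)
    data.frame(position = p, seq = insSeq, stringsAsFactors = FALSE)
    else noIns
  cl <- classifyNet(net, nrow(dels) > 0, nrow(inss) > 0)
  new("MutationEvent", gene = gene, deletions = dels, insertions = inss,
      substitutions = noSub, netChange = as.integer(net),
      mutationClass = cl$mutation_class, frameshift = cl$frameshift,
      label = formatLabel(net, nchar(delSeq), nchar(insSeq)))
}

#' Call events for a table of alleles
#'
#' Convenience wrapper applying [callEvent()] to a long table of alleles.
#'
#' @param wtSeqs Named character vector of wild-type sequences (names are
#'   gene identifiers).
#' @param alleles \code{data.frame} with columns \code{fish_id},
#'   \code{gene} and \code{allele_seq}.
#' @return \code{data.frame} with columns \code{fish_id}, \code{gene},
#'   \code{label}, \code{net_change}, \code{class}, \code{frameshift},
#'   \code{components}.
#' @export
callEvents <- function(wtSeqs, alleles) {
  need <- c("fish_id", "gene", "allele_seq")
  stopifnot(is.character(wtSeqs), !is.null(names(wtSeqs)),
            all(need %in% names(alleles)))
  miss <- setdiff(unique(alleles$gene), names(wtSeqs))
  if (length(miss))
    stop("no wild-type sequence for gene(s): ", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(alleles)), function(i) {
    g <- alleles$gene[i]
    ev <- callEvent(wtSeqs[[g]], alleles$allele_seq[i], gene = g)
    comp <- sprintf("del:%s;ins:%s",
                    paste(ev@deletions$seq, collapse = ","),
                    paste(ev@insertions$seq, collapse = ","))
    data.frame(fish_id = alleles$fish_id[i], gene = g,
               label = ev@label, net_change = ev@netChange,
               class = ev@mutationClass, frameshift = ev@frameshift,
               components = comp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
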