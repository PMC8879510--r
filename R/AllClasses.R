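## S4 classes for the central data objects.

#' Set of candidate gRNA targets found in one sequence
#'
#' Holds protospacer+PAM hits produced by [findTargets()]. Each hit is a
#' 23-nt window whose sequence starts \code{GG} (required by T7
#' transcription initiation) and ends \code{NGG} (the Cas9
#' protospacer-adjacent motif). Coordinates are 0-based half-open on the
#' forward strand of the scanned record; minus-strand hits report their
#' sequence in target-strand orientation (i.e. the reverse complement of
#' the forward-strand window).
#'
#' @slot gene Identifier of the scanned record.
#' @slot hits \code{data.frame} with columns \code{gene}, \code{seq},
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{start}, \code{end}
#'   (0-based half-open), \code{distance_to_cds_start} (\code{NA} until
#'   ranked) and \code{rank} (\code{NA} until ranked).
#' @seealso [findTargets()], [rankTargets()], [maskVariants()]
#' @export
setClass("GuideTargetSet",
  representation(gene = "character", hits = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    need <- c("gene", "seq", "strand", "start", "end",
              "distance_to_cds_start", "rank")
    if (!all(need %in% names(object@hits)))
      msg <- c(msg, paste("hits must have columns:",
                          paste(need, collapse = ", ")))
    else if (nrow(object@hits) > 0) {
      h <- object@hits
      if (!all(nchar(h$seq) == 23L))
        msg <- c(msg, "all target sequences must be 23 nt")
      if (!all(substr(h$seq, 1, 2) == "GG"))
        msg <- c(msg, "all target sequences must start with GG")
      if (!all(substr(h$seq, 22, 23) == "GG"))
        msg <- c(msg, "all target sequences must end with NGG")
      if (!all(h$strand %in% c("+", "-")))
        msg <- c(msg, "strand must be '+' or '-'")
      if (!all(h$end - h$start == 23L))
        msg <- c(msg, "all hit intervals must have width 23")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Full gRNA in-vitro transcription template
#'
#' The DNA template for T7 transcription of one single-guide RNA: a 21-nt
#' T7 promoter, the 23-nt gene-specific spacer region (protospacer + PAM,
#' or the 20-nt protospacer alone when \code{includePAM} is \code{FALSE}),
#' and the constant 81-nt guide scaffold. Lengths are therefore 125 nt
#' (PAM kept) or 122 nt (PAM dropped).
#'
#' @slot gene Gene identifier.
#' @slot targetSeq The 23-nt protospacer+PAM the template was built from.
#' @slot seq The full template sequence.
#' @slot includePAM Whether the 3-nt PAM is retained between spacer and
#'   scaffold.
#' @seealso [buildTemplate()], [splitTemplate()]
#' @export
setClass("GuideTemplate",
  representation(gene = "character", targetSeq = "character",
                 seq = "character", includePAM = "logical"),
  validity = function(object) {
    msg <- character(0)
    if (!isDNA(object@targetSeq) || nchar(object@targetSeq) != 23L)
      msg <- c(msg, "targetSeq must be a 23-nt DNA string")
    expect <- if (object@includePAM) 125L else 122L
    if (nchar(object@seq) != expect)
      msg <- c(msg, sprintf("template length must be %d nt, got %d",
                            expect, nchar(object@seq)))
    if (length(msg)) msg else TRUE
  }
)

#' One sticky-ended duplex fragment of a split template
#'
#' A double-stranded fragment annealed from one top and one bottom oligo.
#' Each end is either blunt or carries a single-stranded overhang described
#' by the protruding strand's sequence (read 5'->3') and the protrusion
#' side (\code{"5p"} or \code{"3p"}).
#'
#' @slot index Fragment index 1..3 (1 is leftmost and target-specific).
#' @slot topOligo,bottomOligo Oligo sequences, each read 5'->3'.
#' @slot leftOverhang,rightOverhang Lists with elements \code{seq} and
#'   \code{side} (\code{"blunt"} ends have \code{seq = ""}).
#' @slot fwdSeq Forward-strand sequence of the fragment's full extent
#'   (double-stranded core plus overhangs), used for reassembly.
#' @export
setClass("DuplexFragment",
  representation(index = "integer", topOligo = "character",
                 bottomOligo = "character", leftOverhang = "list",
                 rightOverhang = "list", fwdSeq = "character"),
  validity = function(object) {
    msg <- character(0)
    for (end in list(object@leftOverhang, object@rightOverhang)) {
      if (!all(c("seq", "side") %in% names(end)))
        msg <- c(msg, "overhangs must be list(seq=, side=)")
      else if (!end$side %in% c("5p", "3p", "blunt"))
        msg <- c(msg, "overhang side must be '5p', '3p' or 'blunt'")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Six-oligo set implementing one guide template
#'
#' The complete synthesis order sheet for one guide: six oligos (top and
#' bottom strands of three duplex fragments). Exactly two oligos - both in
#' fragment 1 - depend on the target sequence; fragments 2 and 3 are
#' constant across guides and never need resynthesis.
#'
#' @slot gene Gene identifier.
#' @slot oligoTable \code{data.frame} with columns \code{name},
#'   \code{sequence}, \code{length}, \code{fragment}, \code{strand},
#'   \code{variable_per_target}.
#' @slot fragments List of three [DuplexFragment-class] objects.
#' @slot overhangLen Junction overhang length used by the split.
#' @slot templateSeq The template the set reassembles to.
#' @seealso [splitTemplate()], [simulateLigation()], [diffOligos()]
#' @export
setClass("OligoSet",
  representation(gene = "character", oligoTable = "data.frame",
                 fragments = "list", overhangLen = "integer",
                 templateSeq = "character"),
  validity = function(object) {
    msg <- character(0)
    ot <- object@oligoTable
    if (nrow(ot) != 6L) msg <- c(msg, "exactly 6 oligos required")
    if (length(object@fragments) != 3L)
      msg <- c(msg, "exactly 3 fragments required")
    if (nrow(ot) == 6L) {
      v <- ot$variable_per_target
      if (sum(v) != 2L || !all(ot$fragment[v] == 1L))
        msg <- c(msg,
          "exactly 2 oligos must be target-variable, both in fragment 1")
    }
    if (length(msg)) msg else TRUE
  }
)

#' A called mutation event for one allele
#'
#' One resolved allele yields one event: its deletion and insertion
#' components, the signed net length change, a class (\code{deletion},
#' \code{insertion}, \code{complex} when both components are present, or
#' \code{none}), a frameshift flag (net change not divisible by 3), and a
#' canonical label in founder-screen notation, e.g. \code{"-8"} or
#' \code{"+2 (-5, +7)"}.
#'
#' @slot gene Gene identifier.
#' @slot deletions \code{data.frame(position, length, seq)}; positions are
#'   0-based on the wild-type sequence.
#' @slot insertions \code{data.frame(position, seq)}; position is the
#'   0-based wild-type coordinate the insertion precedes.
#' @slot substitutions \code{data.frame(position, wt, alt)} side channel
#'   for gap-free mismatches; excluded from the mutation class.
#' @slot netChange Total inserted minus total deleted nucleotides.
#' @slot mutationClass One of \code{deletion}, \code{insertion},
#'   \code{complex}, \code{none}.
#' @slot frameshift Logical.
#' @slot label Canonical label string.
#' @seealso [callEvent()], [classifyNet()], [parseLabel()]
#' @export
setClass("MutationEvent",
  representation(gene = "character", deletions = "data.frame",
                 insertions = "data.frame", substitutions = "data.frame",
                 netChange = "integer", mutationClass = "character",
                 frameshift = "logical", label = "character"),
  validity = function(object) {
    msg <- character(0)
    del <- sum(object@deletions$length)
    ins <- sum(nchar(object@insertions$seq))
    if (object@netChange != ins - del)
      msg <- c(msg, "netChange must equal inserted minus deleted")
    cls <- object@mutationClass
    if (!cls %in% c("deletion", "insertion", "complex", "none"))
      msg <- c(msg, "unknown mutationClass")
    hasDel <- nrow(object@deletions) > 0
    hasIns <- nrow(object@insertions) > 0
    if ((hasDel && hasIns) != (cls == "complex"))
      msg <- c(msg, "class must be 'complex' iff both components present")
    expFS <- object@netChange %% 3L != 0L && cls != "none"
    if (!identical(object@frameshift, expFS))
      msg <- c(msg, "frameshift flag inconsistent with net change")
    if (length(msg)) msg else TRUE
  }
)

#' Fish-by-gene genotype matrix of a founder cohort
#'
#' Rectangular table of called mutation labels: one row per fish, one
#' column per gene; \code{NA} marks "no mutation detected" (the cross in a
#' screening table).
#'
#' @slot fishIds Character vector of fish identifiers.
#' @slot genes Character vector of gene names.
#' @slot labels Character matrix (fish x gene) of canonical event labels,
#'   \code{NA} for no mutation.
#' @seealso [CohortTable()], [perGeneEfficiency()], [summarizeCohort()]
#' @export
setClass("CohortTable",
  representation(fishIds = "character", genes = "character",
                 labels = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (!identical(dim(object@labels),
                   c(length(object@fishIds), length(object@genes))))
      msg <- c(msg, "labels matrix must be fish x gene")
    if (anyDuplicated(object@fishIds))
      msg <- c(msg, "fish ids must be unique")
    if (anyDuplicated(object@genes))
      msg <- c(msg, "gene names must be unique")
    lab <- object@labels[!is.na(object@labels)]
    bad <- lab[!vapply(lab, labelIsValid, logical(1))]
    if (length(bad))
      msg <- c(msg, paste("unparseable labels:",
                          paste(unique(bad), collapse = ", ")))
    if (length(msg)) msg else TRUE
  }
)
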