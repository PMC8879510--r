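## Generics, accessors and show methods.

#' @rdname GuideTargetSet-class
#' @param x,object A \code{GuideTargetSet}.
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "GuideTargetSet",
          function(x, ...) x@hits)

#' @rdname GuideTargetSet-class
#' @export
setMethod("length", "GuideTargetSet", function(x) nrow(x@hits))

#' Target sequences of a GuideTargetSet
#' @param x A \code{GuideTargetSet}.
#' @return Character vector of 23-nt target sequences.
#' @export
targetSeqs <- function(x) {
  stopifnot(is(x, "GuideTargetSet"))
  x@hits$seq
}

setMethod("show", "GuideTargetSet", function(object) {
  cat(sprintf("GuideTargetSet for '%s': %d hit(s)\n",
              object@gene, nrow(object@hits)))
  if (nrow(object@hits)) print(utils::head(object@hits, 10))
  if (nrow(object@hits) > 10) cat("...\n")
})

#' Template sequence accessor
#' @param x A \code{GuideTemplate} or \code{OligoSet}.
#' @return The full template DNA sequence.
#' @export
templateSeq <- function(x) {
  if (is(x, "GuideTemplate")) return(x@seq)
  if (is(x, "OligoSet")) return(x@templateSeq)
  stop("templateSeq() expects a GuideTemplate or OligoSet")
}

setMethod("show", "GuideTemplate", function(object) {
  cat(sprintf("GuideTemplate for '%s' (%d nt, PAM %s)\n", object@gene,
              nchar(object@seq),
              if (object@includePAM) "kept" else "dropped"))
  cat("  target:   ", object@targetSeq, "\n", sep = "")
  cat("  template: ", substr(object@seq, 1, 60), "...\n", sep = "")
})

#' Oligo order sheet of an OligoSet
#' @param x An \code{OligoSet}.
#' @return \code{data.frame} with one row per oligo.
#' @export
oligos <- function(x) {
  stopifnot(is(x, "OligoSet"))
  x@oligoTable
}

#' Duplex fragments of an OligoSet
#' @param x An \code{OligoSet}.
#' @return List of three \code{DuplexFragment} objects.
#' @export
fragments <- function(x) {
  stopifnot(is(x, "OligoSet"))
  x@fragments
}

setMethod("show", "OligoSet", function(object) {
  cat(sprintf("OligoSet for '%s': 6 oligos, 3 fragments, %d-nt overhangs\n",
              object@gene, object@overhangLen))
  print(object@oligoTable)
})

setMethod("show", "DuplexFragment", function(object) {
  fmtEnd <- function(e)
    if (e$side == "blunt") "blunt" else sprintf("%s %s", e$side, e$seq)
  cat(sprintf("DuplexFragment %d [%s | %s]\n", object@index,
              fmtEnd(object@leftOverhang), fmtEnd(object@rightOverhang)))
  cat("  top:    ", object@topOligo, "\n", sep = "")
  cat("  bottom: ", object@bottomOligo, "\n", sep = "")
})

#' Accessors for MutationEvent
#'
#' @param x A \code{MutationEvent}.
#' @return \code{netChange()} the signed net length change;
#'   \code{mutationClass()} the event class; \code{isFrameshift()} logical;
#'   \code{eventLabel()} the canonical label; \code{deletions()} /
#'   \code{insertions()} / \code{substitutions()} component tables.
#' @name MutationEvent-accessors
NULL

#' @rdname MutationEvent-accessors
#' @export
netChange <- function(x) { stopifnot(is(x, "MutationEvent")); x@netChange }

#' @rdname MutationEvent-accessors
#' @export
mutationClass <- function(x) {
  stopifnot(is(x, "MutationEvent")); x@mutationClass
}

#' @rdname MutationEvent-accessors
#' @export
isFrameshift <- function(x) { stopifnot(is(x, "MutationEvent")); x@frameshift }

#' @rdname MutationEvent-accessors
#' @export
eventLabel <- function(x) { stopifnot(is(x, "MutationEvent")); x@label }

#' @rdname MutationEvent-accessors
#' @export
deletions <- function(x) { stopifnot(is(x, "MutationEvent")); x@deletions }

#' @rdname MutationEvent-accessors
#' @export
insertions <- function(x) { stopifnot(is(x, "MutationEvent")); x@insertions }

#' @rdname MutationEvent-accessors
#' @export
substitutions <- function(x) {
  stopifnot(is(x, "MutationEvent")); x@substitutions
}

setMethod("show", "MutationEvent", function(object) {
  cat(sprintf("MutationEvent %s: %s (%s, %s)\n", object@gene, object@label,
              object@mutationClass,
              if (object@frameshift) "frameshift" else "in-frame"))
})

#' Accessors for CohortTable
#' @param x A \code{CohortTable}.
#' @return \code{fishIds()} and \code{genes()} the dimension names;
#'   \code{cohortLabels()} the fish x gene label matrix.
#' @name CohortTable-accessors
NULL

#' @rdname CohortTable-accessors
#' @export
fishIds <- function(x) { stopifnot(is(x, "CohortTable")); x@fishIds }

#' @rdname CohortTable-accessors
#' @export
genes <- function(x) { stopifnot(is(x, "CohortTable")); x@genes }

#' @rdname CohortTable-accessors
#' @export
cohortLabels <- function(x) {
  stopifnot(is(x, "CohortTable"))
  m <- x@labels
  dimnames(m) <- list(x@fishIds, x@genes)
  m
}

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable: %d fish x %d genes, %d called events\n",
              length(object@fishIds), length(object@genes),
              sum(!is.na(object@labels))))
  print(cohortLabels(object))
})
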