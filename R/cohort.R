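## Founder-cohort genotype matrix and its summary statistics.

#' Construct a CohortTable
#'
#' Builds the fish-by-gene genotype matrix from a long table of called
#' events. Fish and genes absent from \code{events} are retained as
#' all-no-mutation rows/columns when listed explicitly, which matters for
#' the efficiency denominators.
#'
#' @param events \code{data.frame} with columns \code{fish_id},
#'   \code{gene}, \code{label}; rows with an empty or \code{NA} label mean
#'   "no mutation". Typically the output of [callEvents()] or a screening
#'   table read with [readCohort()].
#' @param fishIds,genes Optional explicit row/column universes (default:
#'   those observed in \code{events}, in first-appearance order).
#' @return A [CohortTable-class].
#' @export
CohortTable <- function(events, fishIds = NULL, genes = NULL) {
  need <- c("fish_id", "gene", "label")
  stopifnot(all(need %in% names(events)))
  if (is.null(fishIds)) fishIds <- unique(events$fish_id)
  if (is.null(genes)) genes <- unique(events$gene)
  lab <- matrix(NA_character_, nrow = length(fishIds),
                ncol = length(genes))
  keep <- !is.na(events$label) & events$label != ""
  ev <- events[keep, , drop = FALSE]
  bad <- setdiff(ev$fish_id, fishIds)
  if (length(bad)) stop("fish not in fishIds: ", paste(bad, collapse = ", "))
  bad <- setdiff(ev$gene, genes)
  if (length(bad)) stop("gene not in genes: ", paste(bad, collapse = ", "))
  for (i in seq_len(nrow(ev))) {
    r <- match(ev$fish_id[i], fishIds); c <- match(ev$gene[i], genes)
    if (!is.na(lab[r, c]))
      stop("duplicate event for fish '", ev$fish_id[i], "', gene '",
           ev$gene[i], "'")
    lab[r, c] <- ev$label[i]
  }
  new("CohortTable", fishIds = as.character(fishIds),
      genes = as.character(genes), labels = lab)
}

#' Read a cohort genotype table from TSV
#'
#' Long-format TSV with header \code{fish_id}, \code{gene}, \code{label};
#' an empty label field marks "no mutation" (so every fish-gene cell can
#' be listed explicitly, fixing the denominators).
#'
#' @param path Path to the TSV file.
#' @return A [CohortTable-class].
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character",
                         stringsAsFactors = FALSE)
  CohortTable(d)
}

#' Per-gene mutation efficiency
#'
#' Percentage of fish in the cohort carrying at least one called mutation
#' in \code{gene}, rounded to 2 decimals.
#'
#' @param cohort A [CohortTable-class].
#' @param gene Gene name.
#' @return Percentage in \code{[0, 100]}.
#' @export
perGeneEfficiency <- function(cohort, gene) {
  stopifnot(is(cohort, "CohortTable"))
  j <- match(gene, cohort@genes)
  if (is.na(j)) stop("unknown gene: ", gene)
  round(100 * mean(!is.na(cohort@labels[, j])), 2)
}

#' Summarise a founder cohort
#'
#' Computes the screening statistics of a genotype matrix. Two
#' denominators are deliberately distinguished and labelled explicitly:
#' the event-class distribution counts every called cell (an identical
#' allele found in two fish counts twice), whereas the frameshift fraction
#' counts each distinct (gene, label) mutation type once.
#'
#' @param cohort A [CohortTable-class].
#' @return List of class \code{"CohortSummary"} with elements
#'   \code{n_fish}, \code{n_genes}, \code{per_gene_efficiency} (named, 2
#'   decimals), \code{mean_efficiency} (2 decimals),
#'   \code{mean_efficiency_int} (integer-rounded), \code{positive_rate}
#'   (percent of fish with >= 1 mutation), \code{n_events},
#'   \code{event_class_distribution} (percents over events, named
#'   deletion/insertion/complex), \code{n_types},
#'   \code{frameshift_fraction} and \code{inframe_fraction} (percents over
#'   distinct types).
#' @export
summarizeCohort <- function(cohort) {
  stopifnot(is(cohort, "CohortTable"))
  lab <- cohort@labels
  if (length(lab) == 0L) stop("empty cohort")
  eff <- vapply(cohort@genes, function(g) perGeneEfficiency(cohort, g),
                numeric(1))
  called <- which(!is.na(lab), arr.ind = TRUE)
  events <- data.frame(
    fish = cohort@fishIds[called[, 1]],
    gene = cohort@genes[called[, 2]],
    label = lab[called], stringsAsFactors = FALSE)
  parsed <- lapply(events$label, parseLabel)
  events$class <- vapply(parsed, `[[`, character(1), "mutation_class")
  events$frameshift <- vapply(parsed, `[[`, logical(1), "frameshift")
  classes <- c("deletion", "insertion", "complex")
  dist <- if (nrow(events))
    round(100 * as.numeric(table(factor(events$class, classes))) /
            nrow(events), 2) else rep(0, 3)
  names(dist) <- classes
  types <- unique(events[, c("gene", "label", "frameshift")])
  res <- list(
    n_fish = length(cohort@fishIds),
    n_genes = length(cohort@genes),
    per_gene_efficiency = eff,
    mean_efficiency = round(mean(eff), 2),
    mean_efficiency_int = round(mean(eff)),
    positive_rate = round(100 * mean(rowSums(!is.na(lab)) > 0), 2),
    n_events = nrow(events),
    event_class_distribution = dist,
    n_types = nrow(types),
    frameshift_fraction = if (nrow(types))
      round(100 * mean(types$frameshift), 2) else 0,
    inframe_fraction = if (nrow(types))
      round(100 * mean(!types$frameshift), 2) else 0
  )
  class(res) <- "CohortSummary"
  res
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("Cohort of %d fish x %d genes\n", x$n_fish, x$n_genes))
  cat("Per-gene mutation efficiency (%):\n")
  print(x$per_gene_efficiency)
  cat(sprintf("Mean efficiency: %.2f%% (~%d%%); positive rate: %.2f%%\n",
              x$mean_efficiency, x$mean_efficiency_int, x$positive_rate))
  cat(sprintf("Event classes over %d events (%%): ", x$n_events))
  cat(paste(sprintf("%s %.4g", names(x$event_class_distribution),
                    x$event_class_distribution), collapse = ", "), "\n")
  cat(sprintf("Frameshift over %d distinct types: %.4g%% (in-frame %.4g%%)\n",
              x$n_types, x$frameshift_fraction, x$inframe_fraction))
  invisible(x)
}
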