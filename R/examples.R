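## Loaders for the bundled five-gene screening example
## (gabbr1a, gabbr2, necap1, tmem183a, zgc103499).

exampleFile <- function(name) {
  f <- system.file("extdata", name, package = "multiguide",
                   mustWork = TRUE)
  f
}

#' Bundled five-gene screening example
#'
#' Small plain-text fixtures from a published five-gene multiplexed
#' knockout screen in zebrafish: the selected gRNA targets, the wild-type
#' amplicon regions around each target, the Sanger-resolved mutant allele
#' sequences, and the six-founder genotype table.
#'
#' @return \code{exampleTargets()}: \code{data.frame(gene, target_seq)}.
#'   \code{exampleWtRegions()}: named character vector of wild-type
#'   region sequences. \code{exampleAlleles()}: \code{data.frame(gene,
#'   allele_id, allele_seq, published_label)}. \code{exampleCohort()}: a
#'   [CohortTable-class] of 6 founder fish by 5 genes.
#' @name example-data
#' @examples
#' exampleTargets()
NULL

#' @rdname example-data
#' @export
exampleTargets <- function() {
  utils::read.delim(exampleFile("penta_targets.tsv"),
                    stringsAsFactors = FALSE)
}

#' @rdname example-data
#' @export
exampleWtRegions <- function() {
  readFasta(exampleFile("penta_wt_regions.fa"))
}

#' @rdname example-data
#' @export
exampleAlleles <- function() {
  utils::read.delim(exampleFile("penta_alleles.tsv"),
                    stringsAsFactors = FALSE)
}

#' @rdname example-data
#' @export
exampleCohort <- function() {
  readCohort(exampleFile("penta_cohort.tsv"))
}
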