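## FASTA and TSV input/output.

#' Read a DNA FASTA file
#'
#' Reads a (possibly multi-record) FASTA file, normalises sequences to
#' uppercase DNA and converts RNA \code{U} to \code{T} with a warning.
#' Records are returned in file order.
#'
#' @param path Path to the FASTA file.
#' @return Named character vector of sequences (names are record ids).
#'   Empty files yield an empty vector.
#' @details Malformed input (sequence data before the first header, an
#'   empty header, an empty sequence, duplicated ids, or characters outside
#'   \code{A/C/G/T/N/U}) raises an error naming the offending line.
#' @seealso [writeFasta()]
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  isHdr <- startsWith(lines, ">")
  if (!isHdr[1])
    stop("FASTA format error at line ", lineNo[1],
         ": sequence data before first header")
  ids <- sub("^>\\s*", "", lines[isHdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(ids == "")) {
    bad <- lineNo[isHdr][ids == ""][1]
    stop("FASTA format error at line ", bad, ": empty header")
  }
  if (anyDuplicated(ids))
    stop("duplicated record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  grp <- cumsum(isHdr)
  seqs <- vapply(seq_along(ids), function(i) {
    paste(lines[grp == i & !isHdr], collapse = "")
  }, character(1))
  empty <- which(seqs == "")
  if (length(empty))
    stop("FASTA format error at line ", lineNo[isHdr][empty[1]],
         ": record '", ids[empty[1]], "' has an empty sequence")
  seqs <- toupper(gsub("\\s", "", seqs))
  if (any(grepl("U", seqs, fixed = TRUE))) {
    warning("RNA 'U' bases converted to 'T'")
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  }
  badSeq <- which(!grepl("^[ACGTN]+$", seqs))
  if (length(badSeq))
    stop("record '", ids[badSeq[1]],
         "' contains characters outside A/C/G/T/N")
  stats::setNames(seqs, ids)
}

#' Write DNA sequences to a FASTA file
#'
#' Writes a named character vector of sequences as multi-record FASTA,
#' wrapped at 60 columns, via [Biostrings::writeXStringSet()].
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a behavioral trial table
#'
#' Reads a tab-delimited trial table with columns \code{fish_id},
#' \code{group}, \code{trial_index} and \code{latency_ms}. An empty
#' latency field encodes "no response" (0 ms is a legal latency and is
#' never used as a sentinel).
#'
#' @param path Path to a TSV file with a header row.
#' @return \code{data.frame} with \code{latency_ms} numeric and \code{NA}
#'   for no-response trials.
#' @details Validates that \code{trial_index} is unique within each fish
#'   and that latencies are non-negative.
#' @seealso [writeTrialTable()], [scoreTrials()]
#' @export
readTrialTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("fish_id", "group", "trial_index", "latency_ms")
  if (!all(need %in% names(d)))
    stop("trial table must have columns: ", paste(need, collapse = ", "))
  d$trial_index <- as.integer(d$trial_index)
  d$latency_ms <- suppressWarnings(
    ifelse(d$latency_ms == "" | is.na(d$latency_ms), NA_real_,
           as.numeric(d$latency_ms)))
  if (any(d$latency_ms < 0, na.rm = TRUE))
    stop("negative latency values are not allowed")
  dup <- tapply(d$trial_index, d$fish_id, anyDuplicated)
  if (any(unlist(dup) > 0))
    stop("duplicated trial_index within fish: ",
         paste(names(dup)[unlist(dup) > 0], collapse = ", "))
  d
}

#' Write a behavioral trial table
#'
#' @param trials \code{data.frame} as returned by [readTrialTable()] or
#'   [simulateCstartTrials()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeTrialTable <- function(trials, path) {
  need <- c("fish_id", "group", "trial_index", "latency_ms")
  stopifnot(all(need %in% names(trials)))
  out <- trials[, need]
  out$latency_ms <- vapply(out$latency_ms, function(x)
    if (is.na(x)) "" else format(x), character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
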