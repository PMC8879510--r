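## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revComp("GGATCC")
revComp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

## Evaluate `code` under `seed` without disturbing the caller's RNG stream.
## All stochastic generators in the package funnel through this.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv()),
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

## Validate that a string is uppercase DNA over the given alphabet.
isDNA <- function(x, allowN = FALSE) {
  pat <- if (allowN) "^[ACGTN]+$" else "^[ACGT]+$"
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(pat, x)
}

## Longest common prefix / suffix lengths of two strings.
commonPrefixLen <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "")[[1]][seq_len(n)]
  bv <- strsplit(b, "")[[1]][seq_len(n)]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1] - 1L
}

commonSuffixLen <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(strsplit(a, "")[[1]])[seq_len(n)]
  bv <- rev(strsplit(b, "")[[1]])[seq_len(n)]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1] - 1L
}
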