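## Synthetic-data generators. All randomness flows through an explicit
## seed; the caller's RNG state is never disturbed.

randomDNA <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic exon with planted gRNA targets
#'
#' Produces a random exon-like sequence containing exactly
#' \code{nTargets} planted \code{GG + N18 + NGG} motifs at known
#' coordinates and strands. In collision-free mode (the default) the whole
#' sequence is resampled until a scan with [findTargets()] finds no hit
#' other than the planted ones, so the planted coordinates are the full
#' ground truth.
#'
#' @param length Total sequence length (must fit \code{23 * nTargets}).
#' @param nTargets Number of targets to plant.
#' @param seed Integer seed (required: fixtures must be reproducible).
#' @param collisionFree Reject sequences with unplanted motifs.
#' @param maxTries Resampling budget before giving up.
#' @return List with \code{seq} and \code{targets} (a
#'   \code{data.frame} with \code{seq}, \code{strand}, \code{start},
#'   \code{end}, 0-based half-open).
#' @export
synthExon <- function(length, nTargets, seed, collisionFree = TRUE,
                      maxTries = 1000L) {
  stopifnot(nTargets >= 1L)
  if (length < 23L * nTargets)
    stop("infeasible packing: length ", length, " cannot hold ",
         nTargets, " non-overlapping 23-nt targets")
  withSeed(seed, {
    for (try in seq_len(maxTries)) {
      ## choose non-overlapping 23-nt slots
      gapTotal <- length - 23L * nTargets
      cuts <- sort(sample.int(gapTotal + 1L, nTargets, replace = TRUE) - 1L)
      starts <- cuts + 23L * (seq_len(nTargets) - 1L)
      strands <- sample(c("+", "-"), nTargets, replace = TRUE)
      motifs <- vapply(seq_len(nTargets), function(i) {
        paste0("GG", randomDNA(18L), randomDNA(1L), "GG")
      }, character(1))
      chars <- strsplit(randomDNA(length), "")[[1]]
      for (i in seq_len(nTargets)) {
        m <- if (strands[i] == "+") motifs[i] else revComp(motifs[i])
        chars[(starts[i] + 1L):(starts[i] + 23L)] <- strsplit(m, "")[[1]]
      }
      seq <- paste(chars, collapse = "")
      planted <- data.frame(seq = motifs, strand = strands,
                            start = starts, end = starts + 23L,
                            stringsAsFactors = FALSE)
      planted <- planted[order(planted$start,
                               match(planted$strand, c("+", "-"))), ,
                         drop = FALSE]
      rownames(planted) <- NULL
      if (!collisionFree)
        return(list(seq = seq, targets = planted))
      found <- as.data.frame(findTargets(seq, gene = "synth"))
      same <- nrow(found) == nrow(planted) &&
        identical(found$seq, planted$seq) &&
        identical(found$start, planted$start) &&
        identical(found$strand, planted$strand)
      if (same) return(list(seq = seq, targets = planted))
    }
    stop("could not generate a collision-free exon in ", maxTries,
         " attempts; increase length or maxTries")
  })
}

#' Generate mutant alleles with known ground-truth events
#'
#' For each \code{(n_del, n_ins)} specification, deletes \code{n_del}
#' bases starting at a random position inside the target window and
#' inserts \code{n_ins} random bases at the deletion point, emulating
#' repair outcomes at a nuclease cut site. Inserted bases are resampled so
#' that the first/last inserted base differs from the first/last deleted
#' base; without this the planted event is genuinely ambiguous at the
#' sequence level (e.g. deleting \code{A} and inserting \code{AG} is
#' indistinguishable from a pure \code{+1} insertion) and no caller could
#' recover the planted class.
#'
#' @param wtSeq Wild-type sequence.
#' @param targetStart,targetEnd Target window, 0-based half-open.
#' @param specs List of \code{c(n_del, n_ins)} pairs (or an n-by-2
#'   matrix), one allele per spec.
#' @param seed Integer seed.
#' @param strict Error when a deletion cannot fit in the target window
#'   (default); otherwise the deletion is truncated.
#' @return List with one element per spec: \code{allele} (sequence) and
#'   \code{event} (the ground-truth [MutationEvent-class], constructed
#'   directly from the planted edit, independently of [callEvent()]).
#'   A spec deleting and inserting the same number of bases is planted as
#'   a block substitution (class \code{none}), which is what such an edit
#'   is at the sequence level.
#' @export
synthAlleles <- function(wtSeq, targetStart, targetEnd, specs, seed,
                         strict = TRUE) {
  stopifnot(isDNA(wtSeq), targetStart >= 0, targetEnd <= nchar(wtSeq),
            targetEnd > targetStart)
  if (is.matrix(specs)) specs <- asplit(specs, 1)
  win <- targetEnd - targetStart
  withSeed(seed, {
    lapply(specs, function(sp) {
      nDel <- as.integer(sp[1]); nIns <- as.integer(sp[2])
      stopifnot(nDel >= 0L, nIns >= 0L)
      if (nDel > win) {
        if (strict)
          stop("deletion of ", nDel, " nt exceeds the ", win,
               "-nt target window")
        nDel <- win
      }
      pos <- targetStart + sample.int(win - nDel + 1L, 1L) - 1L
      delSeq <- substr(wtSeq, pos + 1L, pos + nDel)
      insSeq <- ""
      if (nIns > 0L) {
        repeat {
          insSeq <- randomDNA(nIns)
          if (nDel == 0L) break
          okFirst <- substr(insSeq, 1L, 1L) != substr(delSeq, 1L, 1L)
          okLast <- substr(insSeq, nIns, nIns) != substr(delSeq, nDel, nDel)
          if (okFirst && okLast) break
        }
      }
      allele <- paste0(substr(wtSeq, 1L, pos), insSeq,
                       substr(wtSeq, pos + nDel + 1L, nchar(wtSeq)))
      list(allele = allele,
           event = plantedEvent(pos, delSeq, insSeq))
    })
  })
}

## Ground-truth event for a planted edit, built directly from the edit
## description (never via callEvent, so recovery tests have an
## independent reference).
plantedEvent <- function(pos, delSeq, insSeq) {
  noDel <- data.frame(position = integer(0), length = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  noIns <- data.frame(position = integer(0), seq = character(0),
                      stringsAsFactors = FALSE)
  noSub <- data.frame(position = integer(0), wt = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
  nDel <- nchar(delSeq); nIns <- nchar(insSeq)
  if (nDel > 0L && nDel == nIns) {
    ## equal-length replacement: a block substitution, not an indel
    w <- strsplit(delSeq, "")[[1]]; a <- strsplit(insSeq, "")[[1]]
    mm <- which(w != a)
    subs <- data.frame(position = pos + mm - 1L, wt = w[mm], alt = a[mm],
                       stringsAsFactors = FALSE)
    return(new("MutationEvent", gene = "synth", deletions = noDel,
               insertions = noIns, substitutions = subs,
               netChange = 0L, mutationClass = "none",
               frameshift = FALSE, label = "0"))
  }
  dels <- if (nDel > 0L)
    data.frame(position = pos, length = nDel, seq = delSeq,
               stringsAsFactors = FALSE) else noDel
  inss <- if (nIns > 0L)
    data.frame(position = pos, seq = insSeq, stringsAsFactors = FALSE)
    else noIns
  net <- nIns - nDel
  cl <- classifyNet(net, nDel > 0L, nIns > 0L)
  new("MutationEvent", gene = "synth", deletions = dels,
      insertions = inss, substitutions = noSub,
      netChange = as.integer(net), mutationClass = cl$mutation_class,
      frameshift = cl$frameshift,
      label = formatLabel(net, nDel, nIns))
}

#' Simulate a C-start trial table
#'
#' Independent Bernoulli trials per fish at a common response rate, or --
#' when \code{betaConcentration} is finite -- with per-fish rates drawn
#' from a Beta distribution with the given mean, modelling fish-to-fish
#' heterogeneity. Responding trials get a latency drawn uniformly from
#' 8-22 ms (well inside the 25-ms gate); non-responses have \code{NA}
#' latency.
#'
#' @param nFish,nTrials Number of fish and trials per fish.
#' @param rate Per-trial response probability.
#' @param group Group label stored in the table.
#' @param seed Integer seed.
#' @param betaConcentration Optional Beta concentration (a+b); per-fish
#'   rates are \code{rbeta(rate*c, (1-rate)*c)}. Default \code{Inf}
#'   (homogeneous fish).
#' @return Trial \code{data.frame} (see [readTrialTable()]).
#' @export
simulateCstartTrials <- function(nFish, nTrials = 10L, rate,
                                 group = "group", seed,
                                 betaConcentration = Inf) {
  stopifnot(nFish >= 1L, nTrials >= 1L, rate >= 0, rate <= 1)
  withSeed(seed, {
    rows <- lapply(seq_len(nFish), function(f) {
      p <- if (is.finite(betaConcentration))
        stats::rbeta(1, rate * betaConcentration,
                     (1 - rate) * betaConcentration) else rate
      resp <- stats::rbinom(nTrials, 1L, p) == 1L
      data.frame(
        fish_id = sprintf("%s_fish%03d", group, f), group = group,
        trial_index = seq_len(nTrials),
        latency_ms = ifelse(resp,
                            round(stats::runif(nTrials, 8, 22), 1),
                            NA_real_),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate staining-intensity samples for two groups
#'
#' Gaussian per-sample intensities: control mean \code{wtMean}, mutant
#' mean \code{ratio * wtMean}, common SD. Defaults emulate a fluorescence
#' readout reduced to ~65 percent of control with a ~10 percent
#' coefficient of variation.
#'
#' @param nMut,nWt Group sizes.
#' @param ratio True mutant/control mean ratio.
#' @param wtMean Control mean (arbitrary units).
#' @param sd Common within-group SD.
#' @param seed Integer seed.
#' @return List with numeric vectors \code{mut} and \code{wt}.
#' @export
simulateIntensity <- function(nMut = 35L, nWt = 32L, ratio = 0.6466,
                              wtMean = 100, sd = 10, seed) {
  stopifnot(nMut >= 1L, nWt >= 1L, ratio >= 0, wtMean > 0, sd >= 0)
  withSeed(seed, list(
    mut = stats::rnorm(nMut, ratio * wtMean, sd),
    wt = stats::rnorm(nWt, wtMean, sd)))
}

#' Simulate hair-cell count samples for two groups
#'
#' Rounded Gaussian counts truncated at zero. The default SD of 2 count
#' units reflects typical neuromast-to-neuromast spread around means of
#' 7-10 clusters.
#'
#' @param nMut,nWt Group sizes.
#' @param meanMut,meanWt True group means.
#' @param sd Common within-group SD (before rounding).
#' @param seed Integer seed.
#' @return List with integer vectors \code{mut} and \code{wt}.
#' @export
simulateCounts <- function(nMut = 38L, nWt = 33L, meanMut = 7.34,
                           meanWt = 10.4, sd = 2, seed) {
  stopifnot(nMut >= 1L, nWt >= 1L, sd >= 0)
  withSeed(seed, list(
    mut = pmax(0L, as.integer(round(stats::rnorm(nMut, meanMut, sd)))),
    wt = pmax(0L, as.integer(round(stats::rnorm(nWt, meanWt, sd))))))
}
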