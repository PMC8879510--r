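## C-start behavioral scoring and downstream phenotype statistics.

#' Score C-start trials with a latency gate
#'
#' A trial counts as a response iff a latency was recorded and it does not
#' exceed the cutoff (inclusive: a C-bend beginning within 25 ms of the
#' stimulus is a response under the default gate). Per-fish rates are
#' responses over trials delivered; the group mean rate is the unweighted
#' mean of per-fish rates (the fish, not the trial, is the independent
#' unit).
#'
#' @param trials \code{data.frame} with columns \code{fish_id},
#'   \code{group}, \code{trial_index}, \code{latency_ms} (\code{NA} = no
#'   response).
#' @param latencyCutoffMs Response-latency gate in ms (default 25).
#' @return List of class \code{"ResponseSummary"}: \code{per_fish}
#'   (\code{data.frame} fish_id, group, n_trials, n_responses, rate) and
#'   \code{group} (\code{data.frame} group, n_fish, mean_rate_pct).
#' @export
scoreTrials <- function(trials, latencyCutoffMs = 25) {
  need <- c("fish_id", "group", "trial_index", "latency_ms")
  stopifnot(all(need %in% names(trials)), latencyCutoffMs > 0)
  if (nrow(trials) == 0L) stop("no trials to score")
  resp <- !is.na(trials$latency_ms) & trials$latency_ms <= latencyCutoffMs
  ids <- unique(trials$fish_id)
  perFish <- do.call(rbind, lapply(ids, function(f) {
    sel <- trials$fish_id == f
    data.frame(fish_id = f, group = trials$group[sel][1],
               n_trials = sum(sel), n_responses = sum(resp[sel]),
               rate = sum(resp[sel]) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  zero <- perFish$n_trials == 0L
  if (any(zero)) {
    warning("excluding fish with zero trials: ",
            paste(perFish$fish_id[zero], collapse = ", "))
    perFish <- perFish[!zero, , drop = FALSE]
  }
  grp <- do.call(rbind, lapply(unique(perFish$group), function(g) {
    sel <- perFish$group == g
    data.frame(group = g, n_fish = sum(sel),
               mean_rate_pct = 100 * mean(perFish$rate[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(perFish) <- rownames(grp) <- NULL
  out <- list(per_fish = perFish, group = grp)
  class(out) <- "ResponseSummary"
  out
}

#' @export
print.ResponseSummary <- function(x, ...) {
  cat("C-start response summary\n")
  print(x$group)
  invisible(x)
}

#' Compare per-fish response rates between two groups
#'
#' Default is Welch's unequal-variance t-test on per-fish rates; a
#' classical Student t-test and a label-permutation test (two-sided, with
#' +1 smoothing so p >= 1/(nPerm+1)) are available.
#'
#' @param ratesA,ratesB Numeric vectors of per-fish rates (or any paired
#'   continuous measurements), at least 2 per group.
#' @param method \code{"welch_t"} (default), \code{"student_t"} or
#'   \code{"permutation"}.
#' @param nPerm Number of permutations for \code{method = "permutation"}.
#' @param seed Optional seed for the permutation draw.
#' @return List of class \code{"GroupComparison"}: \code{statistic},
#'   \code{p_value}, \code{test_name}, \code{n} (per-group sizes),
#'   \code{effect} (difference of means, A minus B).
#' @details Degenerate input with zero variance in both groups yields
#'   \code{p = 1} when the means are equal and \code{p} at the smoothing
#'   floor (permutation) or 0 (t-tests) otherwise.
#' @export
compareGroups <- function(ratesA, ratesB,
                          method = c("welch_t", "student_t", "permutation"),
                          nPerm = 10000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(ratesA), is.numeric(ratesB),
            length(ratesA) >= 2L, length(ratesB) >= 2L)
  effect <- mean(ratesA) - mean(ratesB)
  n <- c(length(ratesA), length(ratesB))
  degenerate <- stats::sd(ratesA) == 0 && stats::sd(ratesB) == 0
  if (method %in% c("welch_t", "student_t")) {
    if (degenerate) {
      stat <- if (effect == 0) 0 else Inf
      p <- if (effect == 0) 1 else 0
    } else {
      ht <- stats::t.test(ratesA, ratesB,
                          var.equal = method == "student_t")
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  } else {
    pooled <- c(ratesA, ratesB)
    obs <- abs(effect)
    exceed <- withSeed(seed, {
      sum(vapply(seq_len(nPerm), function(i) {
        idx <- sample.int(length(pooled), n[1])
        abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12
      }, logical(1)))
    })
    stat <- obs
    p <- (exceed + 1) / (nPerm + 1)
  }
  out <- list(statistic = stat, p_value = p,
              test_name = method, n = n, effect = effect)
  class(out) <- "GroupComparison"
  out
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, effect = %.4g (n = %d/%d)\n",
              x$test_name, x$statistic, x$p_value, x$effect,
              x$n[1], x$n[2]))
  invisible(x)
}

#' Pooled-trial comparison of response counts
#'
#' Sensitivity analysis companion to [compareGroups()]: ignores the fish
#' structure and compares pooled response proportions with a chi-square
#' test ([stats::prop.test()]). Valid only under the stronger assumption
#' that trials are exchangeable across fish.
#'
#' @param responsesA,trialsA,responsesB,trialsB Pooled response and trial
#'   counts per group.
#' @return The \code{htest} object from [stats::prop.test()].
#' @export
comparePooledTrials <- function(responsesA, trialsA, responsesB, trialsB) {
  stats::prop.test(c(responsesA, responsesB), c(trialsA, trialsB))
}

#' Mutant staining intensity relative to control
#'
#' Percent-of-control summary used for dye-uptake readouts: 100 x
#' mean(mutant) / mean(control), with a Welch t-test on the raw values.
#'
#' @param valuesMut,valuesWt Numeric vectors of per-sample intensities.
#' @return List with \code{relative_pct}, \code{mean_mut},
#'   \code{mean_wt} and \code{comparison} (a \code{GroupComparison}, or
#'   \code{NULL} when either group has fewer than 2 values).
#' @details The ratio is invariant under rescaling both groups by the same
#'   positive constant. A zero control mean is an error.
#' @export
relativeIntensity <- function(valuesMut, valuesWt) {
  stopifnot(is.numeric(valuesMut), is.numeric(valuesWt),
            length(valuesMut) >= 1L, length(valuesWt) >= 1L)
  if (mean(valuesWt) == 0) stop("control mean is zero")
  cmp <- if (length(valuesMut) >= 2L && length(valuesWt) >= 2L)
    compareGroups(valuesMut, valuesWt, method = "welch_t") else NULL
  list(relative_pct = 100 * mean(valuesMut) / mean(valuesWt),
       mean_mut = mean(valuesMut), mean_wt = mean(valuesWt),
       comparison = cmp)
}

#' Summarise hair-cell (or other) count data
#'
#' Group means at 2 decimals with a Welch t-test; single-element groups
#' are flagged low-n and skip the test.
#'
#' @param countsMut,countsWt Integer-valued samples.
#' @return List with \code{mean_mut}, \code{mean_wt}, \code{n},
#'   \code{low_n} and \code{comparison} (\code{NULL} when low-n).
#' @export
countSummary <- function(countsMut, countsWt) {
  stopifnot(is.numeric(countsMut), is.numeric(countsWt),
            length(countsMut) >= 1L, length(countsWt) >= 1L,
            all(countsMut == round(countsMut)),
            all(countsWt == round(countsWt)))
  lowN <- length(countsMut) < 2L || length(countsWt) < 2L
  cmp <- if (!lowN) compareGroups(countsMut, countsWt, "welch_t") else NULL
  list(mean_mut = round(mean(countsMut), 2),
       mean_wt = round(mean(countsWt), 2),
       n = c(mut = length(countsMut), wt = length(countsWt)),
       low_n = lowN, comparison = cmp)
}
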