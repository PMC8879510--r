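mkTrials <- function(latencies, fish = "f1", group = "wt") {
  data.frame(fish_id = fish, group = group,
             trial_index = seq_along(latencies),
             latency_ms = latencies, stringsAsFactors = FALSE)
}

test_that("the 25-ms latency gate is inclusive", {
  tr <- mkTrials(c(10, 24, 26, rep(NA, 7)))
  s <- scoreTrials(tr)
  expect_equal(s$per_fish$rate, 0.2)        # 26 ms is not a response
  expect_equal(s$per_fish$n_trials, 10L)

  s <- scoreTrials(mkTrials(c(25, 0, rep(18, 8))))
  expect_equal(s$per_fish$rate, 1.0)        # 25 ms and 0 ms both count
  expect_equal(s$group$mean_rate_pct, 100)
})

test_that("raising the latency cutoff never decreases any rate", {
  set.seed(19)
  tr <- simulateCstartTrials(12, 10, 0.5, seed = 3)
  # spread some latencies beyond the gate
  late <- !is.na(tr$latency_ms) & runif(nrow(tr)) < 0.3
  tr$latency_ms[late] <- tr$latency_ms[late] + 20
  prev <- rep(0, 12)
  for (cut in c(5, 15, 25, 35, 50)) {
    r <- scoreTrials(tr, latencyCutoffMs = cut)$per_fish$rate
    expect_true(all(r >= prev - 1e-12))
    prev <- r
  }
})

test_that("identical groups compare as null", {
  x <- c(0.5, 0.6, 0.7, 0.8)
  p <- compareGroups(x, x, method = "permutation", nPerm = 500, seed = 1)
  expect_equal(p$p_value, 1)
  expect_equal(p$effect, 0)
  w <- compareGroups(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(w$p_value, 1)   # degenerate zero-variance case
  expect_equal(w$effect, 0)
})

test_that("permutation p-value tracks the t-test on Gaussian data", {
  set.seed(44)
  a <- rnorm(48, 0.6, 0.15)
  b <- rnorm(48, 0.55, 0.15)
  pw <- compareGroups(a, b, "welch_t")$p_value
  pp <- compareGroups(a, b, "permutation", nPerm = 4000,
                      seed = 9)$p_value
  expect_lt(abs(pw - pp), 0.03)
  expect_gte(pp, 1 / 4001)
})

test_that("pooled-trial chi-square companion runs", {
  ht <- comparePooledTrials(329, 480, 209, 480)
  expect_lt(ht$p.value, 1e-4)
})

test_that("relativeIntensity is a scale-free percent of control", {
  x <- c(10, 12, 14); y <- c(10, 12, 14)
  expect_equal(relativeIntensity(x, y)$relative_pct, 100)
  r1 <- relativeIntensity(c(1, 2, 4), c(2, 3, 5))
  r2 <- relativeIntensity(17.3 * c(1, 2, 4), 17.3 * c(2, 3, 5))
  expect_equal(r1$relative_pct, r2$relative_pct)
  expect_equal(relativeIntensity(c(0, 0, 0), c(1, 2, 3))$relative_pct, 0)
  expect_error(relativeIntensity(c(1, 2), c(0, 0)), "control mean")
})

test_that("countSummary reports means and flags low n", {
  s <- countSummary(rep(10L, 5), rep(10L, 4))
  expect_equal(s$mean_mut, 10)
  expect_equal(s$mean_wt, 10)
  expect_equal(s$comparison$p_value, 1)
  s <- countSummary(7L, 10L)
  expect_true(s$low_n)
  expect_null(s$comparison)
  expect_error(countSummary(c(1.5, 2), c(1, 2)), "round")
})

test_that("trial generator has the advertised shape and gate behavior", {
  tr <- simulateCstartTrials(7, 10, 0.6, group = "mut", seed = 8)
  expect_identical(nrow(tr), 70L)
  expect_identical(length(unique(tr$fish_id)), 7L)
  expect_true(all(table(tr$fish_id) == 10))
  lat <- tr$latency_ms[!is.na(tr$latency_ms)]
  expect_true(all(lat <= 25))  # generated responses pass the gate
  # beta heterogeneity still yields a valid table
  trb <- simulateCstartTrials(7, 10, 0.6, seed = 8,
                              betaConcentration = 10)
  expect_identical(nrow(trb), 70L)
})
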