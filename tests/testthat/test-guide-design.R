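test_that("all five published target sequences validate", {
  tg <- exampleTargets()
  expect_identical(nrow(tg), 5L)
  verdicts <- lapply(tg$target_seq, validateTarget)
  expect_true(all(vapply(verdicts, `[[`, logical(1), "valid")))
})

test_that("validateTarget reports reason codes for failures", {
  v <- validateTarget("ATATATATATATATATATATATA")
  expect_false(v$valid)
  expect_setequal(v$reasons, c("no_gg_prefix", "no_ngg_suffix"))
  expect_true("bad_length" %in% validateTarget("GGAAGG")$reasons)
  expect_true("bad_alphabet" %in%
                validateTarget("GGNTATATATATATATATATAGG")$reasons)
})

test_that("findTargets reports plus- and minus-strand hits correctly", {
  hits <- as.data.frame(
    findTargets("GGATGTCCCTTGAGAACGGGAGGGTGTCGCTG", gene = "gabbr1a"))
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$seq == "GGATGTCCCTTGAGAACGGGAGG" &
                    plus$start == 0 & plus$end == 23))

  # the guide for this gene targets the minus strand of the printed region
  hits <- as.data.frame(
    findTargets("CCTCCTCTCCCCGAATCTACACCCACT", gene = "tmem183a"))
  minus <- hits[hits$strand == "-", ]
  expect_true("GGTGTAGATTCGGGGAGAGGAGG" %in% minus$seq)
})

test_that("short records yield an empty set, not an error", {
  expect_identical(length(findTargets("ACGTACGT")), 0L)
})

test_that("scanner matches the exhaustive window oracle", {
  set.seed(91)
  for (i in 1:30) {
    n <- sample(23:50, 1)
    alph <- if (i %% 5 == 0) c("A", "C", "G", "T", "N")
            else c("A", "C", "G", "T")
    # GC-skewed draws make GG...NGG hits common enough to exercise
    s <- paste(sample(c(alph, "G", "G"), n, TRUE), collapse = "")
    expect_identical(as.data.frame(findTargets(s, gene = "seq1")),
                     oracleScan(s), info = s)
  }
})

test_that("strand symmetry: scanning the reverse complement flips hits", {
  set.seed(17)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "G", "G"), 60, TRUE),
               collapse = "")
    fwd <- as.data.frame(findTargets(s))
    rev <- as.data.frame(findTargets(oracleRevComp(s)))
    expect_setequal(fwd$seq, rev$seq)
    # mirrored coordinates, flipped strands
    expect_identical(sort(paste(fwd$seq, fwd$strand, fwd$start)),
                     sort(paste(rev$seq, chartr("+-", "-+", rev$strand),
                                nchar(s) - rev$end)))
  }
})

test_that("rankTargets orders by distance with the documented tie-break", {
  mk <- function(starts, strands) {
    hits <- data.frame(
      gene = "g", seq = "GGATGTCCCTTGAGAACGGGAGG",
      strand = strands, start = starts, end = starts + 23L,
      distance_to_cds_start = NA_integer_, rank = NA_integer_,
      stringsAsFactors = FALSE)
    new("GuideTargetSet", gene = "g", hits = hits)
  }
  r <- as.data.frame(rankTargets(mk(c(400L, 10L), c("+", "+")), 0))
  expect_identical(r$start, c(10L, 400L))

  r <- as.data.frame(rankTargets(mk(c(30L, 30L), c("-", "+")), 0))
  expect_identical(r$strand, c("+", "-"))

  set.seed(4)
  starts <- sample(0:500, 20)
  strands <- sample(c("+", "-"), 20, TRUE)
  cds <- 120L
  r <- as.data.frame(rankTargets(mk(as.integer(starts), strands), cds))
  o <- order(abs(starts - cds), match(strands, c("+", "-")), starts)
  expect_identical(r$start, as.integer(starts[o]))
  expect_identical(r$rank, 1:20)
})

test_that("maskVariants uses half-open interval semantics", {
  ts <- findTargets("GGATGTCCCTTGAGAACGGGAGGGTGTCGCTG", gene = "g")
  hit0 <- as.data.frame(ts)$start == 0
  expect_true(any(hit0))
  # variant inside [0,23) removes the hit; at 23 (exclusive end) keeps it
  m5 <- as.data.frame(maskVariants(ts, 5))
  expect_false(any(m5$start == 0))
  m23 <- as.data.frame(maskVariants(ts, 23))
  expect_true(any(m23$start == 0))
})

test_that("maskVariants equals the interval-intersection oracle", {
  set.seed(8)
  for (i in 1:10) {
    ex <- synthExon(140, 2, seed = i, collisionFree = FALSE)
    ts <- findTargets(ex$seq)
    mask <- sample(0:139, sample(0:8, 1))
    got <- as.data.frame(maskVariants(ts, mask))
    h <- as.data.frame(ts)
    keep <- vapply(seq_len(nrow(h)), function(j)
      !any(mask >= h$start[j] & mask < h$end[j]), logical(1))
    expect_identical(got, local({ d <- h[keep, , drop = FALSE]
                                  rownames(d) <- NULL; d }))
  }
})
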