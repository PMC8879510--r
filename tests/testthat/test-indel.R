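test_that("alignAllele recovers the printed single-gap deletion", {
  aln <- alignAllele("GGATGTCCCTTGAGAACGGGAGGGTGTCGCTG",
                     "GGATGTCCCTTGAGGGTGTCGCTG")
  expect_identical(aln$wt, "GGATGTCCCTTGAGAACGGGAGGGTGTCGCTG")
  expect_identical(aln$allele, "GGATGTCCCTTGAG--------GGTGTCGCTG")
})

test_that("identical sequences align without gaps", {
  aln <- alignAllele("ACGTACGT", "ACGTACGT")
  expect_identical(aln$wt, aln$allele)
  expect_false(grepl("-", aln$wt, fixed = TRUE))
  expect_equal(aln$score, 8)
})

test_that("alignment score equals the independent DP oracle", {
  set.seed(13)
  for (i in 1:30) {
    wt <- randomSeq(sample(10:30, 1))
    # mutate: point changes plus a random indel
    allele <- wt
    if (runif(1) < 0.7) {
      p <- sample(nchar(allele), 1)
      substr(allele, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (runif(1) < 0.7) {
      p <- sample(nchar(allele) - 3, 1)
      allele <- if (runif(1) < 0.5)
        paste0(substr(allele, 1, p), substr(allele, p + 3, nchar(allele)))
      else paste0(substr(allele, 1, p), randomSeq(sample(1:4, 1)),
                  substr(allele, p + 1, nchar(allele)))
    }
    expect_equal(alignAllele(wt, allele)$score,
                 oracleAlignScore(wt, allele),
                 info = paste(wt, allele))
  }
})

test_that("callEvent reproduces published allele labels", {
  expect_identical(
    eventLabel(callEvent("CCTCCTCTCCCCGAATCTACACCCACT",
                         "CCTCCCCGAATCTACACCCACT")), "-5")
  ev <- callEvent("CCTGCTTGGTGGGTTTCCGATCCAGG",
                  "CCTGCTATGGTGGGTTTCCGATCCAGG")
  expect_identical(eventLabel(ev), "+1")
  expect_identical(mutationClass(ev), "insertion")
  expect_true(isFrameshift(ev))
  ev <- callEvent("TCCAGTCAGGAGCGTCCAACTTCCAGTCCG",
                  "TCCGTCCAACTTCCAGTCCG")
  expect_identical(eventLabel(ev), "-10")
  expect_identical(mutationClass(ev), "deletion")

  ev <- callEvent("ACGTACGT", "ACGTACGT")
  expect_identical(eventLabel(ev), "0")
  expect_identical(mutationClass(ev), "none")
  expect_false(isFrameshift(ev))
})

test_that("gap-free mismatches are substitutions, not mutation events", {
  ev <- callEvent("ACGTACGTAA", "ACGTTCGTAA")
  expect_identical(mutationClass(ev), "none")
  expect_identical(eventLabel(ev), "0")
  expect_identical(nrow(substitutions(ev)), 1L)
  expect_identical(substitutions(ev)$position, 4L)
  expect_identical(substitutions(ev)$alt, "T")
})

test_that("classifyNet is the modular-arithmetic rule", {
  for (net in -12:12) {
    cl <- classifyNet(net, hasDel = net <= 0, hasIns = net > 0)
    if (net == 0) {
      expect_identical(cl$mutation_class, "deletion") # hasDel, no ins
    }
    expect_identical(cl$frameshift, net %% 3 != 0)
  }
  expect_identical(classifyNet(-33, TRUE, FALSE),
                   list(mutation_class = "deletion", frameshift = FALSE))
  expect_identical(classifyNet(2, TRUE, TRUE),
                   list(mutation_class = "complex", frameshift = TRUE))
  expect_identical(classifyNet(0, FALSE, FALSE),
                   list(mutation_class = "none", frameshift = FALSE))
})

test_that("labels parse back to their component tuples", {
  cases <- list(
    list("-8", -8L, 8L, 0L, "deletion"),
    list("+1", 1L, 0L, 1L, "insertion"),
    list("+2 (-5, +7)", 2L, 5L, 7L, "complex"),
    list("+1 (-2, +3)", 1L, 2L, 3L, "complex"),
    list("0", 0L, 0L, 0L, "none"))
  for (cs in cases) {
    p <- parseLabel(cs[[1]])
    expect_identical(p$net, cs[[2]])
    expect_identical(p$del, cs[[3]])
    expect_identical(p$ins, cs[[4]])
    expect_identical(p$mutation_class, cs[[5]])
  }
  expect_error(parseLabel("banana"), "unparseable")
  expect_error(parseLabel("+2 (-2, +5)"), "inconsistent")
})

test_that("caller recovers planted events on collision-free fixtures", {
  ex <- synthExon(length = 120, nTargets = 1, seed = 101)
  wt <- ex$seq
  set.seed(55)
  specs <- lapply(1:500, function(i) c(sample(0:10, 1), sample(0:6, 1)))
  alleles <- synthAlleles(wt, ex$targets$start, ex$targets$end,
                          specs, seed = 56)
  for (a in alleles) {
    got <- callEvent(wt, a$allele)
    expect_identical(netChange(got), netChange(a$event))
    expect_identical(mutationClass(got), mutationClass(a$event))
    expect_identical(eventLabel(got), eventLabel(a$event))
    expect_identical(isFrameshift(got), isFrameshift(a$event))
  }
})

test_that("callEvents labels a whole allele table", {
  ev <- callEvents(exampleWtRegions(),
                   data.frame(fish_id = "f1", gene = "tmem183a",
                              allele_seq = "CCTCCCCGAATCTACACCCACT"))
  expect_identical(ev$label, "-5")
  expect_true(ev$frameshift)
  expect_error(
    callEvents(c(a = "ACGT"),
               data.frame(fish_id = "f", gene = "b", allele_seq = "ACGT")),
    "no wild-type")
})
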