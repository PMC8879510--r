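T7 <- "AATTTAATACGACTCACTATA"

test_that("buildTemplate follows the printed pattern", {
  tpl <- buildTemplate("GGATGTCCCTTGAGAACGGGAGG", gene = "gabbr1a")
  expect_true(startsWith(
    templateSeq(tpl),
    "AATTTAATACGACTCACTATAGGATGTCCCTTGAGAACGGGAGGGTTTTAGAG"))
  expect_identical(nchar(templateSeq(tpl)), 125L)

  # template = T7 (21) + spacer+PAM (23) + scaffold (81)
  scaffold <- substr(templateSeq(tpl), 45, 125)
  expect_identical(nchar(scaffold), 81L)
  expect_true(startsWith(scaffold, "GTTTTAGAGCTAGAAATAGC"))
  expect_true(endsWith(scaffold, "CACCGAGTCGGTGCTTTTT"))

  set.seed(2)
  for (i in 1:20)
    expect_identical(
      nchar(templateSeq(buildTemplate(randomTarget()))), 125L)
})

test_that("dropping the PAM gives a 122-nt template without NGG", {
  target <- "GGATGTCCCTTGAGAACGGGAGG"
  tpl <- buildTemplate(target, includePAM = FALSE)
  expect_identical(nchar(templateSeq(tpl)), 122L)
  expect_identical(
    templateSeq(tpl),
    paste0(T7, substr(target, 1, 20),
           substr(templateSeq(buildTemplate(target)), 45, 125)))
})

test_that("buildTemplate rejects invalid targets", {
  expect_error(buildTemplate("ATATATATATATATATATATATA"), "invalid target")
})

test_that("splitTemplate meets the six-oligo design contract", {
  set.seed(31)
  targets <- c("GGTGTAGATTCGGGGAGAGGAGG",
               replicate(25, randomTarget()))
  for (tg in targets) {
    os <- splitTemplate(buildTemplate(tg))
    tab <- oligos(os)
    expect_identical(nrow(tab), 6L)
    expect_true(all(tab$length >= 38 & tab$length <= 46))
    expect_identical(sort(unique(tab$fragment)), 1:3)
    # the two target-variable oligos are both in fragment 1
    expect_identical(sum(tab$variable_per_target), 2L)
    expect_true(all(tab$fragment[tab$variable_per_target] == 1L))
    # spacer+PAM (template positions 21..44) lies within fragment 1
    f1 <- fragments(os)[[1]]
    expect_true(startsWith(templateSeq(os), f1@fwdSeq))
    expect_gte(nchar(f1@fwdSeq), 44)
  }
})

test_that("every design reassembles to exactly its template", {
  set.seed(32)
  for (i in 1:50) {
    os <- splitTemplate(buildTemplate(randomTarget()))
    prod <- simulateLigation(os)
    expect_identical(nrow(prod), 1L)
    expect_identical(prod$topology, "linear")
    expect_identical(prod$n_fragments, 3L)
    expect_identical(prod$sequence, templateSeq(os))
  }
})

test_that("junction overhangs satisfy the admissibility constraints", {
  os <- splitTemplate(buildTemplate("GGATGTCCCTTGAGAACGGGAGG"))
  fr <- fragments(os)
  o1 <- fr[[1]]@rightOverhang$seq
  o2 <- fr[[2]]@rightOverhang$seq
  expect_identical(nchar(o1), 4L)
  expect_identical(nchar(o2), 4L)
  expect_false(o1 == o2)
  expect_false(o1 == oracleRevComp(o1))   # non-palindromic
  expect_false(o2 == oracleRevComp(o2))
  expect_false(o2 == oracleRevComp(o1))   # no wrong-order join
  # outer template ends are blunt
  expect_identical(fr[[1]]@leftOverhang$side, "blunt")
  expect_identical(fr[[3]]@rightOverhang$side, "blunt")
})

test_that("frozen design for the tmem183a guide", {
  # golden values verified by simulateLigation reassembly
  os <- splitTemplate(buildTemplate("GGTGTAGATTCGGGGAGAGGAGG",
                                    gene = "tmem183a"))
  tab <- oligos(os)
  expect_identical(tab$length, c(42L, 46L, 40L, 40L, 43L, 39L))
  expect_identical(tab$sequence[1],
    "AATTTAATACGACTCACTATAGGTGTAGATTCGGGGAGAGGA")
  expect_identical(tab$sequence[3],
    "GGGTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAG")
  expect_identical(simulateLigation(os)$sequence, templateSeq(os))
})

test_that("overhang lengths 3 and 5 are supported", {
  tpl <- buildTemplate("GGATGTCCCTTGAGAACGGGAGG")
  os <- splitTemplate(tpl, overhangLen = 3L)
  expect_true(all(oligos(os)$length >= 38 & oligos(os)$length <= 46))
  prod <- simulateLigation(os)
  expect_identical(nrow(prod), 1L)
  expect_identical(prod$sequence, templateSeq(tpl))

  # a 5-nt overhang cannot keep the whole spacer+PAM inside 38-46-nt
  # fragment-1 oligos on the 125-nt template: the solver must say so
  expect_error(splitTemplate(tpl, overhangLen = 5L), "no admissible split")
  # dropping the PAM frees 3 nt and makes the 5-nt overhang feasible
  tpl122 <- buildTemplate("GGATGTCCCTTGAGAACGGGAGG", includePAM = FALSE)
  os5 <- splitTemplate(tpl122, overhangLen = 5L)
  expect_true(all(oligos(os5)$length >= 38 & oligos(os5)$length <= 46))
  expect_identical(simulateLigation(os5)$sequence, templateSeq(tpl122))

  expect_error(splitTemplate(tpl, overhangLen = 2), "must be 3, 4 or 5")
})

test_that("product set is invariant to fragment input order", {
  os <- splitTemplate(buildTemplate("GGATGTCCCTTGAGAACGGGAGG"))
  fr <- fragments(os)
  base <- simulateLigation(fr)
  for (p in list(c(2, 1, 3), c(3, 2, 1), c(3, 1, 2))) {
    perm <- simulateLigation(fr[p])
    expect_identical(perm$topology, base$topology)
    expect_identical(perm$length, base$length)
    expect_identical(perm$sequence, base$sequence)
  }
})

test_that("designs for two guides differ in exactly the two fragment-1 oligos", {
  tg <- exampleTargets()
  sets <- lapply(seq_len(nrow(tg)), function(i)
    splitTemplate(buildTemplate(tg$target_seq[i], gene = tg$gene[i])))
  d <- diffOligos(sets[[1]], sets[[4]])
  expect_identical(nrow(d), 2L)
  expect_true(all(d$fragment == 1L))
  # fragments 2 and 3 are byte-identical across all five designs
  constant <- function(s) oligos(s)$sequence[oligos(s)$fragment != 1L]
  for (s in sets[-1]) expect_identical(constant(s), constant(sets[[1]]))
  expect_identical(nrow(diffOligos(sets[[2]], sets[[2]])), 0L)
})

test_that("circularisable fragment systems are detected", {
  # two fragments whose outer ends are also complementary close a circle
  a <- makeTestFragment(1, randomSeq(20), "5p", "CTAA", "5p", "ACGG")
  b <- makeTestFragment(2, randomSeq(18), "5p", "CCGT", "5p", "TTAG")
  prod <- simulateLigation(list(a, b))
  expect_true("circular" %in% prod$topology)
})

test_that("ligation simulator matches the factorial enumeration oracle", {
  sides <- c("blunt", "5p", "3p")
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(2:4, 1)
    frags <- lapply(seq_len(n), function(i) {
      ls <- sample(sides, 1); rs <- sample(sides, 1)
      makeTestFragment(
        i, randomSeq(sample(8:15, 1)),
        ls, if (ls == "blunt") "" else randomSeq(4),
        rs, if (rs == "blunt") "" else randomSeq(4))
    })
    got <- simulateLigation(frags)
    gotKeys <- sort(unique(paste0(
      got$topology, "|",
      vapply(strsplit(got$fragments, ","), function(x)
        paste(sort(as.integer(sub("[fr]$", "", x))), collapse = ","),
        character(1)))))
    expect_identical(gotKeys, oracleLigation(frags))
  }
})
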