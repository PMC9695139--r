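test_that("genome simulation is deterministic and conserves counts", {
  cfg <- genomeSimConfig(seed = 71, nFull = 3,
                         fullGroups = c("Group 1", "Group 1", "Group 2"),
                         ltrDivergence = c(0L, 5L, 12L),
                         nCrPartial = 2, nLtrFragment = 4)
  a <- simulateGenome(cfg)
  b <- simulateGenome(cfg)
  expect_identical(as.character(a$scaffolds), as.character(b$scaffolds))
  expect_equal(length(a$truth$loci), 3 + 2 + 4)
  expect_equal(sum(a$truth$elements$completeness == "full"), 3)
  expect_equal(sum(a$truth$elements$completeness == "cr_partial"), 2)
  expect_equal(sum(a$truth$elements$completeness == "ltr_fragment"), 4)
})

test_that("planted structural features verify against the truth", {
  me <- miniElement(seed = 72, ltrDivergence = 0)
  loc <- me$locus
  scaf <- me$scaffold
  # planted LTR pair is identical when divergence is 0
  l5 <- substr(scaf, IRanges::start(ltr5(loc)), IRanges::end(ltr5(loc)))
  l3 <- substr(scaf, IRanges::start(ltr3(loc)), IRanges::end(ltr3(loc)))
  expect_equal(countLtrMismatches(l5, l3), 0)
  # TSD flanks duplicated exactly
  span <- locusSpan(loc)
  expect_equal(detectTsd(scaf, IRanges::start(span), IRanges::end(span)),
               tsd(loc))
  # both LTRs carry an intact detectable ribozyme
  expect_length(detectHammerhead(l5), 1)
  expect_length(detectHammerhead(l3), 1)
  expect_true(coreIntact(detectHammerhead(l5)[[1]]))
  # PBS and PPT are where the truth says
  cr_seq <- substr(scaf, IRanges::start(centralRegion(loc)),
                   IRanges::end(centralRegion(loc)))
  pbs_found <- findPbs(cr_seq, me$sim$templates$trna3p)
  expect_equal(IRanges::start(pbs_found), IRanges::start(pbs(loc)))
  ppt_found <- findPpt(cr_seq, minPurineFrac = 1)
  expect_true(IRanges::start(ppt_found) >= IRanges::start(ppt(loc)) - 2)

  # planted divergence is recovered by the mismatch counter
  me2 <- miniElement(seed = 73, ltrDivergence = 17)
  l5 <- substr(me2$scaffold, IRanges::start(ltr5(me2$locus)),
               IRanges::end(ltr5(me2$locus)))
  l3 <- substr(me2$scaffold, IRanges::start(ltr3(me2$locus)),
               IRanges::end(ltr3(me2$locus)))
  expect_equal(countLtrMismatches(l5, l3), 17)
})

test_that("replication accumulates errors at the closed-form rate", {
  withr::with_seed(74, circle <- randomDna(800))
  # no errors -> identical population
  pop0 <- simulateReplication(circle, 20, setNames(1, 5),
                              errorRate = 0, seed = 75)
  expect_true(all(pop0$molecules == circle))
  # degenerate rounds at 0 -> identical even with errors allowed
  popd <- simulateReplication(circle, 20, setNames(1, 0),
                              errorRate = 0.01, seed = 76)
  expect_true(all(popd$molecules == circle))
  # r = 10, eps = 0.001: mean divergence within 3 SE of 1-(1-eps)^r
  pop <- simulateReplication(circle, 2000, setNames(1, 10),
                             errorRate = 0.001, seed = 77)
  div <- pop$lineage$n_substituted / 800
  expected <- 1 - (1 - 0.001)^10
  se <- sd(div) / sqrt(length(div))
  expect_lt(abs(mean(div) - expected), 3 * se)
})

test_that("simulated reads carry circular origins and classify perfectly", {
  withr::with_seed(78, circle <- randomDna(600))
  pop <- simulateReplication(circle, 10, setNames(1, 0), 0, seed = 79)
  rds <- simulateReads(pop$molecules, 200, 100, seed = 80)
  expect_length(rds$reads, 200)
  expect_equal(nrow(rds$origins), 200)
  cls <- alignReadsToRefs(rds$reads, c(src = circle), circular = TRUE)
  expect_equal(attr(cls, "n_dropped"), 0)
  expect_true(all(cls$bin == "perfect"))
  # junction-spanning reads align with zero mismatches
  junction <- rds$origins$offset > 600 - 99
  expect_gt(sum(junction), 0)
  expect_true(all(cls$mismatches[junction] == 0))
  # empty request
  expect_length(simulateReads(pop$molecules, 0, 100, seed = 81)$reads, 0)
})

test_that("small-RNA simulator honors degenerate settings", {
  fx <- miniElement(seed = 82)
  base <- IRanges::start(locusSpan(fx$locus)) - 1L
  ltr <- c(IRanges::shift(ltr5(fx$locus), -base),
           IRanges::shift(ltr3(fx$locus), -base))
  cr <- IRanges::shift(centralRegion(fx$locus), -base)
  sr <- simulateSmallRnas(fx$element, ltr, cr, 500,
                          lengthDist = c("24" = 1), ltrBias = 1.0,
                          seed = 83)
  expect_true(all(nchar(sr$reads) == 24))
  expect_true(all(sr$origins$region == "LTR"))
  regions <- lociRegionTable(list(fx$locus))
  prof <- profileSmallRnas(sr$reads, setNames(fx$element, "planted_01"),
                           regions)
  expect_equal(unname(regionHist(prof)["CR"]), 0L)
  expect_equal(names(lengthHist(prof)), "24")
})

test_that("bisulfite clone simulator hits its rate extremes", {
  withr::with_seed(84, ref <- randomDna(200))
  all1 <- simulateBisulfiteClones(ref, c(CpG = 1, CHG = 1, CHH = 1),
                                  nClones = 4, seed = 85)
  expect_true(all(all1$clones == ref))
  all0 <- simulateBisulfiteClones(ref, c(CpG = 0, CHG = 0, CHH = 0),
                                  nClones = 4, conversionRate = 1,
                                  seed = 86)
  expect_true(all(!grepl("C", all0$clones)))
})

test_that("simulators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulateReplication("ACGTACGTACGT", 3, setNames(1, 2),
                                0.01, seed = 1))
  invisible(simulateGenome(genomeSimConfig(
    nFull = 1, fullGroups = "Group 1", ltrDivergence = 0L,
    nCrPartial = 0, nLtrFragment = 0, seed = 1)))
  expect_identical(.Random.seed, before)
})
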