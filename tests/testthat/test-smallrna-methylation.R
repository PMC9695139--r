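srnaFixture <- function(seed = 51) {
  me <- miniElement(seed = seed)
  loc <- me$locus
  base <- IRanges::start(locusSpan(loc)) - 1L
  list(elem = me$element,
       ltr = c(IRanges::shift(ltr5(loc), -base),
               IRanges::shift(ltr3(loc), -base)),
       cr = IRanges::shift(centralRegion(loc), -base),
       regions = lociRegionTable(list(loc)))
}

test_that("small-RNA profiling keeps exact matches only", {
  fx <- srnaFixture()
  refs <- setNames(fx$elem, locusId(miniElement(seed = 51)$locus))
  refs <- c(planted_01 = fx$elem)
  # verbatim 24-nt LTR reads: modal length 24, LTR fraction 1
  starts <- seq(10, 300, by = 10)
  reads <- setNames(vapply(starts, function(s)
    substr(fx$elem, s, s + 23), ""), sprintf("s%02d", seq_along(starts)))
  prof <- profileSmallRnas(reads, refs, fx$regions)
  expect_equal(prof@nTotal, length(reads))
  expect_equal(names(which.max(lengthHist(prof))), "24")
  expect_equal(ltrFraction(prof), 1.0)

  # a read with one mismatch to every reference is excluded
  bad <- substr(fx$elem, 50, 73)
  substr(bad, 12, 12) <- if (substr(bad, 12, 12) == "A") "C" else "A"
  prof2 <- profileSmallRnas(c(reads, bad = bad), refs, fx$regions)
  expect_equal(prof2@nTotal, length(reads))
  expect_equal(prof2@nDropped, 1L)

  # reads outside 18-30 nt are dropped up front
  prof3 <- profileSmallRnas(c(short = substr(fx$elem, 1, 10)), refs,
                            fx$regions)
  expect_equal(prof3@nTotal, 0L)
  expect_equal(prof3@nDropped, 1L)

  # empty library
  prof4 <- profileSmallRnas(character(0), refs, fx$regions)
  expect_equal(prof4@nTotal, 0L)
  expect_length(lengthHist(prof4), 0)
})

test_that("simulated libraries recover the LTR bias within 3 SE", {
  fx <- srnaFixture(seed = 52)
  n <- 4000
  p <- 0.816
  sr <- simulateSmallRnas(fx$elem, fx$ltr, fx$cr, n, ltrBias = p,
                          seed = 53)
  prof <- profileSmallRnas(sr$reads, c(planted_01 = fx$elem), fx$regions)
  expect_equal(prof@nTotal, n)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(ltrFraction(prof) - p), 3 * se)
  expect_equal(names(which.max(lengthHist(prof))), "24")
})

test_that("miRNA-site scan agrees with a brute-force mismatch counter", {
  withr::with_seed(54, rz <- randomDna(800))
  mir <- substr(oracleRevComp(rz), 101, 121)  # perfect complement, 21 nt
  hits <- scanMirnaSites(rz, c(mirPerfect = mir))
  expect_true(any(hits$mismatches == 0))

  # brute-force agreement over the doubled sequence
  for (seed in 55:57) {
    m <- randomDna(21, seed = seed)
    mm_oracle <- slidingMismatchOracle(oracleRevComp(m),
                                       paste0(rz, rz))
    got <- scanMirnaSites(rz, setNames(m, "m"), maxMismatches = 12)
    want <- which(mm_oracle <= 12)
    want <- want[want <= 800]
    expect_equal(got$position, want)
    expect_equal(got$mismatches, mm_oracle[want])
  }

  # a best site of exactly 5 mismatches is rejected at the default cap
  withr::with_seed(58, {
    site <- substr(rz, 201, 221)
    chars <- strsplit(oracleRevComp(site), "")[[1]]
    pos <- sample(21, 5)
    for (p in pos) chars[p] <- sample(setdiff(c("A","C","G","T"), chars[p]), 1)
    mir5 <- paste(chars, collapse = "")
  })
  best <- min(slidingMismatchOracle(oracleRevComp(mir5), paste0(rz, rz)))
  if (best == 5) {
    expect_equal(nrow(scanMirnaSites(rz, c(m = mir5))), 0)
  }
  expect_equal(nrow(scanMirnaSites(rz, character(0))), 0)
  expect_error(scanMirnaSites(rz, c(m = "ACGT")), "19-24")
})

test_that("bisulfite conversion follows the methylation map", {
  expect_equal(bisulfiteConvert("ACGT", integer(0), 1.0), "ATGT")
  expect_equal(bisulfiteConvert("ACGT", 2L, 1.0), "ACGT")
  expect_error(bisulfiteConvert("ACGT", 1L), "not a C")
  # partial conversion stays within binomial bounds (seeded draw)
  s <- strrep("CA", 500)
  conv <- bisulfiteConvert(s, integer(0), 0.5, seed = 59)
  n_t <- sum(strsplit(conv, "")[[1]] == "T")
  expect_gte(n_t, qbinom(0.0005, 500, 0.5))
  expect_lte(n_t, qbinom(0.9995, 500, 0.5))
})

test_that("methylation calling recovers states and contexts", {
  withr::with_seed(60, ref <- randomDna(300))
  sites <- retrozymer:::cytosineContexts(ref)
  # context partition: every C gets exactly one label
  expect_equal(nrow(sites), sum(strsplit(ref, "")[[1]] == "C"))
  expect_true(all(sites$context %in% c("CpG", "CHG", "CHH")))

  # all clones retain C -> 100%; all convert -> 0%
  keepers <- setNames(rep(ref, 3), paste0("k", 1:3))
  mt <- callMethylation(keepers, ref)
  expect_equal(pctMethylated(mt), 100)
  converted <- setNames(rep(bisulfiteConvert(ref), 3), paste0("c", 1:3))
  mt0 <- callMethylation(converted, ref)
  expect_equal(pctMethylated(mt0), 0)

  # full conversion recovers the planted map exactly, per clone and site
  bs <- simulateBisulfiteClones(ref, c(CpG = 0.9, CHG = 0.7, CHH = 0.4),
                                nClones = 6, conversionRate = 1.0,
                                seed = 61)
  mt2 <- callMethylation(bs$clones, ref)
  for (k in seq_along(bs$clones)) {
    called <- sites$position[methylationCalls(mt2)[k, ] == "methylated"]
    expect_equal(called, sort(bs$maps[[k]]))
  }
})

test_that("per-context rates are recovered within binomial CIs", {
  withr::with_seed(62, ref <- randomDna(400))
  rates <- c(CpG = 0.9, CHG = 0.7, CHH = 0.4)
  bs <- simulateBisulfiteClones(ref, rates, nClones = 20, seed = 63)
  mt <- callMethylation(bs$clones, ref)
  sites <- methylationSites(mt)
  for (ctx in names(rates)) {
    n <- sum(sites$context == ctx) * 20
    got <- pctMethylated(mt, ctx) / 100
    ci <- qbinom(c(0.025, 0.975), n, rates[[ctx]]) / n
    expect_gte(got, ci[1])
    expect_lte(got, ci[2])
  }
})

test_that("the clone-level comparison matches an exact permutation test", {
  withr::with_seed(64, {
    target_ref <- randomDna(350)
    ctrl_ref <- randomDna(350)
  })
  bs_t <- simulateBisulfiteClones(target_ref,
                                  c(CpG = 0.66, CHG = 0.66, CHH = 0.66),
                                  nClones = 10, seed = 65)
  bs_c <- simulateBisulfiteClones(ctrl_ref,
                                  c(CpG = 0.05, CHG = 0.05, CHH = 0.05),
                                  nClones = 10, seed = 66)
  mt <- callMethylation(bs_t$clones, target_ref)
  mc <- callMethylation(bs_c$clones, ctrl_ref)
  cmp <- compareMethylation(mt, mc)
  expect_lt(cmp$p_value, 0.01)
  # exact-permutation oracle on the same per-clone fractions
  p_perm <- permutationRankP(cloneFractions(mt), cloneFractions(mc))
  expect_lt(p_perm, 0.01)

  # identical clone-fraction vectors: no evidence of a difference
  cmp_same <- compareMethylation(mt, mt)
  expect_gt(cmp_same$p_value, 0.9)

  # single-clone tables are rejected
  one <- callMethylation(bs_t$clones[1], target_ref)
  expect_error(compareMethylation(one, mc), "two clones")
})
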