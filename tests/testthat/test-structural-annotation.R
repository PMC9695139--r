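hitRow <- function(scaf, start, end, strand = "+") {
  data.frame(query_id = "LTR", scaffold_id = scaf, start = start,
             end = end, strand = strand, identity = 1,
             aligned_length = end - start + 1L, mismatches = 0L,
             gaps = 0L, score = end - start + 1, evalue_like = 0,
             stringsAsFactors = FALSE)
}

test_that("pairLtrs pairs, fragments and merges tandem chains", {
  # two 350-nt same-strand hits separated by 600 nt -> one full candidate
  hits <- rbind(hitRow("s1", 1001, 1350), hitRow("s1", 1951, 2300))
  out <- pairLtrs(hits)
  expect_equal(nrow(out), 1)
  expect_equal(out$completeness, "full")
  expect_equal(out$cr_start, 1351)
  expect_equal(out$cr_end, 1950)
  expect_false(out$tandem)

  # opposite strands -> no pair, two fragments
  hits <- rbind(hitRow("s1", 1001, 1350),
                hitRow("s1", 1951, 2300, strand = "-"))
  out <- pairLtrs(hits)
  expect_equal(sort(out$completeness), c("ltr_fragment", "ltr_fragment"))

  # three equally spaced collinear hits -> one merged tandem element
  hits <- rbind(hitRow("s1", 1001, 1350), hitRow("s1", 1951, 2300),
                hitRow("s1", 2901, 3250))
  out <- pairLtrs(hits)
  expect_equal(nrow(out), 1)
  expect_true(out$tandem)
  expect_equal(out$ltr5_start, 1001)
  expect_equal(out$ltr3_end, 3250)

  # an unpaired LTR adjacent to a CR hit becomes cr_partial
  cr <- hitRow("s1", 1351, 1950)
  out <- pairLtrs(hitRow("s1", 1001, 1350), crHits = cr)
  expect_equal(out$completeness, "cr_partial")
  expect_equal(out$cr_start, 1351)
})

test_that("detectTsd requires an exact N-free 4/4 flank match", {
  elem <- strrep("G", 50)
  s <- paste0(strrep("T", 10), "ACGT", elem, "ACGT", strrep("T", 10))
  expect_equal(detectTsd(s, 15, 64), "ACGT")
  s2 <- paste0(strrep("T", 10), "ACGT", elem, "ACGA", strrep("T", 10))
  expect_true(is.na(detectTsd(s2, 15, 64)))
  s3 <- paste0(strrep("T", 10), "ACNT", elem, "ACNT", strrep("T", 10))
  expect_true(is.na(detectTsd(s3, 15, 64)))
  # element at the scaffold edge: NA, not an error
  expect_true(is.na(detectTsd(elem, 1, 50)))
})

test_that("findPbs honors complementarity length and window", {
  trna <- "GGGCGTGGTTCGATTCCACGCACCA"
  pbs12 <- oracleRevComp(substr(trna, nchar(trna) - 11, nchar(trna)))
  cr <- paste0(pbs12, randomDna(200, seed = 11))
  r <- findPbs(cr, trna)
  expect_equal(IRanges::start(r), 1)
  expect_equal(IRanges::width(r), 12)

  # random CR with no >= 10-nt complement: confirmed by exhaustive scan
  withr::with_seed(12, cr2 <- randomDna(200))
  found <- FALSE
  for (len in 10:nchar(trna)) {
    pat <- oracleRevComp(substr(trna, nchar(trna) - len + 1, nchar(trna)))
    if (grepl(pat, substr(cr2, 1, 30), fixed = TRUE)) found <- TRUE
  }
  expect_false(found)
  expect_length(findPbs(cr2, trna), 0)

  # complement outside the window is not reported
  cr3 <- paste0(randomDna(49, seed = 13), pbs12, randomDna(100, seed = 14))
  expect_length(findPbs(cr3, trna, window = 30), 0)
})

test_that("findPpt finds the longest 3'-proximal purine run", {
  cr <- paste0(randomDna(100, seed = 15), "CTCTCT", "AGGAAAGAGGGG", "TT")
  r <- findPpt(cr, minPurineFrac = 1)
  expect_equal(IRanges::width(r), 12)
  expect_equal(IRanges::end(r), nchar(cr) - 2)

  # pyrimidine-rich tail -> none
  cr2 <- paste0(randomDna(100, seed = 16), strrep("CT", 20))
  expect_length(findPpt(cr2), 0)

  # two equal qualifying runs -> the one nearer the 3' end wins
  cr3 <- paste0(strrep("C", 60), "AAAAAGGGGG", "CCCC", "GGGGGAAAAA", "CC")
  r3 <- findPpt(cr3, window = 40, minPurineFrac = 1)
  expect_equal(IRanges::end(r3), nchar(cr3) - 2)
  expect_equal(IRanges::width(r3), 10)
})

test_that("countLtrMismatches counts substitutions and gap columns", {
  a <- randomDna(350, seed = 17)
  expect_equal(countLtrMismatches(a, a), 0)
  withr::with_seed(18, {
    chars <- strsplit(a, "")[[1]]
    pos <- sample(350, 32)
    for (p in pos) chars[p] <- sample(setdiff(c("A","C","G","T"), chars[p]), 1)
    b <- paste(chars, collapse = "")
  })
  expect_equal(countLtrMismatches(a, b), 32)
  # a single 1-nt insertion counts as one mismatch (gap column)
  ins <- paste0(substr(a, 1, 100), "A", substr(a, 101, 350))
  expect_equal(countLtrMismatches(a, ins), 1)
})

test_that("classifyGroups separates CR families and labels by size", {
  withr::with_seed(19, {
    cr_a <- randomDna(400)
    cr_b <- randomDna(400)
    mk <- function(tpl, n_sub) {
      chars <- strsplit(tpl, "")[[1]]
      pos <- sample(400, n_sub)
      for (p in pos) chars[p] <- sample(setdiff(c("A","C","G","T"), chars[p]), 1)
      paste(chars, collapse = "")
    }
    seqs <- c(vapply(1:7, function(i) mk(cr_a, 20), ""),
              vapply(1:2, function(i) mk(cr_b, 20), ""))
  })
  names(seqs) <- sprintf("L%d", 1:9)
  g <- classifyGroups(seqs)
  expect_equal(unname(table(g$group)["Group 1"]), 7L)
  expect_equal(unname(table(g$group)["Group 2"]), 2L)
  expect_true(all(g$group[1:7] == "Group 1"))
  expect_true(all(g$max_cr_identity_within[1:7] >= 0.80))

  # single locus -> one group of one
  g1 <- classifyGroups(c(only = cr_a))
  expect_equal(g1$group, "Group 1")

  # two loci with ~30% identity never share a group
  g2 <- classifyGroups(c(x = randomDna(300, seed = 20),
                         y = randomDna(300, seed = 21)))
  expect_equal(length(unique(g2$group)), 2)
})

test_that("predictAmplicon implements divergent-primer circle logic", {
  withr::with_seed(22, template <- randomDna(800))
  # divergent pair: rev binds upstream of fwd on the linear template
  rev_site <- substr(template, 101, 120)
  fwd <- substr(template, 301, 320)
  rev <- oracleRevComp(rev_site)
  circ <- predictAmplicon(template, TRUE, fwd, rev)
  expect_equal(nrow(circ), 1)
  expect_true(circ$spans_junction)
  expect_equal(circ$length, 800 - 300 + 120)
  # rotation oracle: rotate so the primers become convergent, recompute
  rot <- rotateCircle(template, 250)
  lin <- predictAmplicon(rot, FALSE, fwd, rev)
  expect_equal(nrow(lin), 1)
  expect_equal(lin$length, circ$length)
  expect_false(lin$spans_junction)

  # the same divergent pair on the linear template yields nothing
  expect_equal(nrow(predictAmplicon(template, FALSE, fwd, rev)), 0)

  # convergent pair on a linear template: inclusive length arithmetic
  fwd2 <- substr(template, 100, 119)
  rev2 <- oracleRevComp(substr(template, 281, 300))
  conv <- predictAmplicon(template, FALSE, fwd2, rev2)
  expect_equal(conv$length, 201)  # 100..300 inclusive
  expect_error(predictAmplicon(template, FALSE, "ACGTACGTACGTACN", rev2),
               "N")
  expect_error(predictAmplicon(template, FALSE, "ACGTACG", rev2), "15")
})

test_that("amplicons are invariant under rotation of a circular template", {
  withr::with_seed(23, template <- randomDna(600))
  fwd <- substr(template, 401, 420)
  rev <- oracleRevComp(substr(template, 51, 70))
  base <- predictAmplicon(template, TRUE, fwd, rev)
  for (off in c(100, 333, 599)) {
    r <- predictAmplicon(rotateCircle(template, off), TRUE, fwd, rev)
    expect_equal(r$length, base$length)
  }
})
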