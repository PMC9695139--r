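plantIn <- function(background, insert, at) {
  paste0(substr(background, 1, at - 1), insert,
         substr(background, at, nchar(background)))
}

test_that("a verbatim planted query is recovered exactly", {
  withr::with_seed(42, {
    query <- randomDna(352)
    bg <- randomDna(10000)
    scaf <- plantIn(bg, query, 4001)
  })
  hits <- scanGenome(c(s1 = scaf), query)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$start, 4001)
  expect_equal(hits$end, 4001 + 351)
  expect_equal(hits$strand, "+")

  # reverse-complement planting: same span, minus strand
  scaf_rc <- plantIn(bg, oracleRevComp(query), 4001)
  hits_rc <- scanGenome(c(s1 = scaf_rc), query)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, 4001)
  expect_equal(hits_rc$end, 4001 + 351)
})

test_that("a diverged copy matches the exhaustive local-alignment oracle", {
  withr::with_seed(43, {
    query <- randomDna(352)
    qc <- strsplit(query, "")[[1]]
    pos <- sample(352, 35)
    for (p in pos) qc[p] <- sample(setdiff(c("A", "C", "G", "T"), qc[p]), 1)
    copy <- paste(qc, collapse = "")
    scaf <- plantIn(randomDna(2000), copy, 801)
  })
  hits <- scanGenome(c(s1 = scaf), query)
  expect_equal(nrow(hits), 1)
  orc <- swOracle(query, scaf)
  expect_equal(hits$start, orc$s_start)
  expect_equal(hits$end, orc$s_end)
  expect_equal(hits$score, orc$score)
  expect_equal(hits$identity,
               orc$matches / (orc$matches + orc$mismatches + orc$gapcols),
               tolerance = 1e-6)
})

test_that("all planted copies are recovered with no false positives", {
  # n non-overlapping copies at >= 85% identity: precision = recall = 1
  withr::with_seed(44, {
    query <- randomDna(300)
    n <- 6
    starts <- integer(n)
    scaf <- ""
    for (i in seq_len(n)) {
      qc <- strsplit(query, "")[[1]]
      pos <- sample(300, 30)  # 10% divergence
      for (p in pos) qc[p] <- sample(setdiff(c("A","C","G","T"), qc[p]), 1)
      scaf <- paste0(scaf, randomDna(1500))
      starts[i] <- nchar(scaf) + 1L
      scaf <- paste0(scaf, paste(qc, collapse = ""))
    }
    scaf <- paste0(scaf, randomDna(1500))
  })
  hits <- scanGenome(c(s1 = scaf), query)
  expect_equal(nrow(hits), n)
  # each hit recovers its planted copy: >= 85% of the copy covered,
  # local alignment may trim diverged ends
  planted <- IRanges::IRanges(starts, width = 300)
  found <- IRanges::IRanges(hits$start, hits$end)
  ov <- IRanges::pintersect(IRanges::findOverlapPairs(planted, found))
  expect_equal(length(ov), n)
  expect_true(all(IRanges::width(ov) >= 0.85 * 300))
  expect_true(all(hits$identity >= 0.85))
})

test_that("scanning the reverse-complemented scaffold mirrors the hits", {
  withr::with_seed(45, {
    query <- randomDna(200)
    scaf <- plantIn(randomDna(3000), query, 1001)
  })
  L <- nchar(scaf)
  fwd <- scanGenome(c(s = scaf), query)
  rev <- scanGenome(c(s = oracleRevComp(scaf)), query)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(L - rev$end + 1L), sort(fwd$start))
  expect_equal(sort(L - rev$start + 1L), sort(fwd$end))
  expect_true(all(rev$strand != fwd$strand))
})

test_that("importHits converts outfmt-6 coordinates and strand", {
  line <- function(sstart, send, pident = 95.0)
    sprintf("q1\tscaf1\t%.1f\t100\t5\t0\t1\t100\t%d\t%d\t1e-50\t180",
            pident, sstart, send)
  h <- importHits(tmpText(line(101, 200)))
  expect_equal(h$start, 101)
  expect_equal(h$end, 200)
  expect_equal(h$strand, "+")
  h <- importHits(tmpText(line(200, 101)))
  expect_equal(h$start, 101)
  expect_equal(h$end, 200)
  expect_equal(h$strand, "-")
  h <- importHits(tmpText(line(101, 200, pident = 88.4)))
  expect_equal(h$identity, 0.884)
  # non-numeric field -> parse error with line number
  bad <- tmpText(c(line(1, 100), "q1\tscaf1\tX\t100\t5\t0\t1\t100\t1\t100\t0\t1"))
  expect_error(importHits(bad), "line 2")
  # empty file -> empty table
  expect_equal(nrow(importHits(tmpText("# comment only"))), 0)
})

test_that("filterHits applies all thresholds and preserves order", {
  expect_equal(nrow(filterHits(importHits(tmpText("# none")))), 0)
  hits <- data.frame(
    query_id = "q", scaffold_id = "s", start = 1:3, end = 101:103,
    strand = "+", identity = c(0.50, 0.95, 0.99),
    aligned_length = c(100L, 100L, 40L), mismatches = 0L, gaps = 0L,
    score = 10, evalue_like = c(1e-20, 1e-20, 1e-20),
    stringsAsFactors = FALSE)
  out <- filterHits(hits, minIdentity = 0.70, minLength = 50)
  expect_equal(out$start, 2L)  # low identity and short hits removed
  # count conservation when everything passes
  many <- hits[rep(2, 83), ]
  expect_equal(nrow(filterHits(many)), 83)
})

test_that("scanGenome validates its preconditions", {
  expect_error(scanGenome(c(s = "ACGTACGTACGT"), "ACGTAC"), "query shorter")
  expect_error(scanGenome(c(s = "ACGTACGTACGT"), "ACGTACGTAC", k = 6),
               "k must be >= 8")
})
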