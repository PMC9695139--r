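test_that("mismatch binning reproduces the read-spectrum categories", {
  expect_equal(as.character(binMismatchPct(c(0, 1, 2, 3, 13, 14, 50))),
               c("perfect", "1%", "2%", "3-13%", "3-13%", ">13%", ">13%"))
  # round-half-up at the boundaries
  expect_equal(as.character(binMismatchPct(c(0.4, 0.5, 1.49, 1.5, 13.49, 13.5))),
               c("perfect", "1%", "1%", "2%", "3-13%", ">13%"))
})

test_that("reads classify against the closest reference with tie rule", {
  withr::with_seed(31, ref <- randomDna(500))
  refs <- c(refA = ref, refB = randomDna(500, seed = 32))
  # verbatim read -> perfect
  read <- substr(ref, 101, 200)
  cls <- alignReadsToRefs(c(r1 = read), refs, circular = FALSE)
  expect_equal(cls$best_ref_id, "refA")
  expect_equal(cls$mismatches, 0)
  expect_equal(as.character(cls$bin), "perfect")
  expect_equal(cls$offset, 101)

  # one substitution in a 100-nt read -> 1% bin
  r2 <- read
  substr(r2, 50, 50) <- if (substr(r2, 50, 50) == "A") "C" else "A"
  cls2 <- alignReadsToRefs(c(r = r2), refs, circular = FALSE)
  expect_equal(cls2$mismatch_pct, 1.0)
  expect_equal(as.character(cls2$bin), "1%")

  # 13 substitutions -> 3-13% bin
  chars <- strsplit(read, "")[[1]]
  withr::with_seed(33, pos <- sample(100, 13))
  for (p in pos) chars[p] <- setdiff(c("A","C","G","T"), chars[p])[1]
  cls3 <- alignReadsToRefs(c(r = paste(chars, collapse = "")), refs,
                           circular = FALSE)
  expect_equal(cls3$mismatches, 13)
  expect_equal(as.character(cls3$bin), "3-13%")

  # reverse-complement reads align on the minus strand
  cls4 <- alignReadsToRefs(c(r = oracleRevComp(read)), refs,
                           circular = FALSE)
  expect_equal(cls4$strand, "-")
  expect_equal(cls4$mismatches, 0)

  # junction-spanning read on a circular reference
  circ_read <- paste0(substr(ref, 451, 500), substr(ref, 1, 50))
  cls5 <- alignReadsToRefs(c(r = circ_read), c(refA = ref),
                           circular = TRUE)
  expect_equal(cls5$mismatches, 0)
  expect_equal(cls5$offset, 451)

  # unalignable reads are dropped and counted
  cls6 <- alignReadsToRefs(c(r = strrep("ACGT", 25), ok = read), refs,
                           circular = FALSE)
  expect_equal(nrow(cls6), 1)
  expect_equal(attr(cls6, "n_dropped"), 1)
})

test_that("region assignment follows majority overlap with junction ties", {
  ann <- data.frame(ref_id = "el", feature = c("LTR", "CR", "LTR"),
                    start = c(1, 351, 951), end = c(350, 950, 1300),
                    group = c(NA, "Group 2", NA),
                    stringsAsFactors = FALSE)
  expect_equal(assignRegion("el", 100, 100, ann), "LTR")
  expect_equal(assignRegion("el", 400, 100, ann), "CR_group2")
  expect_equal(assignRegion("el", 301, 100, ann), "junction")  # 50/50
  expect_error(assignRegion("missing", 1, 10, ann), "annotation")
})

test_that("assembleStrict merges within the cap and rejects violations", {
  withr::with_seed(34, tpl <- randomDna(200))
  r1 <- substr(tpl, 1, 100)
  # 80-nt exact overlap: extension 20 <= 25 -> one 120-nt contig
  ct <- assembleStrict(c(a = r1, b = substr(tpl, 21, 120)))
  expect_length(ct, 1)
  expect_equal(nchar(contigSeq(ct[[1]])), 120)
  expect_equal(contigSeq(ct[[1]]), substr(tpl, 1, 120))
  expect_equal(extensionLog(ct[[1]]), 20L)

  # 70-nt overlap: extension 30 > 25 -> two singletons
  ct2 <- assembleStrict(c(a = r1, b = substr(tpl, 31, 130)))
  expect_length(ct2, 2)

  # one mismatch inside an 80-nt overlap -> two singletons
  r2 <- substr(tpl, 21, 120)
  substr(r2, 30, 30) <- if (substr(r2, 30, 30) == "A") "C" else "A"
  ct3 <- assembleStrict(c(a = r1, b = r2))
  expect_length(ct3, 2)

  # duplicate ids are an error
  expect_error(assembleStrict(c(a = r1, a = r1)), "unique")
})

test_that("assembly is invariant to read order and passes the audit", {
  withr::with_seed(35, tpl <- randomDna(400))
  reads <- setNames(
    vapply(seq(1, 301, by = 20), function(s) substr(tpl, s, s + 99), ""),
    sprintf("r%02d", seq_len(16)))
  base <- assembleStrict(reads)
  base_seqs <- vapply(base, contigSeq, "")
  for (seed in 1:5) {
    withr::with_seed(seed, perm <- sample(length(reads)))
    shuf <- assembleStrict(reads[perm])
    expect_equal(vapply(shuf, contigSeq, ""), base_seqs)
  }
  # audit: every member matches its placement exactly
  for (ct in base) {
    mem <- contigMembers(ct)
    for (k in seq_len(nrow(mem))) {
      piece <- substr(contigSeq(ct), mem$offset[k],
                      mem$offset[k] + nchar(reads[[mem$read_id[k]]]) - 1)
      expect_equal(piece, unname(reads[[mem$read_id[k]]]))
    }
  }
  # all extensions respect the cap
  expect_true(all(unlist(lapply(base, extensionLog)) <= 25))
})

test_that("greedy assembly matches the exhaustive oracle on small sets", {
  mkReads <- function(seed) {
    withr::with_seed(seed, {
      tpl <- randomDna(220)
      n <- sample(4:7, 1)
      starts <- sort(sample(120, n))
      reads <- vapply(starts, function(s) substr(tpl, s, s + 99), "")
      names(reads) <- sprintf("r%d", seq_len(n))
      reads
    })
  }
  for (seed in 401:420) {
    reads <- mkReads(seed)
    got <- assembleStrict(reads)
    want <- assemblyOracleMinContigs(reads)
    expect_equal(length(got), want, info = paste("seed", seed))
  }
})

test_that("contigsVsGenome separates identical and diverged contigs", {
  withr::with_seed(36, genome_el <- randomDna(900))
  reads <- setNames(
    vapply(seq(1, 101, by = 20), function(s)
      substr(genome_el, s, s + 99), ""),
    sprintf("r%02d", 1:6))
  ct <- assembleStrict(reads)
  tab <- contigsVsGenome(ct, c(el1 = genome_el))
  expect_true(all(tab$identical))
  expect_true(all(tab$best_identity == 1))

  # a contig from a 5%-diverged copy shows ~0.95 identity
  withr::with_seed(37, {
    chars <- strsplit(genome_el, "")[[1]]
    pos <- sample(900, 45)
    for (p in pos) chars[p] <- sample(setdiff(c("A","C","G","T"), chars[p]), 1)
    div <- paste(chars, collapse = "")
  })
  ct2 <- list(new("StrictContig", id = "c1",
                  seq = substr(div, 101, 400),
                  members = data.frame(read_id = "x", offset = 1L),
                  extensionLog = integer(0)))
  tab2 <- contigsVsGenome(ct2, c(el1 = genome_el))
  expect_false(tab2$identical)
  expect_equal(tab2$best_identity, 0.95, tolerance = 0.02)

  expect_equal(nrow(contigsVsGenome(list(), c(el = genome_el))), 0)
})

test_that("mismatchSpectrum is a normalized partition over the bins", {
  cls <- data.frame(bin = binMismatchPct(
    c(rep(0, 51), rep(1, 22), rep(2, 12), rep(5, 15))))
  sp <- mismatchSpectrum(cls)
  expect_equal(unname(sp["perfect"]), 0.51)
  expect_equal(unname(sp["1%"]), 0.22)
  expect_equal(unname(sp["2%"]), 0.12)
  expect_equal(unname(sp["3-13%"]), 0.15)
  expect_equal(unname(sp[">13%"]), 0)
  expect_equal(sum(sp), 1, tolerance = 1e-9)
  # every classified read falls in exactly one bin
  expect_equal(sum(table(cls$bin)), nrow(cls))
})

test_that("tag insertions are recovered with the printed length", {
  me <- miniElement(seed = 38)
  elem <- me$element
  cr_mid <- IRanges::start(centralRegion(me$locus)) -
    IRanges::start(locusSpan(me$locus)) + 300L
  tagged <- insertTag(elem, cr_mid)
  ins <- detectInsertion(tagged, elem)
  expect_equal(nrow(ins), 1)
  expect_equal(ins$length, nchar(retrozymeTag()))
  expect_equal(ins$sequence, retrozymeTag())
  expect_equal(ins$ref_position, cr_mid)
})
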