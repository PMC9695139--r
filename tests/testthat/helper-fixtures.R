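# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no binary fixtures.

hhCassette <- function() retrozymer:::HH_CASSETTE

# a hammerhead construct with the cassette embedded in random flanks
hhConstruct <- function(seed = 1, flank = 60) {
  withr::with_seed(seed, {
    f1 <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
    f2 <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
    list(seq = paste0(f1, hhCassette(), f2),
         cassette_start = flank + 1L)
  })
}

# a miniature retrozyme element: LTR + CR + LTR with ribozymes, PBS, PPT
miniElement <- function(seed = 1, ltrLen = 350, crLen = 600,
                        ltrDivergence = 0) {
  cfg <- genomeSimConfig(
    nScaffolds = 1L, nFull = 1L, fullGroups = "Group 1",
    nCrPartial = 0L, nLtrFragment = 0L, ltrLen = ltrLen,
    crLenByGroup = c("Group 1" = crLen),
    ltrDivergence = as.integer(ltrDivergence), crDivergence = 0,
    seed = seed)
  sim <- simulateGenome(cfg)
  loc <- sim$truth$loci[[1]]
  scaf <- as.character(sim$scaffolds)[[1]]
  span <- locusSpan(loc)
  list(sim = sim, locus = loc,
       element = substr(scaf, IRanges::start(span), IRanges::end(span)),
       scaffold = scaf)
}

# write a temporary text file and return its path
tmpText <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
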