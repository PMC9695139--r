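#' @include smallrna-methylation.R
NULL

# synthetic_data: seeded generators for every input the pipeline
# consumes, with full ground-truth records for parameter-recovery tests.
# Every simulator is a pure function of its configuration including the
# seed, and leaves the caller's RNG stream untouched.

withSeed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  force(expr)
}

randDna <- function(n, gc = 0.38) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# fixed synthetic Type III hammerhead cassette satisfying the package's
# descriptor (three >= 3-bp helices, intact CUGANGA/GAAA core, downstream
# cleavage product starting with G). A test fixture, not a claim about
# any natural ribozyme sequence.
HH_CASSETTE <- paste0("GGC", "CTGATGA", "GCC", "TTCT", "GGC", "GAAA",
                      "CAC", "TTTT", "GTG", "GTC", "GCC")
HH_CASSETTE_OFFSET <- 40L  # cassette planted at LTR positions 41-80

# sample d positions from a sorted candidate vector with an index
# spacing of at least 3, so planted substitutions stay isolated: an
# isolated substitution always costs less as a mismatch than as a gap
# pair under the mismatch-counting alignment, keeping the planted count
# identifiable. Clustered substitutions can create shift-ambiguous
# alignments whose mismatch count undercounts the planted edits.
sampleSpaced <- function(candidates, d, spacing = 3L) {
  F <- length(candidates)
  stopifnot(F - spacing * (d - 1L) >= d)
  j <- sort(sample.int(F - spacing * (d - 1L), d))
  candidates[j + spacing * (seq_len(d) - 1L)]
}

substituteAt <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

plantCassette <- function(seq, cassette, offset) {
  paste0(substr(seq, 1, offset),
         cassette,
         substr(seq, offset + nchar(cassette) + 1, nchar(seq)))
}

#' Genome simulation configuration
#'
#' Validated configuration for [simulateGenome()]. Defaults mirror the
#' study conditions: nine full-length elements in two groups (7 + 2),
#' 350-nt LTRs, group-specific central regions, planted LTR-LTR
#' divergence spanning 0-32 substitutions, 4-nt target-site duplications
#' and an intact hammerhead cassette in every LTR.
#'
#' @param nScaffolds number of scaffolds.
#' @param gc background GC fraction.
#' @param nFull number of full-length elements.
#' @param fullGroups group label per full element.
#' @param nCrPartial,nLtrFragment numbers of incomplete elements.
#' @param ltrLen LTR length (nt).
#' @param crLenByGroup named integer, CR length per group (nt).
#' @param ltrDivergence integer vector (length `nFull`) of planted
#'   LTR-LTR substitution counts, each in 0-32.
#' @param crDivergence per-locus CR substitution rate within a group.
#' @param tandemLoci indices (into the full elements) planted as
#'   incomplete tandem repeats (element + extra CR-LTR copy).
#' @param trna3p tRNA-Met 3'-terminal sequence whose complement is
#'   planted as the PBS.
#' @param fragmentMinusFrac fraction of LTR fragments planted on the
#'   minus strand.
#' @param scaffoldLen optional fixed scaffold length; an error if the
#'   planted elements cannot fit without overlap. NULL sizes scaffolds
#'   automatically.
#' @param seed integer seed.
#' @return a validated config (list, class "GenomeSimConfig").
#' @export
genomeSimConfig <- function(nScaffolds = 3L, gc = 0.38,
                            nFull = 9L,
                            fullGroups = c(rep("Group 1", 7),
                                           rep("Group 2", 2)),
                            nCrPartial = 5L, nLtrFragment = 20L,
                            ltrLen = 350L,
                            crLenByGroup = c("Group 1" = 600L,
                                             "Group 2" = 450L),
                            ltrDivergence = c(1L, 0L, 2L, 7L, 12L, 20L,
                                              32L, 0L, 9L),
                            crDivergence = 0.02,
                            tandemLoci = integer(0),
                            trna3p = "CAGGGTCGCGACCCA",
                            fragmentMinusFrac = 0.25,
                            scaffoldLen = NULL,
                            seed = 1L) {
  cfg <- list(nScaffolds = as.integer(nScaffolds), gc = gc,
              nFull = as.integer(nFull), fullGroups = fullGroups,
              nCrPartial = as.integer(nCrPartial),
              nLtrFragment = as.integer(nLtrFragment),
              ltrLen = as.integer(ltrLen),
              crLenByGroup = crLenByGroup,
              ltrDivergence = as.integer(ltrDivergence),
              crDivergence = crDivergence,
              tandemLoci = as.integer(tandemLoci),
              trna3p = trna3p,
              fragmentMinusFrac = fragmentMinusFrac,
              scaffoldLen = scaffoldLen,
              seed = as.integer(seed))
  stopifnot(cfg$nFull >= 0, cfg$nCrPartial >= 0, cfg$nLtrFragment >= 0,
            length(cfg$fullGroups) == cfg$nFull,
            length(cfg$ltrDivergence) == cfg$nFull,
            all(cfg$ltrDivergence >= 0),
            all(cfg$fullGroups %in% names(cfg$crLenByGroup)),
            cfg$gc > 0, cfg$gc < 1, cfg$ltrLen >= 100,
            cfg$crDivergence >= 0, cfg$crDivergence < 0.2)
  class(cfg) <- "GenomeSimConfig"
  cfg
}

#' Simulate genome scaffolds with planted retrozymes
#'
#' Plants full-length, CR-partial and LTR-fragment retrozyme copies into
#' random background sequence at the configured GC. Every full element
#' carries an exact 4-nt TSD, an intact hammerhead cassette in both LTRs,
#' a PBS complementary to the configured tRNA 3' sequence at the CR 5'
#' end, a polypurine tract at the CR 3' end, and the configured number of
#' planted LTR-LTR substitutions (placed outside the cassette so both
#' ribozyme cores stay intact). Deterministic under the config seed.
#'
#' @param config a [genomeSimConfig()] object.
#' @return list with `scaffolds` ([Biostrings::DNAStringSet]), `truth`
#'   (list of planted [RetrozymeLocus-class] plus an `elements` summary
#'   data.frame) and `templates` (LTR/CR templates per group, the tRNA 3'
#'   sequence and the cassette).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "GenomeSimConfig"))
  withSeed(config$seed, {
    ltrLen <- config$ltrLen
    cass_pos <- (HH_CASSETTE_OFFSET + 1L):(HH_CASSETTE_OFFSET +
                                             nchar(HH_CASSETTE))
    groups <- names(config$crLenByGroup)
    ltr_tpl <- list()
    base_ltr <- plantCassette(randDna(ltrLen, config$gc), HH_CASSETTE,
                              HH_CASSETTE_OFFSET)
    ltr_tpl[[groups[1]]] <- base_ltr
    if (length(groups) > 1) {
      # later groups share the ribozyme-bearing portion of the LTR but
      # diverge elsewhere, as between natural retrozyme groups
      free <- setdiff(seq_len(ltrLen), cass_pos)
      for (g in groups[-1]) {
        npos <- round(0.10 * ltrLen)
        ltr_tpl[[g]] <- substituteAt(base_ltr, sample(free, npos))
      }
    }
    cr_tpl <- list()
    pbs_tpl <- revComp(substr(config$trna3p,
                              nchar(config$trna3p) - 11L,
                              nchar(config$trna3p)))
    ppt_tpl <- paste(sample(c("A", "G"), 14, replace = TRUE),
                     collapse = "")
    for (g in groups) {
      len <- config$crLenByGroup[[g]]
      s <- randDna(len, config$gc)
      s <- paste0(substr(s, 1, 2), pbs_tpl,
                  substr(s, 15, len - 20), ppt_tpl,
                  substr(s, len - 5, len))
      stopifnot(nchar(s) == len)
      cr_tpl[[g]] <- s
    }
    # build element records
    elems <- list()
    mkFull <- function(i) {
      g <- config$fullGroups[i]
      ltr5 <- ltr_tpl[[g]]
      free <- setdiff(seq_len(ltrLen), cass_pos)
      d <- config$ltrDivergence[i]
      ltr3 <- if (d > 0) substituteAt(ltr5, sampleSpaced(free, d))
              else ltr5
      cr <- cr_tpl[[g]]
      ncr <- round(config$crDivergence * nchar(cr))
      # keep the PBS/PPT landmarks fixed; diverge the CR interior
      cr_free <- setdiff(15:(nchar(cr) - 20L), integer(0))
      if (ncr > 0) cr <- substituteAt(cr, sample(cr_free, ncr))
      tandem <- i %in% config$tandemLoci
      parts <- if (tandem) list(ltr5, cr, ltr3, cr, ltr3)
               else list(ltr5, cr, ltr3)
      list(kind = "full", group = g, divergence = d, tandem = tandem,
           parts = parts, strand = "+",
           tsd = paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                       collapse = ""))
    }
    mkPartial <- function(i) {
      g <- groups[(i - 1) %% length(groups) + 1]
      cr <- cr_tpl[[g]]
      ncr <- round(config$crDivergence * nchar(cr))
      if (ncr > 0)
        cr <- substituteAt(cr, sample(15:(nchar(cr) - 20L), ncr))
      list(kind = "cr_partial", group = g, divergence = NA_integer_,
           tandem = FALSE, parts = list(ltr_tpl[[g]], cr), strand = "+",
           tsd = NA_character_)
    }
    mkFragment <- function(i) {
      len <- sample(120:240, 1)
      start <- sample(ltrLen - len + 1L, 1)
      frag <- substr(base_ltr, start, start + len - 1L)
      strand <- if (runif(1) < config$fragmentMinusFrac) "-" else "+"
      list(kind = "ltr_fragment", group = NA_character_,
           divergence = NA_integer_, tandem = FALSE,
           parts = list(frag), strand = strand, tsd = NA_character_)
    }
    for (i in seq_len(config$nFull)) elems[[length(elems) + 1]] <- mkFull(i)
    for (i in seq_len(config$nCrPartial))
      elems[[length(elems) + 1]] <- mkPartial(i)
    for (i in seq_len(config$nLtrFragment))
      elems[[length(elems) + 1]] <- mkFragment(i)
    # lay out round-robin over scaffolds with wide spacing so unrelated
    # hits can never pair
    scafs <- vector("list", config$nScaffolds)
    for (s in seq_len(config$nScaffolds)) scafs[[s]] <-
      list(seq = character(0), cur = 0L, loci = list())
    truth <- list()
    for (ei in seq_along(elems)) {
      e <- elems[[ei]]
      s <- (ei - 1) %% config$nScaffolds + 1
      spacer <- sample(2600:3200, 1)
      elem_seq <- paste(unlist(e$parts), collapse = "")
      if (e$strand == "-") elem_seq <- revComp(elem_seq)
      tsd <- if (is.na(e$tsd)) "" else e$tsd
      chunk <- paste0(randDna(spacer, config$gc), tsd, elem_seq, tsd)
      start <- scafs[[s]]$cur + spacer + nchar(tsd) + 1L
      scafs[[s]]$seq <- c(scafs[[s]]$seq, chunk)
      scafs[[s]]$cur <- scafs[[s]]$cur + nchar(chunk)
      lens <- nchar(unlist(e$parts))
      bounds <- start + cumsum(c(0L, lens))
      id <- sprintf("planted_%02d", ei)
      sid <- sprintf("scaffold_%02d", s)
      part_rng <- function(k)
        IRanges::IRanges(bounds[k], bounds[k + 1] - 1L)
      loc <- switch(e$kind,
        full = new("RetrozymeLocus", id = id, scaffoldId = sid,
          strand = e$strand, ltr5 = part_rng(1), cr = part_rng(2),
          ltr3 = part_rng(length(lens)),
          tsd = e$tsd, pbs = IRanges::IRanges(3, 14),
          ppt = IRanges::IRanges(nchar(e$parts[[2]]) - 19L,
                                 nchar(e$parts[[2]]) - 6L),
          ribozymes = list(), ltrMismatches = as.integer(e$divergence),
          group = e$group, completeness = "full", tandem = e$tandem),
        cr_partial = new("RetrozymeLocus", id = id, scaffoldId = sid,
          strand = e$strand, ltr5 = part_rng(1), cr = part_rng(2),
          ltr3 = IRanges::IRanges(), tsd = NA_character_,
          pbs = IRanges::IRanges(), ppt = IRanges::IRanges(),
          ribozymes = list(), ltrMismatches = NA_integer_,
          group = e$group, completeness = "cr_partial", tandem = FALSE),
        ltr_fragment = new("RetrozymeLocus", id = id, scaffoldId = sid,
          strand = e$strand, ltr5 = part_rng(1),
          ltr3 = IRanges::IRanges(), cr = IRanges::IRanges(),
          tsd = NA_character_, pbs = IRanges::IRanges(),
          ppt = IRanges::IRanges(), ribozymes = list(),
          ltrMismatches = NA_integer_, group = NA_character_,
          completeness = "ltr_fragment", tandem = FALSE))
      truth[[id]] <- loc
    }
    seqs <- character(config$nScaffolds)
    for (s in seq_len(config$nScaffolds)) {
      tail_len <- sample(1500:2000, 1)
      seqs[s] <- paste0(paste(scafs[[s]]$seq, collapse = ""),
                        randDna(tail_len, config$gc))
      if (!is.null(config$scaffoldLen)) {
        if (nchar(seqs[s]) > config$scaffoldLen)
          stop("planted elements do not fit in scaffoldLen = ",
               config$scaffoldLen, call. = FALSE)
        seqs[s] <- paste0(seqs[s],
                          randDna(config$scaffoldLen - nchar(seqs[s]),
                                  config$gc))
      }
    }
    scaffolds <- Biostrings::DNAStringSet(seqs)
    names(scaffolds) <- sprintf("scaffold_%02d", seq_len(config$nScaffolds))
    summary <- do.call(rbind, lapply(names(truth), function(id) {
      l <- truth[[id]]
      span <- locusSpan(l)
      data.frame(locus_id = id, scaffold_id = l@scaffoldId,
                 strand = l@strand, start = IRanges::start(span),
                 end = IRanges::end(span), completeness = l@completeness,
                 group = l@group, ltr_mismatches = l@ltrMismatches,
                 tandem = l@tandem, tsd = l@tsd,
                 stringsAsFactors = FALSE)
    }))
    list(scaffolds = scaffolds,
         truth = list(loci = truth, elements = summary),
         templates = list(ltr = ltr_tpl, cr = cr_tpl,
                          trna3p = config$trna3p,
                          cassette = HH_CASSETTE))
  })
}

#' Simulate rolling-circle RNA replication with error accumulation
#'
#' Each molecule independently inherits a number of replication rounds
#' from `roundsDistribution` and applies that many rounds of per-base
#' substitution at rate `errorRate` (uniform choice among the three
#' alternative bases); the expected per-base divergence after r rounds is
#' 1 - (1 - errorRate)^r up to rare back-substitutions.
#'
#' @param circleSeq the source circular sequence.
#' @param nMolecules number of molecules to generate.
#' @param roundsDistribution named numeric of probabilities over round
#'   counts (names are nonnegative integers; must sum to 1); the default
#'   is a truncated geometric.
#' @param errorRate per-base per-round substitution probability
#'   (0 <= errorRate < 0.05).
#' @param seed integer seed.
#' @return list `molecules` (named character), `lineage` (data.frame
#'   `molecule`, `rounds`, `n_substituted` distinct substituted
#'   positions vs the source).
#' @export
simulateReplication <- function(circleSeq, nMolecules,
                                roundsDistribution = NULL,
                                errorRate = 0.001, seed = 1L) {
  circleSeq <- normalizeDna(as.character(circleSeq))
  stopifnot(nchar(circleSeq) > 0, errorRate >= 0, errorRate < 0.05)
  if (is.null(roundsDistribution)) {
    r <- 0:20
    p <- 0.7 * 0.3^0  # truncated geometric, q = 0.3
    p <- 0.7 * 0.3^r; p <- p / sum(p)
    roundsDistribution <- setNames(p, r)
  }
  stopifnot(abs(sum(roundsDistribution) - 1) < 1e-9)
  L <- nchar(circleSeq)
  src <- strsplit(circleSeq, "")[[1]]
  withSeed(seed, {
    rounds <- as.integer(names(roundsDistribution))[
      sample.int(length(roundsDistribution), nMolecules, replace = TRUE,
                 prob = roundsDistribution)]
    mols <- character(nMolecules)
    nsub <- integer(nMolecules)
    for (m in seq_len(nMolecules)) {
      chars <- src
      for (r in seq_len(rounds[m])) {
        k <- rbinom(1, L, errorRate)
        if (k > 0) {
          pos <- sample.int(L, k)
          for (p in pos)
            chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
        }
      }
      mols[m] <- paste(chars, collapse = "")
      nsub[m] <- sum(chars != src)
    }
    names(mols) <- sprintf("mol_%05d", seq_len(nMolecules))
    list(molecules = mols,
         lineage = data.frame(molecule = names(mols), rounds = rounds,
                              n_substituted = nsub,
                              stringsAsFactors = FALSE))
  })
}

#' Simulate single-end reads from a circular RNA population
#'
#' Uniform start positions on the circle (junction-spanning allowed) and
#' uniform strand; constant quality.
#'
#' @param molecules named character vector of (circular) molecules.
#' @param nReads number of reads.
#' @param readLen read length (nt); must not exceed any molecule length.
#' @param seed integer seed.
#' @return list `reads` ([Biostrings::DNAStringSet] with qualities) and
#'   `origins` (data.frame `read_id`, `molecule`, `offset`, `strand`).
#' @export
simulateReads <- function(molecules, nReads, readLen = 100L, seed = 1L) {
  stopifnot(length(molecules) > 0, all(nchar(molecules) >= readLen))
  withSeed(seed, {
    mi <- sample.int(length(molecules), nReads, replace = TRUE)
    seqs <- character(nReads)
    offs <- integer(nReads)
    strands <- character(nReads)
    for (i in seq_len(nReads)) {
      m <- molecules[[mi[i]]]
      L <- nchar(m)
      off <- sample.int(L, 1)
      r <- substr(doubleCircle(m), off, off + readLen - 1L)
      strand <- if (runif(1) < 0.5) "+" else "-"
      if (strand == "-") r <- revComp(r)
      seqs[i] <- r; offs[i] <- off; strands[i] <- strand
    }
    ids <- sprintf("read_%06d", seq_len(nReads))
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- ids
    mcols(reads) <- DataFrame(qualities = strrep("I", readLen))
    list(reads = reads,
         origins = data.frame(read_id = ids,
                              molecule = names(molecules)[mi],
                              offset = offs, strand = strands,
                              stringsAsFactors = FALSE))
  })
}

#' Simulate a small-RNA library from a retrozyme locus
#'
#' Reads are exact subsequences (no errors): each read is drawn from an
#' LTR span with probability `ltrBias`, otherwise from the CR; lengths
#' follow `lengthDist` (a 24-nt-dominated distribution by default,
#' matching the DCL3 siRNA class); starts are uniform within the chosen
#' region and the read lies entirely inside it; strand is uniform.
#'
#' @param refSeq element sequence.
#' @param ltrRanges [IRanges::IRanges] of the LTR spans (element-local).
#' @param crRange [IRanges::IRanges] of the CR span.
#' @param n library size.
#' @param lengthDist named numeric of probabilities over lengths 18-30.
#' @param ltrBias probability a read originates from the LTR.
#' @param seed integer seed.
#' @return list `reads` (named character) and `origins` (data.frame
#'   `read_id`, `region`, `length`, `start`, `strand`).
#' @export
simulateSmallRnas <- function(refSeq, ltrRanges, crRange, n,
                              lengthDist = c("21" = 0.05, "22" = 0.05,
                                             "23" = 0.08, "24" = 0.72,
                                             "25" = 0.06, "26" = 0.04),
                              ltrBias = 0.816, seed = 1L) {
  refSeq <- normalizeDna(as.character(refSeq))
  stopifnot(abs(sum(lengthDist) - 1) < 1e-9, ltrBias >= 0, ltrBias <= 1,
            all(as.integer(names(lengthDist)) >= 18),
            all(as.integer(names(lengthDist)) <= 30))
  withSeed(seed, {
    lens <- as.integer(names(lengthDist))[
      sample.int(length(lengthDist), n, replace = TRUE,
                 prob = lengthDist)]
    from_ltr <- runif(n) < ltrBias
    seqs <- character(n); starts <- integer(n); strands <- character(n)
    for (i in seq_len(n)) {
      rng <- if (from_ltr[i]) {
        k <- sample.int(length(ltrRanges), 1)
        ltrRanges[k]
      } else crRange
      lo <- IRanges::start(rng); hi <- IRanges::end(rng) - lens[i] + 1L
      st <- if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1) - 1L
      r <- substr(refSeq, st, st + lens[i] - 1L)
      strand <- if (runif(1) < 0.5) "+" else "-"
      if (strand == "-") r <- revComp(r)
      seqs[i] <- r; starts[i] <- st; strands[i] <- strand
    }
    ids <- sprintf("srna_%06d", seq_len(n))
    names(seqs) <- ids
    list(reads = seqs,
         origins = data.frame(read_id = ids,
                              region = ifelse(from_ltr, "LTR", "CR"),
                              length = lens, start = starts,
                              strand = strands, stringsAsFactors = FALSE))
  })
}

#' Simulate bisulfite clone sequences
#'
#' Per-clone methylation states are drawn independently at every
#' reference-strand cytosine from its context rate; bisulfite conversion
#' is then applied via [bisulfiteConvert()].
#'
#' @param referenceSeq the unconverted reference.
#' @param perContextRates named numeric `c(CpG = , CHG = , CHH = )` of
#'   methylation probabilities.
#' @param nClones number of clones.
#' @param conversionRate bisulfite conversion efficiency in (0, 1].
#' @param seed integer seed.
#' @return list `clones` (named character), `maps` (list of methylated
#'   positions per clone), `sites` (the [cytosineContexts()] table).
#' @export
simulateBisulfiteClones <- function(referenceSeq,
                                    perContextRates = c(CpG = 0.9,
                                                        CHG = 0.7,
                                                        CHH = 0.4),
                                    nClones = 20L, conversionRate = 1.0,
                                    seed = 1L) {
  referenceSeq <- normalizeDna(as.character(referenceSeq))
  stopifnot(all(perContextRates >= 0), all(perContextRates <= 1),
            all(c("CpG", "CHG", "CHH") %in% names(perContextRates)))
  sites <- cytosineContexts(referenceSeq)
  withSeed(seed, {
    clones <- character(nClones)
    maps <- vector("list", nClones)
    for (k in seq_len(nClones)) {
      meth <- runif(nrow(sites)) < perContextRates[sites$context]
      maps[[k]] <- sites$position[meth]
      clones[k] <- bisulfiteConvert(referenceSeq, maps[[k]],
                                    conversionRate)
    }
    names(clones) <- sprintf("clone_%03d", seq_len(nClones))
    names(maps) <- names(clones)
    list(clones = clones, maps = maps, sites = sites)
  })
}

#' Region annotation table for simulated loci
#'
#' Builds the `refAnnotations` table consumed by [assignRegion()] and
#' [profileSmallRnas()] from planted (or annotated) loci, in
#' element-local coordinates of the extracted element sequence.
#'
#' @param loci list of [RetrozymeLocus-class].
#' @return data.frame `ref_id`, `feature`, `start`, `end`, `group`.
#' @export
lociRegionTable <- function(loci) {
  rows <- list()
  for (loc in loci) {
    span <- locusSpan(loc)
    base <- IRanges::start(span) - 1L
    add <- function(feature, rng) {
      if (length(rng) == 0) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        ref_id = locusId(loc), feature = feature,
        start = IRanges::start(rng) - base, end = IRanges::end(rng) - base,
        group = groupLabel(loc), stringsAsFactors = FALSE)
    }
    add("LTR", ltr5(loc))
    add("LTR", ltr3(loc))
    add("CR", centralRegion(loc))
  }
  do.call(rbind, rows)
}
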