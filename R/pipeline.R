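#' @include synthetic-data.R tagging.R
NULL

# cli_and_reports: end-to-end orchestration over a validated
# configuration, producing the tabular report bundle plus a run
# manifest. Each stage consumes and produces plain files, so any stage
# can be rerun independently.

PIPELINE_KEYS <- c(
  "seed", "genome", "replication", "reads", "smallrna", "bisulfite",
  "thresholds")
THRESHOLD_KEYS <- c(
  "min_identity", "min_length", "max_evalue", "min_overlap",
  "max_extension", "grouping_identity", "significance_identity")

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected; every threshold must lie in its legal
#' range. Returns the configuration with defaults filled in.
#'
#' @param config a named list (e.g. parsed from YAML with
#'   [yaml::read_yaml()]).
#' @return the validated, completed configuration.
#' @export
validatePipelineConfig <- function(config) {
  bad <- setdiff(names(config), PIPELINE_KEYS)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  th <- config$thresholds
  if (is.null(th)) th <- list()
  badth <- setdiff(names(th), THRESHOLD_KEYS)
  if (length(badth))
    stop("unknown threshold keys: ", paste(badth, collapse = ", "),
         call. = FALSE)
  defaults <- list(min_identity = 0.70, min_length = 50L,
                   max_evalue = 1e-10, min_overlap = 20L,
                   max_extension = 25L, grouping_identity = 0.80,
                   significance_identity = 0.50)
  for (k in names(defaults))
    if (is.null(th[[k]])) th[[k]] <- defaults[[k]]
  if (th$min_identity < 0 || th$min_identity > 1)
    stop("min_identity must be in [0, 1]", call. = FALSE)
  if (th$min_overlap < 15)
    stop("min_overlap must be >= 15", call. = FALSE)
  if (th$max_extension < 0)
    stop("max_extension must be >= 0", call. = FALSE)
  if (th$grouping_identity < th$significance_identity)
    stop("grouping_identity must be >= significance_identity",
         call. = FALSE)
  config$thresholds <- th
  if (is.null(config$replication))
    config$replication <- list(n_molecules = 60, error_rate = 0.001,
                               rounds = 10)
  if (is.null(config$reads)) config$reads <- list(n = 400, length = 100)
  if (is.null(config$smallrna))
    config$smallrna <- list(n = 4000, ltr_bias = 0.816)
  if (is.null(config$bisulfite))
    config$bisulfite <- list(n_clones = 20, rates = c(CpG = 0.9,
                                                      CHG = 0.7,
                                                      CHH = 0.4),
                             control_rate = 0.05)
  config
}

stageFail <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the simulated end-to-end retrozyme pipeline
#'
#' Simulates a genome with planted retrozymes, annotates it, simulates a
#' replicated RNA population with reads, classifies and assembles them,
#' profiles a small-RNA library and calls methylation on simulated
#' bisulfite clones — writing the report bundle (locus GFF3, contig
#' FASTA, classification TSV, mismatch-spectrum TSV, small-RNA profile
#' TSV, methylation table TSV) plus a run manifest (config hash, seed,
#' package version) to `outdir`.
#'
#' @param config configuration list (see [validatePipelineConfig()]); a
#'   path to a YAML file is also accepted.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   paths of all written artifacts.
#' @export
runPipeline <- function(config = list(), outdir = tempfile("rzk_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validatePipelineConfig(config)
  th <- config$thresholds
  seed <- as.integer(config$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  gcfg <- tryCatch(
    do.call(genomeSimConfig,
            c(config$genome, list(seed = seed))),
    error = function(e) stageFail("simulate_genome", e))
  sim <- tryCatch(simulateGenome(gcfg),
                  error = function(e) stageFail("simulate_genome", e))

  ann <- tryCatch(annotateGenome(
    sim$scaffolds, ltrQuery = sim$templates$ltr[[1]],
    crQueries = sim$templates$cr, trna3p = sim$templates$trna3p,
    minIdentity = th$min_identity, minLength = th$min_length,
    maxEvalue = th$max_evalue,
    groupingIdentity = th$grouping_identity,
    significanceIdentity = th$significance_identity),
    error = function(e) stageFail("annotate", e))
  paths$loci_gff3 <- file.path(outdir, "loci.gff3")
  writeGff3(ann$loci, paths$loci_gff3)

  full <- Filter(function(l) completeness(l) == "full", ann$loci)
  if (length(full) == 0) stageFail("annotate",
                                   simpleError("no full-length locus"))
  scafs <- as.character(sim$scaffolds)
  elemSeq <- function(l) {
    span <- locusSpan(l)
    s <- substr(scafs[[scaffoldId(l)]], IRanges::start(span),
                IRanges::end(span))
    if (locusStrand(l) == "-") revComp(s) else s
  }
  refs <- vapply(full, elemSeq, "")
  names(refs) <- vapply(full, locusId, "")
  regions <- lociRegionTable(full)

  rep_cfg <- config$replication
  pop <- tryCatch(simulateReplication(
    refs[[1]], nMolecules = rep_cfg$n_molecules,
    roundsDistribution = setNames(1, rep_cfg$rounds),
    errorRate = rep_cfg$error_rate, seed = seed + 1L),
    error = function(e) stageFail("simulate_replication", e))
  rds <- tryCatch(simulateReads(
    pop$molecules, nReads = config$reads$n,
    readLen = config$reads$length, seed = seed + 2L),
    error = function(e) stageFail("simulate_reads", e))
  paths$reads_fastq <- file.path(outdir, "reads.fastq")
  writeFastq(rds$reads, paths$reads_fastq)

  cls <- tryCatch(alignReadsToRefs(
    rds$reads, refs, circular = TRUE, refAnnotations = regions),
    error = function(e) stageFail("classify", e))
  paths$classifications_tsv <- file.path(outdir, "classifications.tsv")
  writeTsv(cls, paths$classifications_tsv)
  spec_tab <- data.frame(bin = names(mismatchSpectrum(cls)),
                         fraction = as.numeric(mismatchSpectrum(cls)))
  paths$spectrum_tsv <- file.path(outdir, "mismatch_spectrum.tsv")
  writeTsv(spec_tab, paths$spectrum_tsv)

  ctg_reads <- as.character(rds$reads)[cls$read_id[cls$bin != ">13%"]]
  contigs <- tryCatch(assembleStrict(
    ctg_reads, minOverlap = th$min_overlap,
    maxExtension = th$max_extension),
    error = function(e) stageFail("assemble", e))
  paths$contigs_fasta <- file.path(outdir, "contigs.fasta")
  writeFasta(setNames(vapply(contigs, contigSeq, ""),
                      vapply(contigs, function(x) x@id, "")),
             paths$contigs_fasta)

  sr_cfg <- config$smallrna
  l1 <- full[[1]]
  base <- IRanges::start(locusSpan(l1)) - 1L
  sr <- tryCatch(simulateSmallRnas(
    refs[[1]],
    ltrRanges = c(IRanges::shift(ltr5(l1), -base),
                  IRanges::shift(ltr3(l1), -base)),
    crRange = IRanges::shift(centralRegion(l1), -base),
    n = sr_cfg$n, ltrBias = sr_cfg$ltr_bias, seed = seed + 3L),
    error = function(e) stageFail("simulate_smallrna", e))
  prof <- tryCatch(profileSmallRnas(sr$reads, refs[1], regions),
                   error = function(e) stageFail("smallrna", e))
  prof_tab <- data.frame(length = names(lengthHist(prof)),
                         count = as.integer(lengthHist(prof)))
  paths$smallrna_tsv <- file.path(outdir, "smallrna_profile.tsv")
  writeTsv(prof_tab, paths$smallrna_tsv,
           comments = c(sprintf("n_total = %d", prof@nTotal),
                        sprintf("ltr_fraction = %.4f", ltrFraction(prof))))

  bs_cfg <- config$bisulfite
  ltr_seq <- substr(refs[[1]], 1, IRanges::width(ltr5(l1)))
  bs <- tryCatch(simulateBisulfiteClones(
    ltr_seq, perContextRates = bs_cfg$rates, nClones = bs_cfg$n_clones,
    seed = seed + 4L),
    error = function(e) stageFail("simulate_bisulfite", e))
  meth <- tryCatch(callMethylation(bs$clones, ltr_seq),
                   error = function(e) stageFail("methylation", e))
  ctrl_seq <- randDnaSeeded(nchar(ltr_seq), seed + 5L)
  ctrl_rates <- setNames(rep(bs_cfg$control_rate, 3),
                         c("CpG", "CHG", "CHH"))
  ctrl <- simulateBisulfiteClones(ctrl_seq, ctrl_rates,
                                  nClones = bs_cfg$n_clones,
                                  seed = seed + 6L)
  meth_ctrl <- callMethylation(ctrl$clones, ctrl_seq)
  cmp <- compareMethylation(meth, meth_ctrl)
  meth_tab <- data.frame(
    position = methylationSites(meth)$position,
    context = methylationSites(meth)$context,
    pct_methylated = vapply(seq_len(nrow(methylationSites(meth))),
      function(j) {
        col <- methylationCalls(meth)[, j]
        nm <- sum(col == "methylated"); nu <- sum(col == "unmethylated")
        100 * nm / (nm + nu)
      }, 1))
  paths$methylation_tsv <- file.path(outdir, "methylation.tsv")
  writeTsv(meth_tab, paths$methylation_tsv,
           comments = c(
             sprintf("pct_methylated_total = %.2f", pctMethylated(meth)),
             sprintf("control_pct = %.2f", pctMethylated(meth_ctrl)),
             sprintf("mann_whitney_p = %.3g", cmp$p_value)))

  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package = "retrozymer",
    version = as.character(utils::packageVersion("retrozymer")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifacts = unname(unlist(paths)))
  paths$manifest_json <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest_json, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(config = config, annotation = ann,
                 classifications = cls, contigs = contigs,
                 smallrna = prof, methylation = meth,
                 methylation_control = meth_ctrl, comparison = cmp,
                 paths = paths))
}

randDnaSeeded <- function(n, seed, gc = 0.38) {
  withSeed(seed, randDna(n, gc))
}
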