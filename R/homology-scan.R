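#' @include seq-io.R
NULL

# homology_scan: seed-and-extend search for LTR/CR-homologous intervals,
# plus an importer for external BLAST outfmt-6 hits. The scanner mirrors
# the BLAST-style discovery step: exact k-mer seeding on both strands,
# diagonal clustering, then a gapped local refinement (match +1,
# mismatch -2, gap -3) run by the package's own alignment kernel.

# Karlin-Altschul-style significance surrogate: a ranking/filter
# statistic from score and search-space size, not calibrated to NCBI
# BLAST E-values (those are tool-version-dependent).
KA_LAMBDA <- 1.1
KA_K <- 0.35

evalueSurrogate <- function(score, query_len, space_len) {
  KA_K * query_len * space_len * exp(-KA_LAMBDA * score)
}

emptyHits <- function() {
  data.frame(query_id = character(), scaffold_id = character(),
             start = integer(), end = integer(), strand = character(),
             identity = numeric(), aligned_length = integer(),
             mismatches = integer(), gaps = integer(),
             score = numeric(), evalue_like = numeric(),
             stringsAsFactors = FALSE)
}

# cluster seed matches on one strand of one scaffold into candidate
# windows: seeds sharing a diagonal band within `band` and separated by
# less than `join_gap` along the scaffold are grouped.
clusterSeeds <- function(spos, qpos, band = 30L, join_gap = 400L) {
  o <- order(spos - qpos, spos)
  spos <- spos[o]; qpos <- qpos[o]
  diag <- spos - qpos
  cl <- integer(length(spos))
  cur <- 0L
  for (i in seq_along(spos)) {
    if (i == 1 || diag[i] - diag[i - 1] > band ||
        (diag[i] - diag[i - 1] <= band &&
         abs(spos[i] - spos[i - 1]) > join_gap)) {
      cur <- cur + 1L
    }
    cl[i] <- cur
  }
  split(data.frame(spos = spos, qpos = qpos), cl)
}

scanOneStrand <- function(subject, query, query_id, scaffold_id, strand,
                          k, space_len) {
  qlen <- nchar(query)
  slen <- nchar(subject)
  if (slen < k) return(emptyHits())
  kmers <- substring(query, seq_len(qlen - k + 1),
                     seq_len(qlen - k + 1) + k - 1)
  keep <- !grepl("N", kmers, fixed = TRUE)
  if (!any(keep)) return(emptyHits())
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
  mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject))
  counts <- S4Vectors::elementNROWS(mi)
  if (sum(counts) == 0) return(emptyHits())
  qpos <- rep(which(keep), counts)
  spos <- unlist(IRanges::start(mi), use.names = FALSE)
  hits <- list()
  for (cluster in clusterSeeds(spos, qpos)) {
    w_lo <- max(1L, min(cluster$spos) - qlen)
    w_hi <- min(slen, max(cluster$spos) + k + qlen)
    window <- substr(subject, w_lo, w_hi)
    aln <- .sw_align(query, window, 1L, -2L, -3L)
    if (!isTRUE(aln$found)) next
    hits[[length(hits) + 1L]] <- data.frame(
      query_id = query_id, scaffold_id = scaffold_id,
      start = w_lo + aln$b_start - 1L, end = w_lo + aln$b_end - 1L,
      strand = strand,
      identity = aln$matches / aln$aligned_length,
      aligned_length = aln$aligned_length,
      mismatches = aln$mismatches, gaps = aln$gapcols,
      score = as.numeric(aln$score),
      evalue_like = evalueSurrogate(aln$score, qlen, space_len),
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0) return(emptyHits())
  do.call(rbind, hits)
}

# keep the maximal-scoring hit among overlapping same-query same-strand
# hits on one scaffold
mergeOverlapping <- function(hits) {
  if (nrow(hits) < 2) return(hits)
  keep <- rep(TRUE, nrow(hits))
  key <- paste(hits$scaffold_id, hits$query_id, hits$strand)
  for (grp in split(seq_len(nrow(hits)), key)) {
    if (length(grp) < 2) next
    ir <- IRanges::IRanges(hits$start[grp], hits$end[grp])
    ov <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (i in seq_along(qh)) {
      a <- grp[qh[i]]; b <- grp[sh[i]]
      if (a == b || !keep[a] || !keep[b]) next
      drop <- if (hits$score[a] >= hits$score[b]) b else a
      keep[drop] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

#' Scan genome scaffolds for query-homologous intervals
#'
#' Seed-and-extend local search on both strands: exact k-mer seeds are
#' clustered by diagonal and refined by gapped local alignment
#' (match +1, mismatch -2, gap -3). Overlapping hits to the same query on
#' the same strand are reduced to the maximal-scoring one. Minus-strand
#' hits are reported on plus coordinates with strand "-".
#'
#' @param scaffolds named [Biostrings::DNAStringSet] (or named character).
#' @param query a single query sequence (character or DNAString), N-free.
#' @param queryId label recorded in the hit table.
#' @param k seed length (>= 8; query must be at least `k` long).
#' @param minIdentity,minLength,maxEvalue filter thresholds applied to the
#'   raw hit list (see [filterHits()]).
#' @return a hit table (data.frame) sorted by scaffold then start, with
#'   columns `query_id`, `scaffold_id`, `start`, `end` (1-based
#'   inclusive), `strand`, `identity`, `aligned_length`, `mismatches`,
#'   `gaps`, `score`, `evalue_like`.
#' @export
scanGenome <- function(scaffolds, query, queryId = "query", k = 12L,
                       minIdentity = 0.70, minLength = 50L,
                       maxEvalue = 1e-10) {
  if (is(scaffolds, "XStringSet")) scaffolds <- as.character(scaffolds)
  stopifnot(!is.null(names(scaffolds)), !anyDuplicated(names(scaffolds)))
  query <- normalizeDna(as.character(query))
  checkDnaAlphabet(query, "query", allow_n = FALSE)
  if (k < 8) stop("seed length k must be >= 8", call. = FALSE)
  if (nchar(query) < k)
    stop("query shorter than seed length k", call. = FALSE)
  space_len <- sum(nchar(scaffolds))
  rcq <- revComp(query)
  out <- list()
  for (sid in names(scaffolds)) {
    subj <- normalizeDna(scaffolds[[sid]])
    out[[length(out) + 1L]] <- scanOneStrand(
      subj, query, queryId, sid, "+", k, space_len)
    out[[length(out) + 1L]] <- scanOneStrand(
      subj, rcq, queryId, sid, "-", k, space_len)
  }
  hits <- do.call(rbind, out)
  hits <- mergeOverlapping(hits)
  hits <- filterHits(hits, maxEvalue = maxEvalue,
                     minIdentity = minIdentity, minLength = minLength)
  hits[order(hits$scaffold_id, hits$start), , drop = FALSE]
}

#' Import BLAST tabular (outfmt 6) hits
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore. Subject coordinates with sstart > send
#' are encoded as strand "-"; all coordinates are returned 1-based
#' inclusive on the plus strand. Percent identity is rescaled to a
#' fraction.
#'
#' @param path path to a tab-separated hit file ('#' comments allowed).
#' @return a hit table in the [scanGenome()] layout.
#' @export
importHits <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) return(emptyHits())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 12))
    stop("outfmt-6 parse error at line ", keep[which(nf < 12)[1]],
         ": expected 12 fields", call. = FALSE)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
    if (anyNA(v))
      stop("outfmt-6 parse error at line ", keep[which(is.na(v))[1]],
           ": non-numeric ", what, call. = FALSE)
    v
  }
  sstart <- num(9, "sstart"); send <- num(10, "send")
  strand <- ifelse(sstart <= send, "+", "-")
  pident <- num(3, "pident")
  alen <- num(4, "length")
  mism <- num(5, "mismatch")
  gapo <- num(6, "gapopen")
  bits <- num(12, "bitscore")
  ev <- num(11, "evalue")
  data.frame(
    query_id = vapply(fields, `[[`, "", 1),
    scaffold_id = vapply(fields, `[[`, "", 2),
    start = as.integer(pmin(sstart, send)),
    end = as.integer(pmax(sstart, send)),
    strand = strand,
    identity = pident / 100,
    aligned_length = as.integer(alen),
    mismatches = as.integer(mism),
    gaps = as.integer(gapo),
    score = bits,
    evalue_like = ev,
    stringsAsFactors = FALSE)
}

#' Filter a hit table by significance, identity and length
#'
#' @param hits a hit table from [scanGenome()] or [importHits()].
#' @param maxEvalue,minIdentity,minLength finite thresholds.
#' @return the subset passing all thresholds, in stable order.
#' @export
filterHits <- function(hits, maxEvalue = 1e-10, minIdentity = 0.70,
                       minLength = 50L) {
  stopifnot(is.finite(maxEvalue), is.finite(minIdentity),
            is.finite(minLength))
  if (nrow(hits) == 0) return(hits)
  keep <- hits$evalue_like <= maxEvalue &
    hits$identity >= minIdentity &
    hits$aligned_length >= minLength
  hits[keep, , drop = FALSE]
}
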