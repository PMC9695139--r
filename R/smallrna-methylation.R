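#' @include rna-population.R
NULL

# smallrna_methylation: exact-match small-RNA profiling, the miRNA-site
# scan, in-silico bisulfite conversion, per-cytosine methylation calling
# with sequence context, and the target-vs-control comparison.

# hash of every 18-30 nt substring of the doubled references (both
# strands) -> first (ref, unit position, strand); built once per call.
buildExactIndex <- function(refs, minLen = 18L, maxLen = 30L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (rn in sort(names(refs))) {
    L <- nchar(refs[[rn]])
    for (strand in c("+", "-")) {
      s <- doubleCircle(refs[[rn]])
      if (strand == "-") s <- revComp(s)
      for (len in minLen:min(maxLen, L)) {
        starts <- seq_len(nchar(s) - len + 1L)
        subs <- substring(s, starts, starts + len - 1L)
        for (k in seq_along(subs)) {
          key <- subs[k]
          if (!is.null(env[[key]])) next
          pos <- starts[k]
          if (strand == "-") pos <- nchar(s) - (pos + len - 1L) + 1L
          pos <- ((pos - 1L) %% L) + 1L
          env[[key]] <- list(ref = rn, pos = pos, strand = strand)
        }
      }
    }
  }
  env
}

#' Profile retrozyme-specific small RNAs
#'
#' Reads of 18-30 nt are retained; a read is retrozyme-specific iff it
#' matches some reference exactly over its full length (either strand,
#' with circular doubling so junction-spanning reads match). Matched
#' reads are assigned to LTR or CR by majority footprint overlap and
#' tallied into length and region histograms.
#'
#' @param reads named character vector or [Biostrings::DNAStringSet].
#' @param refs named character vector or DNAStringSet of retrozyme
#'   references.
#' @param refAnnotations region table as in [assignRegion()].
#' @return a [SmallRnaProfile-class].
#' @export
profileSmallRnas <- function(reads, refs, refAnnotations) {
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  if (is(refs, "XStringSet")) refs <- as.character(refs)
  refs <- vapply(refs, normalizeDna, "")
  lens <- nchar(reads)
  keep <- lens >= 18 & lens <= 30
  n_dropped <- sum(!keep)
  reads <- reads[keep]
  idx <- buildExactIndex(refs)
  unit_len <- nchar(refs)
  len_hist <- integer(0)
  region_hist <- c(LTR = 0L, CR = 0L)
  n_total <- 0L
  for (r in reads) {
    hit <- idx[[r]]
    if (is.null(hit)) { n_dropped <- n_dropped + 1L; next }
    n_total <- n_total + 1L
    l <- as.character(nchar(r))
    len_hist[l] <- (if (is.na(len_hist[l])) 0L else len_hist[l]) + 1L
    region <- assignRegion(hit$ref, hit$pos, nchar(r), refAnnotations,
                           unitLength = unit_len[[hit$ref]])
    key <- if (region == "LTR") "LTR" else "CR"
    region_hist[key] <- region_hist[key] + 1L
  }
  len_hist <- len_hist[order(as.integer(names(len_hist)))]
  new("SmallRnaProfile", lengthHist = len_hist,
      regionHist = region_hist, nTotal = n_total,
      nDropped = as.integer(n_dropped),
      ltrFraction = if (n_total > 0) region_hist[["LTR"]] / n_total
                    else NaN)
}

#' Scan a retrozyme for candidate miRNA binding sites
#'
#' Slides the reverse complement of each miRNA along the (circularly
#' doubled) retrozyme sequence and reports sites with at most
#' `maxMismatches` mismatches. The default of 4 implements a
#' "fewer than five mismatches" criterion.
#'
#' @param retrozymeSeq retrozyme sequence (treated as circular).
#' @param mirnaSet named character vector of miRNA sequences (19-24 nt;
#'   RNA alphabet accepted).
#' @param maxMismatches maximum mismatch count at a reported site.
#' @return data.frame `mirna_id`, `position` (1-based on the unit
#'   sequence), `mismatches`.
#' @export
scanMirnaSites <- function(retrozymeSeq, mirnaSet, maxMismatches = 4L) {
  retrozymeSeq <- normalizeDna(as.character(retrozymeSeq))
  L <- nchar(retrozymeSeq)
  doubled <- doubleCircle(retrozymeSeq)
  rows <- list()
  for (id in names(mirnaSet)) {
    mir <- normalizeDna(mirnaSet[[id]])
    if (nchar(mir) < 19 || nchar(mir) > 24)
      stop("miRNA ", id, " outside 19-24 nt", call. = FALSE)
    pat <- revComp(mir)
    mm <- .sliding_mismatch(pat, doubled)
    hit <- which(mm <= maxMismatches)
    hit <- hit[hit <= L]  # de-duplicate modulo unit length
    for (h in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = id, position = h, mismatches = mm[h],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(mirna_id = character(), position = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' In-silico bisulfite conversion
#'
#' Unmethylated cytosines are converted C -> T with probability
#' `conversionRate`; methylated cytosines and non-C bases are unchanged.
#'
#' @param seq DNA sequence.
#' @param methylationMap integer positions of methylated cytosines; a
#'   position that is not a C is an error.
#' @param conversionRate conversion probability in (0, 1].
#' @param seed optional integer seed for the conversion draw.
#' @return the converted sequence.
#' @export
bisulfiteConvert <- function(seq, methylationMap = integer(0),
                             conversionRate = 1.0, seed = NULL) {
  seq <- normalizeDna(as.character(seq))
  stopifnot(conversionRate > 0, conversionRate <= 1)
  chars <- strsplit(seq, "")[[1]]
  if (length(methylationMap) &&
      any(chars[methylationMap] != "C"))
    stop("methylation_map position is not a C", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  targets <- setdiff(which(chars == "C"), methylationMap)
  conv <- targets[runif(length(targets)) <= conversionRate]
  chars[conv] <- "T"
  paste(chars, collapse = "")
}

# save/restore the RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# cytosine positions and CpG/CHG/CHH contexts on the reference plus
# strand; positions too close to the 3' end default to CHH
cytosineContexts <- function(refSeq) {
  chars <- strsplit(refSeq, "")[[1]]
  L <- length(chars)
  pos <- which(chars == "C")
  ctx <- vapply(pos, function(p) {
    n1 <- if (p + 1 <= L) chars[p + 1] else ""
    n2 <- if (p + 2 <= L) chars[p + 2] else ""
    if (n1 == "G") "CpG"
    else if (n2 == "G" && n1 %in% c("A", "C", "T")) "CHG"
    else "CHH"
  }, "")
  data.frame(position = pos, context = ctx, stringsAsFactors = FALSE)
}

#' Call per-cytosine methylation from bisulfite clone sequences
#'
#' Each clone is aligned end-to-end to the (unconverted) reference; at
#' every reference-strand cytosine a retained C is called methylated, a T
#' unmethylated, and anything else (including an alignment gap)
#' uncallable. Only plus-strand cytosines of the amplicon are called.
#' Clones below 90% identity to the reference at non-cytosine positions
#' are excluded and reported in `attr(, "excluded")`.
#'
#' @param cloneSeqs named character vector of clone sequences.
#' @param referenceSeq the unconverted reference.
#' @return a [MethylationTable-class].
#' @export
callMethylation <- function(cloneSeqs, referenceSeq) {
  referenceSeq <- normalizeDna(as.character(referenceSeq))
  if (is(cloneSeqs, "XStringSet")) cloneSeqs <- as.character(cloneSeqs)
  cloneSeqs <- vapply(cloneSeqs, normalizeDna, "")
  if (is.null(names(cloneSeqs)))
    names(cloneSeqs) <- sprintf("clone_%02d", seq_along(cloneSeqs))
  sites <- cytosineContexts(referenceSeq)
  ref_chars <- strsplit(referenceSeq, "")[[1]]
  non_c <- which(ref_chars != "C")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE)
  calls <- list()
  excluded <- character(0)
  for (cn in names(cloneSeqs)) {
    clone <- cloneSeqs[[cn]]
    if (clone == referenceSeq || nchar(clone) == nchar(referenceSeq)) {
      aligned <- strsplit(clone, "")[[1]]
      ref_cols <- seq_along(ref_chars)
      clone_at <- aligned
    } else {
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(clone),
        subject = Biostrings::DNAString(referenceSeq),
        type = "global", substitutionMatrix = mat,
        gapOpening = 2, gapExtension = 1)
      sub_aln <- strsplit(as.character(
        Biostrings::alignedSubject(aln)), "")[[1]]
      pat_aln <- strsplit(as.character(
        Biostrings::alignedPattern(aln)), "")[[1]]
      clone_at <- rep("-", length(ref_chars))
      rp <- 0L
      for (k in seq_along(sub_aln)) {
        if (sub_aln[k] != "-") {
          rp <- rp + 1L
          clone_at[rp] <- pat_aln[k]
        }
      }
    }
    ident_non_c <- mean(clone_at[non_c] == ref_chars[non_c])
    if (is.nan(ident_non_c)) ident_non_c <- 1
    if (ident_non_c < 0.90) { excluded <- c(excluded, cn); next }
    row <- vapply(sites$position, function(p) {
      b <- clone_at[p]
      if (b == "C") "methylated"
      else if (b == "T") "unmethylated"
      else "uncallable"
    }, "")
    calls[[cn]] <- row
  }
  calls_mat <- if (length(calls))
    do.call(rbind, calls)
  else matrix(character(0), nrow = 0, ncol = nrow(sites))
  out <- new("MethylationTable", referenceId = "reference",
             sites = sites, calls = calls_mat)
  attr(out, "excluded") <- excluded
  out
}

#' Compare methylation between a target and a control amplicon
#'
#' Two-sided Mann-Whitney U test on per-clone methylated fractions, the
#' distribution-free default for clone-level bisulfite data; with at most
#' `exactMax` clones per table the exact null distribution is used.
#'
#' @param targetTable,controlTable [MethylationTable-class] objects with
#'   at least two clones each; zero callable sites is an error.
#' @param exactMax use the exact test when both tables have at most this
#'   many clones.
#' @return list `statistic` (U), `p_value`.
#' @export
compareMethylation <- function(targetTable, controlTable, exactMax = 10L) {
  x <- cloneFractions(targetTable)
  y <- cloneFractions(controlTable)
  if (length(x) < 2 || length(y) < 2)
    stop("both tables need at least two clones", call. = FALSE)
  if (all(is.nan(x)) || all(is.nan(y)))
    stop("a table has zero callable sites", call. = FALSE)
  exact <- length(x) <= exactMax && length(y) <= exactMax
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
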