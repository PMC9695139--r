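#' @include structural-annotation.R
NULL

# rna_population: transcriptome analysis. Reads are classified against
# the closest genomic retrozyme copy, binned by mismatch percentage, and
# assembled with a strict zero-mismatch assembler whose per-merge contig
# extension is capped to keep foreign reads from anchoring to long
# single-read overhangs.

MISMATCH_BINS <- c("perfect", "1%", "2%", "3-13%", ">13%")

#' Bin a mismatch percentage
#'
#' Round-half-up to the nearest integer percent: 0 is "perfect", 1 "1%",
#' 2 "2%", 3-13 "3-13%", above 13 ">13%" (reported, but treated as
#' non-retrozyme downstream). For 100-nt reads one substitution is one
#' percent, matching the read-spectrum categories.
#'
#' @param mismatchPct numeric vector of mismatch percentages.
#' @return factor with levels `r toString(MISMATCH_BINS)`.
#' @export
binMismatchPct <- function(mismatchPct) {
  r <- floor(mismatchPct + 0.5)
  lab <- ifelse(r == 0, "perfect",
         ifelse(r == 1, "1%",
         ifelse(r == 2, "2%",
         ifelse(r <= 13, "3-13%", ">13%"))))
  factor(lab, levels = MISMATCH_BINS)
}

#' Classify reads against reference retrozyme sequences
#'
#' Each read is aligned end-to-end (ungapped, every placement, both
#' strands; against the doubled sequence when `circular = TRUE`) to every
#' reference; the best reference is the minimum-mismatch one, ties going
#' to the lowest reference id. Reads whose best identity stays below
#' `minIdentity` after a banded gapped fallback (gaps counted as
#' mismatches) are dropped and counted.
#'
#' @param reads named character vector or [Biostrings::DNAStringSet].
#' @param refs named character vector or DNAStringSet of references.
#' @param circular treat references as circles (doubled for alignment;
#'   placements taken modulo the unit length).
#' @param minIdentity identity below which a read is dropped.
#' @param refAnnotations optional region annotation table (see
#'   [assignRegion()]); when given a `region` column is filled in.
#' @return data.frame `read_id`, `best_ref_id`, `strand`, `offset`
#'   (1-based on the unit-length reference), `mismatches`, `aligned_len`,
#'   `mismatch_pct`, `bin`, and `region` when annotations are given; the
#'   number of dropped reads is in `attr(, "n_dropped")`.
#' @export
alignReadsToRefs <- function(reads, refs, circular = TRUE,
                             minIdentity = 0.85, refAnnotations = NULL) {
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  if (is(refs, "XStringSet")) refs <- as.character(refs)
  stopifnot(length(reads) > 0, length(refs) > 0,
            !is.null(names(reads)), !is.null(names(refs)))
  refs <- refs[order(names(refs))]
  unit_len <- nchar(refs)
  subj <- if (circular) vapply(refs, doubleCircle, "") else refs
  subj_rc <- vapply(subj, revComp, "")
  rows <- list()
  n_dropped <- 0L
  for (ri in seq_along(reads)) {
    read <- reads[[ri]]
    lr <- nchar(read)
    best <- NULL
    for (si in seq_along(subj)) {
      for (strand in c("+", "-")) {
        s <- if (strand == "+") subj[[si]] else subj_rc[[si]]
        res <- .best_offset_mismatch(read, s)
        if (!isTRUE(res$found)) next
        if (is.null(best) || res$mismatches < best$mism) {
          off <- res$offset
          if (strand == "-") off <- nchar(s) - (off + lr - 1L) + 1L
          best <- list(ref = si, strand = strand, mism = res$mismatches,
                       offset = off, alen = lr)
        }
      }
    }
    if (is.null(best)) { n_dropped <- n_dropped + 1L; next }
    if (best$mism / lr > 1 - minIdentity) {
      # gapped fallback: align the whole read into the best reference
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(read),
        subject = Biostrings::DNAString(subj[[best$ref]]),
        type = "global-local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = TRUE),
        gapOpening = 1, gapExtension = 1)
      ind <- sum(Biostrings::nindel(aln)@insertion[, "WidthSum"],
                 Biostrings::nindel(aln)@deletion[, "WidthSum"])
      mism2 <- Biostrings::nmismatch(aln) + ind
      if (mism2 < best$mism) {
        best$mism <- mism2
        best$offset <- IRanges::start(Biostrings::subject(aln))
      }
    }
    if (best$mism / lr > 1 - minIdentity) { n_dropped <- n_dropped + 1L; next }
    off <- best$offset
    if (circular) off <- ((off - 1L) %% unit_len[best$ref]) + 1L
    pct <- 100 * best$mism / best$alen
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = names(reads)[ri], best_ref_id = names(refs)[best$ref],
      strand = best$strand, offset = off,
      mismatches = best$mism, aligned_len = best$alen,
      mismatch_pct = pct, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), best_ref_id = character(),
               strand = character(), offset = integer(),
               mismatches = integer(), aligned_len = integer(),
               mismatch_pct = numeric(), stringsAsFactors = FALSE)
  out$bin <- binMismatchPct(out$mismatch_pct)
  if (!is.null(refAnnotations) && nrow(out) > 0) {
    out$region <- vapply(seq_len(nrow(out)), function(i) {
      assignRegion(out$best_ref_id[i], out$offset[i], out$aligned_len[i],
                   refAnnotations,
                   unitLength = unit_len[[out$best_ref_id[i]]])
    }, "")
  }
  attr(out, "n_dropped") <- n_dropped
  rownames(out) <- NULL
  out
}

#' Assign a read footprint to a reference region
#'
#' The label is decided by majority overlap of the read's reference
#' footprint with LTR versus CR spans; an exact 50/50 split is a
#' "junction". CR labels carry the reference's group
#' ("CR_group1"/"CR_group2").
#'
#' @param refId reference the read aligned to.
#' @param offset 1-based start of the footprint on the unit-length
#'   reference.
#' @param len footprint length (nt).
#' @param refAnnotations data.frame `ref_id`, `feature` ("LTR" or "CR"),
#'   `start`, `end`, `group` (group used for CR rows).
#' @param unitLength reference unit length (footprints wrap around it).
#' @return one of "LTR", "CR_group1", "CR_group2", "junction".
#' @export
assignRegion <- function(refId, offset, len, refAnnotations,
                         unitLength = NULL) {
  ann <- refAnnotations[refAnnotations$ref_id == refId, , drop = FALSE]
  if (nrow(ann) == 0)
    stop("reference ", refId, " lacks LTR/CR annotation", call. = FALSE)
  pos <- offset:(offset + len - 1L)
  if (!is.null(unitLength)) pos <- ((pos - 1L) %% unitLength) + 1L
  ltr_n <- 0L; cr_n <- 0L; cr_groups <- character()
  for (k in seq_len(nrow(ann))) {
    inside <- sum(pos >= ann$start[k] & pos <= ann$end[k])
    if (ann$feature[k] == "LTR") ltr_n <- ltr_n + inside
    else {
      cr_n <- cr_n + inside
      if (inside > 0) cr_groups <- c(cr_groups, ann$group[k])
    }
  }
  if (ltr_n > cr_n) return("LTR")
  if (ltr_n == cr_n) return("junction")
  grp <- sort(unique(cr_groups))[1]
  gnum <- sub("^Group ", "", grp)
  paste0("CR_group", gnum)
}

# The extension cap applies at the addition of each following read, so a
# contig-contig merge is legal only when it is realizable as a sequence
# of legal single-read additions: the incoming contig's member reads,
# placed on the merged coordinates, must each overlap the growing contig
# by >= minOverlap and extend it by <= maxExtension. `ends` are the
# member-read end positions on the merged sequence beyond the base
# contig; returns the per-read extension lengths, or NULL when illegal.
simulateAdditions <- function(base_end, starts, ends, minOverlap,
                              maxExtension) {
  o <- order(ends)
  starts <- starts[o]; ends <- ends[o]
  cur <- base_end
  ext <- integer(0)
  for (k in seq_along(ends)) {
    if (ends[k] <= cur) next  # contained in what is already built
    if (cur - starts[k] + 1L < minOverlap) return(NULL)
    step <- ends[k] - cur
    if (step > maxExtension) return(NULL)
    ext <- c(ext, as.integer(step))
    cur <- ends[k]
  }
  ext
}

# legal merge of ordered pair of contigs (a, b) at the junction where a
# suffix of a equals a prefix of b (or b is contained in a). Each contig
# is list(seq, members, lens) with member offsets and read lengths.
legalMerge <- function(a, b, minOverlap, maxExtension) {
  pos <- .find_contained(a$seq, b$seq)
  if (pos > 0)
    return(list(type = "contain", ov = nchar(b$seq), ext = integer(0),
                pos = pos))
  ov <- .longest_overlap(a$seq, b$seq, minOverlap)
  if (ov == 0) return(NULL)
  la <- nchar(a$seq)
  # rightward realization: b's reads added onto a
  starts <- la - ov + b$members$offset
  ext <- simulateAdditions(la, starts, starts + b$lens - 1L,
                           minOverlap, maxExtension)
  if (is.null(ext)) {
    # leftward realization: a's reads added onto b (mirror coordinates)
    lb <- nchar(b$seq)
    merged_len <- la + lb - ov
    m_starts <- a$members$offset
    m_ends <- m_starts + a$lens - 1L
    ext <- simulateAdditions(lb,
                             merged_len - m_ends + 1L,
                             merged_len - m_starts + 1L,
                             minOverlap, maxExtension)
  }
  if (is.null(ext)) return(NULL)
  list(type = "overlap", ov = ov, ext = ext, pos = NA_integer_)
}

#' Strict zero-mismatch greedy overlap assembly
#'
#' Iterative greedy merging: at each step the read/contig pair with the
#' longest exact overlap at least `minOverlap` is merged; any mismatch
#' in the overlap forbids the merge. The extension cap applies at the
#' addition of each following read — a merge is legal only when it is
#' realizable as sequential single-read additions, each extending the
#' growing contig by at most `maxExtension` nt — which prevents foreign
#' reads from anchoring to long single-read overhangs at contig ends.
#' Ties are broken deterministically (longest overlap, then
#' lexicographically smallest contig ids), so the output is independent
#' of input read order. Unmergeable reads become singleton contigs.
#'
#' @param reads named character vector or [Biostrings::DNAStringSet];
#'   duplicate read ids are an error.
#' @param minOverlap minimum exact overlap (nt, >= 15).
#' @param maxExtension maximum new sequence added per merge (nt).
#' @return list of [StrictContig-class], sorted by decreasing length then
#'   sequence; every member placement re-verifies with zero mismatches.
#' @export
assembleStrict <- function(reads, minOverlap = 20L, maxExtension = 25L) {
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  if (is.null(names(reads)) || anyDuplicated(names(reads)))
    stop("reads must carry unique ids", call. = FALSE)
  if (minOverlap < 15) stop("minOverlap must be >= 15", call. = FALSE)
  reads <- vapply(reads, normalizeDna, "")
  # contig state: seq, members (read_id, offset), extension log, id =
  # lexicographically smallest member read id (stable under ordering)
  contigs <- lapply(names(reads), function(id) {
    list(seq = reads[[id]],
         members = data.frame(read_id = id, offset = 1L,
                              stringsAsFactors = FALSE),
         lens = nchar(reads[[id]]),
         ext = integer(0), id = id)
  })
  # incremental candidate set: merges are recomputed only for pairs
  # involving a newly created contig
  active <- seq_along(contigs)
  cand <- list()
  addCands <- function(cand, a, bs) {
    for (b in bs) {
      if (b == a) next
      for (pr in list(c(a, b), c(b, a))) {
        m <- legalMerge(contigs[[pr[1]]], contigs[[pr[2]]],
                        minOverlap, maxExtension)
        if (!is.null(m))
          cand[[length(cand) + 1L]] <- c(list(a = pr[1], b = pr[2]), m)
      }
    }
    cand
  }
  for (i in seq_along(active)) {
    later <- active[active > active[i]]
    for (b in later) {
      for (pr in list(c(active[i], b), c(b, active[i]))) {
        m <- legalMerge(contigs[[pr[1]]], contigs[[pr[2]]],
                        minOverlap, maxExtension)
        if (!is.null(m))
          cand[[length(cand) + 1L]] <- c(list(a = pr[1], b = pr[2]), m)
      }
    }
  }
  repeat {
    if (length(cand) == 0) break
    ovs <- vapply(cand, `[[`, 1L, "ov")
    pick <- which(ovs == max(ovs))
    if (length(pick) > 1) {
      keys <- vapply(pick, function(i)
        paste(contigs[[cand[[i]]$a]]$id, contigs[[cand[[i]]$b]]$id,
              sep = "\r"), "")
      pick <- pick[order(keys)]
    }
    m <- cand[[pick[1]]]
    a <- contigs[[m$a]]; b <- contigs[[m$b]]
    if (m$type == "contain") {
      b$members$offset <- b$members$offset + m$pos - 1L
      merged <- list(seq = a$seq,
                     members = rbind(a$members, b$members),
                     lens = c(a$lens, b$lens),
                     ext = c(a$ext, b$ext),
                     id = min(a$id, b$id))
    } else {
      la <- nchar(a$seq)
      newseq <- paste0(a$seq, substr(b$seq, m$ov + 1L, nchar(b$seq)))
      b$members$offset <- b$members$offset + la - m$ov
      merged <- list(seq = newseq,
                     members = rbind(a$members, b$members),
                     lens = c(a$lens, b$lens),
                     ext = c(a$ext, b$ext, m$ext),
                     id = min(a$id, b$id))
    }
    contigs[[m$a]] <- merged
    contigs[[m$b]] <- list(seq = NULL)
    active <- setdiff(active, m$b)
    dropped <- c(m$a, m$b)
    cand <- Filter(function(x) !(x$a %in% dropped || x$b %in% dropped),
                   cand)
    cand <- addCands(cand, m$a, setdiff(active, m$a))
  }
  contigs <- contigs[active]
  # deterministic output order and ids
  ord <- order(-nchar(vapply(contigs, `[[`, "", "seq")),
               vapply(contigs, `[[`, "", "seq"),
               vapply(contigs, `[[`, "", "id"))
  contigs <- contigs[ord]
  out <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    ct <- contigs[[i]]
    mem <- ct$members[order(ct$members$offset, ct$members$read_id), ,
                      drop = FALSE]
    rownames(mem) <- NULL
    # post-hoc audit: every member must match exactly at its offset
    for (k in seq_len(nrow(mem))) {
      piece <- substr(ct$seq, mem$offset[k],
                      mem$offset[k] + nchar(reads[[mem$read_id[k]]]) - 1L)
      if (piece != reads[[mem$read_id[k]]])
        stop("internal error: member placement mismatch", call. = FALSE)
    }
    out[[i]] <- new("StrictContig", id = sprintf("contig_%03d", i),
                    seq = ct$seq, members = mem,
                    extensionLog = as.integer(ct$ext))
  }
  out
}

#' Compare contigs to genomic retrozyme sequences
#'
#' Per-contig best identity against extracted genomic retrozyme
#' sequences, aligning each contig end-to-end into the reference
#' (contig-global, reference-local); identity is matches over alignment
#' columns. `identical` flags contigs with identity exactly 1.
#'
#' @param contigs list of [StrictContig-class].
#' @param genomeRefs named character vector or DNAStringSet of genomic
#'   retrozyme sequences (doubled upstream if circularity matters).
#' @return data.frame `contig_id`, `best_ref_id`, `best_identity`,
#'   `identical`.
#' @export
contigsVsGenome <- function(contigs, genomeRefs) {
  if (is(genomeRefs, "XStringSet")) genomeRefs <- as.character(genomeRefs)
  if (length(contigs) == 0)
    return(data.frame(contig_id = character(), best_ref_id = character(),
                      best_identity = numeric(), identical = logical()))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE)
  rows <- lapply(contigs, function(ct) {
    seqs_rc <- revComp(contigSeq(ct))
    best_id <- -Inf; best_ref <- NA_character_
    for (rn in sort(names(genomeRefs))) {
      for (s in c(contigSeq(ct), seqs_rc)) {
        aln <- Biostrings::pairwiseAlignment(
          pattern = Biostrings::DNAString(s),
          subject = Biostrings::DNAString(genomeRefs[[rn]]),
          type = "global-local", substitutionMatrix = mat,
          gapOpening = 1, gapExtension = 1)
        ind <- sum(Biostrings::nindel(aln)@insertion[, "WidthSum"],
                   Biostrings::nindel(aln)@deletion[, "WidthSum"])
        idn <- Biostrings::nmatch(aln) /
          (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) + ind)
        if (idn > best_id) { best_id <- idn; best_ref <- rn }
      }
    }
    data.frame(contig_id = ct@id, best_ref_id = best_ref,
               best_identity = best_id, identical = best_id == 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mismatch-bin spectrum of classified reads
#'
#' @param classifications output of [alignReadsToRefs()].
#' @return named numeric of fractions over the five bins (perfect, 1%,
#'   2%, 3-13%, >13%), summing to 1.
#' @export
mismatchSpectrum <- function(classifications) {
  stopifnot(nrow(classifications) > 0)
  tab <- table(classifications$bin)
  frac <- as.numeric(tab) / sum(tab)
  setNames(frac, names(tab))
}
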