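#' @include hammerhead.R homology-scan.R
NULL

# structural_annotation: turn homology hits into annotated retrozyme loci.

#' Count mismatches between the two LTRs of an element
#'
#' Global alignment with match +1, mismatch -1, gap -2; the returned
#' count is substitutions plus gap columns (a gap column counts as one
#' mismatch whatever its length context), giving reproducible integer
#' semantics for the 0-32 range seen between LTR pairs.
#'
#' @param ltr5Seq,ltr3Seq the two LTR sequences (nonempty).
#' @return integer mismatch count.
#' @export
countLtrMismatches <- function(ltr5Seq, ltr3Seq) {
  ltr5Seq <- normalizeDna(as.character(ltr5Seq))
  ltr3Seq <- normalizeDna(as.character(ltr3Seq))
  stopifnot(nchar(ltr5Seq) > 0, nchar(ltr3Seq) > 0)
  st <- .nw_stats(ltr5Seq, ltr3Seq, 1L, -1L, -2L)
  as.integer(st$mismatches + st$gapcols)
}

# global identity between two sequences under the same scoring
globalIdentity <- function(a, b) {
  st <- .nw_stats(as.character(a), as.character(b), 1L, -1L, -2L)
  st$identity
}

#' Detect a 4-nt target-site duplication around an element
#'
#' Returns the 4-nt flank string iff the 4 nt immediately 5' of the
#' element equal the 4 nt immediately 3' of it, exactly and with no
#' ambiguity codes. Elements at a scaffold edge yield NA (not an error).
#'
#' @param scaffoldSeq the scaffold sequence.
#' @param start,end 1-based inclusive element span on the scaffold.
#' @return the TSD string, or NA_character_.
#' @export
detectTsd <- function(scaffoldSeq, start, end) {
  scaffoldSeq <- as.character(scaffoldSeq)
  L <- nchar(scaffoldSeq)
  if (start - 4 < 1 || end + 4 > L) return(NA_character_)
  left <- substr(scaffoldSeq, start - 4, start - 1)
  right <- substr(scaffoldSeq, end + 1, end + 4)
  if (left == right && !grepl("N", left, fixed = TRUE)) left
  else NA_character_
}

#' Locate the primer-binding site at the CR 5' end
#'
#' The PBS is complementary to the 3'-terminal sequence of tRNA-Met. The
#' best (longest) interval lying entirely within the first `window` nt of
#' the CR whose reverse complement equals a 3'-terminal substring of the
#' tRNA of length >= `minComplementary` is returned. The tRNA 3' sequence
#' is a required input: no default sequence is hard-coded.
#'
#' @param crSeq central-region sequence.
#' @param trna3p 3'-terminal tRNA-Met sequence (>= `minComplementary` nt).
#' @param window search window from the CR 5' edge (nt).
#' @param minComplementary minimum complementary length (nt).
#' @return an [IRanges::IRanges] in CR-local coordinates (length 0 when
#'   no match).
#' @export
findPbs <- function(crSeq, trna3p, window = 30L, minComplementary = 10L) {
  crSeq <- normalizeDna(as.character(crSeq))
  trna3p <- normalizeDna(as.character(trna3p))
  stopifnot(nchar(trna3p) >= minComplementary)
  head_seq <- substr(crSeq, 1, min(window, nchar(crSeq)))
  for (len in seq(min(nchar(trna3p), window), minComplementary)) {
    tail3 <- substr(trna3p, nchar(trna3p) - len + 1, nchar(trna3p))
    pat <- revComp(tail3)
    pos <- .find_contained(head_seq, pat)
    if (pos > 0 && pos + len - 1 <= window)
      return(IRanges::IRanges(pos, pos + len - 1))
  }
  IRanges::IRanges()
}

#' Locate the polypurine tract at the CR 3' end
#'
#' The longest run of length >= `minLen` with purine (A/G) fraction >=
#' `minPurineFrac`, searched within the last `window` nt of the CR; ties
#' are broken by proximity to the CR 3' end.
#'
#' @param crSeq central-region sequence.
#' @param window search window from the CR 3' edge (nt).
#' @param minLen minimum run length (nt).
#' @param minPurineFrac minimum A/G fraction of the run.
#' @return an [IRanges::IRanges] in CR-local coordinates (length 0 when
#'   no qualifying run exists).
#' @export
findPpt <- function(crSeq, window = 40L, minLen = 10L,
                    minPurineFrac = 0.9) {
  crSeq <- normalizeDna(as.character(crSeq))
  L <- nchar(crSeq)
  stopifnot(window <= L)
  lo <- L - window + 1L
  tail_chars <- strsplit(substr(crSeq, lo, L), "")[[1]]
  pur <- as.integer(tail_chars %in% c("A", "G"))
  w <- length(pur)
  best <- NULL
  for (i in seq_len(w)) {
    if (i + minLen - 1L > w) break
    for (j in seq(i + minLen - 1L, w)) {
      run <- pur[i:j]
      if (mean(run) >= minPurineFrac) {
        len <- j - i + 1L
        if (is.null(best) || len > best$len ||
            (len == best$len && j > best$j)) {
          best <- list(i = i, j = j, len = len)
        }
      }
    }
  }
  if (is.null(best)) return(IRanges::IRanges())
  IRanges::IRanges(lo + best$i - 1L, lo + best$j - 1L)
}

#' Pair LTR hits into candidate retrozyme loci
#'
#' Same-scaffold, same-strand LTR hits whose widths fall in
#' `[minLtrLen, maxLtrLen]` and whose inter-LTR gap falls in
#' `[minCrLen, maxCrLen]` are paired into full-length candidates; chains
#' of three or more collinear equally spaced LTR hits are merged into one
#' element flagged `tandem`. Unpaired LTR hits adjacent to a CR hit
#' become `cr_partial` candidates; remaining unpaired hits become
#' `ltr_fragment`.
#'
#' @param hits LTR hit table ([scanGenome()] layout) from one genome.
#' @param crHits optional CR hit table used to rescue `cr_partial` loci.
#' @param minLtrLen,maxLtrLen LTR length window (nt).
#' @param minCrLen,maxCrLen inter-LTR gap window (nt).
#' @param maxCrDistance maximum gap between an unpaired LTR and a CR hit
#'   for `cr_partial` rescue (nt).
#' @return a data.frame of candidates with columns `scaffold_id`,
#'   `strand`, `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`,
#'   `cr_start`, `cr_end`, `completeness`, `tandem` (NA fields where a
#'   part is absent).
#' @export
pairLtrs <- function(hits, crHits = NULL, minLtrLen = 250L,
                     maxLtrLen = 450L, minCrLen = 100L, maxCrLen = 1500L,
                     maxCrDistance = 50L) {
  stopifnot(minLtrLen > 0, minCrLen > 0)
  cand <- list()
  add <- function(scaffold, strand, l5s, l5e, l3s, l3e, crs, cre,
                  compl, tandem) {
    cand[[length(cand) + 1L]] <<- data.frame(
      scaffold_id = scaffold, strand = strand,
      ltr5_start = l5s, ltr5_end = l5e,
      ltr3_start = l3s, ltr3_end = l3e,
      cr_start = crs, cr_end = cre,
      completeness = compl, tandem = tandem, stringsAsFactors = FALSE)
  }
  if (nrow(hits) == 0) return(do.call(rbind, cand))
  width <- hits$end - hits$start + 1L
  ltrLike <- width >= minLtrLen & width <= maxLtrLen
  key <- paste(hits$scaffold_id, hits$strand)
  for (grp in split(seq_len(nrow(hits)), key)) {
    g <- grp[order(hits$start[grp])]
    used <- rep(FALSE, length(g))
    li <- which(ltrLike[g])
    # chain adjacent LTR-like hits whose gaps are CR-sized
    i <- 1L
    while (i <= length(li)) {
      chain <- li[i]
      j <- i
      while (j < length(li)) {
        a <- g[li[j]]; b <- g[li[j + 1]]
        gap <- hits$start[b] - hits$end[a] - 1L
        if (gap >= minCrLen && gap <= maxCrLen) {
          chain <- c(chain, li[j + 1]); j <- j + 1L
        } else break
      }
      if (length(chain) >= 2) {
        first <- g[chain[1]]; last <- g[chain[length(chain)]]
        second <- g[chain[2]]
        add(hits$scaffold_id[first], hits$strand[first],
            hits$start[first], hits$end[first],
            hits$start[last], hits$end[last],
            hits$end[first] + 1L, hits$start[second] - 1L,
            "full", length(chain) > 2)
        used[chain] <- TRUE
      }
      i <- j + 1L
    }
    # unpaired hits: cr_partial rescue, else ltr_fragment
    for (idx in seq_along(g)) {
      if (used[idx]) next
      h <- g[idx]
      crs <- NA_integer_; cre <- NA_integer_
      if (!is.null(crHits) && nrow(crHits) > 0) {
        same <- crHits$scaffold_id == hits$scaffold_id[h] &
          crHits$strand == hits$strand[h]
        if (any(same)) {
          cc <- crHits[same, , drop = FALSE]
          gap_right <- cc$start - hits$end[h] - 1L
          gap_left <- hits$start[h] - cc$end - 1L
          near <- (gap_right >= 0 & gap_right <= maxCrDistance) |
                  (gap_left >= 0 & gap_left <= maxCrDistance)
          if (any(near)) {
            cc <- cc[near, , drop = FALSE][1, ]
            crs <- cc$start; cre <- cc$end
          }
        }
      }
      if (!is.na(crs)) {
        if (crs > hits$end[h]) {
          add(hits$scaffold_id[h], hits$strand[h],
              hits$start[h], hits$end[h], NA_integer_, NA_integer_,
              crs, cre, "cr_partial", FALSE)
        } else {
          add(hits$scaffold_id[h], hits$strand[h],
              NA_integer_, NA_integer_, hits$start[h], hits$end[h],
              crs, cre, "cr_partial", FALSE)
        }
      } else {
        add(hits$scaffold_id[h], hits$strand[h],
            hits$start[h], hits$end[h], NA_integer_, NA_integer_,
            NA_integer_, NA_integer_, "ltr_fragment", FALSE)
      }
    }
  }
  out <- do.call(rbind, cand)
  if (is.null(out)) return(out)
  out[order(out$scaffold_id, pmin(out$ltr5_start, out$ltr3_start,
                                  na.rm = TRUE)), , drop = FALSE]
}

#' Assign loci to groups by central-region identity
#'
#' Constrained single-linkage agglomeration on pairwise global CR
#' identity: two clusters merge when their closest pair reaches
#' `groupingIdentity`, but never when any cross pair falls below
#' `significanceIdentity` (loci with no significant CR similarity must
#' not share a group). Groups are labeled "Group 1", "Group 2", ... in
#' decreasing size order, ties broken by the lexicographically smallest
#' member id.
#'
#' @param crSeqs named character vector of CR sequences (one per locus).
#' @param groupingIdentity identity at or above which loci join a group.
#' @param significanceIdentity identity below which loci must never share
#'   a group.
#' @return a data.frame `locus_id`, `group`, `max_cr_identity_within`,
#'   `max_cr_identity_between`.
#' @export
classifyGroups <- function(crSeqs, groupingIdentity = 0.80,
                           significanceIdentity = 0.50) {
  n <- length(crSeqs)
  stopifnot(n >= 1, !is.null(names(crSeqs)))
  ids <- names(crSeqs)
  idm <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      idm[i, j] <- idm[j, i] <- globalIdentity(crSeqs[i], crSeqs[j])
    }
  }
  clusters <- as.list(seq_len(n))
  repeat {
    best <- NULL
    if (length(clusters) < 2) break
    for (a in seq_len(length(clusters) - 1)) {
      for (b in seq(a + 1, length(clusters))) {
        cross <- idm[clusters[[a]], clusters[[b]], drop = FALSE]
        if (max(cross) >= groupingIdentity &&
            min(cross) >= significanceIdentity) {
          if (is.null(best) || max(cross) > best$link)
            best <- list(a = a, b = b, link = max(cross))
        }
      }
    }
    if (is.null(best)) break
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  sizes <- vapply(clusters, length, 1L)
  firsts <- vapply(clusters, function(cl) min(ids[cl]), "")
  ord <- order(-sizes, firsts)
  clusters <- clusters[ord]
  out <- list()
  for (gi in seq_along(clusters)) {
    cl <- clusters[[gi]]
    for (i in cl) {
      within <- if (length(cl) > 1) max(idm[i, setdiff(cl, i)]) else 1
      outside <- setdiff(seq_len(n), cl)
      between <- if (length(outside)) max(idm[i, outside]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        locus_id = ids[i], group = paste("Group", gi),
        max_cr_identity_within = within,
        max_cr_identity_between = between, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out[order(match(out$locus_id, ids)), , drop = FALSE]
}

#' Predict PCR amplicons on a linear or circular template
#'
#' Primers must bind by exact match (forward primer on the sense strand,
#' reverse primer as its reverse complement on the sense strand). On a
#' circular template, binding sites are searched on the doubled sequence,
#' so divergent primer pairs yield junction-spanning amplicons; on a
#' linear template divergent primers yield nothing. Amplicon length runs
#' from the first base of the forward site to the last base of the
#' reverse site, inclusive.
#'
#' @param templateSeq template sequence.
#' @param isCircular logical.
#' @param fwdPrimer,revPrimer primer sequences (>= 15 nt, no N).
#' @param maxLen maximum amplicon length reported.
#' @return data.frame `start`, `end`, `length`, `spans_junction`
#'   (coordinates on the linear template; for circular templates `start`
#'   is normalized to `[1, L]` and `end` may exceed `L` for
#'   junction-spanning products).
#' @export
predictAmplicon <- function(templateSeq, isCircular, fwdPrimer, revPrimer,
                            maxLen = 10000L) {
  templateSeq <- normalizeDna(as.character(templateSeq))
  fwdPrimer <- normalizeDna(as.character(fwdPrimer))
  revPrimer <- normalizeDna(as.character(revPrimer))
  for (p in c(fwdPrimer, revPrimer)) {
    if (nchar(p) < 15) stop("primer shorter than 15 nt", call. = FALSE)
    if (grepl("N", p, fixed = TRUE))
      stop("primer contains N", call. = FALSE)
  }
  L <- nchar(templateSeq)
  subject <- if (isCircular) doubleCircle(templateSeq) else templateSeq
  allStarts <- function(pat) {
    IRanges::start(Biostrings::matchPattern(
      pat, Biostrings::DNAString(subject)))
  }
  f_starts <- allStarts(fwdPrimer)
  r_starts <- allStarts(revComp(revPrimer))
  if (isCircular) f_starts <- f_starts[f_starts <= L]
  out <- list()
  for (fs in f_starts) {
    fe <- fs + nchar(fwdPrimer) - 1L
    for (rs in r_starts) {
      re <- rs + nchar(revPrimer) - 1L
      if (rs <= fe) next
      len <- re - fs + 1L
      if (len > maxLen) next
      if (isCircular && len > L) next
      out[[length(out) + 1L]] <- data.frame(
        start = fs, end = re, length = len,
        spans_junction = isCircular && re > L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), spans_junction = logical()))
  do.call(rbind, out)
}

# Refine a rough LTR hit to exact boundaries: the full query is slid
# (ungapped) over a window around the hit and the minimum-mismatch
# placement is taken. Valid when copies diverge from the query by
# substitutions; hits whose width differs from the query length by more
# than `slack` are left untouched (fragments).
refineLtrBoundary <- function(scaffoldSeq, hit, query, slack = 40L) {
  qlen <- nchar(query)
  width <- hit$end - hit$start + 1L
  if (abs(width - qlen) > slack) return(hit)
  pat <- if (hit$strand == "-") revComp(query) else query
  w_lo <- max(1L, hit$start - slack)
  w_hi <- min(nchar(scaffoldSeq), hit$end + slack)
  res <- .best_offset_mismatch(pat, substr(scaffoldSeq, w_lo, w_hi))
  if (!isTRUE(res$found)) return(hit)
  hit$start <- w_lo + res$offset - 1L
  hit$end <- hit$start + qlen - 1L
  hit
}

#' Annotate retrozyme loci in genome scaffolds
#'
#' The full discovery workflow: scan scaffolds with an LTR query (and
#' optional CR queries), refine hit boundaries, pair LTRs, then annotate
#' each candidate with TSD, PBS, PPT, hammerhead ribozymes, LTR-LTR
#' mismatch count and group membership.
#'
#' @param scaffolds named [Biostrings::DNAStringSet] or character vector.
#' @param ltrQuery LTR query sequence.
#' @param crQueries optional named character vector of CR query sequences
#'   (used to rescue `cr_partial` loci).
#' @param trna3p optional tRNA-Met 3'-terminal sequence for PBS detection.
#' @param hits optional precomputed LTR hit table (e.g. [importHits()]);
#'   when given the LTR scan is skipped.
#' @param minIdentity,minLength,maxEvalue scan thresholds.
#' @param minLtrLen,maxLtrLen,minCrLen,maxCrLen pairing windows (nt).
#' @param groupingIdentity,significanceIdentity grouping thresholds.
#' @return list with `loci` (list of [RetrozymeLocus-class]), `groups`
#'   (the [classifyGroups()] table or NULL) and `hits` (refined LTR hit
#'   table).
#' @export
annotateGenome <- function(scaffolds, ltrQuery, crQueries = NULL,
                           trna3p = NULL, hits = NULL,
                           minIdentity = 0.70, minLength = 50L,
                           maxEvalue = 1e-10,
                           minLtrLen = 250L, maxLtrLen = 450L,
                           minCrLen = 100L, maxCrLen = 1500L,
                           groupingIdentity = 0.80,
                           significanceIdentity = 0.50) {
  if (is(scaffolds, "XStringSet")) scaffolds <- as.character(scaffolds)
  scaffolds <- vapply(scaffolds, normalizeDna, "")
  ltrQuery <- normalizeDna(as.character(ltrQuery))
  if (is.null(hits))
    hits <- scanGenome(scaffolds, ltrQuery, queryId = "LTR",
                       minIdentity = minIdentity, minLength = minLength,
                       maxEvalue = maxEvalue)
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      hits[i, c("start", "end", "strand")] <- refineLtrBoundary(
        scaffolds[[hits$scaffold_id[i]]], hits[i, ], ltrQuery
      )[c("start", "end", "strand")]
    }
  }
  crHits <- NULL
  if (!is.null(crQueries)) {
    crHits <- do.call(rbind, lapply(names(crQueries), function(qid) {
      scanGenome(scaffolds, crQueries[[qid]], queryId = qid,
                 minIdentity = minIdentity, minLength = minLength,
                 maxEvalue = maxEvalue)
    }))
  }
  cand <- pairLtrs(hits, crHits = crHits, minLtrLen = minLtrLen,
                   maxLtrLen = maxLtrLen, minCrLen = minCrLen,
                   maxCrLen = maxCrLen)
  loci <- list()
  if (!is.null(cand) && nrow(cand) > 0) {
    for (i in seq_len(nrow(cand))) {
      row <- cand[i, ]
      seq <- scaffolds[[row$scaffold_id]]
      id <- sprintf("RZ%03d", i)
      ltr5 <- if (!is.na(row$ltr5_start))
        IRanges::IRanges(row$ltr5_start, row$ltr5_end) else IRanges::IRanges()
      ltr3 <- if (!is.na(row$ltr3_start))
        IRanges::IRanges(row$ltr3_start, row$ltr3_end) else IRanges::IRanges()
      cr <- if (!is.na(row$cr_start))
        IRanges::IRanges(row$cr_start, row$cr_end) else IRanges::IRanges()
      span_lo <- min(row$ltr5_start, row$ltr3_start, row$cr_start,
                     na.rm = TRUE)
      span_hi <- max(row$ltr5_end, row$ltr3_end, row$cr_end, na.rm = TRUE)
      tsd_s <- detectTsd(seq, span_lo, span_hi)
      mism <- NA_integer_
      rz <- list()
      ltr5_seq <- if (length(ltr5)) substr(seq, IRanges::start(ltr5),
                                           IRanges::end(ltr5)) else NULL
      ltr3_seq <- if (length(ltr3)) substr(seq, IRanges::start(ltr3),
                                           IRanges::end(ltr3)) else NULL
      if (row$strand == "-") {
        if (!is.null(ltr5_seq)) ltr5_seq <- revComp(ltr5_seq)
        if (!is.null(ltr3_seq)) ltr3_seq <- revComp(ltr3_seq)
      }
      if (!is.null(ltr5_seq) && !is.null(ltr3_seq))
        mism <- countLtrMismatches(ltr5_seq, ltr3_seq)
      for (nm in c("ltr5", "ltr3")) {
        s <- if (nm == "ltr5") ltr5_seq else ltr3_seq
        if (is.null(s) || nchar(s) < 40) next
        m <- detectHammerhead(s)
        if (length(m)) rz[[nm]] <- m[[1]]
      }
      pbs_r <- IRanges::IRanges(); ppt_r <- IRanges::IRanges()
      cr_seq <- NULL
      if (length(cr)) {
        cr_seq <- substr(seq, IRanges::start(cr), IRanges::end(cr))
        if (row$strand == "-") cr_seq <- revComp(cr_seq)
        if (!is.null(trna3p))
          pbs_r <- findPbs(cr_seq, trna3p)
        if (nchar(cr_seq) >= 40)
          ppt_r <- findPpt(cr_seq)
      }
      loci[[id]] <- new("RetrozymeLocus", id = id,
        scaffoldId = row$scaffold_id, strand = row$strand,
        ltr5 = ltr5, ltr3 = ltr3, cr = cr,
        tsd = if (row$completeness == "full") tsd_s else NA_character_,
        pbs = pbs_r, ppt = ppt_r, ribozymes = rz,
        ltrMismatches = mism, group = NA_character_,
        completeness = row$completeness,
        tandem = isTRUE(row$tandem))
    }
  }
  groups <- NULL
  withCr <- vapply(loci, function(l) length(l@cr) == 1, TRUE)
  if (any(withCr)) {
    crSeqs <- vapply(loci[withCr], function(l) {
      s <- substr(scaffolds[[l@scaffoldId]], IRanges::start(l@cr),
                  IRanges::end(l@cr))
      if (l@strand == "-") revComp(s) else s
    }, "")
    groups <- classifyGroups(crSeqs,
                             groupingIdentity = groupingIdentity,
                             significanceIdentity = significanceIdentity)
    for (k in seq_len(nrow(groups))) {
      loci[[groups$locus_id[k]]]@group <- groups$group[k]
    }
  }
  list(loci = loci, groups = groups, hits = hits)
}
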