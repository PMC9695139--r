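#' @include seq-io.R
NULL

# Descriptor-based Type III hammerhead ribozyme search. The motif is
# modeled on the conserved catalytic core (box 1 CUGANGA, box 2 GAAA)
# plus three Watson-Crick helices, laid out 5'->3' as
#
#   [helix III 5' arm] CUGANGA [helix II 5' arm ... helix II 3' arm]
#   GAAA [helix I 5' arm ... helix I 3' arm] N-U-H | [helix III 3' arm]
#
# where "|" is the scissile bond: cleavage occurs immediately 3' of the
# NUH triplet closing helix I, so helix III spans the cleavage site and,
# on a circular monomer, closes the circle. All matching is done on the
# DNA alphabet (U == T). This is a structure descriptor, not a
# thermodynamic fold: minimum-free-energy prediction is out of scope.

HH_BOX1 <- "CTGANGA"
HH_BOX2 <- "GAAA"
HH_MIN_STEM <- 3L
HH_MAX_STEM <- 8L
HH_BOX_GAP <- c(10L, 60L)   # nt between box1 end and box2 start
HH_MAX_CLEAVAGE_DIST <- 60L # nt between box2 end and cleavage site

wcPair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G")
}

# length of the consecutive WC stem pairing s[a5 + i] with s[b3 - i]
# (i = 0, 1, ...), growing outward-in; 0 when the first pair fails.
stemLength <- function(chars, a5, b3, maxLen = HH_MAX_STEM) {
  n <- 0L
  while (n < maxLen) {
    i <- a5 + n; j <- b3 - n
    if (i > j || i < 1 || j > length(chars)) break
    if (!wcPair(chars[i], chars[j])) break
    n <- n + 1L
  }
  n
}

# conserved catalytic residues: all box-1 positions except the N, and all
# of box 2. Returns a data.frame of substitutions (0 rows if intact).
coreMismatches <- function(chars, b1, b2) {
  pat1 <- strsplit(HH_BOX1, "")[[1]]
  pat2 <- strsplit(HH_BOX2, "")[[1]]
  subs <- list()
  for (i in seq_along(pat1)) {
    if (pat1[i] == "N") next
    obs <- chars[b1 + i - 1L]
    if (obs != pat1[i])
      subs[[length(subs) + 1L]] <- data.frame(
        position = b1 + i - 1L, observed = obs, expected = pat1[i],
        stringsAsFactors = FALSE)
  }
  for (i in seq_along(pat2)) {
    obs <- chars[b2 + i - 1L]
    if (obs != pat2[i])
      subs[[length(subs) + 1L]] <- data.frame(
        position = b2 + i - 1L, observed = obs, expected = pat2[i],
        stringsAsFactors = FALSE)
  }
  if (length(subs) == 0)
    data.frame(position = integer(), observed = character(),
               expected = character(), stringsAsFactors = FALSE)
  else do.call(rbind, subs)
}

boxCandidates <- function(seq, pattern, maxMismatch) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                max.mismatch = maxMismatch, fixed = FALSE)
  s <- IRanges::start(m)
  # drop out-of-limit matches hanging off the sequence edges
  s[s >= 1 & s + nchar(pattern) - 1 <= nchar(seq)]
}

#' Detect Type III hammerhead ribozymes by structure descriptor
#'
#' Searches for the conserved catalytic core (box 1 `CUGANGA`, box 2
#' `GAAA` 10-60 nt downstream) and validates three Watson-Crick helices:
#' helix II between the segments adjacent to the boxes, helix I between
#' the segment following box 2 and the segment preceding the cleavage
#' triplet, and helix III flanking the catalytic core across the cleavage
#' site. Each helix must form at least 3 consecutive pairs. The cleavage
#' site is placed immediately 3' of the NUH triplet (H = A, C or U)
#' closing helix I; the reported `cleavageSite` is the 1-based position
#' of the first nucleotide of the downstream product.
#'
#' Up to one substitution at the conserved catalytic residues is
#' tolerated; such matches are reported with `coreIntact = FALSE` and the
#' substitutions listed.
#'
#' @param seq a DNA/RNA sequence (character or XString), length >= 40.
#' @return a list of [RibozymeMatch-class] (empty when no match). At most
#'   one match is reported per box-1 position (the one with the smallest
#'   box-2 position, then the smallest cleavage site).
#' @export
detectHammerhead <- function(seq) {
  seq <- normalizeDna(as.character(seq))
  if (nchar(seq) < 40) stop("sequence shorter than 40 nt", call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  matches <- list()
  for (b1 in boxCandidates(seq, HH_BOX1, 1L)) {
    b1_end <- b1 + 6L
    if (b1 < 1 + HH_MIN_STEM) next  # room for helix III 5' arm
    found <- NULL
    for (b2 in boxCandidates(seq, HH_BOX2, 1L)) {
      gap <- b2 - b1_end - 1L
      if (gap < HH_BOX_GAP[1] || gap > HH_BOX_GAP[2]) next
      nsub <- nrow(coreMismatches(chars, b1, b2))
      if (nsub > 1) next
      # helix II: box1-adjacent vs box2-adjacent segments of the gap
      s2 <- stemLength(chars, b1_end + 1L, b2 - 1L,
                       maxLen = min(HH_MAX_STEM, gap %/% 2L))
      if (s2 < HH_MIN_STEM) next
      b2_end <- b2 + 3L
      # cleavage candidates: NUH triplet at c-3..c-1, helix I closing it
      c_lo <- b2_end + 2L * HH_MIN_STEM + 4L  # arms >= 3 + NUH
      c_hi <- min(L - HH_MIN_STEM + 1L, b2_end + HH_MAX_CLEAVAGE_DIST)
      if (c_lo > c_hi) next
      for (cs in c_lo:c_hi) {
        if (chars[cs - 2L] != "T") next
        if (!chars[cs - 1L] %in% c("A", "C", "T")) next
        s1 <- stemLength(chars, b2_end + 1L, cs - 4L,
                         maxLen = min(HH_MAX_STEM,
                                      (cs - 4L - b2_end) %/% 2L))
        if (s1 < HH_MIN_STEM) next
        # helix III: upstream of box1 pairs with downstream of cleavage
        s3 <- 0L
        while (s3 < HH_MAX_STEM) {
          i <- b1 - 1L - s3; j <- cs + s3
          if (i < 1 || j > L || !wcPair(chars[i], chars[j])) break
          s3 <- s3 + 1L
        }
        if (s3 < HH_MIN_STEM) next
        found <- list(b2 = b2, cs = cs, s1 = s1, s2 = s2, s3 = s3)
        break
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) next
    b2 <- found$b2; cs <- found$cs
    subs <- coreMismatches(chars, b1, b2)
    stems <- data.frame(
      helix = c("I", "II", "III"),
      start5 = c(b2 + 4L, b1_end + 1L, b1 - found$s3),
      end5 = c(b2 + 3L + found$s1, b1_end + found$s2, b1 - 1L),
      start3 = c(cs - 3L - found$s1, b2 - found$s2, cs),
      end3 = c(cs - 4L, b2 - 1L, cs + found$s3 - 1L),
      length = c(found$s1, found$s2, found$s3),
      stringsAsFactors = FALSE)
    matches[[length(matches) + 1L]] <- new(
      "RibozymeMatch",
      start = b1 - found$s3, end = cs + found$s3 - 1L,
      box1Pos = as.integer(b1), box2Pos = as.integer(b2),
      stems = stems, cleavageSite = as.integer(cs),
      coreIntact = nrow(subs) == 0L, coreSubstitutions = subs)
  }
  matches
}

#' Excise the unit-length monomer between two ribozyme cleavage sites
#'
#' Retrozyme primary transcripts spanning LTR-CR-LTR carry a ribozyme in
#' each LTR; self-cleavage at both sites releases the unit-length
#' monomer whose first nucleotide is the nucleotide immediately 3' of the
#' first scissile bond (a G in the elements studied).
#'
#' @param transcriptSeq the transcript sequence.
#' @param ribozymeMatches list of [RibozymeMatch-class] located on the
#'   transcript (e.g. from [detectHammerhead()]).
#' @return the monomer sequence between the first and second cleavage
#'   site, or NULL when fewer than two sites are present.
#' @export
exciseMonomer <- function(transcriptSeq, ribozymeMatches) {
  transcriptSeq <- normalizeDna(as.character(transcriptSeq))
  sites <- sort(vapply(ribozymeMatches, cleavageSite, 1L))
  if (length(sites) < 2) return(NULL)
  substr(transcriptSeq, sites[1], sites[2] - 1L)
}
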