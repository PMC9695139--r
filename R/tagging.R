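#' @include rna-population.R
NULL

#' The 24-nt artificial tag sequence
#'
#' The artificial tag inserted into a cloned retrozyme copy (in a hairpin
#' loop of the central region) to distinguish transgene-derived retrozyme
#' RNA from genome-encoded copies in transport and replication assays.
#'
#' @return the tag sequence (character).
#' @export
retrozymeTag <- function() "GATTACAAGGATGACGATGACAAG"

#' Insert a tag into a sequence
#'
#' @param seq the sequence to tag.
#' @param position 1-based position after which the tag is inserted.
#' @param tag tag sequence (default [retrozymeTag()]).
#' @return the tagged sequence.
#' @export
insertTag <- function(seq, position, tag = retrozymeTag()) {
  seq <- normalizeDna(as.character(seq))
  stopifnot(position >= 0, position <= nchar(seq))
  paste0(substr(seq, 1, position), normalizeDna(tag),
         substr(seq, position + 1, nchar(seq)))
}

#' Detect insertions in a sequence relative to a reference
#'
#' Global alignment of the query against the reference; runs of gap
#' columns in the reference correspond to inserted segments in the
#' query, which are reported with their reference position, length and
#' sequence. Used to recover tag insertions from sequenced amplicons.
#'
#' @param querySeq the (possibly tagged) sequence.
#' @param refSeq the untagged reference.
#' @return data.frame `ref_position` (reference base preceding the
#'   insertion), `length`, `sequence`.
#' @export
detectInsertion <- function(querySeq, refSeq) {
  querySeq <- normalizeDna(as.character(querySeq))
  refSeq <- normalizeDna(as.character(refSeq))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(querySeq),
    subject = Biostrings::DNAString(refSeq),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  rows <- list()
  k <- 1L; rp <- 0L
  while (k <= length(sub)) {
    if (sub[k] == "-") {
      j <- k
      while (j <= length(sub) && sub[j] == "-") j <- j + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        ref_position = rp, length = j - k,
        sequence = paste(pat[k:(j - 1L)], collapse = ""),
        stringsAsFactors = FALSE)
      k <- j
    } else {
      rp <- rp + 1L
      k <- k + 1L
    }
  }
  if (length(rows) == 0)
    return(data.frame(ref_position = integer(), length = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
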