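#' @include AllClasses.R
NULL

# seq_io: format readers/writers and circular-sequence utilities.
# DNA is normalized on ingest: uppercased, U mapped to T. N is tolerated
# in genome scaffolds but rejected in primers/queries by their consumers.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

normalizeDna <- function(x) {
  x <- chartr("u", "T", toupper(x))
  chartr("U", "T", x)
}

checkDnaAlphabet <- function(x, where = "sequence", allow_n = TRUE) {
  ok <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", ok), x)
  if (any(bad))
    stop(sprintf("%s contains characters outside {%s}: %s",
                 where, paste(strsplit(ok, "")[[1]], collapse = ","),
                 substr(x[bad][1], 1, 40)), call. = FALSE)
  invisible(x)
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTA file of DNA sequences
#'
#' Wraps [Biostrings::readDNAStringSet()] with a structural pre-check that
#' reports malformed headers, empty records and duplicate ids with the
#' offending line number. Sequences are uppercased and U is mapped to T.
#'
#' @param path path to an (optionally gzipped) FASTA file.
#' @param allowN allow N in sequences (TRUE for genome scaffolds).
#' @return a named [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path, allowN = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0)
    stop("FASTA parse error at line 1: no '>' header found", call. = FALSE)
  if (hdr[1] > 1) {
    pre <- lines[seq_len(hdr[1] - 1)]
    stray <- which(nzchar(trimws(pre)) & !grepl("^;", pre))
    if (length(stray))
      stop("FASTA parse error at line ", stray[1],
           ": sequence before first header", call. = FALSE)
  }
  ids <- sub("^>\\s*(\\S*).*$", "\\1", lines[hdr])
  empty_id <- which(!nzchar(ids))
  if (length(empty_id))
    stop("FASTA parse error at line ", hdr[empty_id[1]],
         ": empty record id", call. = FALSE)
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("FASTA parse error at line ", hdr[dup[1]],
         ": duplicate record id '", ids[dup[1]], "'", call. = FALSE)
  # every record must contain at least one non-empty sequence line
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    lo <- hdr[i] + 1L
    hi <- bounds[i + 1L] - 1L
    body <- if (lo > hi) character(0) else lines[lo:hi]
    if (!any(nzchar(trimws(body))))
      stop("FASTA parse error at line ", hdr[i], ": empty record '",
           ids[i], "'", call. = FALSE)
  }
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- normalizeDna(as.character(x))
  checkDnaAlphabet(seqs, where = paste0("FASTA record in ", path),
                   allow_n = allowN)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a FASTA file
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  if (!is(seqs, "XStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Read a 4-line-record FASTQ file
#'
#' Enforces the quality/sequence length contract of 100-nt single-end
#' style libraries: a record whose quality string length differs from its
#' sequence length is a parse error naming the record.
#'
#' @param path path to an (optionally gzipped) FASTQ file.
#' @return a named [Biostrings::DNAStringSet] with a `qualities` metadata
#'   column holding the per-base quality strings.
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[seq_len(length(lines))]
  if (length(lines) == 0) {
    out <- Biostrings::DNAStringSet()
    mcols(out) <- DataFrame(qualities = character(0))
    return(out)
  }
  if (length(lines) %% 4 != 0)
    stop("FASTQ parse error: line count ", length(lines),
         " is not a multiple of 4", call. = FALSE)
  n <- length(lines) / 4
  ids <- lines[seq(1, by = 4, length.out = n)]
  seqs <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  quals <- lines[seq(4, by = 4, length.out = n)]
  bad_at <- which(!startsWith(ids, "@"))
  if (length(bad_at))
    stop("FASTQ parse error at line ", (bad_at[1] - 1) * 4 + 1,
         ": expected '@' header", call. = FALSE)
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus))
    stop("FASTQ parse error at line ", (bad_plus[1] - 1) * 4 + 3,
         ": expected '+' separator", call. = FALSE)
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len))
    stop("FASTQ parse error at line ", (bad_len[1] - 1) * 4 + 4,
         ": quality length ", nchar(quals[bad_len[1]]),
         " != sequence length ", nchar(seqs[bad_len[1]]), call. = FALSE)
  ids <- sub("^@\\s*(\\S*).*$", "\\1", ids)
  seqs <- normalizeDna(seqs)
  checkDnaAlphabet(seqs, where = paste0("FASTQ record in ", path))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  mcols(out) <- DataFrame(qualities = quals)
  out
}

#' Write a FASTQ file
#'
#' @param reads named character vector or DNAStringSet; a `qualities`
#'   metadata column is used when present, otherwise constant "I".
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  qual <- NULL
  if (is(reads, "XStringSet") && !is.null(mcols(reads)$qualities))
    qual <- mcols(reads)$qualities
  seqs <- as.character(reads)
  if (is.null(qual)) qual <- strrep("I", nchar(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Rotate a circular sequence
#'
#' `rotateCircle(s, k)` returns the circular permutation starting at
#' position `k + 1`; the length is preserved and `rotateCircle(s, 0)` is
#' the identity. Offsets compose modulo the sequence length, but an
#' offset outside `[0, nchar(s) - 1]` is an error.
#'
#' @param seq a single character sequence.
#' @param offset integer in `[0, nchar(seq) - 1]`.
#' @return the rotated sequence.
#' @export
rotateCircle <- function(seq, offset) {
  stopifnot(is.character(seq), length(seq) == 1)
  L <- nchar(seq)
  if (length(offset) != 1 || is.na(offset) || offset < 0 || offset >= L)
    stop("offset must be in [0, ", L - 1, "]", call. = FALSE)
  if (offset == 0) return(seq)
  paste0(substr(seq, offset + 1, L), substr(seq, 1, offset))
}

#' Double a sequence for circular matching
#'
#' Junction-spanning matches on a circle of length L appear as linear
#' matches on the doubled sequence with a start position in `[1, L]`.
#'
#' @param seq a single character sequence.
#' @return `seq` concatenated with itself.
#' @export
doubleCircle <- function(seq) paste0(seq, seq)

#' Write annotated loci as GFF3
#'
#' Emits one parent `retrozyme` feature per locus with child features
#' `LTR5`, `LTR3`, `CR`, `PBS`, `PPT`, `TSD` and `ribozyme` where present
#' (PBS/PPT/ribozyme coordinates are lifted from local to scaffold
#' coordinates). Attributes carry the group label, completeness class and
#' LTR mismatch count. Coordinates follow the GFF3 1-based inclusive
#' convention.
#'
#' @param loci list of [RetrozymeLocus-class].
#' @param path output path.
#' @param scaffoldLengths optional named integer vector; when given,
#'   features outside their scaffold are an error.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(loci, path, scaffoldLengths = NULL) {
  rows <- list()
  addRow <- function(seqid, type, start, end, strand, attrs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = seqid, source = "retrozymer", type = type,
      start = start, end = end, score = ".", strand = strand,
      phase = ".", attributes = attrs, stringsAsFactors = FALSE)
  }
  for (loc in loci) {
    stopifnot(is(loc, "RetrozymeLocus"))
    span <- locusSpan(loc)
    if (!is.null(scaffoldLengths)) {
      L <- scaffoldLengths[[loc@scaffoldId]]
      if (is.null(L) || IRanges::start(span) < 1 || IRanges::end(span) > L)
        stop("locus ", loc@id, " lies outside scaffold ", loc@scaffoldId,
             call. = FALSE)
    }
    pid <- loc@id
    addRow(loc@scaffoldId, "retrozyme",
           IRanges::start(span), IRanges::end(span), loc@strand,
           sprintf("ID=%s;completeness=%s;group=%s;ltr_mismatches=%s;tandem=%s%s",
                   pid, loc@completeness,
                   ifelse(is.na(loc@group), "NA", loc@group),
                   ifelse(is.na(loc@ltrMismatches), "NA",
                          loc@ltrMismatches),
                   tolower(loc@tandem),
                   ifelse(is.na(loc@tsd), "", paste0(";tsd=", loc@tsd))))
    child <- function(type, rng, extra = "") {
      if (length(rng) == 0) return()
      addRow(loc@scaffoldId, type, IRanges::start(rng), IRanges::end(rng),
             loc@strand,
             sprintf("ID=%s_%s;Parent=%s%s", pid, tolower(type), pid, extra))
    }
    child("LTR5", loc@ltr5)
    child("LTR3", loc@ltr3)
    child("CR", loc@cr)
    if (length(loc@cr) == 1) {
      cr0 <- IRanges::start(loc@cr) - 1L
      if (length(loc@pbs) == 1)
        child("PBS", IRanges::shift(loc@pbs, cr0))
      if (length(loc@ppt) == 1)
        child("PPT", IRanges::shift(loc@ppt, cr0))
    }
    if (!is.na(loc@tsd) && length(loc@ltr5) == 1) {
      addRow(loc@scaffoldId, "TSD",
             IRanges::start(span) - 4L, IRanges::start(span) - 1L,
             loc@strand, sprintf("ID=%s_tsd5;Parent=%s", pid, pid))
      addRow(loc@scaffoldId, "TSD",
             IRanges::end(span) + 1L, IRanges::end(span) + 4L,
             loc@strand, sprintf("ID=%s_tsd3;Parent=%s", pid, pid))
    }
    rzn <- 0L
    for (nm in names(loc@ribozymes)) {
      rz <- loc@ribozymes[[nm]]
      base <- if (identical(nm, "ltr3") && length(loc@ltr3) == 1)
        IRanges::start(loc@ltr3) - 1L
      else if (length(loc@ltr5) == 1) IRanges::start(loc@ltr5) - 1L
      else 0L
      rzn <- rzn + 1L
      addRow(loc@scaffoldId, "ribozyme", base + rz@start, base + rz@end,
             loc@strand,
             sprintf("ID=%s_rz%d;Parent=%s;core_intact=%s;cleavage_site=%d",
                     pid, rzn, pid, tolower(rz@coreIntact),
                     base + rz@cleavageSite))
    }
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write locus spans as BED6
#'
#' One line per locus covering its full element span. Internal 1-based
#' inclusive coordinates are converted to the BED 0-based half-open
#' convention at this boundary.
#'
#' @param loci list of [RetrozymeLocus-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (loc in loci) {
    span <- locusSpan(loc)
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       loc@scaffoldId, IRanges::start(span) - 1L,
                       IRanges::end(span), loc@id, loc@strand), con)
  }
  invisible(path)
}

#' Read a GFF3 file into a GRanges
#'
#' Thin wrapper over [rtracklayer::import()]; used for round-trip checks
#' of [writeGff3()] output.
#'
#' @param path GFF3 path.
#' @return a [GenomicRanges::GRanges].
#' @export
readGff3 <- function(path) rtracklayer::import(path, format = "gff3")

#' Write a TSV with a header row
#'
#' @param df a data.frame.
#' @param path output path.
#' @param comments optional character vector written as leading '#' lines.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [writeTsv()]
#'
#' @param path input path.
#' @return a data.frame ('#' comment lines skipped).
#' @export
readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
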