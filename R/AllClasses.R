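#' @include retrozymer-package.R
NULL

# Central S4 containers. Coordinates throughout are 1-based inclusive
# (IRanges convention); optional intervals are length-0 IRanges.

#' Hammerhead ribozyme descriptor hit
#'
#' A single Type III hammerhead ribozyme match found by
#' [detectHammerhead()], in element-local coordinates. `cleavageSite` is
#' the 1-based position of the first nucleotide of the downstream cleavage
#' product; the scissile phosphodiester bond lies immediately 5' of it.
#'
#' @slot start,end integer, span of the motif (helix III arm to helix III
#'   arm) on the query sequence.
#' @slot box1Pos integer, start of catalytic core box 1 (CUGANGA).
#' @slot box2Pos integer, start of catalytic core box 2 (GAAA).
#' @slot stems data.frame with one row per helix (I, II, III):
#'   `helix`, `start5`, `end5`, `start3`, `end3`, `length`.
#' @slot cleavageSite integer, see description.
#' @slot coreIntact logical; FALSE when any conserved catalytic residue is
#'   substituted.
#' @slot coreSubstitutions data.frame `position`, `observed`, `expected`.
#' @exportClass RibozymeMatch
setClass("RibozymeMatch",
  representation(start = "integer", end = "integer",
                 box1Pos = "integer", box2Pos = "integer",
                 stems = "data.frame", cleavageSite = "integer",
                 coreIntact = "logical", coreSubstitutions = "data.frame"))

setValidity("RibozymeMatch", function(object) {
  msg <- character()
  if (object@box1Pos >= object@box2Pos)
    msg <- c(msg, "box1Pos must precede box2Pos")
  if (nrow(object@coreSubstitutions) > 0 && object@coreIntact)
    msg <- c(msg, "coreIntact must be FALSE when core substitutions exist")
  if (length(msg)) msg else TRUE
})

#' Annotated retrozyme locus
#'
#' A genomic retrozyme element: an LTR pair flanking a central region
#' (CR), with optional target-site duplication (TSD), primer-binding site
#' (PBS), polypurine tract (PPT) and per-LTR hammerhead ribozyme matches.
#' `ltr5`/`ltr3` name the left/right LTR in plus-strand scaffold
#' coordinates; the biological orientation is given by `strand`.
#'
#' @slot id character locus identifier.
#' @slot scaffoldId character scaffold of origin.
#' @slot strand "+" or "-".
#' @slot ltr5,ltr3,cr,pbs,ppt [IRanges::IRanges] (length 0 when absent);
#'   `pbs`/`ppt` are in CR-local coordinates.
#' @slot tsd 4-nt character or NA.
#' @slot ribozymes list of [RibozymeMatch-class] (LTR-local coordinates,
#'   one entry per LTR where detected).
#' @slot ltrMismatches integer, mismatch count (substitutions plus gap
#'   columns) between the two LTRs; NA unless both LTRs present.
#' @slot group character group label or NA.
#' @slot completeness one of "full", "cr_partial", "ltr_fragment".
#' @slot tandem logical, TRUE for merged tandem-repeat elements.
#' @exportClass RetrozymeLocus
setClass("RetrozymeLocus",
  representation(id = "character", scaffoldId = "character",
                 strand = "character",
                 ltr5 = "IRanges", ltr3 = "IRanges", cr = "IRanges",
                 tsd = "character", pbs = "IRanges", ppt = "IRanges",
                 ribozymes = "list", ltrMismatches = "integer",
                 group = "character", completeness = "character",
                 tandem = "logical"))

setValidity("RetrozymeLocus", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (!object@completeness %in% c("full", "cr_partial", "ltr_fragment"))
    msg <- c(msg, "unknown completeness class")
  if (object@completeness == "full" &&
      (length(object@ltr5) == 0 || length(object@ltr3) == 0 ||
       length(object@cr) == 0))
    msg <- c(msg, "'full' requires both LTRs and a CR")
  if (length(object@ltr5) == 1 && length(object@cr) == 1 &&
      length(object@ltr3) == 1) {
    if (!(IRanges::end(object@ltr5) < IRanges::start(object@cr) &&
          IRanges::end(object@cr) < IRanges::start(object@ltr3)))
      msg <- c(msg, "expected ltr5 < cr < ltr3 in plus-strand coordinates")
  }
  if (!is.na(object@tsd) && nchar(object@tsd) != 4L)
    msg <- c(msg, "TSD, when present, must be exactly 4 nt")
  if (length(msg)) msg else TRUE
})

#' Strict zero-mismatch contig
#'
#' A contig built by [assembleStrict()]: every member read matches the
#' contig exactly at its recorded offset, and every merge extended the
#' contig by at most the configured cap.
#'
#' @slot id character contig id.
#' @slot seq character contig sequence.
#' @slot members data.frame `read_id`, `offset` (1-based placement).
#' @slot extensionLog integer vector of per-merge extension lengths (nt).
#' @exportClass StrictContig
setClass("StrictContig",
  representation(id = "character", seq = "character",
                 members = "data.frame", extensionLog = "integer"))

setValidity("StrictContig", function(object) {
  msg <- character()
  m <- object@members
  if (!all(c("read_id", "offset") %in% names(m)))
    msg <- c(msg, "members must have read_id and offset")
  if (length(msg)) msg else TRUE
})

#' Small-RNA profile
#'
#' Length and region (LTR vs CR) histograms of retrozyme-specific small
#' RNAs, as produced by [profileSmallRnas()].
#'
#' @slot lengthHist named integer, read count per length (nt).
#' @slot regionHist named integer with entries "LTR" and "CR".
#' @slot nTotal integer number of retrozyme-specific reads.
#' @slot nDropped integer reads outside 18-30 nt or with no exact match.
#' @slot ltrFraction numeric, `regionHist["LTR"] / nTotal`.
#' @exportClass SmallRnaProfile
setClass("SmallRnaProfile",
  representation(lengthHist = "integer", regionHist = "integer",
                 nTotal = "integer", nDropped = "integer",
                 ltrFraction = "numeric"))

setValidity("SmallRnaProfile", function(object) {
  msg <- character()
  if (object@nTotal > 0 && sum(object@lengthHist) != object@nTotal)
    msg <- c(msg, "lengthHist must sum to nTotal")
  if (length(msg)) msg else TRUE
})

#' Per-cytosine methylation calls
#'
#' One row of `calls` per sequenced clone, one column per reference-strand
#' cytosine; entries are "methylated", "unmethylated" or "uncallable".
#' Site contexts are CpG, CHG or CHH (H = A, C or T) read off the
#' reference.
#'
#' @slot referenceId character.
#' @slot sites data.frame `position`, `context`.
#' @slot calls character matrix, clones x sites.
#' @exportClass MethylationTable
setClass("MethylationTable",
  representation(referenceId = "character", sites = "data.frame",
                 calls = "matrix"))

setValidity("MethylationTable", function(object) {
  msg <- character()
  if (ncol(object@calls) != nrow(object@sites))
    msg <- c(msg, "calls columns must match sites rows")
  bad <- setdiff(unique(as.vector(object@calls)),
                 c("methylated", "unmethylated", "uncallable"))
  if (length(bad)) msg <- c(msg, "invalid call labels")
  if (!all(object@sites$context %in% c("CpG", "CHG", "CHH")))
    msg <- c(msg, "invalid context labels")
  if (length(msg)) msg else TRUE
})
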