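#' @include AllClasses.R
NULL

#' Accessors for retrozymer S4 classes
#'
#' Small accessor generics so downstream code never touches slots.
#'
#' @param x an object of the documented class.
#' @return the slot value; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cleavageSite", function(x) standardGeneric("cleavageSite"))
#' @rdname accessors
#' @export
setMethod("cleavageSite", "RibozymeMatch", function(x) x@cleavageSite)

#' @rdname accessors
#' @export
setGeneric("coreIntact", function(x) standardGeneric("coreIntact"))
#' @rdname accessors
#' @export
setMethod("coreIntact", "RibozymeMatch", function(x) x@coreIntact)

#' @rdname accessors
#' @export
setGeneric("coreSubstitutions",
           function(x) standardGeneric("coreSubstitutions"))
#' @rdname accessors
#' @export
setMethod("coreSubstitutions", "RibozymeMatch",
          function(x) x@coreSubstitutions)

#' @rdname accessors
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))
#' @rdname accessors
#' @export
setMethod("locusId", "RetrozymeLocus", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("completeness", function(x) standardGeneric("completeness"))
#' @rdname accessors
#' @export
setMethod("completeness", "RetrozymeLocus", function(x) x@completeness)

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setMethod("groupLabel", "RetrozymeLocus", function(x) x@group)

#' @rdname accessors
#' @export
setGeneric("ltrMismatches", function(x) standardGeneric("ltrMismatches"))
#' @rdname accessors
#' @export
setMethod("ltrMismatches", "RetrozymeLocus", function(x) x@ltrMismatches)

#' @rdname accessors
#' @export
setGeneric("tsd", function(x) standardGeneric("tsd"))
#' @rdname accessors
#' @export
setMethod("tsd", "RetrozymeLocus", function(x) x@tsd)

#' @rdname accessors
#' @export
setGeneric("ribozymes", function(x) standardGeneric("ribozymes"))
#' @rdname accessors
#' @export
setMethod("ribozymes", "RetrozymeLocus", function(x) x@ribozymes)

#' @rdname accessors
#' @export
setGeneric("ltr5", function(x) standardGeneric("ltr5"))
#' @rdname accessors
#' @export
setMethod("ltr5", "RetrozymeLocus", function(x) x@ltr5)

#' @rdname accessors
#' @export
setGeneric("ltr3", function(x) standardGeneric("ltr3"))
#' @rdname accessors
#' @export
setMethod("ltr3", "RetrozymeLocus", function(x) x@ltr3)

#' @rdname accessors
#' @export
setGeneric("centralRegion", function(x) standardGeneric("centralRegion"))
#' @rdname accessors
#' @export
setMethod("centralRegion", "RetrozymeLocus", function(x) x@cr)

#' @rdname accessors
#' @export
setGeneric("pbs", function(x) standardGeneric("pbs"))
#' @rdname accessors
#' @export
setMethod("pbs", "RetrozymeLocus", function(x) x@pbs)

#' @rdname accessors
#' @export
setGeneric("ppt", function(x) standardGeneric("ppt"))
#' @rdname accessors
#' @export
setMethod("ppt", "RetrozymeLocus", function(x) x@ppt)

#' @rdname accessors
#' @export
setGeneric("isTandem", function(x) standardGeneric("isTandem"))
#' @rdname accessors
#' @export
setMethod("isTandem", "RetrozymeLocus", function(x) x@tandem)

#' @rdname accessors
#' @export
setGeneric("scaffoldId", function(x) standardGeneric("scaffoldId"))
#' @rdname accessors
#' @export
setMethod("scaffoldId", "RetrozymeLocus", function(x) x@scaffoldId)

#' @rdname accessors
#' @export
setGeneric("locusStrand", function(x) standardGeneric("locusStrand"))
#' @rdname accessors
#' @export
setMethod("locusStrand", "RetrozymeLocus", function(x) x@strand)

#' Full element span of a locus on its scaffold
#'
#' @param x a [RetrozymeLocus-class].
#' @return an [IRanges::IRanges] covering the element.
#' @export
setGeneric("locusSpan", function(x) standardGeneric("locusSpan"))
#' @rdname locusSpan
#' @export
setMethod("locusSpan", "RetrozymeLocus", function(x) {
  parts <- list(x@ltr5, x@cr, x@ltr3)
  parts <- parts[vapply(parts, length, 1L) > 0]
  IRanges::IRanges(min(vapply(parts, IRanges::start, 1L)),
                   max(vapply(parts, IRanges::end, 1L)))
})

#' @rdname accessors
#' @export
setGeneric("contigSeq", function(x) standardGeneric("contigSeq"))
#' @rdname accessors
#' @export
setMethod("contigSeq", "StrictContig", function(x) x@seq)

#' @rdname accessors
#' @export
setGeneric("contigMembers", function(x) standardGeneric("contigMembers"))
#' @rdname accessors
#' @export
setMethod("contigMembers", "StrictContig", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("extensionLog", function(x) standardGeneric("extensionLog"))
#' @rdname accessors
#' @export
setMethod("extensionLog", "StrictContig", function(x) x@extensionLog)

#' @rdname accessors
#' @export
setGeneric("lengthHist", function(x) standardGeneric("lengthHist"))
#' @rdname accessors
#' @export
setMethod("lengthHist", "SmallRnaProfile", function(x) x@lengthHist)

#' @rdname accessors
#' @export
setGeneric("regionHist", function(x) standardGeneric("regionHist"))
#' @rdname accessors
#' @export
setMethod("regionHist", "SmallRnaProfile", function(x) x@regionHist)

#' @rdname accessors
#' @export
setGeneric("ltrFraction", function(x) standardGeneric("ltrFraction"))
#' @rdname accessors
#' @export
setMethod("ltrFraction", "SmallRnaProfile", function(x) x@ltrFraction)

#' @rdname accessors
#' @export
setGeneric("methylationCalls",
           function(x) standardGeneric("methylationCalls"))
#' @rdname accessors
#' @export
setMethod("methylationCalls", "MethylationTable", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("methylationSites",
           function(x) standardGeneric("methylationSites"))
#' @rdname accessors
#' @export
setMethod("methylationSites", "MethylationTable", function(x) x@sites)

#' Percentage of methylated cytosines over all callable calls
#'
#' @param x a [MethylationTable-class].
#' @param context optional context ("CpG", "CHG" or "CHH") to restrict to.
#' @return numeric percentage in `[0, 100]` (NaN when nothing is callable).
#' @export
setGeneric("pctMethylated",
           function(x, context = NULL) standardGeneric("pctMethylated"))
#' @rdname pctMethylated
#' @export
setMethod("pctMethylated", "MethylationTable", function(x, context = NULL) {
  calls <- x@calls
  if (!is.null(context)) {
    stopifnot(context %in% c("CpG", "CHG", "CHH"))
    calls <- calls[, x@sites$context == context, drop = FALSE]
  }
  nm <- sum(calls == "methylated")
  nu <- sum(calls == "unmethylated")
  100 * nm / (nm + nu)
})

#' Per-clone methylated fraction
#'
#' @param x a [MethylationTable-class].
#' @return numeric vector, one methylated fraction per clone (callable
#'   sites only).
#' @export
setGeneric("cloneFractions", function(x) standardGeneric("cloneFractions"))
#' @rdname cloneFractions
#' @export
setMethod("cloneFractions", "MethylationTable", function(x) {
  apply(x@calls, 1, function(row) {
    nm <- sum(row == "methylated"); nu <- sum(row == "unmethylated")
    nm / (nm + nu)
  })
})

setMethod("show", "RibozymeMatch", function(object) {
  cat(sprintf(
    "RibozymeMatch: span %d-%d, boxes at %d/%d, cleavage 5' of %d, core %s\n",
    object@start, object@end, object@box1Pos, object@box2Pos,
    object@cleavageSite,
    if (object@coreIntact) "intact" else
      sprintf("substituted (%d)", nrow(object@coreSubstitutions))))
})

setMethod("show", "RetrozymeLocus", function(object) {
  span <- locusSpan(object)
  cat(sprintf("RetrozymeLocus %s [%s:%d-%d(%s)] %s%s\n",
              object@id, object@scaffoldId,
              IRanges::start(span), IRanges::end(span), object@strand,
              object@completeness,
              if (object@tandem) ", tandem" else ""))
  if (!is.na(object@group)) cat("  group: ", object@group, "\n", sep = "")
  if (!is.na(object@tsd)) cat("  TSD: ", object@tsd, "\n", sep = "")
  if (!is.na(object@ltrMismatches))
    cat("  LTR-LTR mismatches: ", object@ltrMismatches, "\n", sep = "")
  cat("  ribozymes: ", length(object@ribozymes), "\n", sep = "")
})

setMethod("show", "StrictContig", function(object) {
  cat(sprintf("StrictContig %s: %d nt, %d reads, max extension %s nt\n",
              object@id, nchar(object@seq), nrow(object@members),
              if (length(object@extensionLog))
                max(object@extensionLog) else "0"))
})

setMethod("show", "SmallRnaProfile", function(object) {
  cat(sprintf(
    "SmallRnaProfile: %d retrozyme-specific reads (%d dropped)\n",
    object@nTotal, object@nDropped))
  if (object@nTotal > 0) {
    mode_len <- names(which.max(object@lengthHist))
    cat(sprintf("  modal length %s nt; LTR fraction %.3f\n",
                mode_len, object@ltrFraction))
  }
})

setMethod("show", "MethylationTable", function(object) {
  cat(sprintf(
    "MethylationTable for %s: %d clones x %d sites, %.1f%% methylated\n",
    object@referenceId, nrow(object@calls), nrow(object@sites),
    pctMethylated(object)))
})
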