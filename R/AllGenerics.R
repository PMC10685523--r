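#' Accessors for aminoMR S4 classes
#'
#' Small accessor generics in the Bioconductor style: `traitName()`,
#' `traitType()` and `variants()` for [SummaryStats-class];
#' `harmonizedPairs()` and `droppedVariants()` for [HarmonizedData-class];
#' `ldPairs()` and `ldPositions()` for [LDTable-class]; `mrBeta()`, `mrSE()`,
#' `mrCI()`, `mrPval()`, `nSNPs()` and `mrMethod()` for [MREstimate-class].
#'
#' @param x an object of the relevant class.
#' @return The slot contents; `mrCI()` returns `c(low, high)`.
#' @name accessors
#' @aliases traitName traitType variants harmonizedPairs droppedVariants
#'   ldPairs ldPositions mrBeta mrSE mrCI mrPval nSNPs mrMethod
NULL

#' @rdname accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))
#' @rdname accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))
#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("harmonizedPairs", function(x) standardGeneric("harmonizedPairs"))
#' @rdname accessors
#' @export
setGeneric("droppedVariants", function(x) standardGeneric("droppedVariants"))
#' @rdname accessors
#' @export
setGeneric("ldPairs", function(x) standardGeneric("ldPairs"))
#' @rdname accessors
#' @export
setGeneric("ldPositions", function(x) standardGeneric("ldPositions"))
#' @rdname accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))
#' @rdname accessors
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))
#' @rdname accessors
#' @export
setGeneric("mrCI", function(x) standardGeneric("mrCI"))
#' @rdname accessors
#' @export
setGeneric("mrPval", function(x) standardGeneric("mrPval"))
#' @rdname accessors
#' @export
setGeneric("nSNPs", function(x) standardGeneric("nSNPs"))
#' @rdname accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname accessors
setMethod("traitName", "SummaryStats", function(x) x@traitName)
#' @rdname accessors
setMethod("traitType", "SummaryStats", function(x) x@traitType)
#' @rdname accessors
setMethod("variants", "SummaryStats", function(x) x@variants)
#' @rdname accessors
setMethod("nVariants", "SummaryStats", function(x) nrow(x@variants))
#' @rdname accessors
setMethod("variants", "InstrumentSet", function(x) x@variants)
#' @rdname accessors
setMethod("nVariants", "InstrumentSet", function(x) nrow(x@variants))
#' @rdname accessors
setMethod("harmonizedPairs", "HarmonizedData", function(x) x@pairs)
#' @rdname accessors
setMethod("droppedVariants", "HarmonizedData", function(x) x@dropped)
#' @rdname accessors
setMethod("ldPairs", "LDTable", function(x) x@pairs)
#' @rdname accessors
setMethod("ldPositions", "LDTable", function(x) x@positions)
#' @rdname accessors
setMethod("mrBeta", "MREstimate", function(x) x@beta)
#' @rdname accessors
setMethod("mrSE", "MREstimate", function(x) x@se)
#' @rdname accessors
setMethod("mrCI", "MREstimate", function(x) c(x@ciLow, x@ciHigh))
#' @rdname accessors
setMethod("mrPval", "MREstimate", function(x) x@pval)
#' @rdname accessors
setMethod("nSNPs", "MREstimate", function(x) x@nSNPs)
#' @rdname accessors
setMethod("mrMethod", "MREstimate", function(x) x@method)

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats:", object@traitName, sprintf("(%s)\n", object@traitType))
  cat(" ", nrow(object@variants), "variants\n")
  if (nrow(object@variants)) {
    v <- utils::head(object@variants, 4L)
    print(v, row.names = FALSE)
    if (nrow(object@variants) > 4L) cat("  ...\n")
  }
})

setMethod("show", "LDTable", function(object) {
  cat("LDTable:", nrow(object@pairs), "stored pairs,",
      nrow(object@positions), "positioned variants\n")
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet for", object@exposureName, "-", nrow(object@variants),
      "instruments\n")
})

setMethod("show", "HarmonizedData", function(object) {
  cat("HarmonizedData:", object@exposureName, "->", object@outcomeName,
      sprintf("(%s outcome)\n", object@outcomeType))
  cat(" ", nrow(object@pairs), "harmonized pairs,",
      nrow(object@dropped), "dropped\n")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s]  beta = %.4f  se = %.4f  95%% CI (%.4f, %.4f)  p = %.3g  nSNPs = %d\n",
              object@method, object@beta, object@se, object@ciLow,
              object@ciHigh, object@pval, object@nSNPs))
  if (!is.na(object@qStat))
    cat(sprintf("  Cochran's Q = %.3f (df = %d), p = %.3g\n", object@qStat,
                object@nSNPs - 1L, object@qPval))
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy:", nVariants(object@exposure), "variants, true theta =",
      object@truth$theta, "\n")
  cat("  exposure n =", object@truth$config$nExposure,
      " outcome n =", object@truth$config$nOutcome,
      sprintf(" (%s outcome)\n", traitType(object@outcome)))
})
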