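# Generics and accessors. Slots are never touched directly by user code.

#' @describeIn ResponseMatrix-class the integer response matrix
#' @param x,object a \code{ResponseMatrix}
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))
#' @export
setMethod("responses", "ResponseMatrix", function(x) x@responses)

#' @export
setGeneric("personIds", function(x) standardGeneric("personIds"))
#' @export
setMethod("personIds", "ResponseMatrix", function(x) rownames(x@responses))
#' @export
setMethod("personIds", "ThetaScores", function(x) x@personIds)

#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))
#' @export
setMethod("itemIds", "ResponseMatrix", function(x) colnames(x@responses))
#' @export
setMethod("itemIds", "GRMFit", function(x) names(x@a))

#' @export
setGeneric("nPersons", function(x) standardGeneric("nPersons"))
#' @export
setMethod("nPersons", "ResponseMatrix", function(x) nrow(x@responses))

#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))
#' @export
setMethod("nItems", "ResponseMatrix", function(x) ncol(x@responses))

#' @export
setGeneric("numCategories", function(x) standardGeneric("numCategories"))
#' @export
setMethod("numCategories", "ResponseMatrix", function(x) x@K)

#' @export
setGeneric("subscales", function(x) standardGeneric("subscales"))
#' @export
setMethod("subscales", "ScaleDefinition", function(x) x@subscales)

#' @export
setGeneric("reverseItems", function(x) standardGeneric("reverseItems"))
#' @export
setMethod("reverseItems", "ScaleDefinition", function(x) x@reverseItems)

#' @export
setGeneric("scaleItems", function(x) standardGeneric("scaleItems"))
#' @export
setMethod("scaleItems", "ScaleDefinition",
          function(x) unlist(x@subscales, use.names = FALSE))

#' @export
setGeneric("discrimination", function(x) standardGeneric("discrimination"))
#' @export
setMethod("discrimination", "GRMFit", function(x) x@a)

#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' @export
setMethod("thresholds", "GRMFit", function(x) x@b)
#' @export
setMethod("thresholds", "DIFRunResult", function(x) x@thresholds)

#' @export
setGeneric("emTrace", function(x) standardGeneric("emTrace"))
#' @export
setMethod("emTrace", "GRMFit", function(x) x@trace)

#' @export
setMethod("logLik", "GRMFit", function(object, ...) object@loglik)

#' @export
setGeneric("traitEstimates", function(x) standardGeneric("traitEstimates"))
#' @export
setMethod("traitEstimates", "ThetaScores", function(x) x@theta)
#' @export
setMethod("traitEstimates", "DIFRunResult", function(x) x@theta)

#' @export
setGeneric("traitSE", function(x) standardGeneric("traitSE"))
#' @export
setMethod("traitSE", "ThetaScores", function(x) x@se)

#' @export
setGeneric("flaggedItems", function(x) standardGeneric("flaggedItems"))
#' @export
setMethod("flaggedItems", "DIFRunResult",
          function(x) as.character(x@finalFlags$item))

#' @export
setGeneric("anchorItems", function(x) standardGeneric("anchorItems"))
#' @export
setMethod("anchorItems", "DIFRunResult", function(x) x@anchorItems)

#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))
#' @export
setMethod("statsTable", "DIFRunResult", function(x) x@statsTable)

#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @export
setMethod("isConverged", "DIFRunResult", function(x) x@converged)
#' @export
setMethod("isConverged", "GRMFit", function(x) x@converged)

#' @export
setGeneric("difIterations", function(x) standardGeneric("difIterations"))
#' @export
setMethod("difIterations", "DIFRunResult", function(x) x@iterations)

#' @export
setGeneric("personTable", function(x) standardGeneric("personTable"))
#' @export
setMethod("personTable", "ImpactSummary", function(x) x@personTable)

#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))
#' @export
setMethod("groupTable", "ImpactSummary", function(x) x@groupTable)

#' @export
setGeneric("salientCount", function(x) standardGeneric("salientCount"))
#' @export
setMethod("salientCount", "ImpactSummary",
          function(x) sum(x@personTable$salient))

#' @export
setGeneric("observedEigenvalues",
           function(x) standardGeneric("observedEigenvalues"))
#' @export
setMethod("observedEigenvalues", "EigenReport", function(x) x@observed)

#' @export
setGeneric("referenceEigenvalues",
           function(x) standardGeneric("referenceEigenvalues"))
#' @export
setMethod("referenceEigenvalues", "EigenReport", function(x) x@reference)

#' @export
setGeneric("nFactorsRetained",
           function(x) standardGeneric("nFactorsRetained"))
#' @export
setMethod("nFactorsRetained", "EigenReport", function(x) x@retained)

# ---- show methods ---------------------------------------------------------

setMethod("show", "ResponseMatrix", function(object) {
  r <- object@responses
  cat(sprintf("ResponseMatrix: %d persons x %d items, K = %d\n",
              nrow(r), ncol(r), object@K))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(r)),
              100 * mean(is.na(r))))
})

setMethod("show", "ScaleDefinition", function(object) {
  cat(sprintf("ScaleDefinition: %d subscales, %d items (%d reverse-scored)\n",
              length(object@subscales),
              length(unlist(object@subscales)),
              length(object@reverseItems)))
  for (nm in names(object@subscales))
    cat(sprintf("  %s: %d items\n", nm, length(object@subscales[[nm]])))
})

setMethod("show", "GRMFit", function(object) {
  cat(sprintf(
    "GRMFit: %d items, logLik = %.3f, %d EM cycles (%sconverged)\n",
    length(object@a), object@loglik, object@cycles,
    if (object@converged) "" else "NOT "))
  cat(sprintf("  discrimination range: [%.2f, %.2f]\n",
              min(object@a), max(object@a)))
})

setMethod("show", "ThetaScores", function(object) {
  cat(sprintf("ThetaScores: %d persons, mean = %.3f, sd = %.3f\n",
              length(object@theta), mean(object@theta),
              stats::sd(object@theta)))
})

setMethod("show", "DIFRunResult", function(object) {
  cat(sprintf(
    "DIFRunResult: %d iterations (%sconverged), threshold = %.2f\n",
    object@nIterations, if (object@converged) "" else "NOT ",
    object@thresholds$threshold))
  fl <- flaggedItems(object)
  if (length(fl)) cat("  flagged:", paste(fl, collapse = ", "), "\n")
  else cat("  no items flagged\n")
})

setMethod("show", "ImpactSummary", function(object) {
  cat(sprintf(
    "ImpactSummary: %d persons, %d salient at |difference| >= %.2f\n",
    nrow(object@personTable), salientCount(object), object@cutoff))
})

setMethod("show", "EigenReport", function(object) {
  cat("EigenReport: leading eigenvalues",
      paste(sprintf("%.2f", head(object@observed, 4)), collapse = ", "),
      "...\n")
  for (nm in names(object@retained))
    cat(sprintf("  %s: retain %d\n", nm, object@retained[[nm]]))
})
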