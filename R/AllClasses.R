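# S4 classes for the central data objects. Small working objects created in
# inner loops (proportional-odds fits, per-item DIF statistics) stay plain
# lists for speed; everything user-facing is a validated S4 object.

#' Ordinal response matrix
#'
#' Respondents-by-items matrix of ordinal codes in \code{1..K}, with
#' \code{NA} for missing responses. Person and item identifiers live in
#' the dimnames. All items share the same nominal number of response
#' categories \code{K} (individual items may use a contiguous prefix
#' \code{1..K'} after sparse-category collapsing).
#'
#' @slot responses integer matrix (persons x items), codes in 1..K or NA.
#' @slot K integer, nominal number of response categories (>= 2).
#' @export
setClass("ResponseMatrix",
  representation(responses = "matrix", K = "integer"),
  validity = function(object) {
    r <- object@responses
    msg <- character(0)
    if (length(object@K) != 1L || is.na(object@K) || object@K < 2L)
      msg <- c(msg, "K must be a single integer >= 2")
    if (is.null(rownames(r)) || is.null(colnames(r)))
      msg <- c(msg, "responses must have person (row) and item (column) names")
    v <- r[!is.na(r)]
    if (length(v) && (any(v != as.integer(v)) || any(v < 1L) ||
                      any(v > object@K)))
      msg <- c(msg, sprintf("non-missing codes must be integers in [1, %d]",
                            object@K))
    if (length(msg)) msg else TRUE
  })

#' Scale definition: subscales and reverse-scored items
#'
#' @slot subscales named list mapping subscale name to an ordered
#'   character vector of item identifiers; item sets are disjoint.
#' @slot reverseItems character vector of reverse-scored item identifiers.
#' @export
setClass("ScaleDefinition",
  representation(subscales = "list", reverseItems = "character"),
  validity = function(object) {
    items <- unlist(object@subscales, use.names = FALSE)
    msg <- character(0)
    if (!length(object@subscales) || is.null(names(object@subscales)))
      msg <- c(msg, "subscales must be a non-empty named list")
    if (anyDuplicated(items))
      msg <- c(msg, "subscale item lists must be disjoint")
    if (!all(object@reverseItems %in% items))
      msg <- c(msg, "reverseItems must be a subset of the scale's items")
    if (length(msg)) msg else TRUE
  })

#' Fitted graded response model
#'
#' Marginal-maximum-likelihood estimates for a set of items: per-item
#' discrimination \code{a > 0} and strictly increasing category
#' thresholds, together with the quadrature grid used (so that trait
#' scoring reuses the identical prior).
#'
#' @slot a named numeric, discriminations.
#' @slot b named list of numeric vectors, ordered thresholds per item.
#' @slot loglik numeric, marginal log-likelihood at the estimates.
#' @slot trace numeric, marginal log-likelihood across EM cycles.
#' @slot cycles integer, EM cycles used.
#' @slot converged logical.
#' @slot quad numeric, quadrature nodes.
#' @slot logPrior numeric, normalised log prior weights at the nodes.
#' @export
setClass("GRMFit",
  representation(a = "numeric", b = "list", loglik = "numeric",
                 trace = "numeric", cycles = "integer",
                 converged = "logical", quad = "numeric",
                 logPrior = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@a <= 0)) msg <- c(msg, "all discriminations must be > 0")
    bad <- vapply(object@b, function(x) any(diff(x) <= 0), logical(1))
    if (any(bad))
      msg <- c(msg, paste("thresholds not strictly increasing for:",
                          paste(names(object@b)[bad], collapse = ", ")))
    if (!identical(names(object@a), names(object@b)))
      msg <- c(msg, "a and b must be aligned on item names")
    if (length(msg)) msg else TRUE
  })

#' EAP trait scores
#'
#' @slot theta numeric, expected a posteriori trait estimates.
#' @slot se numeric, posterior standard deviations.
#' @slot personIds character.
#' @export
setClass("ThetaScores",
  representation(theta = "numeric", se = "numeric", personIds = "character"),
  validity = function(object) {
    if (length(object@theta) != length(object@se) ||
        length(object@theta) != length(object@personIds))
      return("theta, se and personIds must have equal length")
    if (any(!is.finite(object@theta)) || any(!is.finite(object@se)))
      return("theta and se must be finite")
    TRUE
  })

#' Result of an iterative DIF purification run
#'
#' @slot statsTable data.frame of per-item DIF statistics from the final
#'   iteration (log-likelihoods, pseudo-R-squared values and changes).
#' @slot thresholds list with the analysis-level empirical threshold and
#'   the raw Monte-Carlo maxima.
#' @slot iterations list of character vectors: flagged items per iteration.
#' @slot finalFlags data.frame (item, uniform, nonuniform) for flagged items.
#' @slot anchorItems character, final non-flagged item set.
#' @slot converged logical, TRUE when two successive flag sets agreed.
#' @slot nIterations integer.
#' @slot fit final anchor-based \code{GRMFit} used for trait estimates.
#' @slot theta final \code{ThetaScores} used for the reported statistics.
#' @slot config list, the \code{difConfig} used.
#' @export
setClass("DIFRunResult",
  representation(statsTable = "data.frame", thresholds = "list",
                 iterations = "list", finalFlags = "data.frame",
                 anchorItems = "character", converged = "logical",
                 nIterations = "integer", fit = "GRMFit",
                 theta = "ThetaScores", config = "list"))

#' Individual-level DIF impact summary
#'
#' @slot personTable data.frame: personId, group, initial, purified,
#'   difference (= initial - purified), salient.
#' @slot groupTable data.frame of per-group means and salience counts.
#' @slot cutoff numeric, salience cutoff on the trait (SD-unit) scale.
#' @export
setClass("ImpactSummary",
  representation(personTable = "data.frame", groupTable = "data.frame",
                 cutoff = "numeric"))

#' Eigenvalue report from exploratory dimensionality checks
#'
#' @slot observed numeric, descending eigenvalues of the polychoric
#'   correlation matrix.
#' @slot reference list of numeric reference eigenvalue vectors, per method.
#' @slot retained named integer, factors retained per method.
#' @export
setClass("EigenReport",
  representation(observed = "numeric", reference = "list",
                 retained = "integer"),
  validity = function(object) {
    if (is.unsorted(rev(object@observed)))
      return("observed eigenvalues must be in descending order")
    if (any(object@retained < 0)) return("retained counts must be >= 0")
    TRUE
  })
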