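# Samejima graded response model: category probabilities, MML calibration
# (EM on a fixed quadrature grid, implemented in C++), EAP scoring, and
# response simulation.

defaultQuadrature <- function(nPoints = 101L, range = c(-6, 6)) {
  quad <- seq(range[1], range[2], length.out = nPoints)
  lw <- dnorm(quad, log = TRUE)
  lw <- lw - log(sum(exp(lw - max(lw)))) - max(lw)   # normalise
  list(quad = quad, logPrior = lw)
}

#' Graded response model category probabilities
#'
#' \eqn{P(u = k | \theta) = \sigma(a(\theta - b_k)) - \sigma(a(\theta -
#' b_{k+1}))} with logistic \eqn{\sigma}, \eqn{b_1 = -\infty},
#' \eqn{b_{K+1} = +\infty}. Rows sum to one.
#'
#' @param a discrimination (> 0).
#' @param b strictly increasing thresholds \eqn{b_2 .. b_K} (length K-1).
#' @param theta trait value(s).
#' @return if \code{theta} is scalar, a probability vector of length K;
#'   otherwise a \code{length(theta) x K} matrix.
#' @export
grmCategoryProbs <- function(a, b, theta) {
  stopifnot(a > 0, !is.unsorted(b, strictly = TRUE))
  K <- length(b) + 1L
  cum <- cbind(1, plogis(a * outer(theta, b, "-")), 0)
  p <- cum[, 1:K, drop = FALSE] - cum[, 2:(K + 1), drop = FALSE]
  colnames(p) <- paste0("k", seq_len(K))
  if (length(theta) == 1L) drop(p) else p
}

# per-item number of categories actually in use (codes must be 1..K_j,
# every category observed); errors otherwise
itemCategoryCounts <- function(m) {
  r <- responses(m)
  vapply(itemIds(m), function(j) {
    x <- r[, j]
    x <- x[!is.na(x)]
    if (!length(x)) stop("item '", j, "' has no observed responses")
    kj <- max(x)
    if (kj < 2L) stop("item '", j, "' has a single observed category")
    missing_cat <- setdiff(seq_len(kj), unique(x))
    if (length(missing_cat))
      stop(sprintf("item '%s': category %d unobserved", j, missing_cat[1]))
    as.integer(kj)
  }, integer(1))
}

grmStartValues <- function(m, ncat) {
  r <- responses(m)
  J <- nItems(m)
  Kmax <- max(ncat)
  b0 <- matrix(0, J, Kmax - 1L)
  for (j in seq_len(J)) {
    x <- r[, j]
    x <- x[!is.na(x)]
    pk <- vapply(2:ncat[j], function(k) mean(x >= k), numeric(1))
    pk <- pmin(pmax(pk, 0.005), 0.995)
    b <- qnorm(1 - pk) * 1.8
    # enforce strict increase
    for (k in seq_along(b)[-1])
      if (b[k] <= b[k - 1]) b[k] <- b[k - 1] + 0.05
    b0[j, seq_along(b)] <- b
  }
  list(a = rep(1, J), b = b0)
}

#' Fit the graded response model by marginal maximum likelihood
#'
#' EM with the trait integrated over a fixed quadrature grid under a
#' standard-normal prior (the prior anchors the latent metric). The
#' M-step updates each item by Newton steps on the expected
#' complete-data log-likelihood, with threshold order maintained by a
#' log-gap reparameterisation; the marginal log-likelihood is
#' non-decreasing across cycles.
#'
#' @param m a \code{\linkS4class{ResponseMatrix}}; every category
#'   \code{1..K_j} of every item must be observed at least once.
#' @param nQuad,quadRange quadrature grid: 101 equally spaced points on
#'   [-6, 6] by default.
#' @param maxCycles,tol EM stops when the largest absolute parameter
#'   change falls below \code{tol} (default 1e-4), or when the marginal
#'   log-likelihood has been flat to 1e-8 for three consecutive cycles
#'   (weakly identified designs can creep in parameter space long after
#'   the likelihood has converged), or after \code{maxCycles} cycles
#'   (an error carrying the likelihood trace).
#' @return a \code{\linkS4class{GRMFit}}
#' @export
fitGRM <- function(m, nQuad = 101L, quadRange = c(-6, 6),
                   maxCycles = 2000L, tol = 1e-4) {
  if (nItems(m) < 2L) stop("at least 2 items are required")
  ncat <- itemCategoryCounts(m)
  qd <- defaultQuadrature(nQuad, quadRange)
  start <- grmStartValues(m, ncat)
  r <- responses(m)
  r[is.na(r)] <- 0L
  fit <- cpp_fit_grm(r, ncat, qd$quad, qd$logPrior,
                     start$a, start$b, as.integer(maxCycles), tol)
  if (!fit$converged) {
    cnd <- structure(
      class = c("grmNonConvergence", "error", "condition"),
      list(message = sprintf(
             "GRM EM did not converge in %d cycles (last loglik %.6f)",
             maxCycles, tail(fit$trace, 1)),
           call = sys.call(), trace = fit$trace))
    stop(cnd)
  }
  ids <- itemIds(m)
  b <- lapply(seq_along(ids), function(j) fit$b[j, seq_len(ncat[j] - 1L)])
  new("GRMFit",
      a = setNames(as.numeric(fit$a), ids),
      b = setNames(b, ids),
      loglik = fit$loglik, trace = as.numeric(fit$trace),
      cycles = as.integer(fit$cycles), converged = fit$converged,
      quad = qd$quad, logPrior = qd$logPrior)
}

grmParamsToMatrices <- function(a, b) {
  ncat <- vapply(b, length, integer(1)) + 1L
  B <- matrix(0, length(a), max(ncat) - 1L)
  for (j in seq_along(b)) B[j, seq_len(ncat[j] - 1L)] <- b[[j]]
  list(a = as.numeric(a), B = B, ncat = ncat)
}

#' Marginal log-likelihood of a response matrix under given GRM parameters
#'
#' @param fit a \code{\linkS4class{GRMFit}} (or list with elements
#'   \code{a} and \code{b}).
#' @param m a \code{\linkS4class{ResponseMatrix}} with items aligned to
#'   the parameters.
#' @export
grmLogLik <- function(fit, m) {
  p <- extractGrmParams(fit, itemIds(m))
  qd <- grmQuadOf(fit)
  pm <- grmParamsToMatrices(p$a, p$b)
  r <- responses(m)
  r[is.na(r)] <- 0L
  cpp_grm_posterior(r, pm$a, pm$B, pm$ncat, qd$quad, qd$logPrior)$loglik
}

extractGrmParams <- function(fit, items) {
  if (is(fit, "GRMFit")) {
    a <- discrimination(fit); b <- thresholds(fit)
  } else {
    a <- fit$a; b <- fit$b
  }
  if (!all(items %in% names(a)))
    stop("parameters missing for item(s): ",
         paste(setdiff(items, names(a)), collapse = ", "))
  list(a = a[items], b = b[items])
}

grmQuadOf <- function(fit) {
  if (is(fit, "GRMFit") && length(fit@quad))
    list(quad = fit@quad, logPrior = fit@logPrior)
  else defaultQuadrature()
}

#' EAP trait scores
#'
#' Expected a posteriori trait estimates under the standard-normal prior,
#' computed on the calibration's quadrature grid. Missing responses are
#' skipped in the likelihood; a person with no observed responses gets
#' the prior mean (theta 0, se 1).
#'
#' @param fit a \code{\linkS4class{GRMFit}}.
#' @param m a \code{\linkS4class{ResponseMatrix}} whose items all have
#'   parameters in \code{fit}.
#' @return a \code{\linkS4class{ThetaScores}}
#' @export
eapScores <- function(fit, m) {
  p <- extractGrmParams(fit, itemIds(m))
  qd <- grmQuadOf(fit)
  pm <- grmParamsToMatrices(p$a, p$b)
  r <- responses(m)
  allMissing <- rowSums(!is.na(r)) == 0L
  r[is.na(r)] <- 0L
  post <- cpp_grm_posterior(r, pm$a, pm$B, pm$ncat, qd$quad,
                            qd$logPrior)$posterior
  theta <- as.numeric(post %*% qd$quad)
  v <- as.numeric(post %*% qd$quad^2) - theta^2
  se <- sqrt(pmax(v, 0))
  theta[allMissing] <- 0
  se[allMissing] <- 1
  new("ThetaScores", theta = theta, se = se, personIds = personIds(m))
}

#' Simulate graded-response data
#'
#' Draws each cell from \code{\link{grmCategoryProbs}} at the person's
#' trait value. Reproducible under \code{seed}.
#'
#' @param fit a \code{\linkS4class{GRMFit}} or list with elements
#'   \code{a} (named numeric) and \code{b} (named list).
#' @param theta trait vector (one value per simulated person).
#' @param seed optional integer seed.
#' @param personIds optional person identifiers.
#' @return a \code{\linkS4class{ResponseMatrix}}
#' @export
simulateGRM <- function(fit, theta, seed = NULL, personIds = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is(fit, "GRMFit")) {
    a <- discrimination(fit); b <- thresholds(fit)
  } else {
    a <- fit$a; b <- fit$b
  }
  n <- length(theta)
  J <- length(a)
  K <- max(vapply(b, length, integer(1))) + 1L
  m <- matrix(NA_integer_, n, J)
  for (j in seq_len(J)) {
    cum <- plogis(a[[j]] * outer(theta, b[[j]], "-"))  # n x (K_j - 1)
    v <- runif(n)
    m[, j] <- 1L + as.integer(rowSums(v < cum))
  }
  colnames(m) <- names(a)
  rownames(m) <- personIds %||% paste0("p", seq_len(n))
  responseMatrix(m, K = K)
}

#' Serialise fitted GRM parameters to JSON
#'
#' @param fit a \code{\linkS4class{GRMFit}}
#' @param path output file
#' @export
writeGRMParams <- function(fit, path) {
  items <- lapply(itemIds(fit), function(j) {
    list(item = j, a = unname(discrimination(fit)[[j]]),
         b = as.numeric(thresholds(fit)[[j]]))
  })
  jsonlite::write_json(list(model = "graded_response",
                            loglik = fit@loglik, items = items),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GRM parameters written by \code{\link{writeGRMParams}}
#'
#' @param path JSON file
#' @return list with named elements \code{a} and \code{b}, usable where a
#'   fitted model is accepted (scoring, simulation).
#' @export
readGRMParams <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ids <- vapply(obj$items, `[[`, character(1), "item")
  list(a = setNames(vapply(obj$items, `[[`, numeric(1), "a"), ids),
       b = setNames(lapply(obj$items,
                           function(x) as.numeric(unlist(x$b))), ids))
}
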