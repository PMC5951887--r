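# Proportional-odds (cumulative logit) fits oriented as P(u >= k), and the
# Nagelkerke pseudo-R-squared machinery for the three nested DIF models:
#   Model 1 (no DIF):        logit P(u >= k) = alpha_k + beta1 * theta
#   Model 2 (uniform):       ... + beta2 * group
#   Model 3 (non-uniform):   ... + beta3 * theta * group
# For G groups, "group" is G-1 indicator columns (reference = first level
# in sorted label order), so G = 2 reduces to the single-coefficient form.

#' Fit a proportional-odds model for P(u >= k)
#'
#' Maximum likelihood by Newton-Raphson with step-halving on the
#' cumulative-logit model \eqn{logit P(u \ge k) = \alpha_k + x'\beta},
#' k = 2..K. The intercepts \eqn{\alpha_k} are non-increasing in k at the
#' optimum. The log-likelihood is concave in this parameterisation, so
#' the fit is deterministic given the data.
#'
#' @param y integer ordinal outcomes in 1..K with every category present.
#' @param X numeric predictor matrix (or NULL for the intercept-only
#'   model, solved in closed form). Must be full rank jointly with the
#'   intercept.
#' @param maxIter,tol Newton iteration cap and convergence tolerance on
#'   the largest absolute parameter update (default 1e-8).
#' @return list of class \code{OLRFit}: \code{alpha} (length K-1),
#'   \code{beta}, \code{loglik}, \code{n}, \code{iterations},
#'   \code{converged}.
#' @export
fitProportionalOdds <- function(y, X = NULL, maxIter = 100L, tol = 1e-8) {
  y <- as.integer(y)
  n <- length(y)
  K <- max(y)
  if (K < 2L) stop("outcome has a single category")
  counts <- tabulate(y, K)
  if (any(counts == 0L))
    stop("category ", which(counts == 0L)[1], " not present in the outcome")

  if (is.null(X) || NCOL(X) == 0L) {
    # closed-form MLE: alpha_k = logit of the empirical P(u >= k)
    pk <- rev(cumsum(rev(counts)))[-1] / n
    alpha <- qlogis(pk)
    ll <- sum(counts * log(counts / n))
    return(structure(list(alpha = alpha, beta = numeric(0), loglik = ll,
                          n = n, iterations = 0L, converged = TRUE),
                     class = "OLRFit"))
  }

  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and y lengths differ")
  if (any(!is.finite(X))) stop("non-finite values in the predictors")
  p <- ncol(X)
  if (qr(cbind(1, X))$rank < p + 1L)
    stop("design matrix is rank deficient (collinear or constant column)")

  # start: intercept-only alphas, zero slopes
  pk <- rev(cumsum(rev(counts)))[-1] / n
  alpha <- qlogis(pk)
  beta <- numeric(p)

  iy <- cbind(seq_len(n), y)
  iy1 <- cbind(seq_len(n), y + 1L)

  loglikAt <- function(alpha, beta) {
    gam <- cbind(1, plogis(outer(drop(X %*% beta), alpha, "+")), 0)
    Pi <- gam[iy] - gam[iy1]
    if (any(Pi <= 0)) return(list(ll = -Inf))
    list(ll = sum(log(Pi)), gam = gam, Pi = Pi)
  }

  cur <- loglikAt(alpha, beta)
  trace <- cur$ll
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    gam <- cur$gam; Pi <- cur$Pi
    g1 <- gam[iy] * (1 - gam[iy])       # zero when y = 1 (gam = 1)
    g2 <- gam[iy1] * (1 - gam[iy1])     # zero when y = K (gam = 0)
    h1 <- g1 * (1 - 2 * gam[iy])
    h2 <- g2 * (1 - 2 * gam[iy1])
    invP <- 1 / Pi

    # gradient
    gAlpha <- numeric(K - 1L)
    for (k in 2:K) {
      gAlpha[k - 1L] <- sum(g1[y == k] * invP[y == k]) -
                        sum(g2[y == k - 1L] * invP[y == k - 1L])
    }
    wBeta <- (g1 - g2) * invP
    gBeta <- drop(crossprod(X, wBeta))
    grad <- c(gAlpha, gBeta)

    # observed Hessian of the log-likelihood
    d <- K - 1L + p
    H <- matrix(0, d, d)
    for (k in 2:K) {
      A <- y == k          # rows where alpha_k plays the "u" role
      B <- y == k - 1L     # rows where alpha_k plays the "v" role
      H[k - 1L, k - 1L] <-
        sum(h1[A] * invP[A] - (g1[A] * invP[A])^2) +
        sum(-h2[B] * invP[B] - (g2[B] * invP[B])^2)
      if (k < K) {
        cross <- sum(g1[A] * g2[A] * invP[A]^2)
        H[k - 1L, k] <- H[k, k - 1L] <- cross
      }
      if (p > 0) {
        wa <- numeric(n)
        wa[A] <- h1[A] * invP[A] - g1[A] * (g1[A] - g2[A]) * invP[A]^2
        wa[B] <- wa[B] - h2[B] * invP[B] +
                 g2[B] * (g1[B] - g2[B]) * invP[B]^2
        hb <- drop(crossprod(X, wa))
        H[k - 1L, K:d] <- hb
        H[K:d, k - 1L] <- hb
      }
    }
    wbb <- (h1 - h2) * invP - ((g1 - g2) * invP)^2
    H[K:d, K:d] <- crossprod(X, X * wbb)

    step <- tryCatch(solve(H, grad),
                     error = function(e) solve(H - diag(1e-6, d), grad))
    step <- -step   # ascent direction (H is negative definite)

    lam <- 1
    improved <- FALSE
    for (hcnt in 1:30) {
      aNew <- alpha + lam * step[seq_len(K - 1L)]
      bNew <- beta + lam * step[K:d]
      candidate <- loglikAt(aNew, bNew)
      if (is.finite(candidate$ll) && candidate$ll >= cur$ll - 1e-12) {
        alpha <- aNew; beta <- bNew; cur <- candidate
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    trace <- c(trace, cur$ll)
    if (!improved) break
    if (max(abs(lam * step)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(paste0("proportional-odds fit did not converge (possible ",
                "separation); loglik trace: ",
                paste(sprintf("%.4f", tail(trace, 5)), collapse = " -> ")))
  structure(list(alpha = alpha, beta = setNames(beta, colnames(X)),
                 loglik = cur$ll, n = n, iterations = it,
                 converged = converged),
            class = "OLRFit")
}

#' @export
print.OLRFit <- function(x, ...) {
  cat(sprintf("Proportional-odds fit (P(u >= k)): n = %d, logLik = %.4f\n",
              x$n, x$loglik))
  cat("  alpha:", sprintf("%.4f", x$alpha), "\n")
  if (length(x$beta)) cat("  beta: ", sprintf("%.4f", x$beta), "\n")
  invisible(x)
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell \eqn{R^2 = 1 - exp(2(l_0 - l_1)/n)} rescaled by its maximum
#' \eqn{1 - exp(2 l_0 / n)} so the statistic is bounded by 1.
#'
#' @param loglikNull,loglikModel log-likelihoods of the null and fitted
#'   model (\code{loglikModel >= loglikNull} up to 1e-8).
#' @param n number of observations used in both fits.
#' @export
nagelkerkeR2 <- function(loglikNull, loglikModel, n) {
  stopifnot(n >= 1)
  if (loglikModel < loglikNull - 1e-8)
    stop("model log-likelihood is below the null log-likelihood")
  denom <- 1 - exp(2 * loglikNull / n)
  if (denom <= 0)
    stop("null model has likelihood 1; pseudo-R2 undefined")
  r2cs <- 1 - exp(2 * (loglikNull - loglikModel) / n)
  min(max(r2cs / denom, 0), 1)
}

#' Per-item DIF statistics from the three nested ordinal models
#'
#' Fits the intercept-only model and Models 1-3 on the same rows
#' (complete on outcome, trait and group) and returns the nested
#' log-likelihoods, Nagelkerke pseudo-R-squared values, and the changes
#' d12 (uniform DIF), d23 (non-uniform DIF) and d13 = d12 + d23.
#'
#' @param y item responses (integer 1..K; NA rows dropped).
#' @param theta trait estimates (\code{\linkS4class{ThetaScores}} or
#'   numeric vector) aligned with \code{y}.
#' @param groups factor aligned with \code{y} (>= 2 levels after NA
#'   removal).
#' @param itemId optional identifier carried into the result.
#' @return list of class \code{DIFItemStats}.
#' @export
difStatisticsForItem <- function(y, theta, groups, itemId = NA_character_) {
  if (is(theta, "ThetaScores")) theta <- traitEstimates(theta)
  groups <- factor(as.character(groups))   # reference = first sorted level
  keep <- !is.na(y) & !is.na(theta) & !is.na(groups)
  y <- as.integer(y[keep]); theta <- theta[keep]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L)
    stop("item '", itemId, "': fewer than 2 groups after NA removal")
  n <- length(y)

  gd <- model.matrix(~ groups)[, -1, drop = FALSE]  # G-1 indicators
  colnames(gd) <- levels(groups)[-1]
  X1 <- cbind(theta = theta)
  X2 <- cbind(X1, gd)
  X3 <- cbind(X2, gd * theta)
  colnames(X3) <- c(colnames(X2), paste0("theta:", colnames(gd)))

  fits <- tryCatch(list(
    m0 = fitProportionalOdds(y, NULL),
    m1 = fitProportionalOdds(y, X1),
    m2 = fitProportionalOdds(y, X2),
    m3 = fitProportionalOdds(y, X3)
  ), error = function(e)
    stop("item '", itemId, "': ", conditionMessage(e), call. = FALSE))

  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  r2 <- vapply(ll[-1], function(l) nagelkerkeR2(ll[1], l, n), numeric(1))
  structure(list(
    itemId = itemId,
    loglik0 = ll[["m0"]], loglik1 = ll[["m1"]],
    loglik2 = ll[["m2"]], loglik3 = ll[["m3"]],
    r2_1 = r2[["m1"]], r2_2 = r2[["m2"]], r2_3 = r2[["m3"]],
    d12 = r2[["m2"]] - r2[["m1"]],
    d23 = r2[["m3"]] - r2[["m2"]],
    d13 = r2[["m3"]] - r2[["m1"]],
    n = n, fits = fits
  ), class = "DIFItemStats")
}
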