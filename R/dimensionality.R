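# Exploratory dimensionality checks for ordinal items: polychoric
# correlations (two-step ML), permutation-based parallel analysis, and
# the Empirical Kaiser Criterion.

# Standard bivariate normal CDF P(X <= h, Y <= k), vectorised over (h, k)
# for a scalar correlation, via Gauss-Legendre quadrature of the
# correlation-integral representation
#   Phi2(h, k; rho) = Phi(h) Phi(k)
#     + (2*pi)^-1 Int_0^rho exp(-(h^2 - 2 r h k + k^2)/(2(1-r^2)))
#                           / sqrt(1-r^2) dr.
# 48 nodes keep the absolute error around 1e-9 for |rho| <= 0.995.
pbivnorm2 <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, abs(rho) < 1)
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  out <- numeric(n)
  inf <- is.infinite(h) | is.infinite(k)
  if (any(inf)) {
    out[inf] <- ifelse(h[inf] == -Inf | k[inf] == -Inf, 0,
                ifelse(h[inf] == Inf & k[inf] == Inf, 1,
                ifelse(h[inf] == Inf, pnorm(k[inf]), pnorm(h[inf]))))
  }
  if (any(!inf)) {
    hh <- h[!inf]; kk <- k[!inf]
    base <- pnorm(hh) * pnorm(kk)
    if (rho != 0) {
      gl <- gaussLegendre48()
      r <- 0.5 * rho * (gl$nodes + 1)          # map [-1,1] -> [0,rho]
      wr <- 0.5 * rho * gl$weights
      acc <- 0
      for (i in seq_along(r)) {
        ri <- r[i]
        acc <- acc + wr[i] *
          exp(-(hh^2 - 2 * ri * hh * kk + kk^2) / (2 * (1 - ri^2))) /
          sqrt(1 - ri^2)
      }
      base <- base + acc / (2 * pi)
    }
    out[!inf] <- pmin(pmax(base, 0), 1)
  }
  out
}

gaussLegendreCache <- new.env(parent = emptyenv())
gaussLegendre48 <- function() {
  if (is.null(gaussLegendreCache$gl48)) {
    # Golub-Welsch: eigen decomposition of the Jacobi matrix
    n <- 48L
    i <- seq_len(n - 1L)
    bet <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- bet
    J[cbind(i + 1L, i)] <- bet
    e <- eigen(J, symmetric = TRUE)
    gaussLegendreCache$gl48 <- list(nodes = e$values,
                                    weights = 2 * e$vectors[1, ]^2)
  }
  gaussLegendreCache$gl48
}

# thresholds from the marginal distribution of an ordinal variable
# (codes need not be contiguous; observed categories define the cells)
ordinalThresholds <- function(x) {
  tab <- table(x)
  if (length(tab) < 2L) stop("variable has fewer than 2 observed categories")
  qnorm(cumsum(tab)[-length(tab)] / sum(tab))
}

polychoricPair <- function(x, y, tauX = NULL, tauY = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(x, y)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("pair has fewer than 2 observed categories on one side")
  tauX <- tauX %||% ordinalThresholds(x)
  tauY <- tauY %||% ordinalThresholds(y)
  tx <- c(-Inf, tauX, Inf)
  ty <- c(-Inf, tauY, Inf)
  gx <- rep(tx, times = length(ty))
  gy <- rep(ty, each = length(tx))
  nr <- length(tx)
  nc <- length(ty)
  nobs <- tab  # counts
  negll <- function(rho) {
    cdf <- matrix(pbivnorm2(gx, gy, rho), nr, nc)
    p <- cdf[-1, -1] - cdf[-nr, -1] - cdf[-1, -nc] + cdf[-nr, -nc]
    p <- pmax(p, 1e-12)
    -sum(nobs * log(p))
  }
  opt <- optimize(negll, interval = c(-0.995, 0.995), tol = 1e-6)
  rho <- opt$minimum
  if (abs(rho) > 0.99) {
    warning("polychoric likelihood flat or boundary-bound; ",
            "falling back to Pearson for this pair")
    rho <- cor(as.numeric(x), as.numeric(y))
  }
  rho
}

#' Polychoric correlation matrix
#'
#' Two-step maximum-likelihood estimates per item pair: thresholds from
#' the marginal frequencies, correlation by one-dimensional likelihood
#' maximisation over the bivariate-normal cell probabilities
#' (pairwise-complete observations). If the resulting matrix is not
#' positive semi-definite, negative eigenvalues are clipped at zero and
#' the matrix renormalised to unit diagonal.
#'
#' @param m a \code{\linkS4class{ResponseMatrix}} with at least 2 items,
#'   each with at least 2 observed categories.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
polychoricMatrix <- function(m) {
  r <- responses(m)
  p <- ncol(r)
  if (p < 2L) stop("at least 2 items are required")
  taus <- lapply(seq_len(p), function(j) ordinalThresholds(r[, j]))
  R <- diag(1, p)
  dimnames(R) <- list(colnames(r), colnames(r))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      complete <- !is.na(r[, i]) & !is.na(r[, j])
      # margins can shift under pairwise deletion; recompute if needed
      ti <- if (all(complete)) taus[[i]] else NULL
      tj <- if (all(complete)) taus[[j]] else NULL
      R[i, j] <- R[j, i] <- polychoricPair(r[, i], r[, j], ti, tj)
    }
  }
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    v <- pmax(e$values, 0)
    R <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    dimnames(R) <- list(colnames(r), colnames(r))
  }
  R
}

#' Permutation-based parallel analysis on polychoric eigenvalues
#'
#' Reference eigenvalues come from column-permuted copies of the data
#' (each item's values independently permuted, preserving the ordinal
#' margins while destroying inter-item structure), with the polychoric
#' matrix recomputed per copy. Factors are retained while the observed
#' eigenvalue exceeds the chosen quantile of the permuted eigenvalues at
#' the same position, stopping at the first failure.
#'
#' @param m a \code{\linkS4class{ResponseMatrix}}.
#' @param R number of permuted copies (default 100).
#' @param quantile reference quantile (default 0.95).
#' @param seed optional integer seed.
#' @return an \code{\linkS4class{EigenReport}} with method
#'   \code{"parallel"}.
#' @export
parallelAnalysis <- function(m, R = 100L, quantile = 0.95, seed = NULL) {
  stopifnot(R >= 1L)
  if (!is.null(seed)) set.seed(seed)
  obs <- sort(eigen(polychoricMatrix(m), symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  r <- responses(m)
  p <- ncol(r)
  perms <- matrix(NA_real_, R, p)
  for (rep in seq_len(R)) {
    shuffled <- apply(r, 2, function(col) sample(col))
    rownames(shuffled) <- rownames(r)
    perms[rep, ] <- sort(eigen(polychoricMatrix(
      responseMatrix(shuffled, K = m@K)), symmetric = TRUE,
      only.values = TRUE)$values, decreasing = TRUE)
  }
  ref <- apply(perms, 2, stats::quantile, probs = quantile, names = FALSE)
  retained <- 0L
  for (j in seq_len(p)) {
    if (obs[j] > ref[j]) retained <- retained + 1L else break
  }
  new("EigenReport", observed = obs,
      reference = list(parallel = ref),
      retained = c(parallel = retained))
}

#' Empirical Kaiser Criterion
#'
#' Retains leading eigenvalues of a correlation spectrum while
#' \eqn{l_j} exceeds its sample-size-adjusted reference
#' \eqn{max(((p - \sum_{i<j} l_i)/(p - j + 1)) (1 + \sqrt{p/n})^2, 1)},
#' stopping at the first failure.
#'
#' @param eigenvalues descending eigenvalues of a correlation matrix
#'   (sum approximately p).
#' @param n sample size (> 0).
#' @param p number of variables (> 0), default \code{length(eigenvalues)}.
#' @return integer count of retained factors; the reference values are
#'   attached as attribute \code{"reference"}.
#' @export
empiricalKaiserCriterion <- function(eigenvalues, n, p = length(eigenvalues)) {
  if (n <= 0 || p <= 0) stop("n and p must be positive")
  if (is.unsorted(rev(eigenvalues)))
    stop("eigenvalues must be in descending order")
  infl <- (1 + sqrt(p / n))^2
  ref <- numeric(length(eigenvalues))
  retained <- 0L
  for (j in seq_along(eigenvalues)) {
    ref[j] <- max(((p - sum(eigenvalues[seq_len(j - 1L)])) / (p - j + 1)) *
                    infl, 1)
    if (eigenvalues[j] > ref[j] && retained == j - 1L) retained <- j
  }
  structure(retained, reference = ref)
}

#' Combined dimensionality report
#'
#' Runs parallel analysis and the Empirical Kaiser Criterion on the
#' polychoric eigenvalues of the same data.
#'
#' @inheritParams parallelAnalysis
#' @return an \code{\linkS4class{EigenReport}} with both methods.
#' @export
dimensionalityReport <- function(m, R = 100L, quantile = 0.95, seed = NULL) {
  pa <- parallelAnalysis(m, R = R, quantile = quantile, seed = seed)
  ekc <- empiricalKaiserCriterion(observedEigenvalues(pa), n = nPersons(m))
  new("EigenReport", observed = observedEigenvalues(pa),
      reference = c(referenceEigenvalues(pa),
                    list(ekc = attr(ekc, "reference"))),
      retained = c(nFactorsRetained(pa), ekc = as.integer(ekc)))
}

#' Write an EigenReport as JSON
#'
#' @param report an \code{\linkS4class{EigenReport}}
#' @param path output JSON path
#' @export
writeEigenReport <- function(report, path) {
  jsonlite::write_json(
    list(observed_eigenvalues = observedEigenvalues(report),
         reference_eigenvalues = referenceEigenvalues(report),
         n_factors_retained = as.list(nFactorsRetained(report))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
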