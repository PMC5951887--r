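# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed by the callers.

# item parameter draws matching the synthetic-study priors
makeItemParams <- function(J, aRange = c(1.2, 2.5), K = 4,
                           thresholdSd = 1, minGap = 0.3,
                           prefix = "it") {
  items <- paste0(prefix, seq_len(J))
  a <- setNames(runif(J, aRange[1], aRange[2]), items)
  b <- setNames(lapply(seq_len(J), function(j) {
    repeat {
      cand <- sort(rnorm(K - 1, 0, thresholdSd))
      if (all(diff(cand) >= minGap)) return(cand)
    }
  }), items)
  list(a = a, b = b)
}

# constant-parameter item set (a = 1.8, b = (-1, 0, 1))
uniformItemParams <- function(J, a = 1.8, b = c(-1, 0, 1)) {
  items <- paste0("it", seq_len(J))
  list(a = setNames(rep(a, J), items),
       b = setNames(rep(list(b), J), items))
}

# shift all thresholds of selected items for one set of draws (uniform DIF)
shiftThresholds <- function(params, items, delta) {
  for (j in items) params$b[[j]] <- params$b[[j]] + delta
  params
}

# two-group GRM sample: group B optionally generated from shifted params
simulateTwoGroup <- function(paramsA, paramsB = paramsA, nA = 300, nB = 300,
                             meanA = 0, meanB = 0) {
  mA <- simulateGRM(paramsA, rnorm(nA, meanA))
  mB <- simulateGRM(paramsB, rnorm(nB, meanB))
  m <- responseMatrix(rbind(responses(mA), responses(mB)), K = 4,
                      personIds = paste0("p", seq_len(nA + nB)))
  list(m = m, groups = factor(rep(c("A", "B"), c(nA, nB))))
}

# ordinal items from a linear factor model, discretised at normal quartiles
makeFactorOrdinal <- function(n, loadingsMatrix) {
  p <- nrow(loadingsMatrix)
  q <- ncol(loadingsMatrix)
  eta <- matrix(rnorm(n * q), n, q)
  cutq <- qnorm(c(0.25, 0.5, 0.75))
  X <- sapply(seq_len(p), function(j) {
    lam <- loadingsMatrix[j, ]
    y <- drop(eta %*% lam) + sqrt(max(1 - sum(lam^2), 1e-6)) * rnorm(n)
    as.integer(cut(y, c(-Inf, cutq, Inf), labels = FALSE))
  })
  colnames(X) <- paste0("v", seq_len(p))
  responseMatrix(X, K = 4)
}

# independent reimplementation of the EAP integral on a finer grid
# (Riemann sum with normal weights); oracle for the quadrature scoring
eapOracleFineGrid <- function(a, b, resp, nQ = 1001) {
  quad <- seq(-6, 6, length.out = nQ)
  w <- dnorm(quad)
  w <- w / sum(w)
  vapply(seq_len(nrow(resp)), function(i) {
    L <- w
    for (j in seq_along(a)) {
      u <- resp[i, j]
      if (is.na(u)) next
      C <- cbind(1, plogis(outer(quad, b[[j]],
                                 function(t, bb) a[j] * (t - bb))), 0)
      L <- L * (C[, u] - C[, u + 1])
    }
    sum(L * quad) / sum(L)
  }, numeric(1))
}

# independent negative log-likelihood of the P(u >= k) cumulative model,
# for derivative-free oracle maximisation
olrNegLogLik <- function(y, X) {
  n <- length(y)
  K <- max(y)
  i <- seq_len(n)
  function(par) {
    alpha <- par[seq_len(K - 1)]
    beta <- par[K:length(par)]
    gam <- cbind(1, plogis(outer(drop(X %*% beta), alpha, "+")), 0)
    P <- gam[cbind(i, y)] - gam[cbind(i, y + 1)]
    if (any(P <= 0)) return(1e10)
    -sum(log(P))
  }
}
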