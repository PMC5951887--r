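test_that("category probabilities follow the two-logistic difference", {
  # symmetric binary item
  expect_equal(unname(grmCategoryProbs(1, 0, 0)), c(0.5, 0.5))

  # hand evaluation of the cumulative-difference formula
  a <- 2; b <- c(-1, 0, 1); th <- 0.5
  cum <- plogis(a * (th - b))
  expect_equal(unname(grmCategoryProbs(a, b, th)),
               c(1 - cum[1], cum[1] - cum[2], cum[2] - cum[3], cum[3]),
               tolerance = 1e-12)

  # normalisation and monotone cumulative probabilities everywhere
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 0.3, 3)
    b <- sort(rnorm(3))
    th <- seq(-4, 4, length.out = 9)
    p <- grmCategoryProbs(a, b, th)
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 9), tolerance = 1e-12)
    # P(u >= k | theta) increasing in theta for a > 0
    cumk <- t(apply(p, 1, function(x) rev(cumsum(rev(x)))))
    expect_true(all(diff(cumk[, 2]) > 0))
  }
})

test_that("GRM calibration is deterministic and dominates the truth", {
  set.seed(5)
  params <- makeItemParams(6)
  m <- simulateGRM(params, rnorm(700), seed = 8)

  fit1 <- fitGRM(m)
  fit2 <- fitGRM(m)
  expect_identical(discrimination(fit1), discrimination(fit2))
  expect_identical(thresholds(fit1), thresholds(fit2))

  # EM trace monotone (tolerance 1e-8)
  expect_true(all(diff(emTrace(fit1)) > -1e-8))

  # marginal likelihood at the MLE at least that of the generating values
  expect_gte(logLik(fit1), grmLogLik(params, m))

  # thresholds returned sorted
  expect_true(all(vapply(thresholds(fit1),
                         function(b) !is.unsorted(b, strictly = TRUE),
                         logical(1))))
})

test_that("calibration fails informatively on unobserved categories", {
  set.seed(6)
  r <- matrix(sample(c(1L, 2L, 4L), 200, TRUE), 100, 2,
              dimnames = list(NULL, c("i1", "i2")))
  r[1, 1] <- 3L  # i1 has all four; i2 lacks category 3
  expect_error(fitGRM(responseMatrix(r, K = 4)), "i2.*category 3")
  expect_error(fitGRM(responseMatrix(r[, 1, drop = FALSE], K = 4)),
               "at least 2 items")
})

test_that("simulate-then-fit recovery sharpens with sample size", {
  params <- uniformItemParams(8)
  recovery <- function(n, seed) {
    m <- simulateGRM(params, {set.seed(seed); rnorm(n)}, seed = seed + 1)
    fit <- fitGRM(m)
    mean(abs(discrimination(fit) - 1.8)) +
      mean(abs(do.call(rbind, thresholds(fit)) -
                 matrix(c(-1, 0, 1), 8, 3, byrow = TRUE)))
  }
  errSmall <- recovery(500, 31)
  errLarge <- recovery(4000, 32)
  expect_lt(errLarge, errSmall)
  expect_lt(errLarge, 0.1)
})

test_that("EAP scoring handles missingness and is monotone in responses", {
  set.seed(7)
  params <- makeItemParams(5)
  m <- simulateGRM(params, rnorm(50), seed = 9)
  r <- responses(m)
  r[1, ] <- NA  # person with no observed responses
  r[2, 3] <- NA
  m2 <- responseMatrix(r, K = 4)
  fit <- fitGRM(m)
  sc <- eapScores(fit, m2)
  expect_equal(traitEstimates(sc)[1], 0)
  expect_equal(traitSE(sc)[1], 1)
  expect_true(all(is.finite(traitEstimates(sc))))

  # monotonicity: enumerate all patterns of 3 binary items; raising one
  # response never lowers the EAP
  bin <- list(a = setNames(c(1.2, 0.8, 1.7), paste0("b", 1:3)),
              b = setNames(list(-0.5, 0.2, 0.8), paste0("b", 1:3)))
  pats <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  colnames(pats) <- paste0("b", 1:3)
  mp <- responseMatrix(pats, K = 2)
  th <- traitEstimates(eapScores(bin, mp))
  for (i in seq_len(nrow(pats))) {
    for (j in 1:3) {
      if (pats[i, j] == 1) {
        up <- pats[i, ]
        up[j] <- 2
        k <- which(apply(pats, 1, function(row) all(row == up)))
        expect_gt(th[k], th[i])
      }
    }
  }
})

test_that("simulated responses match the model frequencies and the seed", {
  # degenerate high-discrimination item: theta far above the threshold
  steep <- list(a = c(i1 = 50, i2 = 50), b = list(i1 = 0, i2 = 0))
  m <- simulateGRM(steep, rep(3, 400), seed = 10)
  expect_gt(mean(responses(m) == 2L), 0.999)

  # empirical frequencies within 3 SE of the category probabilities
  params <- list(a = c(i1 = 1.5, i2 = 1.5),
                 b = list(i1 = c(-1, 0, 1), i2 = c(-0.5, 0.3, 1.2)))
  n <- 5000
  m2 <- simulateGRM(params, rep(0, n), seed = 11)
  for (j in c("i1", "i2")) {
    p <- grmCategoryProbs(params$a[[j]], params$b[[j]], 0)
    emp <- tabulate(responses(m2)[, j], 4) / n
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(emp - p) <= 3 * se + 1e-9),
                label = paste("frequencies for", j))
  }

  # reproducibility
  m3 <- simulateGRM(params, rep(0.3, 30), seed = 13)
  m4 <- simulateGRM(params, rep(0.3, 30), seed = 13)
  expect_identical(responses(m3), responses(m4))
})

test_that("fitted parameters serialise to JSON and back", {
  set.seed(8)
  params <- makeItemParams(4)
  m <- simulateGRM(params, rnorm(400), seed = 14)
  fit <- fitGRM(m)
  path <- withr::local_tempfile(fileext = ".json")
  writeGRMParams(fit, path)
  back <- readGRMParams(path)
  expect_equal(back$a, discrimination(fit))
  expect_equal(back$b, thresholds(fit))
  # usable for scoring in place of the fit object
  expect_equal(traitEstimates(eapScores(back, m)),
               traitEstimates(eapScores(fit, m)))
})
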