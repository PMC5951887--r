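test_that("intercept-only cumulative model has closed-form logits", {
  y <- rep(1:2, each = 30)
  f <- fitProportionalOdds(y, NULL)
  expect_equal(unname(f$alpha), 0)           # logit of P(u >= 2) = 0.5
  expect_equal(f$loglik, 60 * log(0.5))

  y4 <- rep(1:4, c(10, 20, 40, 30))
  f4 <- fitProportionalOdds(y4, NULL)
  expect_equal(unname(f4$alpha), qlogis(c(0.9, 0.7, 0.3)))
})

test_that("Newton fit agrees with an independent implementation", {
  # cross-check against MASS::polr, which models P(u <= k) with
  # logit P(u <= k) = zeta_k - eta: alpha_{k+1} = -zeta_k, same slopes
  skip_if_not_installed("MASS")
  set.seed(20)
  n <- 400
  X <- cbind(theta = rnorm(n), z = rbinom(n, 1, 0.4))
  y <- as.integer(cut(0.8 * X[, 1] - 0.5 * X[, 2] + rlogis(n),
                      c(-Inf, -1, 0.2, 1, Inf)))
  f <- fitProportionalOdds(y, X)
  pf <- MASS::polr(factor(y) ~ X, method = "logistic")
  expect_equal(unname(f$beta), unname(pf$coefficients), tolerance = 1e-4)
  expect_equal(unname(f$alpha), unname(-pf$zeta), tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(logLik(pf)), tolerance = 1e-8)

  # alphas non-increasing (P(u >= k) decreases in k)
  expect_true(all(diff(f$alpha) < 0))
})

test_that("degenerate designs are rejected", {
  y <- rep(1:3, each = 20)
  expect_error(fitProportionalOdds(rep(1L, 10), NULL), "single category")
  expect_error(fitProportionalOdds(c(1L, 1L, 3L, 3L), NULL),
               "category 2 not present")
  # constant column is collinear with the intercepts
  expect_error(fitProportionalOdds(y, cbind(x = rnorm(60), const = 1)),
               "rank deficient")
})

test_that("Nagelkerke R2 follows the rescaled Cox-Snell formula", {
  expect_equal(nagelkerkeR2(-100, -100, 50), 0)
  # perfect fit against a balanced binary null reaches the bound 1
  expect_equal(nagelkerkeR2(10 * log(0.5), 0, 10), 1)
  # arithmetic oracle: direct evaluation of the two-line formula
  ll0 <- -140; ll1 <- -120; n <- 200
  r2cs <- 1 - exp(2 * (ll0 - ll1) / n)
  expect_equal(nagelkerkeR2(ll0, ll1, n), r2cs / (1 - exp(2 * ll0 / n)))
  expect_error(nagelkerkeR2(-100, -120, 50), "below the null")
  expect_error(nagelkerkeR2(0, 0, 50), "undefined")
})

test_that("exchangeable groups produce no spurious DIF signal", {
  set.seed(21)
  params <- makeItemParams(4)
  th <- rnorm(250)
  m <- simulateGRM(params, th, seed = 22)
  y <- responses(m)[, 1]
  # two byte-identical groups: duplicate every person under both labels
  y2 <- c(y, y); th2 <- c(th, th)
  g <- factor(rep(c("A", "B"), each = 250))
  s <- difStatisticsForItem(y2, th2, g, "it1")
  expect_lt(abs(s$d12), 1e-6)
  expect_lt(abs(s$d23), 1e-6)
})

test_that("label shuffling keeps pseudo-R2 changes near zero", {
  set.seed(23)
  params <- makeItemParams(6)
  th <- rnorm(600)
  m <- simulateGRM(params, th, seed = 24)
  sc <- traitEstimates(eapScores(fitGRM(m), m))
  y <- responses(m)[, 3]
  small <- replicate(100, {
    g <- factor(sample(rep(c("A", "B"), each = 300)))
    s <- difStatisticsForItem(y, sc, g, "it3")
    s$d12 < 0.01 && s$d23 < 0.01
  })
  expect_gte(sum(small), 95)
})

test_that("injected uniform DIF shows up as a d12-dominant signal", {
  set.seed(25)
  params <- uniformItemParams(6)
  shifted <- shiftThresholds(params, "it1", 1.0)
  tg <- simulateTwoGroup(params, shifted, nA = 500, nB = 500)
  sc <- traitEstimates(eapScores(fitGRM(tg$m), tg$m))
  s <- difStatisticsForItem(responses(tg$m)[, "it1"], sc, tg$groups, "it1")
  expect_gt(s$d12, 0.02)
  expect_gt(s$d12, s$d23)
})

test_that("multi-group statistics reduce to the two-group form at G = 2", {
  set.seed(26)
  params <- makeItemParams(4)
  tg <- simulateTwoGroup(params, params, nA = 200, nB = 200)
  sc <- traitEstimates(eapScores(fitGRM(tg$m), tg$m))
  y <- responses(tg$m)[, 1]
  s <- difStatisticsForItem(y, sc, tg$groups, "it1")
  # explicit two-group fit: single indicator and single interaction column
  ind <- as.numeric(tg$groups == "B")
  m2 <- fitProportionalOdds(y, cbind(theta = sc, B = ind))
  m3 <- fitProportionalOdds(y, cbind(theta = sc, B = ind, tB = sc * ind))
  expect_equal(s$loglik2, m2$loglik, tolerance = 1e-8)
  expect_equal(s$loglik3, m3$loglik, tolerance = 1e-8)
})
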