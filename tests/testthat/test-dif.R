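test_that("threshold is the grid ceiling strictly above the null maximum", {
  expect_equal(hybridDIF:::gridCeiling(0.0137, 0.01), 0.02)
  expect_equal(hybridDIF:::gridCeiling(0.0201, 0.01), 0.03)
  # exactly on the grid still moves strictly above
  expect_equal(hybridDIF:::gridCeiling(0.02, 0.01), 0.03)
})

test_that("Monte-Carlo thresholds are reproducible and bound the null", {
  set.seed(30)
  params <- makeItemParams(4)
  tg <- simulateTwoGroup(params, params, nA = 80, nB = 80)
  fit <- fitGRM(tg$m)
  sc <- eapScores(fit, tg$m)
  cfg <- difConfig(nMcReplications = 5, seed = 99)
  t1 <- monteCarloThresholds(fit, sc, tg$groups, cfg)
  t2 <- monteCarloThresholds(fit, sc, tg$groups, cfg)
  expect_identical(t1, t2)
  expect_gt(t1$threshold, max(t1$d12Max, t1$d23Max))
  expect_equal(t1$nReplicationsUsed, 5L)
})

test_that("byte-identical groups yield no flags in a single iteration", {
  set.seed(31)
  params <- makeItemParams(5)
  th <- rnorm(200)
  m1 <- simulateGRM(params, th, seed = 32)
  r <- rbind(responses(m1), responses(m1))
  rownames(r) <- paste0("p", seq_len(400))
  m <- responseMatrix(r, K = 4)
  g <- factor(rep(c("A", "B"), each = 200))
  res <- runDIFPurification(m, g, difConfig(thresholds = 0.01, seed = 1))
  expect_equal(length(flaggedItems(res)), 0L)
  expect_equal(res@nIterations, 1L)
  expect_true(isConverged(res))
  expect_equal(sort(anchorItems(res)), sort(itemIds(m)))
})

test_that("an infinite threshold flags nothing and stops immediately", {
  set.seed(33)
  params <- makeItemParams(4)
  tg <- simulateTwoGroup(params, params, nA = 100, nB = 100)
  res <- runDIFPurification(tg$m, tg$groups,
                            difConfig(thresholds = Inf, seed = 2))
  expect_equal(length(flaggedItems(res)), 0L)
  expect_equal(res@nIterations, 1L)
})

test_that("flag decisions are invariant to renaming the group labels", {
  set.seed(34)
  params <- uniformItemParams(6)
  shifted <- shiftThresholds(params, c("it1", "it2"), 0.9)
  tg <- simulateTwoGroup(params, shifted, nA = 300, nB = 300)
  cfg <- difConfig(thresholds = 0.02, seed = 3)
  res1 <- runDIFPurification(tg$m, tg$groups, cfg)
  # rename so the sorted order of the labels flips
  g2 <- factor(ifelse(tg$groups == "A", "Z", "M"))
  res2 <- runDIFPurification(tg$m, g2, cfg)
  expect_identical(flaggedItems(res1), flaggedItems(res2))
  expect_equal(statsTable(res1)$d12, statsTable(res2)$d12, tolerance = 1e-8)
  expect_equal(statsTable(res1)$d23, statsTable(res2)$d23, tolerance = 1e-8)
})

test_that("the stats table carries the published layout and is exportable", {
  set.seed(35)
  params <- makeItemParams(4)
  tg <- simulateTwoGroup(params, params, nA = 120, nB = 120)
  res <- runDIFPurification(tg$m, tg$groups,
                            difConfig(thresholds = 0.02, seed = 4))
  tab <- statsTable(res)
  expect_true(all(c("item", "d12", "d23", "d13", "threshold",
                    "flagged_uniform", "flagged_nonuniform") %in%
                    names(tab)))
  expect_equal(tab$item, itemIds(tg$m))
  # telescoping identity and monotone nested log-likelihoods
  expect_equal(tab$d13, tab$d12 + tab$d23, tolerance = 1e-12)
  expect_true(all(tab$loglik1 >= tab$loglik0 - 1e-8))
  expect_true(all(tab$loglik2 >= tab$loglik1 - 1e-8))
  expect_true(all(tab$loglik3 >= tab$loglik2 - 1e-8))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  exportStatsTable(res, tsv)
  lines <- readLines(tsv)
  expect_match(lines[1], "^# hybridDIF stats table")
  back <- read.delim(tsv, comment.char = "#")
  expect_equal(nrow(back), nItems(tg$m))

  js <- withr::local_tempfile(fileext = ".json")
  writeDIFRunResult(res, js)
  obj <- jsonlite::fromJSON(js)
  expect_true(obj$converged)
  expect_equal(obj$thresholds$threshold, res@thresholds$threshold)
})

test_that("purification removes planted DIF items from the anchor set", {
  set.seed(36)
  params <- uniformItemParams(8)
  shifted <- shiftThresholds(params, c("it2", "it5"), 1.2)
  tg <- simulateTwoGroup(params, shifted, nA = 400, nB = 400)
  res <- runDIFPurification(tg$m, tg$groups,
                            difConfig(thresholds = 0.02, seed = 5))
  expect_true(all(c("it2", "it5") %in% flaggedItems(res)))
  expect_true(isConverged(res))
  expect_false(any(c("it2", "it5") %in% anchorItems(res)))
  # the final two recorded iterations agree
  nIt <- length(difIterations(res))
  if (nIt >= 2)
    expect_identical(difIterations(res)[[nIt]],
                     difIterations(res)[[nIt - 1]])
})
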