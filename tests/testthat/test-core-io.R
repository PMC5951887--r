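test_that("CSV responses read back exactly and bad cells are rejected", {
  sc <- scaleDefinition(list(s1 = c("item_1", "item_2", "item_3")))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item_1,item_2,item_3,group",
               "1,2,3,A", "4,4,1,A", "2,,3,B"), path)
  out <- loadResponses(path, sc)
  expect_equal(nPersons(out$responses), 3L)
  expect_equal(unname(responses(out$responses)[1, ]), c(1L, 2L, 3L))
  expect_true(is.na(responses(out$responses)[3, "item_2"]))
  expect_equal(as.character(out$groups), c("A", "A", "B"))

  writeLines(c("item_1,item_2,item_3,group", "1,5,3,A"), path)
  expect_error(loadResponses(path, sc), "item_2.*row 1|row 1.*item_2")

  writeLines(c("item_1,item_2,item_3,group", "1,2.5,3,A"), path)
  expect_error(loadResponses(path, sc), "non-integer")

  writeLines(c("item_1,item_3,group", "1,3,A"), path)
  expect_error(loadResponses(path, sc), "item_2")
})

test_that("a generated study round-trips through write and load", {
  spec <- studySpec(groups = data.frame(
    name = c("A", "B"), n = c(25L, 25L), theta_mean = c(0, 0),
    theta_sd = 1, female = c(0.5, 0.5)), seed = 1)
  st <- generateStudy(spec)
  dir <- withr::local_tempdir()
  files <- writeStudy(st, dir)
  back <- loadResponses(files["responses"], hivStigmaScale32(),
                        idColumn = "person_id")
  expect_identical(responses(back$responses), responses(st$responses))
  expect_equal(as.character(back$groups), as.character(st$groups))
})

test_that("reverse coding flips codes, is an involution, keeps missingness", {
  sc <- hivStigmaScale32()
  items <- scaleItems(sc)
  set.seed(2)
  r <- matrix(sample(c(1:4, NA), 20 * 32, TRUE, prob = c(rep(.23, 4), .08)),
              20, 32, dimnames = list(paste0("p", 1:20), items))
  m <- responseMatrix(r, K = 4)
  rc <- applyReverseCoding(m, sc)
  # code 1 on item 21 becomes 4
  idx <- which(r[, "item_21"] == 1)
  expect_true(all(responses(rc)[idx, "item_21"] == 4L))
  # untouched items unchanged
  expect_identical(responses(rc)[, "item_4"], r[, "item_4"])
  # involution and missingness pattern
  expect_identical(responses(applyReverseCoding(rc, sc)), r)
  expect_identical(is.na(responses(rc)), is.na(r))
  # empty reverse set is the identity
  sc0 <- scaleDefinition(subscales(sc))
  expect_identical(responses(applyReverseCoding(m, sc0)), r)
})

test_that("listwise subsetting drops incomplete persons and missing groups", {
  r <- matrix(c(1, 2, 3,
                2, NA, 4,
                3, 3, 3,
                4, 1, 2), 4, 3, byrow = TRUE,
              dimnames = list(paste0("p", 1:4), paste0("i", 1:3)))
  storage.mode(r) <- "integer"
  m <- responseMatrix(r, K = 4)
  g <- factor(c("A", "A", "B", "B"))

  out <- listwiseSubset(m, g, c("i1", "i2", "i3"))
  expect_equal(personIds(out$responses), c("p1", "p3", "p4"))
  expect_false(anyNA(responses(out$responses)))

  # person with missing group label (e.g. a recoded respondent) is excluded
  g2 <- factor(c("A", "A", NA, "B"))
  out2 <- listwiseSubset(m, g2, c("i1", "i3"))
  expect_equal(personIds(out2$responses), c("p1", "p2", "p4"))

  # nothing missing: identity
  m3 <- responseMatrix(r[c(1, 3, 4), ], K = 4)
  out3 <- listwiseSubset(m3, factor(c("A", "B", "B")))
  expect_identical(responses(out3$responses), r[c(1, 3, 4), ])

  expect_error(listwiseSubset(m, factor(rep(NA_character_, 4)), "i1"),
               "no persons remain")
})

test_that("sparse categories merge inward and recounts respect the minimum", {
  # per-group minimum 6 at minCell 5: untouched
  set.seed(3)
  x <- rep(1:4, c(6, 10, 9, 7))
  m <- responseMatrix(cbind(i1 = x, i2 = rev(x)), K = 4)
  g <- factor(rep(c("A"), 32))
  out <- collapseSparseCategories(m, g, minCell = 5)
  expect_identical(responses(out$responses), responses(m))
  expect_equal(nrow(out$report), 0L)

  # counts (3, 10, 12, 9): categories 1 and 2 merge, K' = 3
  x2 <- rep(1:4, c(3, 10, 12, 9))
  m2 <- responseMatrix(cbind(i1 = x2, i2 = sample(x2)), K = 4)
  out2 <- collapseSparseCategories(m2, factor(rep("A", 34)), minCell = 5)
  expect_equal(sort(unique(responses(out2$responses)[, "i1"])), 1:3)
  expect_equal(out2$report$mergedFrom[1], 1)
  expect_equal(out2$report$mergedInto[1], 2)
  expect_equal(max(table(responses(out2$responses)[, "i1"])[1]), 13)

  # recount oracle: after collapsing, every group x category count >= minCell
  for (seed in 1:5) {
    set.seed(seed)
    r <- matrix(sample(1:4, 200, TRUE, prob = c(.04, .3, .36, .3)), 100, 2,
                dimnames = list(NULL, c("a", "b")))
    mm <- responseMatrix(r, K = 4)
    gg <- factor(rep(c("G1", "G2"), each = 50))
    res <- collapseSparseCategories(mm, gg, minCell = 5)
    for (j in itemIds(res$responses)) {
      tab <- table(gg, responses(res$responses)[, j])
      expect_true(all(tab >= 5),
                  label = sprintf("seed %d item %s all cells >= 5", seed, j))
    }
    # deterministic: identical rerun
    res2 <- collapseSparseCategories(mm, gg, minCell = 5)
    expect_identical(responses(res$responses), responses(res2$responses))
    expect_identical(res$report, res2$report)
  }

  # an item whose categories all merge away fails with a diagnostic
  x3 <- rep(1:4, c(2, 2, 2, 2))
  m3 <- responseMatrix(cbind(i1 = x3), K = 4)
  expect_error(collapseSparseCategories(m3, factor(rep("A", 8)), minCell = 5),
               "single category")
})

test_that("the bundled scale fixture matches the 32-item instrument layout", {
  sc <- hivStigmaScale32()
  sizes <- vapply(subscales(sc), length, integer(1))
  expect_equal(unname(sizes), c(11L, 8L, 6L, 7L))
  expect_equal(sort(reverseItems(sc)), c("item_21", "item_8"))
  expect_equal(length(scaleItems(sc)), 32L)
  expect_false(anyDuplicated(scaleItems(sc)) > 0)
})
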