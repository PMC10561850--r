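test_that("confusion matrices count actual-by-predicted", {
  groups <- c("a", "b")
  cm <- confusionCounts(c("a", "b", "a"), c("a", "b", "a"), groups)
  expect_equal(unname(diag(cm)), c(2L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  expect_equal(sum(confusionCounts(character(0), character(0), groups)), 0L)
  expect_error(confusionCounts("c", "a", groups), "outside groups")

  fx <- workedFixtures()$table11_labels
  cm <- confusionCounts(fx$actual, fx$predicted, fx$groups)
  expect_equal(unname(cm),
               rbind(c(17L, 1L, 0L, 0L), c(0L, 26L, 0L, 0L),
                     c(0L, 0L, 10L, 0L), c(0L, 0L, 0L, 10L)))
  expect_equal(unname(rowSums(cm)), c(18L, 26L, 10L, 10L))
})

test_that("metrics reproduce the worked four-group example", {
  fx <- workedFixtures()$table11_labels
  cm <- confusionCounts(fx$actual, fx$predicted, fx$groups)
  ex <- classificationMetrics(cm, "exact")
  expect_equal(ex$accuracy, 100 * 63 / 64)
  expect_equal(ex$perClass$recall[1], 17 / 18)
  expect_equal(ex$perClass$precision[2], 26 / 27)
  expect_equal(ex$perClass$f1[1], 2 / (18 / 17 + 1))
  expect_equal(unname(ex$macro["f1"]), 0.9881, tolerance = 1e-4)

  pa <- classificationMetrics(cm, "paper")
  expect_equal(pa$perClass$f1, c(0.97, 0.98, 1, 1))
  expect_equal(unname(pa$macro["f1"]), 0.9875)
  # the published table's "Precision" column is row-normalized (recall)
  po <- classificationMetrics(cm, "paper", paperOrientation = TRUE)
  expect_equal(po$perClass$precision, c(0.94, 1, 1, 1))
  expect_equal(unname(po$macro["precision"]), 0.985)
})

test_that("metric edge cases behave as contracted", {
  id <- confusionCounts(c("a", "b"), c("a", "b"), c("a", "b"))
  m <- classificationMetrics(id)
  expect_equal(m$accuracy, 100)
  expect_equal(m$perClass$f1, c(1, 1))

  cm <- matrix(c(2L, 1L, 0L, 0L), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  m <- classificationMetrics(cm)
  expect_equal(m$perClass$precision[2], 1)   # empty predicted column
  expect_equal(m$perClass$recall[2], 0)
  expect_equal(m$perClass$f1[2], 0)
  cm0 <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(classificationMetrics(cm0), "no actual samples")
})

test_that("pairwise precision counts per-pair binary decisions", {
  x <- toyDataset()
  planes <- fitAllPairs(x)
  cal <- calibrateAllPlanes(planes, x)
  tab <- pairwisePrecision(x, cal)
  cc <- unname(classCounts(x))
  expect_equal(tab$total,
               c(cc[1] + cc[2], cc[1] + cc[3], cc[2] + cc[3]))
  expect_equal(tab$correct, tab$total)  # separable fixture: all correct
  ftab <- formatPairwise(tab)
  expect_equal(ftab["1", "2"], sprintf("%d/%d", cc[1] + cc[2], cc[1] + cc[2]))

  # inverting a threshold caps the entry at the majority class size
  inv <- cal
  far <- max(abs(planeProjection(x, cal[[1]]))) + 10
  inv[[1]]@threshold <- far    # everything falls to the negative side
  tinv <- pairwisePrecision(x, inv)
  expect_equal(tinv$correct[1], unname(classCounts(x)[2]))
  expect_lte(tinv$correct[1], max(cc[1], cc[2]))
})

test_that("evaluated totals follow the reference test counts", {
  x <- simulateExpression(seed = 5)
  sp <- stratifiedSplit(x, 39 / 64, seed = 5)
  # test counts (3,4,10,4,4): class 1 pair denominators 7, 13, 7, 7
  cc <- unname(classCounts(sp@test))
  expect_equal(cc, c(3L, 4L, 10L, 4L, 4L))
  expect_equal(cc[1] + cc[2], 7L)
  expect_equal(cc[1] + cc[3], 13L)
})
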