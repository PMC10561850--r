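mkset <- function(vals, labels = rep("a", nrow(as.matrix(vals))))
  ExpressionDataset(as.matrix(vals), labels = labels)

test_that("the affine map hits its endpoints and midpoints", {
  x <- mkset(cbind(c(0, 5, 10)))
  p <- fitMinmax(x, alpha = 2, beta = 1)
  expect_equal(p@featureMin, 0, ignore_attr = TRUE)
  expect_equal(p@featureMax, 10, ignore_attr = TRUE)
  expect_equal(as.vector(transformMinmax(x, p)), c(-1, 0, 1))

  y <- mkset(cbind(c(1, 2, 4)))
  expect_equal(as.vector(transformMinmax(y, fitMinmax(y))),
               c(-1, -1 / 3, 1))
})

test_that("every non-degenerate training feature attains -beta and alpha-beta", {
  set.seed(8)
  x <- mkset(matrix(rnorm(40), 8, 5))
  for (ab in list(c(2, 1), c(3, 0.5))) {
    p <- fitMinmax(x, alpha = ab[1], beta = ab[2])
    z <- transformMinmax(x, p)
    expect_equal(unname(apply(z, 2, min)), rep(-ab[2], 5))
    expect_equal(unname(apply(z, 2, max)), rep(ab[1] - ab[2], 5))
  }
})

test_that("degenerate features map to the range midpoint and are flagged", {
  x <- mkset(cbind(c(3, 3, 3), c(0, 1, 2)))
  p <- fitMinmax(x, alpha = 2, beta = 1)
  expect_equal(p@degenerate, c(TRUE, FALSE), ignore_attr = TRUE)
  expect_equal(transformMinmax(x, p)[, 1], rep(0, 3), ignore_attr = TRUE)
})

test_that("fitting rejects invalid constants and mismatched probes", {
  x <- mkset(cbind(1:3))
  expect_error(fitMinmax(x, alpha = 1, beta = 1), "alpha")
  p <- fitMinmax(x)
  expect_error(transformMinmax(matrix(1, 1, 2), p), "mismatch")
})

test_that("refitting on normalized training output is idempotent", {
  set.seed(9)
  x <- mkset(matrix(rnorm(30), 6, 5))
  p <- fitMinmax(x)
  z <- transformMinmax(x, p)
  p2 <- fitMinmax(mkset(z))
  expect_equal(unname(p2@featureMin), rep(-1, 5))
  expect_equal(unname(p2@featureMax), rep(1, 5))
  expect_equal(transformMinmax(mkset(z), p2), z, tolerance = 1e-12)
})

test_that("test samples may map outside the fitted range", {
  x <- mkset(cbind(c(0, 10)))
  p <- fitMinmax(x)
  expect_equal(as.vector(transformMinmax(matrix(c(-5, 15), 2, 1), p)),
               c(-2, 2))
})

test_that("per-class centering removes block means and is a projection", {
  z <- rbind(c(1, 2), c(3, 4))
  cc <- centerByClass(z, c(1, 1))
  expect_equal(cc@centered, rbind(c(-1, -1), c(1, 1)))

  # two classes, different means: offsets removed, within-class spread kept
  z <- cbind(c(0, 2, 10, 14))
  cc <- centerByClass(z, c(1, 1, 2, 2))
  expect_equal(as.vector(cc@centered), c(-1, 1, -2, 2))
  expect_equal(as.vector(cc@classMeans), c(1, 12))

  set.seed(10)
  z <- matrix(rnorm(40), 8, 5)
  codes <- rep(1:2, each = 4)
  cc <- centerByClass(z, codes)
  for (blk in cc@classBlocks)
    expect_lt(max(abs(colMeans(cc@centered[blk, ]))), 1e-9)
  twice <- centerByClass(cc@centered, codes[cc@rowIndex])
  expect_equal(twice@centered, cc@centered, tolerance = 1e-12)
})
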