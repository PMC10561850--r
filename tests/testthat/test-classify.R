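mkplane <- function(w, pair = c(1L, 2L)) new("SeparatingPlane",
  pair = as.integer(pair), pairLabels = as.character(pair),
  weights = w, bias = 0, objectiveValue = 0, separable = TRUE,
  solverStatus = "optimal")

test_that("projection is the bias-free linear map", {
  p <- mkplane(c(1, 0))
  s <- rbind(c(3, 9), c(-1, 5))
  expect_equal(planeProjection(s, p), c(3, -1))
  expect_equal(planeProjection(s, mkplane(c(0, 0))), c(0, 0))
  expect_equal(planeProjection(2 * s, p), 2 * planeProjection(s, p))
  expect_error(planeProjection(matrix(1, 1, 3), p), "mismatch")
})

test_that("optimal threshold maximizes correct decisions, widest-gap rule", {
  r <- optimalThreshold(c(1, 2, -2, -1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$threshold, 0)
  expect_equal(r$accuracy, 1)

  r <- optimalThreshold(c(0, 2, 1), c(TRUE, TRUE, FALSE))
  expect_equal(r$accuracy, 2 / 3)
  expect_equal(r$accuracy * 3,
               oracleBestCutAccuracy(c(0, 2, 1), c(TRUE, TRUE, FALSE)))

  # single-label degenerate cases decide everything correctly
  r <- optimalThreshold(c(1, 3), c(TRUE, TRUE))
  expect_equal(r$threshold, 0)
  expect_equal(r$accuracy, 1)
  r <- optimalThreshold(c(1, 3), c(FALSE, FALSE))
  expect_equal(r$accuracy, 1)
  expect_gte(r$threshold, 3)

  # one distinct projection with both labels: majority fraction
  r <- optimalThreshold(c(5, 5, 5), c(TRUE, FALSE, FALSE))
  expect_equal(r$accuracy, 2 / 3)
})

test_that("threshold search equals the exhaustive scan on random instances", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:60, 1)
    proj <- round(rnorm(n, sd = sample(c(0.5, 2), 1)), sample(0:2, 1))
    pos <- as.logical(sample(0:1, n, replace = TRUE))
    r <- optimalThreshold(proj, pos)
    best <- oracleBestCutAccuracy(proj, pos)
    expect_equal(r$accuracy * n, best)
    got <- sum(pos & proj > r$threshold) + sum(!pos & proj <= r$threshold)
    expect_equal(got, best)   # the returned threshold attains the optimum
  }
})

test_that("calibration accuracy is invariant under increasing transforms", {
  set.seed(32)
  proj <- rnorm(30); pos <- proj + rnorm(30, sd = 0.5) > 0
  r1 <- optimalThreshold(proj, pos)
  r2 <- optimalThreshold(exp(proj), pos)   # strictly increasing
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("pairwise voting reduces to the plane sign for two classes", {
  p <- new("CalibratedPlane", plane = mkplane(1), threshold = 0.5,
           calibrationAccuracy = 1)
  s <- rbind(2, -1, 0.5)
  expect_equal(classifyVote(s, list("1|2" = p)), c(1L, 2L, 2L))
})

test_that("the three-class voting cycle resolves by summed margins", {
  fx <- workedFixtures()$vote_cycle3
  expect_equal(classifyVote(fx$sample, fx$planes), fx$expected)
  # with equal margins the smallest class code wins
  eq <- lapply(fx$planes, function(p) {
    p@threshold <- sign(p@threshold); p })
  expect_equal(classifyVote(fx$sample, eq), 1L)
  expect_error(classifyVote(fx$sample, fx$planes[1:2]), "every class pair")
})

test_that("decision lists descend thresholded planes to a singleton", {
  # two 1-D features: feature 1 separates {1,2} from {3}, feature 2 splits 1|2
  pl <- list(A = mkplane(c(1, 0), c(1L, 3L)), B = mkplane(c(0, 1), c(1L, 2L)))
  nodes <- list(
    decisionNode(1:3, "A", 0, left = 1:2, right = 3),
    decisionNode(1:2, "B", 0, left = 1, right = 2))
  samples <- rbind(c(1, 1), c(1, -1), c(-1, 0))
  expect_equal(classifyDecisionList(samples, nodes, pl), c(1L, 2L, 3L))
  expect_error(classifyDecisionList(rbind(c(1, 1)), nodes[1],
                                    pl["A"]), "no decision node")
  # a single node over two classes behaves like one calibrated plane
  single <- list(decisionNode(1:2, "B", 0, left = 1, right = 2))
  expect_equal(classifyDecisionList(samples, single, pl), c(1L, 2L, 2L))
})

test_that("greedy decision list agrees with voting on separable data", {
  x <- toyDataset()
  planes <- fitAllPairs(x)
  cal <- calibrateAllPlanes(planes, x)
  nodes <- greedyDecisionList(cal, x)
  expect_true(all(vapply(nodes, function(n)
    length(n$left) >= 1 && length(n$right) >= 1, logical(1))))
  voted <- classifyVote(x, cal)
  listed <- classifyDecisionList(x, nodes, cal)
  expect_equal(listed, voted)
  expect_equal(voted, classCodes(x))   # training-set reproduction
})

test_that("overlapping branch sets still resolve the ambiguous class", {
  # mirrors the published tree shape: class 3 resolvable on either branch
  pl <- list(A = mkplane(c(1, 0), c(1L, 2L)), B = mkplane(c(0, 1), c(1L, 3L)),
             C = mkplane(c(0, 1), c(2L, 3L)))
  nodes <- list(
    decisionNode(1:3, "A", 0, left = c(1, 3), right = c(2, 3)),
    decisionNode(c(1, 3), "B", 0, left = 1, right = 3),
    decisionNode(c(2, 3), "C", 0, left = 2, right = 3))
  samples <- rbind(c(1, 1), c(1, -1), c(-1, -1), c(-1, 1))
  expect_equal(classifyDecisionList(samples, nodes, pl),
               c(1L, 3L, 3L, 2L))
})
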