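test_that("the pairwise LP has the stated shape and coefficients", {
  Di <- matrix(2, 1, 1); Dj <- matrix(0, 1, 1)
  pb <- buildPairLP(Di, Dj)
  expect_equal(dim(pb@constraints), c(2L, 4L))      # k+1+ni+nj variables
  expect_equal(pb@constraints, rbind(c(2, -1, 1, 0), c(0, 1, 0, 1)))
  expect_equal(pb@rhs, c(1, 1))
  expect_equal(pb@objective, c(0, 0, 1, 1))

  pb2 <- buildPairLP(matrix(1:6, 2, 3), matrix(1:9, 3, 3))
  expect_equal(pb2@objective,
               c(rep(0, 4), rep(1 / 2, 2), rep(1 / 3, 3)))
  # constraint signs flip between the classes
  expect_equal(pb2@constraints[1, 1:3], c(1, 3, 5))
  expect_equal(pb2@constraints[3, 1:3], -c(1, 4, 7))
  expect_error(buildPairLP(matrix(1, 1, 2), matrix(1, 1, 3)), "mismatch")
})

test_that("worked 1-D instances give the forced objectives", {
  # separable pair: plane with unit margins exists
  pl <- solvePlane(buildPairLP(matrix(2, 1, 1), matrix(0, 1, 1)))
  expect_equal(pl@objectiveValue, 0, tolerance = 1e-9)
  expect_true(pl@separable)
  expect_true(2 * pl@weights - pl@bias >= 1 - 1e-9)
  expect_true(-pl@bias <= -1 + 1e-9)

  # identical points: min over b of max(0,1+b) + max(0,1-b) = 2
  fx <- workedFixtures()$lp_identical_points
  pl <- solvePlane(buildPairLP(fx$Di, fx$Dj))
  expect_equal(pl@objectiveValue, 2, tolerance = 1e-9)
  expect_false(pl@separable)

  # interleaved {0,2} vs {1}: grid search over (w, b) bounds the optimum
  Di <- matrix(c(0, 2), 2, 1); Dj <- matrix(1, 1, 1)
  pl <- solvePlane(buildPairLP(Di, Dj))
  grid <- expand.grid(w = seq(-4, 4, 0.05), b = seq(-6, 6, 0.05))
  best <- min(mapply(function(w, b) slackObjectiveAt(w, b, Di, Dj),
                     grid$w, grid$b))
  expect_gt(pl@objectiveValue, 1e-6)
  expect_equal(pl@objectiveValue, best, tolerance = 1e-6)
})

test_that("solved planes attain the slack objective they report", {
  set.seed(30)
  for (rep in 1:10) {
    k <- sample(1:3, 1)
    Di <- matrix(rnorm(sample(2:5, 1) * k), ncol = k)
    Dj <- matrix(rnorm(sample(2:5, 1) * k), ncol = k)
    pl <- solvePlane(buildPairLP(Di, Dj))
    direct <- slackObjectiveAt(pl@weights, pl@bias, Di, Dj)
    expect_equal(direct, pl@objectiveValue, tolerance = 1e-8)
    expect_gte(pl@objectiveValue, 0)
    # pair-swap symmetry of the optimal objective
    rev <- solvePlane(buildPairLP(Dj, Di))
    expect_equal(rev@objectiveValue, pl@objectiveValue, tolerance = 1e-8)
    # translation invariance: b absorbs a common shift
    shift <- matrix(rnorm(k), 1)
    pls <- solvePlane(buildPairLP(sweep(Di, 2, -shift),
                                  sweep(Dj, 2, -shift)))
    expect_equal(pls@objectiveValue, pl@objectiveValue, tolerance = 1e-8)
  }
})

test_that("fitAllPairs enumerates pairs in table order", {
  x <- toyDataset()
  planes <- fitAllPairs(x)
  expect_named(planes, c("1|2", "1|3", "2|3"))
  expect_equal(planes[["1|3"]]@pair, c(1L, 3L))
  expect_equal(planes[["1|3"]]@pairLabels, c("A", "C"))
  # feature 2 separates everything at spacing 5 with sd 0.1 noise
  expect_true(all(vapply(planes, function(p) p@separable, logical(1))))
  expect_error(fitAllPairs(x[, classCodes(x) == 1]), ">= 2 classes")
})

test_that("merging classes relabels without touching values", {
  x <- simulateExpression(seed = 4)
  m <- mergeClasses(x, c(1, 2))
  expect_equal(unname(classCounts(m)), c(18L, 26L, 10L, 10L))
  expect_equal(classSet(m)[1], "Bone_Marrow_CD34&Bone_Marrow")
  expect_equal(expressionMatrix(m), expressionMatrix(x))
  expect_equal(length(fitAllPairs(restrictFeatures(
    m, S4Vectors::metadata(x)$informative))), 6L)

  one <- mergeClasses(x, "AML", "relabeled")
  expect_true("relabeled" %in% classSet(one))
  expect_error(mergeClasses(x, "nope"), "unknown class")
  allm <- mergeClasses(x, classSet(x), "all")
  expect_equal(length(classSet(allm)), 1L)
  expect_error(fitAllPairs(allm), ">= 2 classes")
})
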