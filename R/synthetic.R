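#' Simulate multiclass expression data with planted separable features
#'
#' Generates a Gaussian class-conditional dataset shaped like the GSE9476
#' leukemia profile: five classes with counts 8/10/26/10/10 by default,
#' many uninformative probes, and a small planted set of class-separating
#' probes.  Each informative probe assigns the classes distinct mean
#' offsets (a seeded random permutation of \eqn{0, 1, \ldots, c-1} scaled
#' by \code{separation * noiseSd}), so every class pair is separated on
#' every informative probe; null probes share the baseline mean.  All
#' values are mean plus \eqn{N(0, \sigma^2)} noise with shared diagonal
#' covariance — the model keeps linear separability controllable through
#' the ratio \code{separation}.
#'
#' @param classCounts samples per class (default \code{c(8,10,26,10,10)}).
#' @param nFeatures total probes (default 500; desk-scale stand-in for the
#'   22283-probe array, selectable up to full size).
#' @param nInformative number of planted separating probes (default 25).
#' @param separation class-mean spacing in noise-SD units (default 6).
#' @param noiseSd noise standard deviation (default 1).
#' @param baseline mean expression level of null probes (default 7, a
#'   typical log2-scale microarray intensity).
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param classNames labels; defaults to the five leukemia group names when
#'   five classes are requested.
#' @return An [ExpressionDataset-class]; the planted probe indices are in
#'   \code{metadata(x)$informative}.
#' @export
simulateExpression <- function(classCounts = c(8, 10, 26, 10, 10),
                               nFeatures = 500, nInformative = 25,
                               separation = 6, noiseSd = 1, baseline = 7,
                               seed = 0, classNames = NULL) {
  if (nInformative > nFeatures) stop("nInformative must be <= nFeatures")
  if (separation < 0 || noiseSd < 0) stop("separation and noiseSd must be >= 0")
  if (any(classCounts < 1)) stop("classCounts must all be >= 1")
  nc <- length(classCounts)
  if (is.null(classNames)) {
    classNames <- if (nc == 5)
      c("Bone_Marrow_CD34", "Bone_Marrow", "AML", "PB", "PBSC_CD34")
    else sprintf("class%d", seq_len(nc))
  }
  n <- sum(classCounts)
  codes <- rep(seq_len(nc), classCounts)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  informative <- sort(sample.int(nFeatures, nInformative))
  means <- matrix(baseline, n, nFeatures)
  for (f in informative) {
    offsets <- sample.int(nc) - 1L      # distinct per-class levels
    means[, f] <- baseline + separation * noiseSd * offsets[codes]
  }
  vals <- means + matrix(stats::rnorm(n * nFeatures, sd = noiseSd),
                         n, nFeatures)
  x <- ExpressionDataset(vals, labels = classNames[codes],
                         sampleIds = sprintf("S%02d", seq_len(n)),
                         probeIds = sprintf("SYN_%05d", seq_len(nFeatures)))
  S4Vectors::metadata(x)$informative <- informative
  x
}

#' Hand-sized worked fixtures
#'
#' Deterministic miniature instances used throughout the examples and
#' tests:
#' \describe{
#'   \item{\code{table11_labels}}{64 actual/predicted label pairs over the
#'     merged four-group scheme whose confusion matrix has rows
#'     (17,1,0,0), (0,26,0,0), (0,0,10,0), (0,0,0,10).}
#'   \item{\code{lp_identical_points}}{the 1-D instance with both classes
#'     at the same point, whose slack LP attains objective exactly 2.}
#'   \item{\code{vote_cycle3}}{a 3-class voting cycle: one sample and three
#'     calibrated 1-D planes, each voting for a different class, with
#'     distinct margins so the tie resolves deterministically by summed
#'     distance (class 2 wins).}
#' }
#'
#' @return Named list of fixtures.
#' @export
workedFixtures <- function() {
  groups <- c("Class 1&2", "Class 3", "Class 4", "Class 5")
  actual <- rep(groups, c(18, 26, 10, 10))
  predicted <- c(rep(groups[1], 17), groups[2],      # one 1&2 -> 3 error
                 rep(groups[2], 26), rep(groups[3], 10), rep(groups[4], 10))
  mkPlane <- function(i, j, w) new("SeparatingPlane",
    pair = c(i, j), pairLabels = as.character(c(i, j)),
    weights = w, bias = 0, objectiveValue = 0, separable = TRUE,
    solverStatus = "optimal")
  cal <- function(p, q) new("CalibratedPlane", plane = p, threshold = q,
                            calibrationAccuracy = 1)
  cycle <- list(
    "1|2" = cal(mkPlane(1L, 2L, 1), -3),  # proj 0 > -3: votes 1, margin 3
    "1|3" = cal(mkPlane(1L, 3L, 1), 1),   # proj 0 <= 1: votes 3, margin 1
    "2|3" = cal(mkPlane(2L, 3L, 1), -5))  # proj 0 > -5: votes 2, margin 5
  list(
    table11_labels = list(actual = actual, predicted = predicted,
                          groups = groups),
    lp_identical_points = list(Di = matrix(0, 1, 1), Dj = matrix(0, 1, 1)),
    vote_cycle3 = list(sample = matrix(0, 1, 1), planes = cycle,
                       expected = 2L))
}
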