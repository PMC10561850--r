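#' Read a CuMiDa-style expression CSV
#'
#' Reads the Kaggle/CuMiDa layout: a comma-separated UTF-8 file with a
#' mandatory header, one row per sample, a sample-id column (default
#' \code{"samples"}), a class-label column (default \code{"type"}), and one
#' numeric column per probe whose header carries the probe-set ID.  Column
#' order of the file is preserved as feature order of the matrix.
#'
#' @param path path to the CSV file.
#' @param labelColumn,idColumn header names of the label and sample-id
#'   columns.
#' @return An [ExpressionDataset-class].
#' @seealso [writeCumidaCsv()] for the inverse.
#' @export
readCumidaCsv <- function(path, labelColumn = "type", idColumn = "samples") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L) stop("empty file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  hdr <- colnames(df)
  if (anyDuplicated(hdr)) stop("duplicate header names in ", path)
  for (col in c(idColumn, labelColumn))
    if (!col %in% hdr) stop("missing column '", col, "' in ", path)
  probeCols <- setdiff(hdr, c(idColumn, labelColumn))
  vals <- matrix(NA_real_, nrow(df), length(probeCols))
  for (j in seq_along(probeCols)) {
    raw <- df[[probeCols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(is.na(raw)))
    if (length(bad) || anyNA(raw))
      stop("non-numeric or missing value at row ",
           if (length(bad)) bad[1] else which(is.na(raw))[1],
           ", column '", probeCols[j], "'")
    vals[, j] <- num
  }
  ExpressionDataset(vals, labels = df[[labelColumn]],
                    sampleIds = df[[idColumn]], probeIds = probeCols)
}

#' Write an ExpressionDataset as a CuMiDa-style CSV
#'
#' Inverse of [readCumidaCsv()]: writes the sample-id column, the label
#' column, then one column per probe, comma-separated with a header row.
#'
#' @param x an [ExpressionDataset-class].
#' @param path output path.
#' @param labelColumn,idColumn header names to use.
#' @return Invisibly, \code{path}.
#' @export
writeCumidaCsv <- function(x, path, labelColumn = "type",
                           idColumn = "samples") {
  m <- expressionMatrix(x)
  df <- data.frame(a = sampleIds(x), b = classLabels(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(idColumn, labelColumn)
  if (ncol(m) > 0) {
    vals <- as.data.frame(m, check.names = FALSE)
    colnames(vals) <- probeIds(x)
    df <- cbind(df, vals)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Seeded stratified train/test split
#'
#' Partitions samples within each class uniformly at random without
#' replacement.  Per-class training counts follow round-half-up of
#' \code{trainFraction * N_i}, the rule that reproduces the leukemia
#' reference split (5, 6, 16, 6, 6 train from counts 8, 10, 26, 10, 10 at
#' fraction 39/64).  The same seed and fraction always give the identical
#' split.
#'
#' @param x an [ExpressionDataset-class].
#' @param trainFraction proportion in \code{[0, 1]}.
#' @param seed integer seed.
#' @return A [SplitResult-class].
#' @export
stratifiedSplit <- function(x, trainFraction, seed) {
  if (trainFraction < 0 || trainFraction > 1)
    stop("trainFraction must be in [0, 1]")
  codes <- classCodes(x)
  cs <- classSet(x)
  counts <- classCounts(x)
  if (any(counts[unique(codes)] < 1)) stop("every class needs >= 1 sample")
  trainIdx <- integer(0)
  nTrain <- integer(length(cs))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  for (ci in seq_along(cs)) {
    idx <- which(codes == ci)
    nt <- floor(trainFraction * length(idx) + 0.5)  # round half up
    nTrain[ci] <- nt
    if (nt > 0) trainIdx <- c(trainIdx, sort(sample(idx, nt)))
  }
  if (any(nTrain == 0 & tabulate(codes, length(cs)) > 0))
    warning("some class receives 0 training samples; plane fitting will fail")
  testIdx <- setdiff(seq_len(ncol(x)), trainIdx)
  pcc <- data.frame(class = cs, nTrain = nTrain,
                    nTest = as.integer(counts) - nTrain)
  new("SplitResult", train = x[, trainIdx], test = x[, testIdx],
      perClassCounts = pcc, seed = as.integer(seed))
}

setMethod("show", "SplitResult", function(object) {
  cat("SplitResult (seed ", object@seed, ")\n", sep = "")
  print(object@perClassCounts, row.names = FALSE)
})
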