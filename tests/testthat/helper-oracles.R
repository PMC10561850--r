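# Independent brute-force oracles used to validate the implementation.

# Strict linear separability of two finite 2-D point sets, by exhaustive
# candidate directions: if the convex hulls are disjoint the minimum-distance
# pair is vertex-vertex, vertex-edge or edge-edge, so some direction of the
# form p - q or perp(p - q), p, q in the union, separates strictly.
oracleSeparable2d <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  pts <- rbind(A, B)
  n <- nrow(pts)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (p == q) next
    d <- pts[p, ] - pts[q, ]
    if (all(d == 0)) next
    for (w in list(d, c(-d[2], d[1]))) {
      pa <- A %*% w; pb <- B %*% w
      if (min(pa) > max(pb) || min(pb) > max(pa)) return(TRUE)
    }
  }
  FALSE
}

# Exhaustive decision-threshold scan: best achievable count of correct
# binary decisions (positive <=> projection > cut) over all cut positions.
oracleBestCutAccuracy <- function(proj, positive) {
  v <- sort(unique(proj))
  cuts <- c(v[1] - 1, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2,
            v[length(v)] + 1)
  max(vapply(cuts, function(q)
    sum(positive & proj > q) + sum(!positive & proj <= q), numeric(1)))
}

# Direct evaluation of the pairwise L1-slack objective at given (w, b):
# mean positive-side violations plus mean negative-side violations.
slackObjectiveAt <- function(w, b, Di, Dj) {
  mean(pmax(0, 1 - (Di %*% w - b))) + mean(pmax(0, 1 + (Dj %*% w - b)))
}

# Can some threshold on a single feature perfectly split a pair of classes?
oracleSingleFeatureSplit <- function(values, codes) {
  cls <- sort(unique(codes))
  for (a in cls) for (b in cls) {
    if (a >= b) next
    va <- values[codes == a]; vb <- values[codes == b]
    if (min(va) > max(vb) || min(vb) > max(va)) return(TRUE)
  }
  FALSE
}

# Small labelled dataset used across tests: 3 classes, 2 informative of 6
# features, integer-friendly values.
toyDataset <- function() {
  set.seed(42)
  codes <- rep(1:3, c(4, 3, 5))
  vals <- matrix(rnorm(12 * 6, sd = 0.1), 12, 6)
  vals[, 2] <- vals[, 2] + 5 * codes          # separates all pairs
  vals[, 5] <- vals[, 5] + 3 * (codes == 2)   # separates class 2
  ExpressionDataset(vals, labels = c("A", "B", "C")[codes],
                    sampleIds = sprintf("t%02d", 1:12),
                    probeIds = sprintf("P%d", 1:6))
}
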