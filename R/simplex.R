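# Dense two-phase tableau simplex with Bland's anti-cycling rule.
# Solves  min c'x  s.t.  A x >= b, x >= 0.  Problems here are tiny
# (tens of rows), so a plain tableau is adequate and fully deterministic.

.lpSimplex <- function(obj, A, b, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m)
  # equality form: A x - s = b, s >= 0; flip rows so rhs >= 0
  Af <- cbind(A, -diag(m))
  bf <- b
  neg <- bf < 0
  if (any(neg)) { Af[neg, ] <- -Af[neg, ]; bf[neg] <- -bf[neg] }
  ntot <- n + m

  pivotRun <- function(Tab, basis, cost, ncols) {
    repeat {
      cb <- cost[basis]
      red <- cost[seq_len(ncols)] -
        as.vector(cb %*% Tab[, seq_len(ncols), drop = FALSE])
      enter <- which(red < -tol)
      if (!length(enter))
        return(list(Tab = Tab, basis = basis, status = 0L))
      j <- min(enter)                       # Bland: smallest index enters
      col <- Tab[, j]
      pos <- which(col > tol)
      if (!length(pos))
        return(list(Tab = Tab, basis = basis, status = 1L))  # unbounded
      ratio <- Tab[pos, ncols + 1L] / col[pos]
      cand <- pos[ratio <= min(ratio) + tol]
      r <- cand[which.min(basis[cand])]     # Bland: smallest basis leaves
      piv <- Tab[r, j]
      Tab[r, ] <- Tab[r, ] / piv
      for (i in seq_len(nrow(Tab)))
        if (i != r && abs(Tab[i, j]) > 1e-14)
          Tab[i, ] <- Tab[i, ] - Tab[i, j] * Tab[r, ]
      basis[r] <- j
    }
  }

  # phase 1: artificial basis
  Tab <- cbind(Af, diag(m), bf)
  basis <- ntot + seq_len(m)
  cost1 <- c(rep(0, ntot), rep(1, m))
  r1 <- pivotRun(Tab, basis, cost1, ntot + m)
  if (r1$status != 0L) return(list(status = 3L))
  Tab <- r1$Tab; basis <- r1$basis
  if (sum(cost1[basis] * Tab[, ncol(Tab)]) > 1e-7)
    return(list(status = 2L))               # infeasible
  # pivot remaining artificials out where a nonzero structural entry exists
  for (r in which(basis > ntot)) {
    j <- which(abs(Tab[r, seq_len(ntot)]) > tol)[1]
    if (!is.na(j)) {
      piv <- Tab[r, j]
      Tab[r, ] <- Tab[r, ] / piv
      for (i in seq_len(nrow(Tab)))
        if (i != r && abs(Tab[i, j]) > 1e-14)
          Tab[i, ] <- Tab[i, ] - Tab[i, j] * Tab[r, ]
      basis[r] <- j
    }
  }
  keep <- basis <= ntot                     # drop redundant all-zero rows
  Tab <- Tab[keep, c(seq_len(ntot), ncol(Tab)), drop = FALSE]
  basis <- basis[keep]

  # phase 2
  cost2 <- c(obj, rep(0, m))
  r2 <- pivotRun(Tab, basis, cost2, ntot)
  if (r2$status != 0L) return(list(status = r2$status))
  x <- numeric(ntot)
  x[r2$basis] <- r2$Tab[, ntot + 1L]
  list(status = 0L, x = x[seq_len(n)],
       value = sum(obj * x[seq_len(n)]))
}
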