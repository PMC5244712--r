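## Independent LP oracle: exhaustive enumeration of basic solutions of
##   max/min c'x  s.t.  A x = b,  l <= x <= u.
## Every vertex fixes n - rank(A) variables at a bound; the rest solve the
## equality system.  Used to validate the simplex solver on problems with
## <= 10 variables; deliberately shares no code with solveLP().

enumerateVertexOptimum <- function(cost, A, b = NULL, lower, upper,
                                   sense = "max", tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A); m <- nrow(A)
  if (is.null(b)) b <- numeric(m)
  r <- if (m) qr(A)$rank else 0L
  nFix <- n - r
  best <- NULL
  subsets <- if (nFix == 0) list(integer(0))
             else asplit(utils::combn(n, nFix), 2)
  for (Fidx in subsets) {
    Fidx <- as.integer(Fidx)
    Bidx <- setdiff(seq_len(n), Fidx)
    grid <- if (length(Fidx))
      expand.grid(rep(list(c(FALSE, TRUE)), length(Fidx)))
    else data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      if (length(Fidx)) {
        atUpper <- unlist(grid[g, ])
        x[Fidx] <- ifelse(atUpper, upper[Fidx], lower[Fidx])
      }
      rhs <- b - if (length(Fidx)) A[, Fidx, drop = FALSE] %*% x[Fidx]
                 else 0
      if (length(Bidx)) {
        sol <- tryCatch(qr.solve(A[, Bidx, drop = FALSE], rhs,
                                 tol = 1e-12),
                        error = function(e) NULL)
        if (is.null(sol)) next
        x[Bidx] <- sol
      }
      if (max(abs(A %*% x - b)) > tol) next
      if (any(x < lower - tol) || any(x > upper + tol)) next
      val <- sum(cost * x)
      if (is.null(best) ||
          (sense == "max" && val > best$value + 1e-12) ||
          (sense == "min" && val < best$value - 1e-12))
        best <- list(value = val, x = x)
    }
  }
  best   # NULL when infeasible
}
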