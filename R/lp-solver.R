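#' Solve a bounded-variable linear program
#'
#' Self-contained two-phase primal simplex for problems of the form
#' \deqn{\max\ c^\top x \quad s.t.\quad A x = b,\ \ l \le x \le u,}
#' the computational form taken by flux balance analysis (\eqn{A = S},
#' \eqn{b = 0}).  All structural bounds must be finite; genome-scale
#' metabolic models use the +/-1000 sentinel convention, so this is not a
#' restriction in practice.  Bland's rule is used throughout, which makes
#' the method immune to cycling on the degenerate vertices that are common
#' in metabolic networks.
#'
#' @param cost numeric objective coefficients, length \code{ncol(A)}.
#' @param A constraint matrix (dense or \pkg{Matrix} sparse; coerced dense).
#' @param b right-hand side, length \code{nrow(A)}.
#' @param lower,upper finite variable bounds.
#' @param sense \code{"max"} or \code{"min"}.
#' @param tol optimality/feasibility tolerance on reduced costs and bound
#'   violations (default \code{1e-9}).
#' @param maxit iteration cap across both phases.
#' @param warm optional status vector from a previous \code{solveLP} on a
#'   problem with the same \code{A} (slot \code{$stat} of a result); used to
#'   skip phase 1 when the old basis is still feasible.
#'
#' @return a list with elements \code{status} (\code{"optimal"},
#'   \code{"infeasible"} or \code{"unbounded"}), \code{x}, \code{objective}
#'   and \code{stat} (basis status usable as \code{warm}).
#' @export
solveLP <- function(cost, A, b = NULL, lower, upper,
                    sense = c("max", "min"), tol = 1e-9,
                    maxit = 50000L, warm = NULL) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (is.null(b)) b <- numeric(m)
  stopifnot(length(cost) == n, length(lower) == n, length(upper) == n,
            length(b) == m)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("solveLP requires finite variable bounds")
  if (any(lower > upper + 1e-12))
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                stat = NULL))
  obj <- if (sense == "min") -cost else cost

  if (m == 0L) {
    x <- ifelse(obj > 0, upper, lower)
    val <- sum(obj * x)
    return(list(status = "optimal", x = x,
                objective = if (sense == "min") -val else val,
                stat = rep(1L, n)))
  }

  ## -- warm start: previous structural basis, no artificials -------------
  if (!is.null(warm) && length(warm) == n && sum(warm == 0L) == m) {
    res <- .simplexCore(A, b, obj, lower, upper, warm, tol, maxit)
    if (res$status %in% c("optimal", "unbounded")) {
      val <- sum(obj * res$x)
      return(list(status = res$status, x = res$x,
                  objective = if (sense == "min") -val else val,
                  stat = res$stat))
    }
    ## basis stale or singular: fall through to cold start
  }

  ## -- phase 1: artificial variables -------------------------------------
  ## nonbasic structurals start at the bound nearer zero
  stat <- ifelse(abs(lower) <= abs(upper), 1L, 2L)
  x0 <- ifelse(stat == 1L, lower, upper)
  r <- b - drop(A %*% x0)
  sg <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sg, nrow = m))
  lo1 <- c(lower, numeric(m))
  up1 <- c(upper, rep(Inf, m))
  stat1 <- c(stat, rep(0L, m))
  obj1 <- c(numeric(n), rep(-1, m))
  p1 <- .simplexCore(Afull, b, obj1, lo1, up1, stat1, tol, maxit)
  if (p1$status != "optimal")
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                stat = NULL))
  if (sum(p1$x[(n + 1):(n + m)]) > 1e-7)
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                stat = NULL))

  ## -- phase 2: pin artificials at zero, optimize true objective ---------
  up2 <- up1; up2[(n + 1):(n + m)] <- 0
  obj2 <- c(obj, numeric(m))
  p2 <- .simplexCore(Afull, b, obj2, lo1, up2, p1$stat, tol, maxit)
  if (p2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objective = NA_real_,
                stat = NULL))
  if (p2$status != "optimal")
    stop("simplex failed to converge (status ", p2$status, ")")
  x <- p2$x[seq_len(n)]
  ## snap to bounds to remove solver noise
  x <- pmin(pmax(x, lower), upper)
  val <- sum(obj * x)
  list(status = "optimal", x = x,
       objective = if (sense == "min") -val else val,
       stat = p2$stat[seq_len(n)])
}

## Bounded-variable primal simplex core.  `stat`: 0 basic, 1 at lower,
## 2 at upper.  Returns status in {"optimal","unbounded","singular","maxit"}.
.simplexCore <- function(Afull, b, obj, lo, up, stat, tol, maxit) {
  m <- nrow(Afull); N <- ncol(Afull)
  basis <- which(stat == 0L)
  if (length(basis) != m) return(list(status = "singular"))
  piv <- max(tol, 1e-11)
  for (it in seq_len(maxit)) {
    nonb <- which(stat != 0L)
    xN <- ifelse(stat[nonb] == 1L, lo[nonb], up[nonb])
    B <- Afull[, basis, drop = FALSE]
    rhs <- b - if (length(nonb)) drop(Afull[, nonb, drop = FALSE] %*% xN)
           else numeric(m)
    xB <- tryCatch(drop(solve(B, rhs)), error = function(e) NULL)
    if (is.null(xB)) return(list(status = "singular"))
    if (any(xB < lo[basis] - 1e-7) || any(xB > up[basis] + 1e-7))
      return(list(status = "infeasible-basis"))
    y <- drop(solve(t(B), obj[basis]))
    d <- obj[nonb] - drop(crossprod(Afull[, nonb, drop = FALSE], y))
    entering <- nonb[(stat[nonb] == 1L & d > tol) |
                     (stat[nonb] == 2L & d < -tol)]
    if (!length(entering)) {
      x <- numeric(N); x[nonb] <- xN; x[basis] <- xB
      return(list(status = "optimal", x = x, stat = stat))
    }
    j <- min(entering)                       # Bland's rule
    dirj <- if (stat[j] == 1L) 1 else -1     # entering moves off its bound
    w <- drop(solve(B, Afull[, j]))
    delta <- -dirj * w                       # xB change per unit t
    tb <- rep(Inf, m)
    inc <- delta > piv; dec <- delta < -piv
    tb[inc] <- (up[basis[inc]] - xB[inc]) / delta[inc]
    tb[dec] <- (lo[basis[dec]] - xB[dec]) / delta[dec]
    tb[tb < 0] <- 0
    tOwn <- up[j] - lo[j]
    tBasic <- if (any(is.finite(tb))) min(tb) else Inf
    tStep <- min(tOwn, tBasic)
    if (!is.finite(tStep)) return(list(status = "unbounded"))
    if (tOwn <= tBasic) {
      stat[j] <- if (stat[j] == 1L) 2L else 1L    # bound flip
    } else {
      cand <- which(abs(tb - tBasic) <= 1e-12 & (inc | dec))
      if (!length(cand)) cand <- which.min(tb)
      r <- cand[which.min(basis[cand])]           # Bland on leaving
      leave <- basis[r]
      stat[leave] <- if (delta[r] > 0) 2L else 1L
      stat[j] <- 0L
      basis[r] <- j
    }
  }
  list(status = "maxit")
}
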