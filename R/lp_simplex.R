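# A small bounded-variable primal simplex solver.
#
#   minimize    c' x
#   subject to  A x = b,   l <= x <= u   (l, u finite)
#
# Two-phase method with artificial variables and Bland's smallest-index
# anti-cycling rule.  The flux polytopes solved here are tiny (tens of
# variables), so numerical sophistication is traded for determinism and
# transparency.

LP_TOL <- 1e-9

lp_bounded_simplex <- function(cc, A, b, lb, ub, maximize = FALSE) {
  n <- length(cc)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + LP_TOL)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  obj_sign <- if (maximize) -1 else 1
  # extended problem: structural variables then one artificial per row
  x <- numeric(n + m)
  x[1:n] <- lb
  resid <- b - as.numeric(A %*% lb)
  sgn <- ifelse(resid >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  lext <- c(lb, rep(0, m))
  uext <- c(ub, rep(Inf, m))
  x[n + seq_len(m)] <- abs(resid)
  basis <- n + seq_len(m)
  at_ub <- rep(FALSE, n + m)  # nonbasic variables: at lb unless flagged

  run_phase <- function(cost, x, basis, at_ub, lext, uext) {
    maxit <- 500L * (n + m)
    for (iter in seq_len(maxit)) {
      B <- Aext[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) {
        return(list(status = "singular", x = x, basis = basis,
                    at_ub = at_ub))
      }
      y <- as.numeric(crossprod(Binv, cost[basis]))
      nonbasic <- setdiff(seq_len(n + m), basis)
      d <- cost[nonbasic] - as.numeric(t(Aext[, nonbasic, drop = FALSE]) %*% y)
      # Bland: smallest index with a strictly improving reduced cost
      improving <- nonbasic[(d < -LP_TOL & !at_ub[nonbasic]) |
                              (d > LP_TOL & at_ub[nonbasic])]
      if (length(improving) == 0) {
        return(list(status = "optimal", x = x, basis = basis,
                    at_ub = at_ub))
      }
      j <- min(improving)
      sigma <- if (at_ub[j]) -1 else 1
      w <- as.numeric(Binv %*% Aext[, j])
      # max step before a basic variable or the entering bound is hit
      step <- uext[j] - lext[j]
      leave <- 0L  # 0: entering flips to its other bound
      for (i in seq_len(m)) {
        wi <- sigma * w[i]
        ti <- if (wi > LP_TOL) (x[basis[i]] - lext[basis[i]]) / wi
              else if (wi < -LP_TOL) (x[basis[i]] - uext[basis[i]]) / wi
              else Inf
        if (ti < step - LP_TOL ||
            (ti < step + LP_TOL && leave > 0L &&
             basis[i] < basis[leave])) {
          step <- ti
          leave <- i
        }
      }
      if (!is.finite(step)) {
        return(list(status = "unbounded", x = x, basis = basis,
                    at_ub = at_ub))
      }
      step <- max(step, 0)
      x[basis] <- x[basis] - step * sigma * w
      x[j] <- x[j] + sigma * step
      if (leave == 0L) {
        at_ub[j] <- !at_ub[j]
      } else {
        out <- basis[leave]
        wi <- sigma * w[leave]
        at_ub[out] <- wi < 0  # left towards its upper bound
        x[out] <- if (at_ub[out]) uext[out] else lext[out]
        basis[leave] <- j
        at_ub[j] <- FALSE
      }
    }
    list(status = "maxit", x = x, basis = basis, at_ub = at_ub)
  }

  # phase 1: drive the artificials to zero
  ph1_cost <- c(numeric(n), rep(1, m))
  r1 <- run_phase(ph1_cost, x, basis, at_ub, lext, uext)
  if (r1$status != "optimal" ||
      sum(r1$x[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  # pin artificials to zero and optimize the true objective
  uext[n + seq_len(m)] <- 0
  ph2_cost <- c(obj_sign * cc, numeric(m))
  r2 <- run_phase(ph2_cost, r1$x, r1$basis, r1$at_ub, lext, uext)
  if (r2$status != "optimal") {
    return(list(status = r2$status, x = NULL, objective = NA_real_))
  }
  v <- r2$x[1:n]
  list(status = "optimal", x = v, objective = sum(cc * v))
}
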