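# Bounded-variable linear programming: a dense two-phase tableau
# simplex. All flux LPs in the package are box-bounded (infinite
# bounds are clamped to the +/-1000 global flux convention), so the
# feasible region is a polytope and the solver either returns an
# optimal vertex or proves infeasibility. Problem sizes are small
# (tens of variables), so a dense tableau with Dantzig pricing and a
# Bland anti-cycling fallback is both simple and adequate.

GLOBAL_FLUX_BOUND <- 1000

#' Solve a bounded linear program
#'
#' Solves `max/min c'x` subject to `Aeq x = beq`, `Aineq x <= bineq`,
#' `lb <= x <= ub`. Intended for the small dense LPs arising from flux
#' balance analysis of the package's networks; feasibility tolerance
#' 1e-9.
#'
#' @param obj objective coefficient vector.
#' @param Aeq,beq equality constraints (matrix may be `NULL`).
#' @param Aineq,bineq `<=` inequality constraints (may be `NULL`).
#' @param lb,ub variable bounds; non-finite entries are clamped to
#'   the +/-1000 global bound.
#' @param maximize logical.
#' @return list with `status` (`"optimal"` or `"infeasible"`),
#'   `objective`, and the solution `x`.
#' @keywords internal
#' @export
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Aineq = NULL,
                     bineq = NULL, lb, ub, maximize = TRUE) {
  n <- length(obj)
  lb <- pmax(lb, -GLOBAL_FLUX_BOUND)
  ub <- pmin(ub, GLOBAL_FLUX_BOUND)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  ub <- pmax(ub, lb)
  shift <- lb
  # build equality system over x' = x - lb >= 0 with slack variables:
  #   Aeq x' = beq - Aeq lb
  #   Aineq x' + s = bineq - Aineq lb,  s >= 0
  #   x'_i + t_i = ub_i - lb_i,         t >= 0
  A <- diag(n)
  b <- ub - lb
  slack_sign <- rep(1, n)
  if (!is.null(Aineq)) {
    Aineq <- as.matrix(Aineq)
    A <- rbind(A, Aineq)
    b <- c(b, as.numeric(bineq) - as.numeric(Aineq %*% shift))
    slack_sign <- c(slack_sign, rep(1, nrow(Aineq)))
  }
  if (!is.null(Aeq)) {
    Aeq <- as.matrix(Aeq)
    A <- rbind(A, Aeq)
    b <- c(b, as.numeric(beq) - as.numeric(Aeq %*% shift))
    slack_sign <- c(slack_sign, rep(0, nrow(Aeq)))   # no slack
  }
  m <- nrow(A)
  n_slack <- sum(slack_sign != 0)
  Afull <- cbind(A, matrix(0, m, n_slack))
  k <- n
  for (i in which(slack_sign != 0)) {
    k <- k + 1L
    Afull[i, k] <- 1
  }
  # normalise to b >= 0
  neg <- b < 0
  Afull[neg, ] <- -Afull[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  cvec <- c(if (maximize) -obj else obj, rep(0, n_slack))
  res <- simplex_two_phase(Afull, b, cvec)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  x <- res$x[seq_len(n)] + shift
  list(status = "optimal", objective = sum(obj * x), x = x)
}

# minimize c'x s.t. Ax = b (b >= 0), x >= 0; dense two-phase tableau
simplex_two_phase <- function(A, b, cvec, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  # phase 1: artificial basis
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  Tb <- simplex_iterate(Tb, basis, cost1, tol)
  basis <- attr(Tb, "basis")
  p1 <- sum(cost1[basis] * Tb[, ncol(Tb)])
  if (p1 > 1e-7) {
    return(list(status = "infeasible"))
  }
  # drive remaining artificials out of the basis
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      piv <- which(abs(Tb[i, seq_len(n)]) > tol)
      piv <- setdiff(piv, basis)
      if (length(piv) > 0) {
        Tb <- simplex_pivot(Tb, i, piv[1])
        basis[i] <- piv[1]
      }
      # else: redundant row, artificial stays basic at zero
    }
  }
  # phase 2 on original columns
  keep <- c(seq_len(n), ncol(Tb))
  Tb2 <- Tb[, keep, drop = FALSE]
  # zero out columns of basic artificials (redundant rows)
  art_rows <- which(basis > n)
  Tb2 <- simplex_iterate(Tb2, basis, cvec, tol, frozen_rows = art_rows)
  basis <- attr(Tb2, "basis")
  x <- numeric(n)
  rhs <- Tb2[, ncol(Tb2)]
  for (i in seq_len(m)) {
    if (basis[i] <= n) x[basis[i]] <- rhs[i]
  }
  list(status = "optimal", x = x, objective = sum(cvec * x))
}

simplex_pivot <- function(Tb, row, col) {
  Tb[row, ] <- Tb[row, ] / Tb[row, col]
  other <- setdiff(seq_len(nrow(Tb)), row)
  Tb[other, ] <- Tb[other, ] - outer(Tb[other, col], Tb[row, ])
  Tb
}

simplex_iterate <- function(Tb, basis, cost, tol, frozen_rows = integer(0)) {
  m <- nrow(Tb); ncols <- ncol(Tb); n <- ncols - 1L
  max_iter <- 200L * (m + n)
  bland_after <- 10L * (m + n)
  for (it in seq_len(max_iter)) {
    # reduced costs: c_j - c_B' B^-1 A_j (tableau already in B^-1 A
    # form); basic artificials surviving into phase 2 carry zero cost
    cb <- ifelse(basis <= n, cost[pmin(basis, n)], 0)
    red <- cost[seq_len(n)] - as.numeric(crossprod(cb, Tb[, seq_len(n)]))
    red[basis[basis <= n]] <- 0
    cand <- which(red < -tol)
    if (length(cand) == 0) break
    j <- if (it > bland_after) min(cand) else cand[which.min(red[cand])]
    col <- Tb[, j]
    rows <- which(col > tol)
    rows <- setdiff(rows, frozen_rows)
    if (length(rows) == 0) {
      # unbounded direction: cannot occur for box-bounded flux LPs
      # except through frozen redundant rows; treat as no improvement
      break
    }
    ratios <- Tb[rows, ncols] / col[rows]
    rmin <- min(ratios)
    tie <- rows[ratios <= rmin + tol]
    i <- tie[which.min(basis[tie])]     # Bland-style tie-break
    Tb <- simplex_pivot(Tb, i, j)
    basis[i] <- j
  }
  attr(Tb, "basis") <- basis
  Tb
}
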