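#' Solve a dense linear program with box-bounded variables
#'
#' Maximizes (or minimizes) `obj %*% v` subject to general linear rows
#' `A v {=,<=,>=} rhs` and finite box bounds `lb <= v <= ub`. Solved by a
#' two-phase full-tableau primal simplex with Bland's anti-cycling rule, so
#' repeated calls on the same input are bit-identical. Intended for the small
#' dense programs arising from flux balance analysis of compact metabolic
#' models; all bounds must be finite (genome-scale conventions cap fluxes at
#' +/- 1000 mmol/gDW/h, which keeps every program bounded).
#'
#' @param obj numeric objective vector, length n.
#' @param A constraint matrix (m x n); may have zero rows.
#' @param rel character vector of row relations, each `"="`, `"<="` or `">="`.
#' @param rhs numeric right-hand sides, length m.
#' @param lb,ub finite numeric bounds, length n, `lb <= ub`.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot/feasibility tolerance.
#'
#' @return list with `status` (`"optimal"` or `"infeasible"`), `objective`
#'   (numeric, `NA` unless optimal) and `solution` (numeric length n).
#' @keywords internal
lp_solve <- function(obj, A, rel, rhs, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  A <- matrix(as.numeric(A), ncol = n)
  m <- nrow(A)
  stopifnot(length(rel) == m, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (!all(is.finite(lb)) || !all(is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  if (any(lb > ub + tol))
    stop("lp_solve: lb > ub for some variable")

  ## shift x = v - lb so x >= 0; box upper bounds become extra <= rows
  d <- ub - lb
  rhs_s <- rhs - as.vector(A %*% lb)
  A_all <- rbind(A, diag(n))
  rhs_all <- c(rhs_s, d)
  rel_all <- c(rel, rep("<=", n))

  ## slack/surplus columns for inequality rows
  ineq <- which(rel_all != "=")
  n_sl <- length(ineq)
  M <- nrow(A_all)
  Sl <- matrix(0, M, n_sl)
  for (k in seq_along(ineq)) {
    i <- ineq[k]
    Sl[i, k] <- if (rel_all[i] == "<=") 1 else -1
  }
  Afull <- cbind(A_all, Sl)
  bfull <- rhs_all

  ## make rhs nonnegative
  neg <- bfull < 0
  Afull[neg, ] <- -Afull[neg, , drop = FALSE]
  bfull[neg] <- -bfull[neg]

  ncol_struct <- n + n_sl
  ## artificial columns, one per row
  Tab <- cbind(Afull, diag(M), bfull)
  basis <- ncol_struct + seq_len(M)

  pivot <- function(Tab, cost, pr, pc) {
    piv <- Tab[pr, pc]
    Tab[pr, ] <- Tab[pr, ] / piv
    fac <- Tab[, pc]
    fac[pr] <- 0
    Tab <- Tab - outer(fac, Tab[pr, ])
    cost <- cost - cost[pc] * Tab[pr, ]
    list(Tab = Tab, cost = cost)
  }

  run_simplex <- function(Tab, basis, costs, active_cols) {
    rhs_col <- ncol(Tab)
    ## reduced-cost row (includes objective value in rhs position, negated)
    cost <- c(costs, 0)
    for (i in seq_along(basis)) {
      cb <- costs[basis[i]]
      if (cb != 0) cost <- cost - cb * Tab[i, ]
    }
    repeat {
      cand <- active_cols[cost[active_cols] < -tol]
      if (length(cand) == 0L) break
      pc <- min(cand)  # Bland: smallest index
      col <- Tab[, pc]
      rows <- which(col > tol)
      if (length(rows) == 0L) return(list(unbounded = TRUE))
      ratio <- Tab[rows, rhs_col] / col[rows]
      best <- min(ratio)
      tie <- rows[ratio <= best + tol]
      pr <- tie[which.min(basis[tie])]
      res <- pivot(Tab, cost, pr, pc)
      Tab <- res$Tab
      cost <- res$cost
      basis[pr] <- pc
    }
    list(Tab = Tab, basis = basis, cost = cost, unbounded = FALSE)
  }

  ## phase 1: minimize sum of artificials
  ntot <- ncol_struct + M
  costs1 <- c(rep(0, ncol_struct), rep(1, M))
  ph1 <- run_simplex(Tab, basis, costs1, seq_len(ntot))
  if (isTRUE(ph1$unbounded)) stop("internal: phase-1 unbounded")
  obj1 <- -ph1$cost[ncol(Tab)]
  if (obj1 > 1e-7)
    return(list(status = "infeasible", objective = NA_real_,
                solution = rep(NA_real_, n)))
  Tab <- ph1$Tab
  basis <- ph1$basis

  ## drive any residual (zero-valued) artificials out of the basis
  rhs_col <- ncol(Tab)
  for (i in seq_along(basis)) {
    if (basis[i] > ncol_struct) {
      cand <- which(abs(Tab[i, seq_len(ncol_struct)]) > tol)
      if (length(cand) > 0L) {
        res <- pivot(Tab, rep(0, rhs_col), i, cand[1])
        Tab <- res$Tab
        basis[i] <- cand[1]
      }
      ## else: redundant row, harmless -- artificial stays basic at value 0
    }
  }

  ## phase 2 over structural columns only
  sense <- if (maximize) -1 else 1
  costs2 <- c(sense * c(obj, rep(0, n_sl)), rep(0, M))
  ph2 <- run_simplex(Tab, basis, costs2, seq_len(ncol_struct))
  if (isTRUE(ph2$unbounded))
    return(list(status = "unbounded", objective = NA_real_,
                solution = rep(NA_real_, n)))

  x <- rep(0, ntot)
  x[ph2$basis] <- ph2$Tab[, ncol(Tab)]
  v <- x[seq_len(n)] + lb
  list(status = "optimal",
       objective = sum(obj * v),
       solution = v)
}
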