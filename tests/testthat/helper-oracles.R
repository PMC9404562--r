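# Independent oracles used across the suite. These stay deliberately
# brute-force: they re-derive expected values without touching the package's
# own solver or statistics code paths.

# Optimum of max obj'v over {v : S v = 0, lb <= v <= ub} by enumerating basic
# solutions: fix (n - rank(S)) variables at a bound, solve the rest exactly.
# Returns -Inf when no feasible vertex exists. Only for tiny n.
enum_vertex_optimum <- function(S, lb, ub, obj, tol = 1e-8) {
  n <- length(lb)
  if (is.null(dim(S))) S <- matrix(S, ncol = n)
  k <- if (nrow(S) == 0) 0L else qr(S)$rank
  f <- n - k
  best <- -Inf
  try_point <- function(v) {
    if (all(v >= lb - tol) && all(v <= ub + tol)) {
      val <- sum(obj * v)
      if (val > best) best <<- val
    }
  }
  subsets <- if (f == 0) list(integer(0)) else
    utils::combn(n, f, simplify = FALSE)
  for (F in subsets) {
    free <- setdiff(seq_len(n), F)
    Sf <- S[, free, drop = FALSE]
    if (length(free) > 0 && qr(Sf)$rank < length(free)) next
    grid <- if (length(F) == 0) matrix(0, 1, 0) else
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(F))))
    for (g in seq_len(nrow(grid))) {
      vF <- ifelse(grid[g, ], ub[F], lb[F])
      v <- numeric(n)
      v[F] <- vF
      if (length(free) > 0) {
        rhs <- -S[, F, drop = FALSE] %*% vF
        if (nrow(S) == 0) next
        sol <- qr.coef(qr(Sf), rhs)
        if (any(is.na(sol))) next
        if (max(abs(Sf %*% sol - rhs)) > tol) next  # inconsistent system
        v[free] <- sol
      } else {
        if (nrow(S) > 0 && max(abs(S %*% v)) > tol) next
      }
      try_point(v)
    }
  }
  best
}

# Random small stoichiometric LP with 0 guaranteed feasible (lb <= 0 <= ub).
random_small_model <- function(n_rxn, n_met) {
  S <- matrix(sample(c(-2, -1, -1, 0, 0, 0, 1, 1, 2), n_met * n_rxn,
                     replace = TRUE), n_met, n_rxn)
  lb <- -round(runif(n_rxn, 0, 10), 2)
  ub <- round(runif(n_rxn, 0, 10), 2)
  obj <- round(runif(n_rxn, -1, 1), 2)
  list(S = S, lb = lb, ub = ub, obj = obj)
}

# Kendall tau-b by explicit enumeration of all pairs, with tie denominators.
brute_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_pairs(x)
  n2 <- tie_pairs(y)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}
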