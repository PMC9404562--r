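#' Kendall tau-b rank correlation with tie-corrected inference
#'
#' Computes tau-b (tie correction in both margins) by explicit pair counting.
#' The two-sided p-value uses the tie-adjusted normal approximation of the
#' concordance statistic S for n > 8, and exact enumeration of the
#' permutation distribution of S (conditional on both tie patterns) for
#' n <= 8, where the normal approximation is poor.
#'
#' @param x,y numeric vectors of equal length >= 5, finite, non-constant.
#' @param p_method `"auto"` (exact for n <= 8, else normal), `"exact"` or
#'   `"normal"`.
#' @return list of class `association_result`: `tau_b`, `p_value`, `n`,
#'   `method`.
#' @export
kendall_tau_b <- function(x, y, p_method = c("auto", "exact", "normal")) {
  p_method <- match.arg(p_method)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 5) stop("kendall_tau_b requires n >= 5")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("tau-b is undefined for a constant vector (zero tie denominator)")

  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  S <- sum(sx * sy) / 2  # concordant minus discordant
  n0 <- n * (n - 1) / 2
  tie_counts <- function(v) as.vector(table(v))
  tx <- tie_counts(x)
  ty <- tie_counts(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))

  method <- if (p_method == "auto") {
    if (n <= 8) "exact" else "normal"
  } else p_method

  if (method == "exact") {
    perms <- all_permutations(n)
    sy_flat <- sy
    stat <- vapply(seq_len(nrow(perms)), function(k) {
      p <- perms[k, ]
      sum(sx * sy_flat[p, p]) / 2
    }, 0)
    p_value <- mean(abs(stat) >= abs(S) - 1e-9)
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_S <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(var_S)
    p_value <- min(1, 2 * stats::pnorm(-abs(z)))
    p_value <- max(p_value, .Machine$double.xmin)
  }
  structure(list(tau_b = tau, p_value = p_value, n = n, method = method),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> tau_b = %.4f, p = %.4g (n = %d, %s)\n",
              x$tau_b, x$p_value, x$n, x$method))
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows); n <= 8 keeps this small
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n)
      block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                     sub[, pos:(n - 1), drop = FALSE])
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Dirichlet Monte Carlo centered log-ratio transformation
#'
#' Propagates count uncertainty in compositional taxa data: for each of
#' `n_instances` instances, every subject's underlying composition is drawn
#' from Dirichlet(counts + prior) and clr-transformed (log abundance minus
#' the subject's mean log abundance, so every clr row sums to zero).
#'
#' @param counts subject x taxon matrix of nonnegative integer counts; no
#'   subject row may be all zero.
#' @param n_instances number of Monte Carlo instances (default 128).
#' @param prior Dirichlet pseudo-count per taxon (default 0.5).
#' @param seed optional integer seed for reproducible instance stacks.
#' @return numeric array `[subject, taxon, instance]`.
#' @export
dirichlet_clr <- function(counts, n_instances = 128, prior = 0.5,
                          seed = NULL) {
  counts <- as.matrix(counts)
  stopifnot(n_instances >= 1, prior > 0, all(counts >= 0))
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop("all-zero count row for subject(s): ",
         paste(rownames(counts)[zero] %||% which(zero), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  ns <- nrow(counts)
  nt <- ncol(counts)
  out <- array(NA_real_, c(ns, nt, n_instances),
               dimnames = list(rownames(counts), colnames(counts), NULL))
  shape <- counts + prior
  for (k in seq_len(n_instances)) {
    g <- matrix(stats::rgamma(ns * nt, shape = shape), ns, nt)
    comp <- g / rowSums(g)
    lg <- log(comp)
    out[, , k] <- lg - rowMeans(lg)
  }
  out
}

#' Per-taxon association with a clinical variable across Dirichlet instances
#'
#' For each taxon, Kendall tau-b between its clr value and the variable is
#' computed in every Dirichlet Monte Carlo instance; the instance
#' distribution is summarized by the median tau-b and median p-value (a
#' robust aggregation of the per-instance results).
#'
#' @param counts subject x taxon count matrix.
#' @param variable numeric vector, one value per subject.
#' @param n_instances,prior,seed passed to [dirichlet_clr()].
#' @return data.frame with `taxon`, `median_tau_b`, `median_p`, `n`.
#' @export
taxa_association <- function(counts, variable, n_instances = 128,
                             prior = 0.5, seed = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(variable))
    stop("counts rows and variable length differ")
  clr <- dirichlet_clr(counts, n_instances, prior, seed)
  nt <- ncol(counts)
  taus <- matrix(NA_real_, n_instances, nt)
  ps <- matrix(NA_real_, n_instances, nt)
  for (k in seq_len(n_instances)) {
    for (j in seq_len(nt)) {
      a <- kendall_tau_b(clr[, j, k], variable)
      taus[k, j] <- a$tau_b
      ps[k, j] <- a$p_value
    }
  }
  data.frame(taxon = colnames(counts) %||% paste0("taxon_", seq_len(nt)),
             median_tau_b = apply(taus, 2, stats::median),
             median_p = apply(ps, 2, stats::median),
             n = length(variable))
}

#' Multiple linear regression report for insulin sensitivity
#'
#' Ordinary least squares of an outcome (default the clamp M-value) on the
#' given predictors, reported in the conventional clinical layout:
#' unstandardized B with SE and 95 percent CI, standardized Beta
#' (`B * sd(x) / sd(y)`), per-predictor p, plus multiple R and R squared.
#'
#' @param cohort data.frame with the outcome and predictor columns.
#' @param predictors character vector of predictor column names.
#' @param outcome outcome column name (default `"M_value"`).
#' @return list of class `regression_fit`: `coefficients` (data.frame with
#'   `term`, `B`, `SE`, `ci_low`, `ci_high`, `beta_std`, `p`), `R`,
#'   `R_squared`, `n`, `outcome`.
#' @export
mvalue_regression <- function(cohort, predictors, outcome = "M_value") {
  missing_cols <- setdiff(c(outcome, predictors), names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(cohort)
  if (n <= length(predictors) + 1)
    stop("need n > number of predictors + 1")
  X <- as.matrix(cohort[predictors])
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    kept <- qx$pivot[seq_len(qx$rank)]
    collinear <- predictors[!(seq_along(predictors) + 1) %in% kept]
    stop("rank-deficient design; collinear predictor(s): ",
         paste(collinear, collapse = ", "))
  }
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(fml, data = cohort)
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- stats::confint(fit, level = 0.95)
  y_sd <- stats::sd(cohort[[outcome]])
  beta_std <- c(NA_real_,
                co[-1, 1] * apply(X, 2, stats::sd)[rownames(co)[-1]] / y_sd)
  coefs <- data.frame(term = rownames(co),
                      B = co[, 1], SE = co[, 2],
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      beta_std = beta_std, p = co[, 4])
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs,
                 R = sqrt(sm$r.squared), R_squared = sm$r.squared,
                 n = n, outcome = outcome),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("Linear regression for %s (R = %.3f; R^2 = %.3f; n = %d)\n",
              x$outcome, x$R, x$R_squared, x$n))
  co <- x$coefficients
  cat(sprintf("%-18s %9s %8s %18s %8s %8s\n",
              "", "B", "SE", "95% CI", "Beta", "p"))
  for (i in seq_len(nrow(co)))
    cat(sprintf("%-18s %9.3f %8.3f [%7.3f, %7.3f] %8s %8.3g\n",
                co$term[i], co$B[i], co$SE[i], co$ci_low[i], co$ci_high[i],
                ifelse(is.na(co$beta_std[i]), "-",
                       sprintf("%.3f", co$beta_std[i])), co$p[i]))
  invisible(x)
}

#' Univariate predictor screen followed by the multivariable model
#'
#' `univariate_screen()` tests each candidate against the outcome one at a
#' time (simple OLS p-value by default, Kendall tau-b optionally) and keeps
#' those with p below the threshold. `fit_mvalue_model()` chains the screen
#' and [mvalue_regression()] into the standard two-stage clinical modeling
#' procedure; an empty survivor set yields a `NULL` fit with a warning.
#'
#' @param cohort data.frame of subjects.
#' @param outcome outcome column name.
#' @param candidates character vector of candidate predictor columns.
#' @param threshold univariate p-value threshold in (0, 1), default 0.05.
#' @param method `"ols"` or `"kendall"`.
#' @return `univariate_screen()`: data.frame `variable`, `p`, `selected`;
#'   `fit_mvalue_model()`: list with `screen` and `fit` (a `regression_fit`
#'   or `NULL`).
#' @export
univariate_screen <- function(cohort, outcome, candidates, threshold = 0.05,
                              method = c("ols", "kendall")) {
  method <- match.arg(method)
  stopifnot(threshold > 0, threshold < 1)
  p <- vapply(candidates, function(v) {
    if (method == "ols") {
      fit <- stats::lm(stats::reformulate(v, response = outcome),
                       data = cohort)
      stats::coef(summary(fit))[2, 4]
    } else {
      kendall_tau_b(cohort[[v]], cohort[[outcome]])$p_value
    }
  }, 0)
  data.frame(variable = candidates, p = unname(p),
             selected = unname(p) < threshold)
}

#' @rdname univariate_screen
#' @export
fit_mvalue_model <- function(cohort, candidates, outcome = "M_value",
                             threshold = 0.05,
                             method = c("ols", "kendall")) {
  scr <- univariate_screen(cohort, outcome, candidates, threshold, method)
  surv <- scr$variable[scr$selected]
  if (length(surv) == 0) {
    warning("no candidate passed the univariate screen; no model fitted")
    return(list(screen = scr, fit = NULL))
  }
  list(screen = scr, fit = mvalue_regression(cohort, surv, outcome))
}
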