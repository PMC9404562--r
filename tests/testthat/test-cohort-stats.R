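test_that("tau-b agrees with brute-force pair enumeration on tied data", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:8, 1)
    alpha <- sample(2:5, 1)
    x <- sample(seq_len(alpha), n, replace = TRUE)
    y <- sample(seq_len(alpha), n, replace = TRUE)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    a <- kendall_tau_b(x, y)
    expect_equal(a$tau_b, brute_tau_b(x, y), tolerance = 1e-12)
    ## cross-check against the reference implementation
    expect_equal(a$tau_b, stats::cor(x, y, method = "kendall"),
                 tolerance = 1e-12)
  }
})

test_that("perfect concordance and discordance hit the tau-b extremes", {
  expect_equal(kendall_tau_b(1:5, 1:5)$tau_b, 1)
  expect_equal(kendall_tau_b(1:5, 5:1)$tau_b, -1)
  expect_error(kendall_tau_b(1:5, rep(2, 5)), "constant")
  expect_error(kendall_tau_b(1:5, 1:4), "equal length")
})

test_that("exact p-values match the reference exact distribution on untied data", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    x <- sample(100, n)
    y <- sample(100, n)
    a <- kendall_tau_b(x, y, p_method = "exact")
    ct <- stats::cor.test(x, y, method = "kendall", exact = TRUE)
    expect_equal(a$p_value, ct$p.value, tolerance = 1e-10)
  }
})

test_that("normal-approximation p-values carry the tie correction", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(15:40, 1)
    x <- sample(5, n, replace = TRUE)
    y <- x + sample(3, n, replace = TRUE)
    a <- kendall_tau_b(x, y, p_method = "normal")
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "kendall", exact = FALSE))
    expect_equal(a$p_value, ct$p.value, tolerance = 1e-10)
  }
})

test_that("Dirichlet clr rows are centered, seeded, and guard zero subjects", {
  counts <- matrix(rpois(6 * 10, 40), 6, 10,
                   dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  clr <- dirichlet_clr(counts, n_instances = 32, seed = 11)
  expect_equal(dim(clr), c(6, 10, 32))
  expect_lt(max(abs(apply(clr, c(1, 3), sum))), 1e-10)
  expect_identical(clr, dirichlet_clr(counts, n_instances = 32, seed = 11))
  expect_false(identical(clr[, , 1], clr[, , 2]))
  bad <- counts
  bad[2, ] <- 0
  expect_error(dirichlet_clr(bad, 4), "s2")
})

test_that("uniform count rows have near-zero expected clr", {
  counts <- matrix(1, 40, 4)
  clr <- dirichlet_clr(counts, n_instances = 128, seed = 3)
  m <- apply(clr, 2, mean)   # over subjects and instances
  mc_se <- apply(clr, 2, stats::sd) / sqrt(40 * 128)
  expect_true(all(abs(m) < 3 * pmax(mc_se, 1e-3)))
})

test_that("a single clr instance reduces taxa association to plain clr + tau", {
  set.seed(21)
  sim <- simulate_cohort(cohort_sim_params(seed = 21))
  res <- taxa_association(sim$taxa_counts, sim$cohort$M_value,
                          n_instances = 1, seed = 4)
  clr <- dirichlet_clr(sim$taxa_counts, n_instances = 1, seed = 4)
  direct <- kendall_tau_b(clr[, 1, 1], sim$cohort$M_value)
  expect_equal(res$median_tau_b[1], direct$tau_b)
  expect_equal(res$median_p[1], direct$p_value)
})

test_that("noise-free linear data are interpolated exactly", {
  x1 <- c(80, 95, 100, 110, 120, 90, 85, 105)
  x2 <- c(5.1, 5.3, 5.6, 5.0, 5.9, 5.2, 5.8, 5.4)
  d <- data.frame(plasma = x1, hba1c = x2,
                  M_value = 30 - 0.07 * x1 - 3.4 * x2)
  fit <- mvalue_regression(d, c("plasma", "hba1c"))
  co <- fit$coefficients
  expect_equal(co$B[co$term == "plasma"], -0.07, tolerance = 1e-8)
  expect_equal(co$B[co$term == "hba1c"], -3.4, tolerance = 1e-8)
  expect_equal(co$B[co$term == "(Intercept)"], 30, tolerance = 1e-8)
  expect_equal(fit$R_squared, 1, tolerance = 1e-8)
})

test_that("standardized Beta equals B * sd(x) / sd(y) and CIs use the t quantile", {
  sim <- simulate_cohort(cohort_sim_params(seed = 5))
  fit <- mvalue_regression(sim$cohort, c("plasma_succinate", "HbA1c"))
  co <- fit$coefficients
  y_sd <- stats::sd(sim$cohort$M_value)
  for (v in c("plasma_succinate", "HbA1c")) {
    i <- which(co$term == v)
    expect_equal(co$beta_std[i],
                 co$B[i] * stats::sd(sim$cohort[[v]]) / y_sd,
                 tolerance = 1e-12)
    tq <- stats::qt(0.975, fit$n - 3)
    expect_equal(co$ci_low[i], co$B[i] - tq * co$SE[i], tolerance = 1e-9)
    expect_equal(co$ci_high[i], co$B[i] + tq * co$SE[i], tolerance = 1e-9)
  }
})

test_that("collinear predictors are rejected by name", {
  sim <- simulate_cohort(cohort_sim_params(seed = 6))
  d <- sim$cohort
  d$plasma_copy <- 2 * d$plasma_succinate
  expect_error(mvalue_regression(d, c("plasma_succinate", "plasma_copy")),
               "plasma_copy")
})

test_that("univariate screen keeps self-predictors and feeds the pipeline", {
  sim <- simulate_cohort(cohort_sim_params(seed = 12))
  d <- sim$cohort
  d$self <- d$M_value
  scr <- suppressWarnings(  # lm warns on the essentially perfect self-fit
    univariate_screen(d, "M_value", c("self", "age")))
  expect_true(scr$selected[scr$variable == "self"])
  expect_lt(scr$p[scr$variable == "self"], 1e-12)
  res <- fit_mvalue_model(d, c("plasma_succinate", "HbA1c", "age"))
  expect_s3_class(res$fit, "regression_fit")
  ## pure-noise candidates: screen can come up empty without crashing
  d$noise <- stats::rnorm(nrow(d))
  expect_warning(out <- fit_mvalue_model(d, "noise", threshold = 1e-6),
                 "no candidate")
  expect_null(out$fit)
})

test_that("null univariate rejection rate sits at the nominal level", {
  set.seed(33)
  n_reps <- 400
  rej <- replicate(n_reps, {
    y <- stats::rnorm(25)
    x <- stats::rnorm(25)
    d <- data.frame(M_value = y, x = x)
    univariate_screen(d, "M_value", "x")$selected
  })
  rate <- mean(rej)
  ## binomial 99% band around 0.05 for 400 reps
  expect_gt(rate, 0.05 - 2.58 * sqrt(0.05 * 0.95 / n_reps))
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_reps))
})
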