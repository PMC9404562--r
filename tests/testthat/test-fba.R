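test_that("FBA recovers the analytic optimum of the 3-reaction toy", {
  sol <- solve_fba(tiny_model())
  expect_equal(sol$status, "optimal")
  expect_equal(sol$growth_rate, 5, tolerance = 1e-9)
  ## no carbon, zero flux is optimal and feasible
  sol0 <- solve_fba(tiny_model(glc_lb = 0))
  expect_equal(sol0$status, "optimal")
  expect_equal(sol0$growth_rate, 0, tolerance = 1e-12)
})

test_that("optimal solutions satisfy mass balance and bounds", {
  suite <- make_suite(2, seed = 11)
  wd <- demo_western_diet()
  for (m in suite$models) {
    mm <- apply_medium(m, medium_condition(
      stats::setNames(rep(10, length(m$exchange_ids) - 1),
                      setdiff(m$exchange_ids, m$oxygen_exchange_id))))
    sol <- solve_fba(mm)
    expect_equal(sol$status, "optimal")
    S <- succscreen:::s_matrix(mm)
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
    expect_true(all(sol$fluxes >= mm$reactions$lower_bound - 1e-6))
    expect_true(all(sol$fluxes <= mm$reactions$upper_bound + 1e-6))
  }
})

test_that("apply_medium implements the limiting/absent bound protocol", {
  c1 <- make_consumer(toy_model_spec("consumer", n_decoy_nutrients = 1,
                                     seed = 2), id = "C1")$model
  med <- medium_condition(c(EX_succ_e = 10), aerobic = FALSE)
  m <- apply_medium(c1, med)
  lb <- stats::setNames(m$reactions$lower_bound, m$reactions$id)
  expect_equal(unname(lb["EX_succ_e"]), -10)   # limiting -> -10
  expect_equal(unname(lb["EX_o2_e"]), 0)       # anaerobic -> 0
  ## unlisted exchange absent, secretion still open
  other_ex <- setdiff(m$exchange_ids, c("EX_succ_e", "EX_o2_e"))
  expect_true(all(lb[other_ex] == 0))
  ub <- stats::setNames(m$reactions$upper_bound, m$reactions$id)
  expect_true(all(ub[other_ex] > 0))
  ## idempotence
  m2 <- apply_medium(m, med)
  expect_equal(m2$reactions, m$reactions)
  ## aerobic flag opens oxygen
  ma <- apply_medium(c1, medium_condition(c(EX_succ_e = 10), aerobic = TRUE))
  expect_equal(ma$reactions$lower_bound[ma$reactions$id == "EX_o2_e"], -10)
  ## unknown / non-exchange medium ids are an error
  expect_error(apply_medium(c1, medium_condition(c(BIOMASS = 5))),
               "non-exchange")
})

test_that("flux_range brackets the FBA point and nests across fractions", {
  c1 <- make_consumer(toy_model_spec("consumer", n_decoy_nutrients = 2,
                                     seed = 4), id = "C1")$model
  nutrients <- setdiff(c1$exchange_ids, c("EX_o2_e", "EX_prop_e"))
  m <- apply_medium(c1, medium_condition(
    stats::setNames(rep(10, length(nutrients)), nutrients)))
  iv1 <- flux_range(m, "EX_succ_e", 1.0)
  iv9 <- flux_range(m, "EX_succ_e", 0.999)
  expect_lte(iv1$min_flux, iv1$max_flux + 1e-9)
  expect_lte(iv9$min_flux, iv1$min_flux + 1e-9)  # relaxation widens
  expect_gte(iv9$max_flux, iv1$max_flux - 1e-9)
  sol <- solve_fba(m)
  expect_gte(sol$fluxes[["EX_succ_e"]], iv1$min_flux - 1e-8)
  expect_lte(sol$fluxes[["EX_succ_e"]], iv1$max_flux + 1e-8)
  ## a reaction pinned by equal bounds has a point interval
  m$reactions$lower_bound[m$reactions$id == "EX_succ_e"] <- -3
  m$reactions$upper_bound[m$reactions$id == "EX_succ_e"] <- -3
  ivp <- flux_range(m, "EX_succ_e", 1.0)
  expect_equal(ivp$min_flux, -3, tolerance = 1e-9)
  expect_equal(ivp$max_flux, -3, tolerance = 1e-9)
})

test_that("parsimonious fluxes silence futile cycles at unchanged growth", {
  ## tiny model plus a reversible A<->B futile cycle that FBA may spin
  m <- metabolic_model(
    id = "cycle",
    metabolites = data.frame(id = c("glc_e", "bio_c", "a_c", "b_c"),
                             compartment = c("e", "c", "c", "c")),
    reactions = data.frame(
      id = c("EX_glc_e", "R_grow", "BIOMASS", "CYC1", "CYC2"),
      lower_bound = c(-10, 0, 0, 0, 0),
      upper_bound = c(1000, 1000, 1000, 500, 500),
      objective_coefficient = c(0, 0, 1, 0, 0)),
    stoichiometry = list(EX_glc_e = c(glc_e = -1),
                         R_grow = c(glc_e = -1, bio_c = 0.5),
                         BIOMASS = c(bio_c = -1),
                         CYC1 = c(a_c = -1, b_c = 1),
                         CYC2 = c(b_c = -1, a_c = 1)))
  base <- solve_fba(m)
  pf <- parsimonious_fluxes(m)
  expect_equal(pf$growth_rate, base$growth_rate, tolerance = 1e-9)
  expect_equal(unname(pf$fluxes[c("CYC1", "CYC2")]), c(0, 0),
               tolerance = 1e-9)
  expect_lte(attr(pf, "total_flux"), sum(abs(base$fluxes)) + 1e-9)
})

test_that("relaxing an exchange bound never decreases optimal growth", {
  set.seed(31)
  suite <- make_suite(2, seed = 8)
  for (m in suite$models) {
    ex <- setdiff(m$exchange_ids, m$oxygen_exchange_id)
    med10 <- medium_condition(stats::setNames(rep(10, length(ex)), ex))
    med20 <- medium_condition(stats::setNames(rep(20, length(ex)), ex))
    g10 <- solve_fba(apply_medium(m, med10))$growth_rate
    g20 <- solve_fba(apply_medium(m, med20))$growth_rate
    expect_gte(g20, g10 - 1e-9)
  }
})

test_that("scaling all bounds by k scales optimal growth by exactly k", {
  m <- tiny_model()
  g1 <- solve_fba(m)$growth_rate
  k <- 3.5
  m$reactions$lower_bound <- k * m$reactions$lower_bound
  m$reactions$upper_bound <- k * m$reactions$upper_bound
  expect_equal(solve_fba(m)$growth_rate, k * g1, tolerance = 1e-9)
})
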