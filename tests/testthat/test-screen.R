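test_that("phenotype labels partition every (growth, interval) input", {
  params <- screen_params()
  set.seed(19)
  labels <- c("no_growth", "consumer", "producer", "facultative", "neutral")
  for (i in 1:300) {
    growth <- sample(c(0, 10^runif(1, -8, 1)), 1)
    a <- runif(1, -20, 20)
    b <- runif(1, -20, 20)
    iv <- c(min(a, b), max(a, b))
    lab <- classify_phenotype(growth, iv, params)
    expect_true(lab %in% labels)
    ## re-derive independently from the definition table
    eps <- params$flux_epsilon
    want <- if (growth < params$growth_epsilon) "no_growth"
      else if (iv[2] < -eps) "consumer"
      else if (iv[1] > eps) "producer"
      else if (iv[1] < -eps) "facultative"
      else "neutral"
    expect_identical(lab, want)
  }
})

test_that("usable nutrients exclude oxygen and secretion-only exchanges", {
  c1 <- make_consumer(toy_model_spec("consumer", n_decoy_nutrients = 2,
                                     seed = 6), id = "C1")$model
  u <- usable_nutrients(c1)
  expect_false("EX_o2_e" %in% u)
  expect_false("EX_prop_e" %in% u)  # propionate is secretion-only
  expect_true("EX_succ_e" %in% u)
  expect_equal(u, sort(u, method = "radix"))
})

test_that("the nutrient iteration yields 2 records per nutrient, all consumer for the consumer archetype", {
  c1 <- make_consumer(toy_model_spec("consumer", n_decoy_nutrients = 2,
                                     seed = 6), id = "C1")$model
  recs <- single_nonlimiting_screen(c1)
  u <- usable_nutrients(c1)
  expect_equal(nrow(recs), 2 * length(u))
  expect_true(all(recs$label == "consumer"))
  ## succinate-non-limiting anaerobic condition: uptake saturates the cap
  r <- recs[recs$nonlimiting_nutrient == "EX_succ_e" & !recs$aerobic, ]
  expect_equal(r$succ_min, -1000, tolerance = 1e-9)
  expect_lt(r$succ_max, -1e-6)
})

test_that("a disconnected succinate exchange forces neutral records", {
  i1 <- make_inert(toy_model_spec("inert", n_decoy_nutrients = 1,
                                  seed = 3), id = "I1")$model
  recs <- single_nonlimiting_screen(i1)
  grown <- recs[recs$label != "no_growth", ]
  expect_true(all(grown$label == "neutral"))
  expect_true(all(abs(grown$succ_min) < 1e-9 & abs(grown$succ_max) < 1e-9))
})

test_that("gut-condition simulation classifies consumer/producer and handles missing succinate", {
  wd <- demo_western_diet()
  c1 <- make_consumer(toy_model_spec("consumer", n_decoy_nutrients = 0,
                                     seed = 2), id = "C1")$model
  p1 <- make_producer(toy_model_spec("producer", seed = 2), id = "P1")$model
  expect_equal(gut_condition_screen(c1, wd)$label, "consumer")
  expect_equal(gut_condition_screen(p1, wd)$label, "producer")
  ## diet without succinate: uptake cap 0 forces a [0,0] interval
  no_succ <- medium_condition(
    wd$uptake_caps[names(wd$uptake_caps) != "EX_succ_e"], aerobic = FALSE)
  g <- gut_condition_screen(c1, no_succ)
  expect_equal(g$label, "no_growth")  # C1 grows only on succinate here
  c2 <- make_consumer(toy_model_spec("consumer", n_decoy_nutrients = 2,
                                     seed = 2), id = "C2")$model
  g2 <- gut_condition_screen(c2, no_succ)
  expect_equal(g2$label, "neutral")
  expect_equal(c(g2$succ_min, g2$succ_max), c(0, 0), tolerance = 1e-9)
  ## aerobic diet flag warns and still runs anaerobically
  aer <- medium_condition(wd$uptake_caps, aerobic = TRUE)
  expect_warning(gut_condition_screen(c1, aer), "anaerobic")
})

test_that("species summary applies the verdict thresholds", {
  params <- screen_params()
  rec <- function(label, n) data.frame(
    model_id = "m", nonlimiting_nutrient = "x", aerobic = FALSE,
    growth_rate = ifelse(label == "no_growth", 0, 1),
    succ_min = 0, succ_max = 0, label = rep(label, n))
  gut <- function(label) {
    g <- rec(label, 1)
    g$nonlimiting_nutrient <- "western_diet"
    g
  }
  ## 1 consumer / 9 neutral, gut neutral -> partial (fraction 0.1 < 0.8)
  r <- rbind(rec("consumer", 1), rec("neutral", 9))
  s <- summarize_species(r, gut("neutral"), params)
  expect_equal(s$species_verdict, "partial_consumer")
  expect_equal(s$consumer_fraction, 0.1)
  ## all consumer but gut producer -> not clear
  s2 <- summarize_species(rec("consumer", 5), gut("producer"), params)
  expect_equal(s2$species_verdict, "partial_consumer")
  ## consumer fraction over growth-supporting records only
  r3 <- rbind(rec("consumer", 4), rec("no_growth", 6))
  s3 <- summarize_species(r3, gut("consumer"), params)
  expect_equal(s3$consumer_fraction, 1)
  expect_equal(s3$species_verdict, "clear_consumer")
  ## producers outnumber consumers -> producer
  s4 <- summarize_species(rbind(rec("producer", 3), rec("neutral", 2)),
                          gut("producer"), params)
  expect_equal(s4$species_verdict, "producer")
  expect_error(summarize_species(r3[0, ], gut("neutral"), params), "empty")
})

test_that("screening requires a succinate exchange annotation", {
  m <- tiny_model()
  expect_error(single_nonlimiting_screen(m), "succinate_exchange_id")
})

test_that("raising the non-limiting cap never flips consumer to neutral", {
  suite <- make_suite(2, seed = 13)
  cons <- suite$models[grep("^consumer", names(suite$models))]
  for (m in cons) {
    r1 <- single_nonlimiting_screen(m, screen_params(nonlimiting_uptake = 20))
    r2 <- single_nonlimiting_screen(m, screen_params(nonlimiting_uptake = 1000))
    was_consumer <- r1$label == "consumer"
    expect_true(all(r2$label[was_consumer] != "neutral"))
  }
})

test_that("batch screening writes deterministic outputs and survives bad paths", {
  dir <- withr::local_tempdir()
  suite <- make_suite(1, seed = 21)
  paths <- vapply(names(suite$models), function(id) {
    p <- file.path(dir, paste0(id, ".json"))
    write_model(suite$models[[id]], p)
    p
  }, "")
  out1 <- file.path(dir, "run1")
  out2 <- file.path(dir, "run2")
  wd <- demo_western_diet()
  res <- run_screen_batch(c(paths, file.path(dir, "nope.json")), wd,
                          out_dir = out1)
  expect_equal(res$n_failed, 1)
  expect_equal(sum(res$summary$status == "ok"), 3)
  run_screen_batch(c(paths, file.path(dir, "nope.json")), wd, out_dir = out2)
  expect_identical(readLines(file.path(out1, "screen_records.tsv")),
                   readLines(file.path(out2, "screen_records.tsv")))
  expect_identical(readLines(file.path(out1, "screen_summary.tsv")),
                   readLines(file.path(out2, "screen_summary.tsv")))
})
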