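#' Nutrient exchange ids of the demo western-diet medium
#'
#' A fixed 12-nutrient pool (succinate, glucose and ten further carbon
#' sources) used both by the shipped `western_diet_demo.tsv` medium and by the
#' toy-model generators, so that generated organisms can always be simulated
#' under the demo gut condition.
#'
#' @return character vector of exchange reaction ids.
#' @export
western_diet_nutrients <- function() {
  c("EX_succ_e", "EX_glc_e", "EX_fru_e", "EX_gal_e", "EX_man_e",
    "EX_xyl_e", "EX_arab_e", "EX_rib_e", "EX_cellb_e", "EX_lac_e",
    "EX_mal_e", "EX_ac_e")
}

#' Specification for one toy genome-scale model
#'
#' Toy organisms come in three archetypes with closed-form succinate
#' phenotypes: `consumer` (succinate -> propionate + growth energy),
#' `producer` (glucose -> growth energy with stoichiometrically coupled
#' succinate secretion) and `inert` (a succinate exchange exists but is
#' disconnected from metabolism). Energy is a single abstract currency
#' metabolite, which keeps every linear program hand-solvable while still
#' coupling growth to uptake/secretion.
#'
#' @param archetype `"consumer"`, `"producer"` or `"inert"`.
#' @param n_decoy_nutrients number of additional growth substrates (>= 0).
#' @param biomass_yield_per_succinate growth energy per succinate taken up
#'   (consumer only, > 0).
#' @param succinate_yield_per_glucose succinate secreted per glucose consumed
#'   (producer only, > 0).
#' @param seed integer seed used for any randomized nuisance yields.
#' @return list of class `toy_model_spec`.
#' @export
toy_model_spec <- function(archetype = c("consumer", "producer", "inert"),
                           n_decoy_nutrients = 2,
                           biomass_yield_per_succinate = NULL,
                           succinate_yield_per_glucose = NULL,
                           seed = 1L) {
  archetype <- match.arg(archetype)
  stopifnot(n_decoy_nutrients >= 0)
  if (archetype == "consumer") {
    if (is.null(biomass_yield_per_succinate)) biomass_yield_per_succinate <- 0.5
    if (biomass_yield_per_succinate <= 0)
      stop("biomass_yield_per_succinate must be > 0")
    if (!is.null(succinate_yield_per_glucose))
      stop("succinate_yield_per_glucose applies only to the producer archetype")
  } else if (archetype == "producer") {
    if (is.null(succinate_yield_per_glucose)) succinate_yield_per_glucose <- 0.5
    if (succinate_yield_per_glucose <= 0)
      stop("succinate_yield_per_glucose must be > 0")
    if (!is.null(biomass_yield_per_succinate))
      stop("biomass_yield_per_succinate applies only to the consumer archetype")
  } else {
    if (!is.null(biomass_yield_per_succinate) ||
        !is.null(succinate_yield_per_glucose))
      stop("yield parameters apply only to consumer/producer archetypes")
  }
  structure(list(archetype = archetype,
                 n_decoy_nutrients = as.integer(n_decoy_nutrients),
                 biomass_yield_per_succinate = biomass_yield_per_succinate,
                 succinate_yield_per_glucose = succinate_yield_per_glucose,
                 seed = as.integer(seed)),
            class = "toy_model_spec")
}

# decoy exchange ids come from the western-diet pool (minus succinate and,
# for producers/inert models, glucose which is the primary substrate)
decoy_pool <- function(exclude) setdiff(western_diet_nutrients(), exclude)

# paste0 recycles zero-length args to "", so guard the empty-decoy case
cat_names <- function(decoys) {
  if (length(decoys) == 0) return(character(0))
  paste0("CAT_", sub("^EX_|_e$", "", decoys))
}

toy_exchange <- function(ex_id, met_id) {
  list(id = ex_id, met = met_id,
       row = data.frame(id = ex_id, lower_bound = -1000, upper_bound = 1000,
                        objective_coefficient = 0))
}

build_toy_model <- function(id, mets, rxns, stoich, succ_ex, truth) {
  model <- metabolic_model(
    id = id,
    metabolites = mets,
    reactions = rxns,
    stoichiometry = stoich,
    biomass_id = "BIOMASS",
    succinate_exchange_id = succ_ex,
    oxygen_exchange_id = "EX_o2_e")
  list(model = model, truth = truth)
}

#' Generate a toy succinate consumer
#'
#' Network: succinate uptake feeds `succ -> propionate + y * energy`
#' (`y = biomass_yield_per_succinate`), propionate leaves through a
#' secretion-only exchange, and biomass consumes energy. Decoy nutrients feed
#' energy with strictly lower yields (drawn as a seeded uniform fraction of
#' `y`), so at near-optimal growth the organism must still take succinate up
#' in every growth-supporting condition: the species verdict is
#' `clear_consumer` by construction, and when succinate is the non-limiting
#' nutrient its uptake saturates the cap exactly.
#'
#' @param spec a [toy_model_spec()] with `archetype = "consumer"`.
#' @param id model id.
#' @return list with `model` (a [metabolic_model()]) and `truth` (data.frame
#'   with `model_id`, `archetype`, `expected_verdict`, `expected_gut_label`).
#' @export
make_consumer <- function(spec = toy_model_spec("consumer"),
                          id = "toy_consumer") {
  stopifnot(inherits(spec, "toy_model_spec"), spec$archetype == "consumer")
  y <- spec$biomass_yield_per_succinate
  nd <- spec$n_decoy_nutrients
  set.seed(spec$seed)
  decoys <- decoy_pool("EX_succ_e")[seq_len(nd)]
  decoy_yield <- y * stats::runif(nd, 0.1, 1)

  met_ids <- c("succ_e", "prop_e", "o2_e", "energy_c",
               sub("^EX_", "", decoys))
  mets <- data.frame(id = met_ids,
                     compartment = ifelse(grepl("_e$", met_ids), "e", "c"))
  rxns <- data.frame(
    id = c("EX_succ_e", "EX_prop_e", "EX_o2_e", "CAT_succ", "BIOMASS",
           decoys, cat_names(decoys)),
    lower_bound = c(-1000, 0, -1000, 0, 0, rep(-1000, nd), rep(0, nd)),
    upper_bound = 1000,
    objective_coefficient = c(0, 0, 0, 0, 1, rep(0, 2 * nd)))
  stoich <- c(
    list(EX_succ_e = c(succ_e = -1),
         EX_prop_e = c(prop_e = -1),
         EX_o2_e = c(o2_e = -1),
         CAT_succ = c(succ_e = -1, prop_e = 1, energy_c = y),
         BIOMASS = c(energy_c = -1)),
    stats::setNames(lapply(decoys, function(d) c(d = -1)), decoys),
    stats::setNames(lapply(seq_len(nd), function(i) {
      s <- c(-1, decoy_yield[i])
      names(s) <- c(sub("^EX_", "", decoys[i]), "energy_c")
      s
    }), cat_names(decoys)))
  ## fix decoy exchange stoich names
  for (d in decoys) names(stoich[[d]]) <- sub("^EX_", "", d)

  build_toy_model(id, mets, rxns, stoich, "EX_succ_e",
                  data.frame(model_id = id, archetype = "consumer",
                             expected_verdict = "clear_consumer",
                             expected_gut_label = "consumer"))
}

#' Generate a toy succinate producer
#'
#' Network: glucose uptake drives `glc -> y_s * succinate + y_e * energy`, so
#' succinate secretion is stoichiometrically coupled to growth
#' (`secretion = y_s * glucose uptake`, closed form). Decoy nutrients have
#' strictly lower energy yields, so glucose (and with it succinate secretion)
#' is required at near-optimal growth in every condition: the species verdict
#' is `producer` by construction.
#'
#' @inheritParams make_consumer
#' @param spec a [toy_model_spec()] with `archetype = "producer"`.
#' @export
make_producer <- function(spec = toy_model_spec("producer"),
                          id = "toy_producer") {
  stopifnot(inherits(spec, "toy_model_spec"), spec$archetype == "producer")
  ys <- spec$succinate_yield_per_glucose
  nd <- spec$n_decoy_nutrients
  set.seed(spec$seed)
  ye <- stats::runif(1, 0.1, 1)  # growth energy per glucose
  decoys <- decoy_pool(c("EX_succ_e", "EX_glc_e"))[seq_len(nd)]
  decoy_yield <- ye * stats::runif(nd, 0.1, 1)

  met_ids <- c("glc_e", "succ_e", "o2_e", "energy_c",
               sub("^EX_", "", decoys))
  mets <- data.frame(id = met_ids,
                     compartment = ifelse(grepl("_e$", met_ids), "e", "c"))
  rxns <- data.frame(
    id = c("EX_glc_e", "EX_succ_e", "EX_o2_e", "FERM_glc", "BIOMASS",
           decoys, cat_names(decoys)),
    lower_bound = c(-1000, -1000, -1000, 0, 0, rep(-1000, nd), rep(0, nd)),
    upper_bound = 1000,
    objective_coefficient = c(0, 0, 0, 0, 1, rep(0, 2 * nd)))
  stoich <- c(
    list(EX_glc_e = c(glc_e = -1),
         EX_succ_e = c(succ_e = -1),
         EX_o2_e = c(o2_e = -1),
         FERM_glc = c(glc_e = -1, succ_e = ys, energy_c = ye),
         BIOMASS = c(energy_c = -1)),
    stats::setNames(lapply(decoys, function(d)
      stats::setNames(-1, sub("^EX_", "", d))), decoys),
    stats::setNames(lapply(seq_len(nd), function(i)
      stats::setNames(c(-1, decoy_yield[i]),
                      c(sub("^EX_", "", decoys[i]), "energy_c"))),
      cat_names(decoys)))

  out <- build_toy_model(id, mets, rxns, stoich, "EX_succ_e",
                         data.frame(model_id = id, archetype = "producer",
                                    expected_verdict = "producer",
                                    expected_gut_label = "producer"))
  out$energy_yield_per_glucose <- ye
  out
}

#' Generate a toy succinate-inert organism
#'
#' Growth runs entirely on glucose (plus decoys); a succinate exchange is
#' present but its metabolite is consumed by no internal reaction, so mass
#' balance forces zero succinate flux: every record is `neutral` (or
#' `no_growth`) and the species verdict is `non_consumer`.
#'
#' @inheritParams make_consumer
#' @param spec a [toy_model_spec()] with `archetype = "inert"`.
#' @export
make_inert <- function(spec = toy_model_spec("inert"), id = "toy_inert") {
  stopifnot(inherits(spec, "toy_model_spec"), spec$archetype == "inert")
  nd <- spec$n_decoy_nutrients
  set.seed(spec$seed)
  ye <- stats::runif(1, 0.1, 1)
  decoys <- decoy_pool(c("EX_succ_e", "EX_glc_e"))[seq_len(nd)]
  decoy_yield <- stats::runif(nd, 0.1, 1)

  met_ids <- c("glc_e", "succ_e", "o2_e", "energy_c",
               sub("^EX_", "", decoys))
  mets <- data.frame(id = met_ids,
                     compartment = ifelse(grepl("_e$", met_ids), "e", "c"))
  rxns <- data.frame(
    id = c("EX_glc_e", "EX_succ_e", "EX_o2_e", "CAT_glc", "BIOMASS",
           decoys, cat_names(decoys)),
    lower_bound = c(-1000, -1000, -1000, 0, 0, rep(-1000, nd), rep(0, nd)),
    upper_bound = 1000,
    objective_coefficient = c(0, 0, 0, 0, 1, rep(0, 2 * nd)))
  stoich <- c(
    list(EX_glc_e = c(glc_e = -1),
         EX_succ_e = c(succ_e = -1),
         EX_o2_e = c(o2_e = -1),
         CAT_glc = c(glc_e = -1, energy_c = ye),
         BIOMASS = c(energy_c = -1)),
    stats::setNames(lapply(decoys, function(d)
      stats::setNames(-1, sub("^EX_", "", d))), decoys),
    stats::setNames(lapply(seq_len(nd), function(i)
      stats::setNames(c(-1, decoy_yield[i]),
                      c(sub("^EX_", "", decoys[i]), "energy_c"))),
      cat_names(decoys)))

  build_toy_model(id, mets, rxns, stoich, "EX_succ_e",
                  data.frame(model_id = id, archetype = "inert",
                             expected_verdict = "non_consumer",
                             expected_gut_label = "neutral"))
}

#' Generate a reproducible suite of toy models with ground truth
#'
#' Draws `n_per_archetype` consumers, producers and inert organisms with
#' seeded randomized yields (uniform on \[0.1, 1\]) and decoy counts
#' (0 to 3), and returns models together with a ground-truth table derived in
#' closed form from the archetype construction.
#'
#' @param n_per_archetype models per archetype.
#' @param seed integer seed; the suite is identical across reruns for a fixed
#'   seed.
#' @return list with `models` (named list of [metabolic_model()]) and `truth`
#'   (data.frame).
#' @export
make_suite <- function(n_per_archetype = 10, seed = 1L) {
  set.seed(seed)
  draws <- data.frame(
    archetype = rep(c("consumer", "producer", "inert"),
                    each = n_per_archetype),
    idx = rep(seq_len(n_per_archetype), 3),
    yield = round(stats::runif(3 * n_per_archetype, 0.1, 1), 4),
    n_decoy = sample(0:3, 3 * n_per_archetype, replace = TRUE),
    sub_seed = sample.int(1e6, 3 * n_per_archetype))
  models <- list()
  truths <- list()
  for (i in seq_len(nrow(draws))) {
    d <- draws[i, ]
    id <- sprintf("%s_%02d", d$archetype, d$idx)
    out <- switch(d$archetype,
      consumer = make_consumer(
        toy_model_spec("consumer", n_decoy_nutrients = d$n_decoy,
                       biomass_yield_per_succinate = d$yield,
                       seed = d$sub_seed), id = id),
      producer = make_producer(
        toy_model_spec("producer", n_decoy_nutrients = d$n_decoy,
                       succinate_yield_per_glucose = d$yield,
                       seed = d$sub_seed), id = id),
      inert = make_inert(
        toy_model_spec("inert", n_decoy_nutrients = d$n_decoy,
                       seed = d$sub_seed), id = id))
    models[[id]] <- out$model
    truths[[id]] <- out$truth
  }
  list(models = models, truth = do.call(rbind, truths))
}

#' Write a toy-model suite as a fixtures directory
#'
#' Emits one model JSON per suite member plus `ground_truth.tsv`.
#'
#' @param suite result of [make_suite()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_suite <- function(suite, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(suite$models))
    write_model(suite$models[[id]], file.path(dir, paste0(id, ".json")))
  utils::write.table(suite$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
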