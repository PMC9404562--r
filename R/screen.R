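#' Parameters of the nutrient-limitation phenotypic screen
#'
#' Encodes the bound protocol of the screen: in each condition exactly one
#' usable nutrient is non-limiting (uptake cap `nonlimiting_uptake`,
#' effectively unconstrained since the protocol only bounds it from below),
#' every other usable nutrient is limiting (cap `limiting_uptake`, magnitude
#' 10), and all remaining exchanges are absent (cap 0). Oxygen is a separate
#' axis: each condition is run both aerobically (oxygen cap
#' `limiting_uptake`) and anaerobically (cap 0).
#'
#' @param limiting_uptake uptake cap for limiting nutrients (mmol/gDW/h),
#'   default 10.
#' @param nonlimiting_uptake uptake cap for the one non-limiting nutrient,
#'   default 1000.
#' @param flux_epsilon threshold below which a succinate flux counts as zero,
#'   default 1e-6.
#' @param fva_fraction fraction of optimal growth retained when computing the
#'   succinate flux interval, default 0.999.
#' @param growth_epsilon growth rate below which a condition counts as
#'   no-growth, default 1e-6.
#' @param clear_consumer_fraction fraction of growth-supporting conditions
#'   that must be consumer records for a `clear_consumer` verdict ("almost
#'   all"), default 0.8.
#' @return list of class `screen_params`.
#' @export
screen_params <- function(limiting_uptake = 10, nonlimiting_uptake = 1000,
                          flux_epsilon = 1e-6, fva_fraction = 0.999,
                          growth_epsilon = 1e-6,
                          clear_consumer_fraction = 0.8) {
  stopifnot(nonlimiting_uptake > limiting_uptake, limiting_uptake > 0,
            fva_fraction > 0, fva_fraction <= 1,
            clear_consumer_fraction > 0, clear_consumer_fraction <= 1,
            flux_epsilon > 0, growth_epsilon > 0)
  structure(list(limiting_uptake = limiting_uptake,
                 nonlimiting_uptake = nonlimiting_uptake,
                 absent_uptake = 0,
                 flux_epsilon = flux_epsilon,
                 fva_fraction = fva_fraction,
                 growth_epsilon = growth_epsilon,
                 clear_consumer_fraction = clear_consumer_fraction),
            class = "screen_params")
}

#' Nutrients a model can actually use
#'
#' All exchange reactions except oxygen and except pure-secretion exchanges:
#' those whose flux can never be negative while the organism grows, judged by
#' minimizing the exchange flux subject to growth of at least
#' `growth_epsilon` under an all-open medium (every non-oxygen exchange at
#' `nonlimiting_uptake`, oxygen open too). Returned in lexicographic order.
#'
#' @param model a [metabolic_model()].
#' @param params a [screen_params()].
#' @return character vector of exchange reaction ids (possibly empty, with a
#'   warning when the model has no exchanges or cannot grow at all).
#' @export
usable_nutrients <- function(model, params = screen_params()) {
  ex <- setdiff(model$exchange_ids, model$oxygen_exchange_id)
  if (length(ex) == 0) {
    warning("model '", model$id, "' has no non-oxygen exchange reactions")
    return(character(0))
  }
  open <- medium_condition(
    stats::setNames(rep(params$nonlimiting_uptake, length(ex)), ex),
    aerobic = TRUE)
  m <- apply_medium(model, open, default_o2_cap = params$nonlimiting_uptake)
  S <- s_matrix(m)
  obj <- m$reactions$objective_coefficient
  A <- rbind(S, obj)
  rel <- c(rep("=", nrow(S)), ">=")
  rhs <- c(rep(0, nrow(S)), params$growth_epsilon)
  usable <- character(0)
  for (e in ex) {
    target <- as.numeric(m$reactions$id == e)
    lo <- lp_solve(target, A, rel, rhs, m$reactions$lower_bound,
                   m$reactions$upper_bound, maximize = FALSE)
    if (lo$status == "infeasible") {
      warning("model '", model$id, "' cannot grow under an all-open medium")
      return(character(0))
    }
    if (lo$objective < -params$flux_epsilon) usable <- c(usable, e)
  }
  sort(usable, method = "radix")
}

#' Classify a succinate phenotype from growth and a flux interval
#'
#' Pure, total labeling rule: `no_growth` when growth is below
#' `growth_epsilon`; otherwise `consumer` when even the maximum succinate
#' exchange flux is uptake (`max < -flux_epsilon`), `producer` when even the
#' minimum is secretion (`min > flux_epsilon`), `facultative` when the
#' interval reaches into uptake without forcing it (`min < -flux_epsilon`,
#' `max >= -flux_epsilon`), and `neutral` otherwise.
#'
#' @param growth growth rate (1/h).
#' @param interval a `flux_interval` (or numeric `c(min, max)`).
#' @param params a [screen_params()].
#' @return one of `"no_growth"`, `"consumer"`, `"producer"`, `"facultative"`,
#'   `"neutral"`.
#' @export
classify_phenotype <- function(growth, interval, params = screen_params()) {
  if (inherits(interval, "flux_interval"))
    interval <- c(interval$min_flux, interval$max_flux)
  stopifnot(length(interval) == 2, interval[1] <= interval[2] + 1e-12)
  eps <- params$flux_epsilon
  if (growth < params$growth_epsilon) return("no_growth")
  if (interval[2] < -eps) return("consumer")
  if (interval[1] > eps) return("producer")
  if (interval[1] < -eps) return("facultative")
  "neutral"
}

#' Media generated by the nutrient-iteration screen
#'
#' Enumerates, without solving anything, the exact medium of every screen
#' condition for a model: for each usable nutrient and oxygen state, the
#' medium in which that nutrient is non-limiting, all other usable nutrients
#' are limiting, and every other exchange is absent. Useful for auditing the
#' bound protocol.
#'
#' @param model a [metabolic_model()].
#' @param params a [screen_params()].
#' @return list of conditions, each a list with `nonlimiting` (exchange id),
#'   `aerobic` (logical) and `medium` (a [medium_condition()]).
#' @export
screen_media <- function(model, params = screen_params()) {
  nutrients <- usable_nutrients(model, params)
  out <- list()
  for (n in nutrients)
    for (aerobic in c(FALSE, TRUE)) {
      caps <- stats::setNames(rep(params$limiting_uptake, length(nutrients)),
                              nutrients)
      caps[n] <- params$nonlimiting_uptake
      out[[length(out) + 1L]] <-
        list(nonlimiting = n, aerobic = aerobic,
             medium = medium_condition(caps, aerobic = aerobic))
    }
  out
}

# one screen condition: apply medium, solve, classify
screen_condition <- function(model, cond, params) {
  m <- apply_medium(model, cond$medium,
                    default_o2_cap = params$limiting_uptake)
  phenotype_record(m, cond$nonlimiting, cond$aerobic, params)
}

phenotype_record <- function(m, nutrient_label, aerobic, params) {
  sol <- solve_fba(m)
  if (sol$status != "optimal")
    stop("screen: FBA ", sol$status, " for model '", m$id, "', condition '",
         nutrient_label, "'")
  if (sol$growth_rate < params$growth_epsilon) {
    smin <- smax <- 0
    label <- "no_growth"
  } else {
    iv <- flux_range(m, m$succinate_exchange_id, params$fva_fraction)
    smin <- iv$min_flux
    smax <- iv$max_flux
    label <- classify_phenotype(sol$growth_rate, iv, params)
  }
  data.frame(model_id = m$id, nonlimiting_nutrient = nutrient_label,
             aerobic = aerobic, growth_rate = sol$growth_rate,
             succ_min = smin, succ_max = smax, label = label)
}

#' Iterated single-non-limiting-nutrient screen
#'
#' For each usable nutrient and each oxygen state (anaerobic, then aerobic),
#' builds the medium in which that nutrient alone is non-limiting and all
#' other usable nutrients are limiting, solves FBA, and classifies the
#' succinate phenotype from the flux-variability interval at
#' `fva_fraction` of optimal growth. Produces exactly `2 * n_nutrients`
#' records in deterministic order.
#'
#' @param model a [metabolic_model()] with `succinate_exchange_id` annotated.
#' @param params a [screen_params()].
#' @return data.frame of phenotype records with columns `model_id`,
#'   `nonlimiting_nutrient`, `aerobic`, `growth_rate`, `succ_min`,
#'   `succ_max`, `label`.
#' @export
single_nonlimiting_screen <- function(model, params = screen_params()) {
  if (is.na(model$succinate_exchange_id))
    stop("model '", model$id, "' has no succinate_exchange_id annotation; ",
         "annotate the succinate exchange reaction before screening")
  conds <- screen_media(model, params)
  if (length(conds) == 0)
    stop("model '", model$id, "' has no usable nutrients")
  recs <- lapply(conds, function(cond) screen_condition(model, cond, params))
  do.call(rbind, recs)
}

#' Western-diet gut-condition simulation
#'
#' One additional record under the western-diet medium. The gut lumen is
#' anaerobic: if the medium is flagged aerobic a warning is issued and the
#' simulation still runs anaerobically. Diet nutrients the model cannot
#' exchange are dropped (a diet is defined over a universal exchange
#' namespace, models only see their own exchanges).
#'
#' @param model a [metabolic_model()] with `succinate_exchange_id` annotated.
#' @param western_diet a [medium_condition()].
#' @param params a [screen_params()].
#' @return one-row phenotype record data.frame with
#'   `nonlimiting_nutrient = "western_diet"`.
#' @export
gut_condition_screen <- function(model, western_diet,
                                 params = screen_params()) {
  if (is.na(model$succinate_exchange_id))
    stop("model '", model$id, "' has no succinate_exchange_id annotation")
  if (western_diet$aerobic) {
    warning("gut simulation forces anaerobic conditions; ",
            "ignoring aerobic medium flag")
  }
  caps <- western_diet$uptake_caps
  caps <- caps[names(caps) %in% model$exchange_ids]
  med <- medium_condition(caps, aerobic = FALSE)
  m <- apply_medium(model, med)
  phenotype_record(m, "western_diet", FALSE, params)
}

#' Species-level screen summary
#'
#' Aggregates per-condition records into a species verdict. The consumer
#' fraction is computed over growth-supporting records only (a species cannot
#' consume while dead). Verdict order: `clear_consumer` when the consumer
#' fraction reaches `clear_consumer_fraction` and the gut record is consumer
#' or facultative; else `partial_consumer` when any record is consumer; else
#' `producer` when producer records strictly outnumber consumer records;
#' else `non_consumer`.
#'
#' @param records data.frame from [single_nonlimiting_screen()].
#' @param gut_record one-row data.frame from [gut_condition_screen()].
#' @param params a [screen_params()].
#' @return list of class `screen_result` with `records`, `gut_record`,
#'   `species_verdict`, `conditions_tested`, `consumer_fraction`.
#' @export
summarize_species <- function(records, gut_record,
                              params = screen_params()) {
  if (is.null(records) || nrow(records) == 0)
    stop("summarize_species: empty record set")
  growing <- records[records$label != "no_growth", , drop = FALSE]
  n_cons <- sum(growing$label == "consumer")
  n_prod <- sum(growing$label == "producer")
  frac <- if (nrow(growing) == 0) 0 else n_cons / nrow(growing)
  verdict <-
    if (frac >= params$clear_consumer_fraction && nrow(growing) > 0 &&
        gut_record$label %in% c("consumer", "facultative")) "clear_consumer"
    else if (n_cons > 0) "partial_consumer"
    else if (n_prod > n_cons) "producer"
    else "non_consumer"
  structure(list(records = records, gut_record = gut_record,
                 species_verdict = verdict,
                 conditions_tested = nrow(records),
                 consumer_fraction = frac),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>", x$records$model_id[1], "verdict:",
      x$species_verdict,
      sprintf("(consumer fraction %.2f over %d conditions + gut)",
              x$consumer_fraction, x$conditions_tested), "\n")
  invisible(x)
}

#' Full screen of one model
#'
#' Convenience wrapper: nutrient-iteration screen, gut-condition record, and
#' species summary.
#'
#' @inheritParams gut_condition_screen
#' @return a `screen_result`.
#' @export
run_screen <- function(model, western_diet, params = screen_params()) {
  recs <- single_nonlimiting_screen(model, params)
  gut <- gut_condition_screen(model, western_diet, params)
  summarize_species(recs, gut, params)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

#' Screen a batch of model files
#'
#' Loads each model path, runs the full screen, and writes deterministic
#' outputs to `out_dir`: `screen_records.tsv` (all per-condition records,
#' gut included) and `screen_summary.tsv` (one verdict row per model, with a
#' `status` column; a model that fails to load or screen is recorded as a
#' `failed` row and the batch continues).
#'
#' @param model_paths character vector of model JSON paths.
#' @param western_diet a [medium_condition()].
#' @param params a [screen_params()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `results` (named list of `screen_result`),
#'   `summary` (data.frame) and `n_failed`.
#' @export
run_screen_batch <- function(model_paths, western_diet,
                             params = screen_params(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  summ <- list()
  recs <- list()
  for (p in model_paths) {
    res <- tryCatch({
      model <- load_model(p)
      run_screen(model, western_diet, params)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      summ[[p]] <- data.frame(model_id = basename(p), verdict = NA,
                              consumer_fraction = NA_real_,
                              conditions_tested = NA_integer_,
                              status = "failed")
      next
    }
    id <- res$records$model_id[1]
    results[[id]] <- res
    recs[[id]] <- rbind(res$records, res$gut_record)
    summ[[p]] <- data.frame(model_id = id, verdict = res$species_verdict,
                            consumer_fraction = res$consumer_fraction,
                            conditions_tested = res$conditions_tested,
                            status = "ok")
  }
  summary_df <- do.call(rbind, summ)
  rownames(summary_df) <- NULL
  all_recs <- do.call(rbind, recs)
  if (!is.null(all_recs)) {
    num <- vapply(all_recs, is.numeric, logical(1))
    all_recs[num] <- lapply(all_recs[num], fmt_num)
    rownames(all_recs) <- NULL
    utils::write.table(all_recs, file.path(out_dir, "screen_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out_summary <- summary_df
  out_summary$consumer_fraction <- fmt_num(out_summary$consumer_fraction)
  utils::write.table(out_summary, file.path(out_dir, "screen_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(results = results, summary = summary_df,
                 n_failed = sum(summary_df$status == "failed")))
}
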