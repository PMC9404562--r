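#' Apply a medium to a model
#'
#' Sets exchange lower bounds from a medium: each listed exchange gets
#' `lower_bound = -cap`, every unlisted exchange gets `lower_bound = 0`
#' (absent nutrient), and upper bounds are untouched so secretion is never
#' blocked by medium choice. The oxygen exchange is controlled solely by the
#' medium's `aerobic` flag: its lower bound is `-oxygen_cap` when aerobic
#' (the medium's cap for the oxygen exchange if listed, else `default_o2_cap`)
#' and 0 when anaerobic.
#'
#' @param model a [metabolic_model()].
#' @param medium a [medium_condition()]; ids must be exchange reactions of
#'   `model` (unknown ids are an error).
#' @param default_o2_cap oxygen uptake cap (mmol/gDW/h) used when aerobic and
#'   the medium does not list the oxygen exchange. Default 10.
#' @return a copy of `model` with exchange lower bounds set.
#' @export
apply_medium <- function(model, medium, default_o2_cap = 10) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(medium, "medium_condition"))
  caps <- medium$uptake_caps
  unknown <- setdiff(names(caps), model$exchange_ids)
  if (length(unknown) > 0)
    stop("medium names non-exchange or unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  o2 <- model$oxygen_exchange_id
  lb <- model$reactions$lower_bound
  is_ex <- model$reactions$id %in% model$exchange_ids
  lb[is_ex] <- 0
  listed <- intersect(names(caps), model$reactions$id)
  lb[match(listed, model$reactions$id)] <- -caps[listed]
  if (o2 %in% model$reactions$id) {
    o2_cap <- if (o2 %in% names(caps)) caps[[o2]] else default_o2_cap
    lb[match(o2, model$reactions$id)] <- if (medium$aerobic) -o2_cap else 0
  }
  model$reactions$lower_bound <- lb
  model
}

#' Solve flux balance analysis
#'
#' Maximizes the biomass objective subject to steady-state mass balance
#' `S v = 0` and flux bounds. The solver is the package's deterministic
#' simplex, so repeated solves of the same model are bit-identical. The
#' returned optimum is additionally verified post hoc: `max |S v|` and bound
#' violations beyond `check_tol` raise an error rather than returning a
#' silently wrong solution.
#'
#' @param model a [metabolic_model()] (typically after [apply_medium()]).
#' @param check_tol post-hoc feasibility verification tolerance (default 1e-6).
#' @return object of class `fba_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `growth_rate` (1/h; flux through the
#'   biomass reaction) and `fluxes` (named, mmol/gDW/h).
#' @export
solve_fba <- function(model, check_tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- s_matrix(model)
  obj <- model$reactions$objective_coefficient
  res <- lp_solve(obj, S, rep("=", nrow(S)), rep(0, nrow(S)),
                  model$reactions$lower_bound, model$reactions$upper_bound)
  if (res$status != "optimal")
    return(structure(list(status = res$status, growth_rate = NA_real_,
                          fluxes = stats::setNames(rep(NA_real_, ncol(S)),
                                                   colnames(S))),
                     class = "fba_solution"))
  v <- stats::setNames(res$solution, model$reactions$id)
  if (max(abs(S %*% v)) > check_tol ||
      any(v < model$reactions$lower_bound - check_tol) ||
      any(v > model$reactions$upper_bound + check_tol))
    stop("FBA solution failed post-hoc feasibility verification for model '",
         model$id, "'")
  structure(list(status = "optimal",
                 growth_rate = unname(v[model$biomass_id]),
                 fluxes = v),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution>", x$status, "growth_rate:",
      format(x$growth_rate, digits = 6), "\n")
  invisible(x)
}

#' Flux variability interval at near-optimal growth
#'
#' Minimum and maximum flux a reaction can carry over all flux vectors whose
#' growth is at least `fraction_of_optimum` times the FBA optimum (two extra
#' linear programs). This makes "consumption or production rate" well defined
#' even when the FBA optimum is degenerate.
#'
#' @param model a [metabolic_model()].
#' @param reaction_id reaction whose flux range is wanted.
#' @param fraction_of_optimum growth fraction in (0, 1], default 1.
#' @return list of class `flux_interval` with `reaction_id`, `min_flux`,
#'   `max_flux`, `fraction_of_optimum`.
#' @export
flux_range <- function(model, reaction_id, fraction_of_optimum = 1) {
  stopifnot(inherits(model, "metabolic_model"),
            fraction_of_optimum > 0, fraction_of_optimum <= 1)
  if (!reaction_id %in% model$reactions$id)
    stop("unknown reaction: ", reaction_id)
  base <- solve_fba(model)
  if (base$status != "optimal")
    stop("flux_range: base FBA is ", base$status, " for model '",
         model$id, "'")
  S <- s_matrix(model)
  obj <- model$reactions$objective_coefficient
  A <- rbind(S, obj)
  rel <- c(rep("=", nrow(S)), ">=")
  rhs <- c(rep(0, nrow(S)), fraction_of_optimum * base$growth_rate)
  target <- as.numeric(model$reactions$id == reaction_id)
  lo <- lp_solve(target, A, rel, rhs, model$reactions$lower_bound,
                 model$reactions$upper_bound, maximize = FALSE)
  hi <- lp_solve(target, A, rel, rhs, model$reactions$lower_bound,
                 model$reactions$upper_bound, maximize = TRUE)
  if (lo$status != "optimal" || hi$status != "optimal")
    stop("flux_range: variability LP was not optimal (", lo$status, "/",
         hi$status, ")")
  structure(list(reaction_id = reaction_id,
                 min_flux = lo$objective, max_flux = hi$objective,
                 fraction_of_optimum = fraction_of_optimum),
            class = "flux_interval")
}

#' Parsimonious flux distribution (pFBA)
#'
#' Among flux vectors attaining the FBA optimum, returns one minimizing the
#' total absolute flux `sum(|v|)` (linear program via flux splitting
#' `v = p - q`, `p, q >= 0`). This selects a canonical flux vector for
#' reporting, independent of which optimal vertex the primary solve lands on;
#' futile cycles carry zero flux in it.
#'
#' @param model a [metabolic_model()].
#' @return an `fba_solution` whose `fluxes` minimize total absolute flux at
#'   optimal growth; the attribute `total_flux` holds `sum(|v|)`.
#' @export
parsimonious_fluxes <- function(model) {
  base <- solve_fba(model)
  if (base$status != "optimal")
    stop("parsimonious_fluxes: base FBA is ", base$status)
  S <- s_matrix(model)
  n <- ncol(S)
  obj <- model$reactions$objective_coefficient
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  ## variables [p, q], v = p - q
  A_split <- cbind(S, -S)
  A_obj <- c(obj, -obj)
  A <- rbind(A_split, A_obj)
  rel <- c(rep("=", nrow(S)), "=")
  rhs <- c(rep(0, nrow(S)), base$growth_rate)
  ## forced-flux variables (lb > 0 or ub < 0) need explicit net-flux rows
  forced <- which(lb > 0 | ub < 0)
  for (j in forced) {
    row <- numeric(2 * n)
    row[j] <- 1; row[n + j] <- -1
    if (lb[j] > 0) { A <- rbind(A, row); rel <- c(rel, ">="); rhs <- c(rhs, lb[j]) }
    if (ub[j] < 0) { A <- rbind(A, row); rel <- c(rel, "<="); rhs <- c(rhs, ub[j]) }
  }
  lbs <- rep(0, 2 * n)
  ubs <- c(pmax(ub, 0), pmax(-lb, 0))
  res <- lp_solve(rep(1, 2 * n), A, rel, rhs, lbs, ubs, maximize = FALSE)
  if (res$status != "optimal")
    stop("parsimonious_fluxes: flux-minimization LP was ", res$status)
  v <- stats::setNames(res$solution[seq_len(n)] - res$solution[n + seq_len(n)],
                       model$reactions$id)
  out <- structure(list(status = "optimal",
                        growth_rate = unname(v[model$biomass_id]),
                        fluxes = v),
                   class = "fba_solution")
  attr(out, "total_flux") <- res$objective
  out
}
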