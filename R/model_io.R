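#' Construct a metabolic model
#'
#' A `metabolic_model` is a stoichiometric network with flux bounds, a biomass
#' objective and a set of exchange reactions. Sign convention (asserted, not
#' configurable): an exchange reaction carries exactly one extracellular
#' metabolite with coefficient -1, so negative exchange flux is uptake and
#' positive flux is secretion.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `compartment`.
#' @param reactions data.frame with columns `id`, `lower_bound`, `upper_bound`,
#'   `objective_coefficient`.
#' @param stoichiometry named list (one entry per reaction id) of named numeric
#'   vectors mapping metabolite id to signed coefficient.
#' @param exchange_ids character vector of exchange reaction ids; if `NULL`,
#'   auto-detected as single-metabolite reactions on an extracellular
#'   metabolite (compartment `"e"` or `"extracellular"`).
#' @param biomass_id id of the biomass reaction; if `NULL`, the unique reaction
#'   with nonzero objective coefficient.
#' @param succinate_exchange_id id of the succinate exchange reaction, or `NA`.
#' @param oxygen_exchange_id id of the oxygen exchange reaction (default
#'   `"EX_o2_e"`; it need not exist in the model).
#'
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            exchange_ids = NULL, biomass_id = NULL,
                            succinate_exchange_id = NA_character_,
                            oxygen_exchange_id = "EX_o2_e") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "compartment") %in% names(metabolites)),
            all(c("id", "lower_bound", "upper_bound",
                  "objective_coefficient") %in% names(reactions)))
  stoichiometry <- stoichiometry[reactions$id]

  if (is.null(biomass_id)) {
    cand <- reactions$id[reactions$objective_coefficient != 0]
    if (length(cand) != 1L)
      stop("cannot infer biomass_id: ", length(cand),
           " reactions have nonzero objective_coefficient")
    biomass_id <- cand
  }
  if (is.null(exchange_ids)) {
    extra <- metabolites$id[metabolites$compartment %in%
                              c("e", "extracellular")]
    exchange_ids <- reactions$id[vapply(stoichiometry, function(s) {
      length(s) == 1L && names(s) %in% extra && s[[1]] == -1
    }, logical(1))]
  }

  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry,
         exchange_ids = sort(unique(exchange_ids)),
         biomass_id = biomass_id,
         succinate_exchange_id = succinate_exchange_id,
         oxygen_exchange_id = oxygen_exchange_id),
    class = "metabolic_model")
  diag <- validate_model(model)
  err <- diag[diag$level == "error", , drop = FALSE]
  if (nrow(err) > 0)
    stop("invalid metabolic model '", id, "':\n  ",
         paste(err$message, collapse = "\n  "))
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$id, "\n",
      " metabolites:", nrow(x$metabolites),
      " reactions:", nrow(x$reactions),
      " exchanges:", length(x$exchange_ids), "\n",
      " biomass:", x$biomass_id,
      " succinate exchange:", x$succinate_exchange_id, "\n")
  invisible(x)
}

#' Validate a metabolic model
#'
#' Report-only diagnostics: invariant violations are level `"error"`, orphan
#' metabolites (appearing in no reaction) are level `"warning"`. An empty
#' report means the model is valid.
#'
#' @param model a `metabolic_model` (or an untrusted list with its fields).
#' @return data.frame with columns `level`, `field`, `message`.
#' @export
validate_model <- function(model) {
  out <- list()
  add <- function(level, field, message)
    out[[length(out) + 1L]] <<- data.frame(level = level, field = field,
                                           message = message)
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id))
    add("error", "metabolites",
        paste("duplicate metabolite id:",
              paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  if (any(!nzchar(mets$compartment)))
    add("error", "metabolites", "empty compartment")
  if (anyDuplicated(rxns$id))
    add("error", "reactions",
        paste("duplicate reaction id:",
              paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")))
  bad_bounds <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  for (b in bad_bounds)
    add("error", b, paste0("lower_bound > upper_bound in reaction '", b, "'"))
  if (!all(is.finite(rxns$lower_bound)) || !all(is.finite(rxns$upper_bound)))
    add("error", "reactions", "non-finite flux bound")
  for (rid in rxns$id) {
    s <- model$stoichiometry[[rid]]
    if (is.null(s) || length(s) == 0L) {
      add("error", rid, paste0("reaction '", rid, "' has empty stoichiometry"))
      next
    }
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown) > 0)
      add("error", rid,
          paste0("reaction '", rid, "' references undefined metabolite: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!model$biomass_id %in% rxns$id)
    add("error", "biomass_id",
        paste0("biomass_id '", model$biomass_id, "' is not a reaction"))
  missing_ex <- setdiff(model$exchange_ids, rxns$id)
  if (length(missing_ex) > 0)
    add("error", "exchange_ids",
        paste("exchange ids not in reactions:",
              paste(missing_ex, collapse = ", ")))
  extra <- mets$id[mets$compartment %in% c("e", "extracellular")]
  for (ex in intersect(model$exchange_ids, rxns$id)) {
    s <- model$stoichiometry[[ex]]
    if (!(length(s) == 1L && s[[1]] == -1 && names(s) %in% extra))
      add("error", ex,
          paste0("exchange '", ex, "' must have exactly one extracellular ",
                 "metabolite with coefficient -1"))
  }
  if (!is.na(model$succinate_exchange_id) &&
      !model$succinate_exchange_id %in% rxns$id)
    add("error", "succinate_exchange_id",
        paste0("succinate_exchange_id '", model$succinate_exchange_id,
               "' is not a reaction"))
  used <- unique(unlist(lapply(model$stoichiometry, names)))
  for (o in setdiff(mets$id, used))
    add("warning", o, paste0("orphan metabolite '", o,
                             "' appears in no reaction"))
  if (length(out) == 0)
    return(data.frame(level = character(), field = character(),
                      message = character()))
  do.call(rbind, out)
}

#' Read a metabolic model from JSON
#'
#' The dialect is structurally compatible with community COBRA-JSON field
#' names: top-level `id`, `metabolites` (`id`, `compartment`), `reactions`
#' (`id`, `metabolites` map, `lower_bound`, `upper_bound`,
#' `objective_coefficient`) and an `annotations` object naming the
#' `biomass`, `succinate_exchange` and `oxygen_exchange` reactions.
#'
#' @param path path to a model JSON file.
#' @return a [metabolic_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed model JSON in '", path, "': ",
                         conditionMessage(e)))
  for (field in c("id", "metabolites", "reactions"))
    if (is.null(raw[[field]]))
      stop("model JSON missing required field '", field, "'")
  mets <- data.frame(
    id = vapply(raw$metabolites, function(m) as.character(m$id), ""),
    compartment = vapply(raw$metabolites,
                         function(m) as.character(m$compartment %||% ""), ""))
  rxns <- data.frame(
    id = vapply(raw$reactions, function(r) as.character(r$id), ""),
    lower_bound = vapply(raw$reactions,
                         function(r) as.numeric(r$lower_bound %||% NA), 0),
    upper_bound = vapply(raw$reactions,
                         function(r) as.numeric(r$upper_bound %||% NA), 0),
    objective_coefficient = vapply(raw$reactions,
      function(r) as.numeric(r$objective_coefficient %||% 0), 0))
  stoich <- lapply(raw$reactions, function(r) {
    s <- unlist(r$metabolites)
    if (is.null(s)) return(numeric(0))
    stats::setNames(as.numeric(s), names(s))
  })
  names(stoich) <- rxns$id
  ann <- raw$annotations %||% list()
  metabolic_model(
    id = raw$id, metabolites = mets, reactions = rxns, stoichiometry = stoich,
    exchange_ids = if (!is.null(ann$exchanges)) unlist(ann$exchanges) else NULL,
    biomass_id = ann$biomass %||% NULL,
    succinate_exchange_id = ann$succinate_exchange %||% NA_character_,
    oxygen_exchange_id = ann$oxygen_exchange %||% "EX_o2_e")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metabolic model to JSON
#'
#' Emits the dialect read by [load_model()] with canonical key ordering, so
#' re-serializing an unchanged model is byte-stable.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  rx <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    s <- model$stoichiometry[[r$id]]
    list(id = r$id,
         metabolites = as.list(stats::setNames(as.numeric(s), names(s))),
         lower_bound = r$lower_bound,
         upper_bound = r$upper_bound,
         objective_coefficient = r$objective_coefficient)
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i)
    list(id = model$metabolites$id[i],
         compartment = model$metabolites$compartment[i]))
  ann <- list(biomass = model$biomass_id,
              oxygen_exchange = model$oxygen_exchange_id,
              exchanges = as.list(model$exchange_ids))
  if (!is.na(model$succinate_exchange_id))
    ann$succinate_exchange <- model$succinate_exchange_id
  obj <- list(id = model$id, metabolites = mets, reactions = rx,
              annotations = ann)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Construct a medium condition
#'
#' A medium maps exchange reaction ids to maximum uptake magnitudes
#' (mmol/gDW/h). Exchanges not listed are absent (uptake cap 0); secretion is
#' never restricted by a medium. The `aerobic` flag alone controls the oxygen
#' exchange.
#'
#' @param uptake_caps named nonnegative numeric vector, names are exchange
#'   reaction ids.
#' @param aerobic logical flag.
#' @return object of class `medium_condition`.
#' @export
medium_condition <- function(uptake_caps, aerobic = FALSE) {
  if (length(uptake_caps) > 0 && is.null(names(uptake_caps)))
    stop("uptake_caps must be named by exchange reaction id")
  if (anyDuplicated(names(uptake_caps)))
    stop("duplicate exchange reaction id in medium: ",
         paste(unique(names(uptake_caps)[duplicated(names(uptake_caps))]),
               collapse = ", "))
  if (any(!is.finite(uptake_caps)) || any(uptake_caps < 0))
    stop("uptake caps must be finite and nonnegative")
  structure(list(uptake_caps = uptake_caps, aerobic = isTRUE(aerobic)),
            class = "medium_condition")
}

#' Read a medium definition from TSV
#'
#' Format: optional pragma line `#aerobic: true|false` (default anaerobic),
#' then a header `reaction_id<TAB>max_uptake` and one row per nutrient.
#'
#' @param path path to the TSV file.
#' @return a [medium_condition()].
#' @export
load_medium <- function(path) {
  if (!file.exists(path)) stop("medium file not found: ", path)
  lines <- readLines(path)
  aerobic <- FALSE
  pragma <- grep("^#", lines)
  for (p in pragma) {
    m <- regmatches(lines[p],
                    regexec("^#\\s*aerobic:\\s*(true|false)\\s*$", lines[p]))[[1]]
    if (length(m) == 2) aerobic <- m[2] == "true"
  }
  body <- lines[setdiff(seq_along(lines), pragma)]
  body <- body[nzchar(body)]
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  if (!identical(names(tab), c("reaction_id", "max_uptake")))
    stop("medium TSV must have columns 'reaction_id', 'max_uptake'; got: ",
         paste(names(tab), collapse = ", "))
  caps <- suppressWarnings(as.numeric(tab$max_uptake))
  if (any(is.na(caps))) stop("non-numeric max_uptake in medium TSV")
  if (any(caps < 0))
    stop("negative max_uptake for: ",
         paste(tab$reaction_id[caps < 0], collapse = ", "))
  medium_condition(stats::setNames(caps, tab$reaction_id), aerobic = aerobic)
}

#' Write a medium definition to TSV
#'
#' @param medium a [medium_condition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_medium <- function(medium, path) {
  lines <- c(paste0("#aerobic: ", if (medium$aerobic) "true" else "false"),
             "reaction_id\tmax_uptake",
             paste(names(medium$uptake_caps),
                   format(medium$uptake_caps, trim = TRUE, scientific = FALSE),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# dense stoichiometric matrix (metabolites x reactions)
s_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (rid in model$reactions$id) {
    s <- model$stoichiometry[[rid]]
    S[names(s), rid] <- s
  }
  S
}
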