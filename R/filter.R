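#' Marker genes used as succinate-consumption evidence
#'
#' The four marker genes whose homology hits feed the candidate funnel:
#' propionyl-CoA:succinate CoA transferase (`scpC`), succinyl-CoA:CoA
#' transferase (`cat1`), succinate dehydrogenase (`sdh`) and acetyl-CoA
#' hydrolase (`ach`).
#'
#' @return character vector of gene symbols.
#' @export
marker_genes <- function() c("scpC", "cat1", "sdh", "ach")

#' Homology-threshold parameters for marker-gene hits
#'
#' Defaults are the screen's operating point: sequence identity strictly
#' above 80 percent and e-value strictly below 1e-5.
#'
#' @param min_identity identity threshold in \[0, 100\].
#' @param max_evalue e-value threshold (> 0).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_identity = 80, max_evalue = 1e-5) {
  stopifnot(min_identity >= 0, min_identity <= 100, max_evalue > 0)
  structure(list(min_identity = min_identity, max_evalue = max_evalue),
            class = "filter_params")
}

check_hits <- function(hits) {
  need <- c("strain_id", "gene", "identity_pct", "evalue")
  if (!all(need %in% names(hits)))
    stop("marker hit table needs columns: ", paste(need, collapse = ", "))
  bad <- !hits$gene %in% marker_genes()
  if (any(bad))
    stop("unknown marker gene(s): ",
         paste(unique(hits$gene[bad]), collapse = ", "))
  if (any(hits$identity_pct < 0 | hits$identity_pct > 100))
    stop("identity_pct outside [0, 100]")
  if (any(hits$evalue < 0)) stop("negative evalue")
  invisible(hits)
}

#' Threshold marker-gene hits
#'
#' A strain is retained when at least one single hit passes both thresholds
#' jointly: `identity_pct > min_identity` and `evalue < max_evalue` (strict
#' inequalities; a hit is one alignment, so its two statistics are not
#' combined across different hits). Any of the four marker genes qualifies.
#'
#' @param hits data.frame with columns `strain_id`, `gene`, `identity_pct`,
#'   `evalue`.
#' @param params a [filter_params()].
#' @return sorted character vector of retained strain ids.
#' @export
threshold_hits <- function(hits, params = filter_params()) {
  check_hits(hits)
  pass <- hits$identity_pct > params$min_identity &
    hits$evalue < params$max_evalue
  sort(unique(hits$strain_id[pass]), method = "radix")
}

#' Apply habitat/pathogenicity/assembly annotations
#'
#' A strain is retained iff it is a human-gut resident, not pathogenic, and a
#' genome assembly is available. For an excluded strain the recorded reason
#' is the first failing check in the fixed order `not_gut`, `pathogen`,
#' `no_assembly`.
#'
#' @param strains character vector of strain ids (e.g. from
#'   [threshold_hits()]).
#' @param annotations data.frame with columns `strain_id`,
#'   `human_gut_resident`, `pathogenic`, `assembly_available` (logical) and
#'   optionally `evidence`; every strain must have exactly one row.
#' @return list of class `candidate_list` with `retained` (sorted character)
#'   and `excluded` (data.frame `strain_id`, `reason`).
#' @export
apply_annotations <- function(strains, annotations) {
  need <- c("strain_id", "human_gut_resident", "pathogenic",
            "assembly_available")
  if (!all(need %in% names(annotations)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(annotations$strain_id))
    stop("duplicate annotation rows for: ",
         paste(unique(annotations$strain_id[
           duplicated(annotations$strain_id)]), collapse = ", "))
  missing <- setdiff(strains, annotations$strain_id)
  if (length(missing) > 0)
    stop("missing annotations for strain(s): ",
         paste(missing, collapse = ", "))
  ann <- annotations[match(strains, annotations$strain_id), ]
  reason <- ifelse(!ann$human_gut_resident, "not_gut",
            ifelse(ann$pathogenic, "pathogen",
            ifelse(!ann$assembly_available, "no_assembly", NA)))
  retained <- sort(strains[is.na(reason)], method = "radix")
  excl <- data.frame(strain_id = strains[!is.na(reason)],
                     reason = reason[!is.na(reason)])
  excl <- excl[order(excl$strain_id, method = "radix"), , drop = FALSE]
  rownames(excl) <- NULL
  structure(list(retained = retained, excluded = excl),
            class = "candidate_list")
}

#' @export
print.candidate_list <- function(x, ...) {
  cat("<candidate_list> retained:", length(x$retained),
      " excluded:", nrow(x$excluded), "\n")
  invisible(x)
}

#' Candidate funnel: thresholds, then annotation blocklists
#'
#' Runs [threshold_hits()] then [apply_annotations()] and reports the funnel
#' stage counts. Strains dropped at the threshold stage are recorded with
#' reason `low_identity` when no hit clears the identity threshold, else
#' `high_evalue`. Output ordering is deterministic.
#'
#' @inheritParams threshold_hits
#' @inheritParams apply_annotations
#' @return list of class `funnel_report`: `candidates` (a `candidate_list`
#'   whose `excluded` covers both stages), `counts` (named integer vector
#'   `input`, `post_threshold`, `post_annotation`).
#' @export
funnel_report <- function(hits, annotations, params = filter_params()) {
  check_hits(hits)
  all_strains <- sort(unique(hits$strain_id), method = "radix")
  passed <- threshold_hits(hits, params)
  dropped <- setdiff(all_strains, passed)
  drop_reason <- vapply(dropped, function(s) {
    h <- hits[hits$strain_id == s, ]
    if (all(h$identity_pct <= params$min_identity)) "low_identity"
    else "high_evalue"
  }, "")
  cand <- apply_annotations(passed, annotations)
  excl <- rbind(data.frame(strain_id = dropped, reason = unname(drop_reason)),
                cand$excluded)
  excl <- excl[order(excl$strain_id, method = "radix"), , drop = FALSE]
  rownames(excl) <- NULL
  structure(list(
    candidates = structure(list(retained = cand$retained, excluded = excl),
                           class = "candidate_list"),
    counts = c(input = length(all_strains),
               post_threshold = length(passed),
               post_annotation = length(cand$retained))),
    class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report> strains:", x$counts[["input"]],
      "-> past thresholds:", x$counts[["post_threshold"]],
      "-> candidates:", x$counts[["post_annotation"]], "\n")
  invisible(x)
}

#' Read marker-gene hit and strain-annotation tables
#'
#' `read_marker_hits()` expects the TSV columns `strain_id`, `gene`,
#' `identity_pct`, `evalue`; `read_strain_annotations()` expects
#' `strain_id`, `human_gut_resident`, `pathogenic`, `assembly_available`,
#' `evidence`.
#'
#' @param path path to a TSV file.
#' @return validated data.frame.
#' @export
read_marker_hits <- function(path) {
  if (!file.exists(path)) stop("hits file not found: ", path)
  hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_hits(hits)
  hits
}

#' @rdname read_marker_hits
#' @export
read_strain_annotations <- function(path) {
  if (!file.exists(path)) stop("annotations file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("human_gut_resident", "pathogenic", "assembly_available"))
    ann[[col]] <- as.logical(ann[[col]])
  ann
}

#' Simulate a marker-hit funnel with known stage counts
#'
#' Generates a synthetic hit table plus annotations whose funnel ground truth
#' is exact: `n_pass_threshold` strains carry at least one hit clearing both
#' thresholds, `n_fail_threshold` strains carry only failing hits, and the
#' annotations retain exactly `n_retained` of the passing strains (the
#' remainder is spread over the three exclusion reasons). The default shape
#' (89 past thresholds, 22 retained) mirrors a published succinate-consumer
#' discovery funnel; strains and statistics are synthetic, not a reproduction
#' of that study's strains.
#'
#' @param n_pass_threshold strains passing the homology thresholds.
#' @param n_retained strains surviving the annotation stage.
#' @param n_fail_threshold strains failing the thresholds.
#' @param params a [filter_params()] (thresholds the draws respect).
#' @param seed integer seed.
#' @return list with `hits`, `annotations` (data.frames) and `truth`
#'   (named integer vector of expected stage counts).
#' @export
simulate_marker_funnel <- function(n_pass_threshold = 89, n_retained = 22,
                                   n_fail_threshold = 31,
                                   params = filter_params(), seed = 1L) {
  stopifnot(n_retained <= n_pass_threshold)
  set.seed(seed)
  n <- n_pass_threshold + n_fail_threshold
  ids <- sprintf("synthetic_strain_%03d", seq_len(n))
  pass_ids <- sort(sample(ids, n_pass_threshold))
  hit_rows <- list()
  genes <- marker_genes()
  for (s in ids) {
    k <- sample(1:3, 1)
    g <- sample(genes, k, replace = TRUE)
    if (s %in% pass_ids) {
      idy <- c(stats::runif(1, params$min_identity + 2, 99.9),
               stats::runif(k - 1, 40, 99.9))
      ev <- c(10^stats::runif(1, -30, log10(params$max_evalue) - 1),
              10^stats::runif(k - 1, -30, 2))
    } else {
      ## never let a failing strain draw a hit passing both thresholds
      low_id <- stats::runif(k) < 0.5
      idy <- ifelse(low_id, stats::runif(k, 40, params$min_identity),
                    stats::runif(k, params$min_identity + 1, 99.9))
      ev <- ifelse(low_id, 10^stats::runif(k, -30, 2),
                   10^stats::runif(k, log10(params$max_evalue) + 1, 2))
    }
    hit_rows[[s]] <- data.frame(strain_id = s, gene = g,
                                identity_pct = round(idy, 1),
                                evalue = signif(ev, 3))
  }
  hits <- do.call(rbind, hit_rows)
  rownames(hits) <- NULL

  keep <- sort(sample(pass_ids, n_retained))
  rest <- setdiff(pass_ids, keep)
  reason <- sample(c("not_gut", "pathogen", "no_assembly"), length(rest),
                   replace = TRUE)
  ann <- data.frame(strain_id = ids,
                    human_gut_resident = TRUE, pathogenic = FALSE,
                    assembly_available = TRUE,
                    evidence = "synthetic annotation")
  ann$human_gut_resident[match(rest[reason == "not_gut"], ids)] <- FALSE
  ann$pathogenic[match(rest[reason == "pathogen"], ids)] <- TRUE
  ann$assembly_available[match(rest[reason == "no_assembly"], ids)] <- FALSE
  ann <- ann[order(ann$strain_id, method = "radix"), ]
  rownames(ann) <- NULL
  list(hits = hits, annotations = ann,
       truth = c(input = n, post_threshold = n_pass_threshold,
                 post_annotation = n_retained))
}
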