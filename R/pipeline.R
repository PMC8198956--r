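# End-to-end orchestration: cohort (from files or synthetic) -> QC ->
# normalization -> positivity -> healthy-vs-sCRC immunome -> metastasis
# differential -> balanced LOO LASSO voting -> ROC of the top-voted
# marker, with a machine-readable, deterministic run summary.

#' Pipeline run configuration
#'
#' Central, frozen home of the analysis defaults: positivity threshold at
#' empty-vector mean + 3 SD, Mann-Whitney cutoffs 0.05 (immunome and
#' metastasis differential) and 0.01 (strict reporting subset), at least
#' 2 positive sCRC samples, mean fold-change gate 1, linear-interpolation
#' first quartile for background correction.
#'
#' @param sd_multiplier positivity SD multiplier (default 3).
#' @param p_cutoff Mann-Whitney significance cutoff (default 0.05).
#' @param p_strict strict reporting cutoff (default 0.01).
#' @param min_crc_positives immunome criterion iii minimum (default 2).
#' @param fc_gate mean fold-change gate (default 1).
#' @param quantile_type background-quartile estimator (default 7).
#' @param selection a [selection_config()]; its `rng_seed` is overridden
#'   by `seed` so one global seed reproduces the whole run.
#' @param selection_universe `"immunome"` (default) or `"all"`: feature
#'   universe handed to the LASSO stage.
#' @param drop_degenerate drop samples with degenerate empty-vector
#'   controls instead of failing (default FALSE).
#' @param seed single global seed expanded into the stage substreams.
#' @return a `run_config` list.
#' @export
run_config <- function(sd_multiplier = 3, p_cutoff = 0.05, p_strict = 0.01,
                       min_crc_positives = 2, fc_gate = 1,
                       quantile_type = 7,
                       selection = selection_config(),
                       selection_universe = c("immunome", "all"),
                       drop_degenerate = FALSE, seed = 1L) {
  selection_universe <- match.arg(selection_universe)
  cfg <- as.list(environment())
  cfg$selection$rng_seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

#' Run the full screening pipeline
#'
#' Executes every stage on a cohort, either given directly (e.g. from
#' [generate_cohort()]) or read from a manifest. Stages that lack their
#' inputs degrade gracefully: marker selection needs at least two
#' metastatic samples, the metastasis differential a non-empty immunome.
#' Identical cohort + config give an identical summary.
#'
#' @param cohort named list of [array_sample()] (takes precedence), or
#' @param manifest path to a sample manifest to read the cohort from.
#' @param config a [run_config()].
#' @param role_map used when reading from a manifest.
#' @param out_dir optional directory; when given, stage tables are
#'   written there as TSV.
#' @return list of class `run_summary` with per-stage outputs and counts:
#'   `qc`, `reactivity`, `calls`, `healthy_vs_crc`, `immunome_features`,
#'   `met_diff`, `selection`, `curves`, `roc`, `counts`, `config_echo`.
#' @export
run_pipeline <- function(cohort = NULL, manifest = NULL,
                         config = run_config(),
                         role_map = default_role_map(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    if (is.null(manifest))
      stop("run_pipeline: provide a cohort or a manifest path")
    cohort <- read_cohort(manifest, role_map)
  }
  groups <- cohort_groups(cohort)
  qc <- qc_report(cohort)
  rm_ <- build_reactivity_matrix(cohort, config$quantile_type,
                                 config$drop_degenerate)
  calls <- call_positives(rm_, config$sd_multiplier)
  groups <- rm_$groups
  healthy_ids <- names(groups)[groups == "healthy"]
  crc_ids <- names(groups)[groups %in% c("crc_nonmet", "crc_met")]
  nonmet_ids <- names(groups)[groups == "crc_nonmet"]
  met_ids <- names(groups)[groups == "crc_met"]

  hvc <- NULL; immunome_features <- character(); met_diff <- NULL
  if (length(healthy_ids) && length(crc_ids)) {
    hvc <- compare_groups(rm_, calls, healthy_ids, crc_ids,
                          label = "healthy_vs_crc")
    hvc <- define_immunome(hvc, config$p_cutoff,
                           config$min_crc_positives, config$fc_gate)
    immunome_features <- hvc$feature_id[hvc$in_immunome]
  }
  if (length(immunome_features) && length(nonmet_ids) && length(met_ids))
    met_diff <- metastasis_differential(rm_, calls, immunome_features,
                                        nonmet_ids, met_ids,
                                        config$p_cutoff)

  universe <- if (config$selection_universe == "immunome")
    immunome_features else colnames(rm_$values)
  selection <- NULL; curves <- NULL; roc <- NULL; top_marker <- NA_character_
  scrc_groups <- groups[c(nonmet_ids, met_ids)]
  if (length(universe) && length(met_ids) >= 2 &&
      length(nonmet_ids) > length(met_ids) - 1) {
    selection <- balanced_loocv(
      rm_$values[c(nonmet_ids, met_ids), universe, drop = FALSE],
      scrc_groups, config$selection)
    curves <- accuracy_recall_curves(selection)
    v1 <- selection$vote_histogram[, 1]
    top_marker <- rownames(selection$vote_histogram)[
      order(-v1, seq_along(v1))[1]]
    # orient the score by the marker's fitted direction (its summed k=1
    # coefficient across rounds), so AUC reflects the classifier's rule
    direction <- sum(vapply(selection$rounds, function(r)
      r$per_k[[1]]$coefficients[top_marker], numeric(1)))
    orient <- if (direction < 0) -1 else 1
    roc <- roc_auc(orient * rm_$values[c(nonmet_ids, met_ids), top_marker],
                   groups[c(nonmet_ids, met_ids)] == "crc_met")
  }

  counts <- list(
    n_samples = length(cohort),
    n_healthy = length(healthy_ids), n_crc_nonmet = length(nonmet_ids),
    n_crc_met = length(met_ids),
    n_features = ncol(rm_$values),
    n_dropped_samples = length(rm_$dropped),
    n_tested = if (is.null(hvc)) 0L else nrow(hvc),
    immunome_size = length(immunome_features),
    immunome_strict = if (is.null(hvc)) 0L else
      sum(hvc$in_immunome & hvc$p_value < config$p_strict),
    n_met_discriminant = if (is.null(met_diff)) 0L else
      sum(met_diff$discriminant),
    loo_rounds = if (is.null(selection)) 0L else selection$n_rounds)

  summary <- structure(
    list(qc = qc, reactivity = rm_, calls = calls, healthy_vs_crc = hvc,
         immunome_features = immunome_features, met_diff = met_diff,
         selection = selection, curves = curves, roc = roc,
         top_marker = top_marker, counts = counts,
         config_echo = unclass(config), seed = config$seed),
    class = "run_summary")
  if (!is.null(out_dir)) write_run_outputs(summary, out_dir)
  summary
}

write_run_outputs <- function(summary, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(summary$qc$per_array, "qc_per_array.tsv")
  wt(summary$qc$pairwise_r2, "qc_pairwise_r2.tsv")
  wt(data.frame(sample_id = rownames(summary$reactivity$values),
                summary$reactivity$values, check.names = FALSE),
     "reactivity_matrix.tsv")
  wt(summary$reactivity$controls, "control_summary.tsv")
  wt(data.frame(sample_id = rownames(summary$calls$calls),
                summary$calls$calls, check.names = FALSE),
     "positivity_calls.tsv")
  wt(reactivity_percentages(summary$calls), "reactivity_percentages.tsv")
  if (!is.null(summary$healthy_vs_crc))
    wt(report_table3_style(summary$healthy_vs_crc, p_cutoff = 1),
       "healthy_vs_crc.tsv")
  if (!is.null(summary$met_diff))
    wt(report_table3_style(summary$met_diff, p_cutoff = 1), "met_diff.tsv")
  if (!is.null(summary$selection)) {
    wt(summary$curves$summary, "selection_curves.tsv")
    wt(data.frame(feature_id = rownames(summary$selection$vote_histogram),
                  summary$selection$vote_histogram, check.names = FALSE),
       "vote_histogram.tsv")
  }
  invisible(out_dir)
}

#' @export
print.run_summary <- function(x, ...) {
  c_ <- x$counts
  cat("run_summary:", c_$n_samples, "samples (",
      c_$n_healthy, "healthy /", c_$n_crc_nonmet, "non-met /",
      c_$n_crc_met, "met ),", c_$n_features, "TAA features\n")
  cat("  tested:", c_$n_tested, "| immunome:", c_$immunome_size,
      "( p <", x$config_echo$p_strict, ":", c_$immunome_strict,
      ") | met-discriminant:", c_$n_met_discriminant, "\n")
  if (!is.null(x$roc))
    cat(sprintf("  LOO rounds: %d | top k=1 marker: %s (AUC %.3f)\n",
                c_$loo_rounds, x$top_marker, x$roc$auc))
  invisible(x)
}

#' Format a differential table in the reference reporting style
#'
#' Filters to `p_value < p_cutoff` and sorts ascending by p-value, ties
#' broken by feature id, with the columns of the published immunome
#' table: feature, p-value, positives out of group-2 size, mean and
#' median FC, percent of cases with FC > 1.
#'
#' @param table an `immunome_table` (from [compare_groups()] /
#'   [define_immunome()] / [metastasis_differential()]).
#' @param p_cutoff reporting cutoff (default 0.01; use 1 to keep all).
#' @return data frame sorted for reporting.
#' @export
report_table3_style <- function(table, p_cutoff = 0.01) {
  stopifnot(inherits(table, "immunome_table"))
  if (!nrow(table)) stop("report_table3_style: table is empty")
  n2 <- length(attr(table, "group2_ids"))
  out <- data.frame(
    taa_id = table$feature_id,
    p_value = table$p_value,
    n_positive = table$n_pos_group2,
    n_group = n2,
    fc_mean = table$fc_mean,
    fc_median = table$fc_median,
    pct_cases_fc_gt1 = table$pct_cases_fc_gt1,
    stringsAsFactors = FALSE)
  out <- out[out$p_value < p_cutoff, , drop = FALSE]
  out <- out[order(out$p_value, out$taa_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
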