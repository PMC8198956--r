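# Two-step control-spot normalization and the empty-vector 3SD positivity
# rule. Step 1: subtract the first quartile of the nonspot (background)
# intensities, clamping at zero. Step 2: divide by the median of the
# background-corrected empty expression-vector spots. A spot is called
# positive when its normalized ratio exceeds the per-sample
# mean + k*SD of the normalized empty-vector spots (k = 3 by default).

#' Background-correct one array against its nonspot spots
#'
#' Background is estimated as the first quartile of the nonspot
#' intensities (linear-interpolation quantile by default; the estimator is
#' configurable because the convention is not universal). Every spot's
#' corrected value is `max(intensity - q1, 0)`: spots below background are
#' clamped to zero so downstream ratios stay non-negative.
#'
#' @param array an [array_sample()] with at least one nonspot spot.
#' @param quantile_type quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return list with `corrected` (numeric, aligned to `array$spots`) and
#'   `background_q1`.
#' @export
background_correct <- function(array, quantile_type = 7) {
  validate_array_sample(array)
  ns <- array$spots$intensity_532[array$spots$role == "nonspot"]
  if (!length(ns))
    stop("background_correct: array '", array$sample_id,
         "' has no nonspot spots")
  q1 <- unname(quantile(ns, 0.25, type = quantile_type))
  list(corrected = pmax(array$spots$intensity_532 - q1, 0),
       background_q1 = q1)
}

#' Normalize corrected values to the empty-vector median
#'
#' Each background-corrected value is divided by the median of the
#' corrected empty-vector spots of the same array, making the normalized
#' empty-vector median exactly 1 and cancelling any per-array
#' multiplicative scale. The control summary records the divisor and the
#' mean/SD of the normalized empty-vector values that the positivity
#' threshold is built from.
#'
#' @param corrected numeric vector from [background_correct()].
#' @param roles character vector of spot roles aligned to `corrected`.
#' @param sample_id used in error messages.
#' @return list with `ratios` and `control_summary`
#'   (`empty_vector_median`, `empty_vector_norm_mean`,
#'   `empty_vector_norm_sd`).
#' @export
normalize_to_empty_vector <- function(corrected, roles,
                                      sample_id = "<unnamed>") {
  ev <- corrected[roles == "empty_vector"]
  if (!length(ev))
    stop("normalize_to_empty_vector: sample '", sample_id,
         "' has no empty_vector spots")
  med <- median(ev)
  if (med <= 0)
    stop("normalize_to_empty_vector: degenerate control in sample '",
         sample_id, "': empty-vector median is ", med)
  ratios <- corrected / med
  ev_norm <- ratios[roles == "empty_vector"]
  list(ratios = ratios,
       control_summary = list(
         empty_vector_median = med,
         empty_vector_norm_mean = mean(ev_norm),
         empty_vector_norm_sd = if (length(ev_norm) > 1) sd(ev_norm) else 0))
}

#' Build the samples-by-TAA reactivity matrix for a cohort
#'
#' Applies [background_correct()] and [normalize_to_empty_vector()] to
#' every array and assembles the normalized ratios of the TAA features
#' into one matrix (controls are summarized, not kept as columns). For
#' layouts that print a feature more than once per array, replicate spots
#' are averaged after normalization. Samples with a degenerate
#' empty-vector control are reported together by ID; with
#' `drop_degenerate = TRUE` they are excluded instead.
#'
#' @param cohort named list of [array_sample()] sharing one layout.
#' @param quantile_type passed to [background_correct()].
#' @param drop_degenerate drop unusable samples instead of failing.
#' @return object of class `reactivity_matrix`: list with `values`
#'   (samples x features matrix), `controls` (per-sample data frame),
#'   `groups` (named character).
#' @export
build_reactivity_matrix <- function(cohort, quantile_type = 7,
                                    drop_degenerate = FALSE) {
  if (!length(cohort)) stop("build_reactivity_matrix: cohort is empty")
  check_shared_layout(cohort)
  taa_mask <- cohort[[1L]]$spots$role == "taa"
  taa_ids <- unique(cohort[[1L]]$spots$feature_id[taa_mask])
  rows <- list(); controls <- list(); degenerate <- character()
  for (a in cohort) {
    bc <- background_correct(a, quantile_type)
    nm <- tryCatch(
      normalize_to_empty_vector(bc$corrected, a$spots$role, a$sample_id),
      error = function(e) e)
    if (inherits(nm, "error")) {
      degenerate <- c(degenerate, a$sample_id)
      next
    }
    taa_vals <- tapply(nm$ratios[taa_mask],
                       factor(a$spots$feature_id[taa_mask], levels = taa_ids),
                       mean)
    rows[[a$sample_id]] <- as.numeric(taa_vals)
    controls[[a$sample_id]] <- data.frame(
      sample_id = a$sample_id,
      background_q1 = bc$background_q1,
      empty_vector_median = nm$control_summary$empty_vector_median,
      empty_vector_norm_mean = nm$control_summary$empty_vector_norm_mean,
      empty_vector_norm_sd = nm$control_summary$empty_vector_norm_sd,
      stringsAsFactors = FALSE)
  }
  if (length(degenerate) && !drop_degenerate)
    stop("build_reactivity_matrix: degenerate empty-vector controls in ",
         length(degenerate), " sample(s): ",
         paste(degenerate, collapse = ", "),
         " (use drop_degenerate = TRUE to exclude them)")
  if (!length(rows))
    stop("build_reactivity_matrix: no usable samples")
  values <- do.call(rbind, rows)
  dimnames(values) <- list(names(rows), taa_ids)
  ctrl <- do.call(rbind, controls)
  rownames(ctrl) <- NULL
  groups <- cohort_groups(cohort)[names(rows)]
  structure(list(values = values, controls = ctrl, groups = groups,
                 dropped = degenerate),
            class = "reactivity_matrix")
}

#' @export
print.reactivity_matrix <- function(x, ...) {
  cat("reactivity_matrix:", nrow(x$values), "samples x",
      ncol(x$values), "TAA features\n")
  if (!all(is.na(x$groups)))
    print(table(x$groups))
  invisible(x)
}

#' Call seropositive reactivities against the empty-vector threshold
#'
#' A feature is positive in a sample when its normalized value is strictly
#' greater than that sample's `empty_vector_norm_mean +
#' sd_multiplier * empty_vector_norm_sd`. The threshold is per sample,
#' built from the sample's own normalized empty-vector spots, so residual
#' array effects are absorbed.
#'
#' @param matrix a [build_reactivity_matrix()] result.
#' @param sd_multiplier number of empty-vector SDs above the mean
#'   (default 3).
#' @return object of class `positivity_matrix`: list with `calls`
#'   (logical samples x features), `thresholds` (named numeric),
#'   `sd_multiplier`.
#' @export
call_positives <- function(matrix, sd_multiplier = 3) {
  stopifnot(inherits(matrix, "reactivity_matrix"))
  ctrl <- matrix$controls
  thresholds <- setNames(
    ctrl$empty_vector_norm_mean + sd_multiplier * ctrl$empty_vector_norm_sd,
    ctrl$sample_id)[rownames(matrix$values)]
  calls <- sweep(matrix$values, 1, thresholds, `>`)
  structure(list(calls = calls, thresholds = thresholds,
                 sd_multiplier = sd_multiplier),
            class = "positivity_matrix")
}

#' Per-sample positive counts and percentages
#'
#' @param calls a [call_positives()] result.
#' @return data frame with `sample_id`, `n_positive`, `pct_raw`
#'   (exact percentage of the feature universe) and `pct` (round-half-up
#'   integer percent, the reporting convention of the reference tables).
#' @export
reactivity_percentages <- function(calls) {
  stopifnot(inherits(calls, "positivity_matrix"))
  n <- rowSums(calls$calls)
  data.frame(sample_id = rownames(calls$calls),
             n_positive = as.integer(n),
             pct_raw = 100 * n / ncol(calls$calls),
             pct = round_half_up(100 * n / ncol(calls$calls)),
             row.names = NULL, stringsAsFactors = FALSE)
}
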