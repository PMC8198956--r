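# Differential reactivity statistics and the four-criterion immunome:
# (i) Mann-Whitney p < 0.05 on normalized values, (ii) no positive call in
# any healthy donor, (iii) positive in >= 2 sCRC samples, (iv) mean
# per-case fold change above 1, with FC = log2(value / group1 median + 1).

#' Two-sided Mann-Whitney (rank-sum) p-value
#'
#' Thin, explicit wrapper around [stats::wilcox.test()]: exact enumeration
#' when both groups have at most 8 observations and there are no ties,
#' otherwise the tie-corrected normal approximation with continuity
#' correction. No multiple-testing correction is applied anywhere in the
#' package, so reports record the number of tests performed.
#'
#' @param x,y numeric samples of the two groups (both non-empty).
#' @return two-sided p-value.
#' @export
mann_whitney_p <- function(x, y) {
  if (!length(x) || !length(y))
    stop("mann_whitney_p: both groups must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)  # no variation, no evidence
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wilcox.test(x, y, alternative = "two.sided", exact = exact,
              correct = TRUE)$p.value
}

#' Per-case fold change against the reference-group median
#'
#' `FC = log2(case_value / group1_median + 1)`, so FC equals 1 exactly
#' when the case sits at the reference median and 0 when the case value is
#' 0. When the reference median is not positive (feature at background in
#' every reference sample), the divisor falls back to 1, the empty-vector
#' reference level of the normalized scale, keeping FC finite and
#' interpretable as signal over control.
#'
#' @param case_value non-negative normalized value(s) of group-2 cases.
#' @param group1_median median normalized value of the reference group.
#' @return fold change(s), same length as `case_value`.
#' @export
fold_change <- function(case_value, group1_median) {
  if (any(case_value < 0))
    stop("fold_change: case_value must be non-negative")
  divisor <- if (group1_median > 0) group1_median else 1
  log2(case_value / divisor + 1)
}

#' Differential reactivity statistics between two sample groups
#'
#' For every feature with a positive call in at least one sample of the
#' two groups (the testing universe), computes the two-sided Mann-Whitney
#' p-value on normalized values, positive-call counts per group, the
#' per-case fold change of every group-2 sample against the group-1
#' median, and the mean/median FC and percent of group-2 cases with
#' FC > 1.
#'
#' @param matrix a [build_reactivity_matrix()] result.
#' @param calls the matching [call_positives()] result.
#' @param group1_ids,group2_ids disjoint, non-empty sample ID sets present
#'   in the matrix (group 1 is the reference for fold changes).
#' @param label comparison label, e.g. `"healthy_vs_crc"`.
#' @param features optional explicit feature universe (still intersected
#'   with the positivity gate); default all matrix features.
#' @return data frame of class `immunome_table`, one row per tested
#'   feature, with attributes `label`, `group1_ids`, `group2_ids`,
#'   `n_tests`. Column `fc_per_case` is a list column aligned to
#'   `group2_ids`.
#' @export
compare_groups <- function(matrix, calls, group1_ids, group2_ids,
                           label = "comparison", features = NULL) {
  stopifnot(inherits(matrix, "reactivity_matrix"),
            inherits(calls, "positivity_matrix"))
  if (!length(group1_ids) || !length(group2_ids))
    stop("compare_groups: both groups must be non-empty")
  if (length(intersect(group1_ids, group2_ids)))
    stop("compare_groups: groups overlap")
  unknown <- setdiff(c(group1_ids, group2_ids), rownames(matrix$values))
  if (length(unknown))
    stop("compare_groups: unknown sample ID(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(features)) features <- colnames(matrix$values)
  unknown_f <- setdiff(features, colnames(matrix$values))
  if (length(unknown_f))
    stop("compare_groups: unknown feature(s): ",
         paste(unknown_f, collapse = ", "))
  union_ids <- c(group1_ids, group2_ids)
  tested <- features[colSums(calls$calls[union_ids, features, drop = FALSE]) > 0]
  rows <- lapply(tested, function(f) {
    v1 <- matrix$values[group1_ids, f]
    v2 <- matrix$values[group2_ids, f]
    fc <- fold_change(v2, median(v1))
    data.frame(
      feature_id = f,
      p_value = mann_whitney_p(v1, v2),
      n_pos_group1 = sum(calls$calls[group1_ids, f]),
      n_pos_group2 = sum(calls$calls[group2_ids, f]),
      fc_mean = mean(fc),
      fc_median = median(fc),
      pct_cases_fc_gt1 = 100 * mean(fc > 1),
      stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(), p_value = numeric(),
               n_pos_group1 = integer(), n_pos_group2 = integer(),
               fc_mean = numeric(), fc_median = numeric(),
               pct_cases_fc_gt1 = numeric(), stringsAsFactors = FALSE)
  tab$fc_per_case <- lapply(tested, function(f)
    setNames(fold_change(matrix$values[group2_ids, f],
                         median(matrix$values[group1_ids, f])), group2_ids))
  structure(tab, label = label, group1_ids = group1_ids,
            group2_ids = group2_ids, n_tests = nrow(tab),
            class = c("immunome_table", "data.frame"))
}

#' Apply the four immunome criteria to a healthy-vs-sCRC comparison
#'
#' Flags, per feature: (i) p < `p_cutoff`; (ii) zero positive calls among
#' the healthy (group 1) samples; (iii) at least `min_group2_positives`
#' positive sCRC samples; (iv) mean per-case fold change above `fc_gate`.
#' `in_immunome` is the conjunction of the four.
#'
#' @param table a [compare_groups()] result with healthy donors as group 1
#'   and sCRC patients as group 2.
#' @param p_cutoff significance cutoff (default 0.05).
#' @param min_group2_positives minimum positive sCRC samples (default 2).
#' @param fc_gate mean-FC gate (default 1).
#' @return the table with logical columns `crit_i` .. `crit_iv` and
#'   `in_immunome` added.
#' @export
define_immunome <- function(table, p_cutoff = 0.05,
                            min_group2_positives = 2, fc_gate = 1) {
  stopifnot(inherits(table, "immunome_table"))
  table$crit_i <- table$p_value < p_cutoff
  table$crit_ii <- table$n_pos_group1 == 0
  table$crit_iii <- table$n_pos_group2 >= min_group2_positives
  table$crit_iv <- table$fc_mean > fc_gate
  table$in_immunome <-
    table$crit_i & table$crit_ii & table$crit_iii & table$crit_iv
  table
}

#' Metastasis differential on the immunome feature set
#'
#' Re-runs the group comparison with non-metastatic sCRC as group 1 and
#' metastatic sCRC as group 2, restricted to the previously defined
#' immunome features; features with p below `p_cutoff` are flagged as
#' discriminant candidates.
#'
#' @param matrix,calls as in [compare_groups()].
#' @param immunome_features non-empty character vector of feature ids.
#' @param nonmet_ids,met_ids sample ID sets of the two sCRC subgroups.
#' @param p_cutoff significance cutoff (default 0.05).
#' @return an `immunome_table` with a logical `discriminant` column.
#' @export
metastasis_differential <- function(matrix, calls, immunome_features,
                                    nonmet_ids, met_ids, p_cutoff = 0.05) {
  if (!length(immunome_features))
    stop("metastasis_differential: immunome feature set is empty")
  tab <- compare_groups(matrix, calls, nonmet_ids, met_ids,
                        label = "nonmet_vs_met",
                        features = immunome_features)
  tab$discriminant <- tab$p_value < p_cutoff
  tab
}
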