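# Array-level quality metrics: inter-array reproducibility, replicate
# variation, and the expressed-spot fraction against the nonspot-based
# threshold. QC is reported, never enforced: arrays failing the
# customary gates (R^2 > 0.85, CV < 5%) are flagged, not dropped.

#' Squared Pearson correlation of raw intensities between two arrays
#'
#' @param a,b two [array_sample()] objects with identical feature layouts.
#' @return squared Pearson correlation over matched spots.
#' @export
interarray_r2 <- function(a, b) {
  validate_array_sample(a); validate_array_sample(b)
  if (!identical(a$spots[c("block", "row", "column", "feature_id", "role")],
                 b$spots[c("block", "row", "column", "feature_id", "role")]))
    stop("interarray_r2: arrays '", a$sample_id, "' and '", b$sample_id,
         "' do not share a feature layout")
  x <- a$spots$intensity_532
  y <- b$spots$intensity_532
  if (sd(x) == 0 || sd(y) == 0)
    stop("interarray_r2: zero intensity variance in array '",
         if (sd(x) == 0) a$sample_id else b$sample_id,
         "'; correlation undefined")
  cor(x, y)^2
}

#' Coefficient of variation of replicate measurements, in percent
#'
#' `100 * sd(values) / mean(values)` with the sample (n-1) standard
#' deviation; scale-invariant by construction.
#'
#' @param values at least two strictly positive replicate values.
#' @return CV in percent.
#' @export
replicate_cv <- function(values) {
  if (length(values) < 2)
    stop("replicate_cv: need at least 2 values")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("replicate_cv: values must be finite and > 0")
  100 * sd(values) / mean(values)
}

#' Fraction of TAA spots expressed above the nonspot threshold
#'
#' The expression threshold is `median(nonspot) + 2 * sd(nonspot)` over
#' the array's nonspot (negative-control) intensities, with the sample
#' (n-1) standard deviation; the fraction counts TAA spots strictly above
#' it.
#'
#' @param array an [array_sample()] with at least two nonspot spots.
#' @return list with `fraction` and `threshold`.
#' @export
expressed_fraction <- function(array) {
  validate_array_sample(array)
  ns <- array$spots$intensity_532[array$spots$role == "nonspot"]
  if (length(ns) < 2)
    stop("expressed_fraction: array '", array$sample_id,
         "' has fewer than 2 nonspot spots")
  threshold <- median(ns) + 2 * sd(ns)
  taa <- array$spots$intensity_532[array$spots$role == "taa"]
  list(fraction = mean(taa > threshold), threshold = threshold)
}

#' Cohort-level quality-control report
#'
#' All pairwise inter-array squared correlations of raw intensities, the
#' per-array expressed fraction and nonspot-based threshold, and flags
#' against the customary platform gates. Flags are informational; no
#' array is excluded.
#'
#' @param cohort named list of [array_sample()] sharing one layout.
#' @param r2_gate,expressed_gate reporting gates (defaults 0.85 and 0.92).
#' @return list of class `qc_report` with `pairwise_r2` (data frame),
#'   `per_array` (data frame) and the gates used.
#' @export
qc_report <- function(cohort, r2_gate = 0.85, expressed_gate = 0.92) {
  check_shared_layout(cohort)
  ids <- names(cohort)
  pairs <- if (length(cohort) >= 2) t(combn(length(cohort), 2)) else
    matrix(integer(), 0, 2)
  pairwise <- data.frame(
    array_a = ids[pairs[, 1]],
    array_b = ids[pairs[, 2]],
    r_squared = apply(pairs, 1, function(p)
      interarray_r2(cohort[[p[1]]], cohort[[p[2]]])),
    stringsAsFactors = FALSE
  )
  pairwise$passes_gate <- pairwise$r_squared > r2_gate
  per_array <- do.call(rbind, lapply(cohort, function(a) {
    ef <- expressed_fraction(a)
    data.frame(sample_id = a$sample_id, group = a$group,
               expressed_fraction = ef$fraction,
               expression_threshold = ef$threshold,
               passes_gate = ef$fraction > expressed_gate,
               stringsAsFactors = FALSE)
  }))
  rownames(per_array) <- NULL
  structure(list(pairwise_r2 = pairwise, per_array = per_array,
                 r2_gate = r2_gate, expressed_gate = expressed_gate),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", nrow(x$per_array), "arrays\n")
  if (nrow(x$pairwise_r2))
    cat(sprintf("  pairwise R^2: median %.3f, %d/%d pairs > %.2f\n",
                median(x$pairwise_r2$r_squared),
                sum(x$pairwise_r2$passes_gate), nrow(x$pairwise_r2),
                x$r2_gate))
  cat(sprintf("  expressed fraction: median %.3f, %d/%d arrays > %.2f\n",
              median(x$per_array$expressed_fraction),
              sum(x$per_array$passes_gate), nrow(x$per_array),
              x$expressed_gate))
  invisible(x)
}
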