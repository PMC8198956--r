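# Panel evaluation: ROC curves with a dual-route AUC (trapezoid over the
# threshold sweep and the tie-corrected rank statistic, required to agree
# to 1e-12), standardized panel scores, and Ward hierarchical clustering.

#' ROC curve and AUC for a score against binary labels
#'
#' Sweeps a threshold over the unique scores (classifying `score >=
#' threshold` as positive) and computes the AUC twice: by trapezoid over
#' the resulting (FPR, TPR) points, and as the tie-corrected rank
#' statistic `(sum of positive ranks - n1(n1+1)/2) / (n1 n0)`. The two
#' routes must agree to 1e-12 (internal consistency check); ties
#' contribute half a concordance.
#'
#' @param scores numeric per-sample scores (higher = more positive-like).
#' @param labels logical, or anything coercible via `labels ==
#'   positive_label`.
#' @param positive_label value of `labels` treated as positive (ignored
#'   when `labels` is logical).
#' @return object of class `roc_result`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `positive_label`.
#' @export
roc_auc <- function(scores, labels, positive_label = NULL) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- if (is.logical(labels)) labels else {
    if (is.null(positive_label))
      stop("roc_auc: positive_label required for non-logical labels")
    labels == positive_label
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("roc_auc: both label classes must be present; ROC is undefined")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(scores[!pos] >= t), numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  r <- rank(scores)  # midranks give ties half credit
  auc_rank <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (abs(auc_trap - auc_rank) > 1e-12)
    stop("roc_auc: internal AUC routes disagree (",
         auc_trap, " vs ", auc_rank, ")")
  structure(list(thresholds = c(Inf, thresholds), tpr = tpr, fpr = fpr,
                 auc = auc_rank, positive_label = positive_label),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f over %d thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Combined score of a marker panel
#'
#' Standardizes each panel feature over the scored samples (zero mean,
#' unit sample SD; constant features contribute zero) and returns the
#' weighted sum, equal weights by default. Feeds [roc_auc()].
#'
#' @param matrix a [build_reactivity_matrix()] result, or a plain
#'   samples x features matrix.
#' @param features feature ids of the panel (must exist in the matrix).
#' @param weights optional numeric weights aligned to `features`.
#' @return named numeric vector of per-sample scores.
#' @export
panel_score <- function(matrix, features, weights = NULL) {
  values <- if (inherits(matrix, "reactivity_matrix")) matrix$values else
    as.matrix(matrix)
  unknown <- setdiff(features, colnames(values))
  if (length(unknown))
    stop("panel_score: unknown feature(s): ", paste(unknown, collapse = ", "))
  if (is.null(weights)) weights <- rep(1, length(features))
  stopifnot(length(weights) == length(features))
  Z <- vapply(features, function(f) {
    v <- values[, f]
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }, numeric(nrow(values)))
  setNames(as.numeric(Z %*% weights), rownames(values))
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering with Ward linkage (`ward.D2`) on Euclidean
#' distances over normalized reactivities; deterministic given input
#' order.
#'
#' @param matrix a [build_reactivity_matrix()] result or plain matrix
#'   (samples in rows).
#' @param n_clusters number of clusters, at most the number of samples.
#' @return list with `assignments` (named integer vector) and `tree`
#'   (the [stats::hclust()] merge tree).
#' @export
ward_clusters <- function(matrix, n_clusters) {
  values <- if (inherits(matrix, "reactivity_matrix")) matrix$values else
    as.matrix(matrix)
  if (n_clusters > nrow(values))
    stop("ward_clusters: n_clusters (", n_clusters,
         ") exceeds the number of samples (", nrow(values), ")")
  tree <- hclust(dist(values), method = "ward.D2")
  list(assignments = cutree(tree, k = n_clusters), tree = tree)
}
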