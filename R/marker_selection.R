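# Balanced leave-one-out LASSO marker voting. The model is an L1-penalized
# LEAST-SQUARES regression on +/-1 group labels with sign classification
# (a separating hyperplane fitted by constrained least squares), not
# penalized logistic regression; a logistic variant is available behind
# `family = "logistic"` for sensitivity analysis. Each round holds out one
# metastatic sample, trains on the remaining metastatic samples plus an
# equal-size random draw of non-metastatic samples, and validates on the
# held-out metastatic sample plus every non-metastatic sample not drawn
# for training. Features chosen per round are tallied into a cross-round
# vote histogram.

soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

# Internal standardization: center always (for the unpenalized intercept);
# scale by the population (1/n) standard deviation when standardize = TRUE.
standardize_design <- function(X, standardize) {
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm, `-`)
  xs <- if (standardize) sqrt(colMeans(Xc^2)) else rep(1, ncol(X))
  xs[xs == 0] <- 1  # constant columns stay at coefficient zero
  list(X = sweep(Xc, 2, xs, `/`), center = xm, scale = xs)
}

#' Smallest penalty that zeroes every coefficient
#'
#' `lambda_max = max_j |(1/n) x_j' (y - mean(y))|` over (standardized)
#' feature columns: at or above it, every coordinate-descent update is
#' soft-thresholded to zero.
#'
#' @param X samples x features numeric matrix.
#' @param y numeric response (+1/-1 labels).
#' @param standardize match the standardization of the fit.
#' @return the critical penalty value.
#' @export
lasso_lambda_max <- function(X, y, standardize = TRUE) {
  sd_ <- standardize_design(X, standardize)
  max(abs(colMeans(sd_$X * (y - mean(y)))))
}

#' L1-penalized least-squares fit by coordinate descent
#'
#' Minimizes `1/(2n) * sum((y - b0 - X b)^2) + lambda * sum(|b|)` with an
#' unpenalized intercept, by cyclic coordinate descent with residual
#' updates, iterated until the largest coefficient change falls below
#' `tol`. With `standardize = TRUE` the penalty applies on the
#' unit-variance scale of the training columns; returned coefficients are
#' always on the original scale. `family = "logistic"` replaces the
#' squared error by the penalized logistic log-likelihood (labels +1/-1),
#' fitted by iteratively reweighted coordinate descent.
#'
#' @param X samples x features numeric matrix (finite).
#' @param y numeric response; for classification, +1/-1 labels with both
#'   classes present.
#' @param lambda non-negative penalty.
#' @param standardize standardize columns before penalization
#'   (default TRUE).
#' @param family `"gaussian"` (default) or `"logistic"`.
#' @param tol convergence tolerance on coefficient changes.
#' @param max_iter cap on coordinate-descent sweeps.
#' @param init optional warm-start coefficient vector (standardized
#'   scale, internal use).
#' @return list with `coefficients` (named, original scale), `intercept`,
#'   `lambda`, and `std_coef` (standardized scale, for warm starts).
#' @export
lasso_fit <- function(X, y, lambda, standardize = TRUE,
                      family = c("gaussian", "logistic"),
                      tol = 1e-9, max_iter = 100000L, init = NULL) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("lasso_fit: X and y must be finite")
  if (length(unique(y)) < 2)
    stop("lasso_fit: constant label/response vector; fit is degenerate")
  if (lambda < 0) stop("lasso_fit: lambda must be non-negative")
  n <- nrow(X); p <- ncol(X)
  sd_ <- standardize_design(X, standardize)
  Xs <- sd_$X
  v <- colMeans(Xs^2)
  b <- if (is.null(init)) numeric(p) else init

  if (family == "gaussian") {
    ym <- mean(y)
    r <- (y - ym) - Xs %*% b
    for (iter in seq_len(max_iter)) {
      delta <- 0
      for (j in seq_len(p)) {
        if (v[j] == 0) next
        old <- b[j]
        z <- mean(Xs[, j] * r) + v[j] * old
        new <- soft_threshold(z, lambda) / v[j]
        if (new != old) {
          r <- r - (new - old) * Xs[, j]
          b[j] <- new
          delta <- max(delta, abs(new - old))
        }
      }
      if (delta < tol) break
    }
    b0s <- ym
  } else {
    # outer IRLS on the logistic loss, inner weighted coordinate descent
    b0s <- 0
    for (outer in seq_len(50L)) {
      eta <- as.numeric(b0s + Xs %*% b)
      prob <- 1 / (1 + exp(-eta))            # P(y = +1)
      w <- pmax(prob * (1 - prob), 1e-5)
      z <- eta + ((y + 1) / 2 - prob) / w    # working response
      b_old <- b; b0_old <- b0s
      for (inner in seq_len(1000L)) {
        delta <- 0
        r <- z - b0s - Xs %*% b
        b0_new <- b0s + mean(w * r) / mean(w)
        delta <- max(delta, abs(b0_new - b0s))
        r <- r - (b0_new - b0s); b0s <- b0_new
        for (j in seq_len(p)) {
          vj <- mean(w * Xs[, j]^2)
          if (vj == 0) next
          old <- b[j]
          zj <- mean(w * Xs[, j] * r) + vj * old
          new <- soft_threshold(zj, lambda) / vj
          if (new != old) {
            r <- r - (new - old) * Xs[, j]
            b[j] <- new
            delta <- max(delta, abs(new - old))
          }
        }
        if (delta < 1e-7) break
      }
      if (max(abs(c(b - b_old, b0s - b0_old))) < 1e-7) break
    }
  }
  beta <- b / sd_$scale
  intercept <- b0s - sum(beta * sd_$center)
  names(beta) <- colnames(X)
  list(coefficients = beta, intercept = intercept, lambda = lambda,
       std_coef = b)
}

#' Predict with a LASSO fit; sign classifies
#'
#' @param fit a [lasso_fit()] or [select_k_features()] result.
#' @param X samples x features matrix with the training columns.
#' @return numeric predictions `intercept + X b`; a strictly positive
#'   prediction classifies as the +1 class, zero or below as -1.
#' @export
lasso_predict <- function(fit, X) {
  as.numeric(fit$intercept + as.matrix(X) %*% fit$coefficients)
}

#' Configuration for marker selection
#'
#' @param k_values target active-set sizes (default 1:3, mirroring tuning
#'   for three, two or one protein).
#' @param standardize standardize training columns (default TRUE).
#' @param rng_seed seed for the per-round non-metastatic draws.
#' @param n_lambda geometric penalty-path length (default 100).
#' @param lambda_min_ratio smallest path penalty as a fraction of
#'   `lambda_max` (default 1e-3).
#' @param family passed to [lasso_fit()].
#' @return a `selection_config` list.
#' @export
selection_config <- function(k_values = 1:3, standardize = TRUE,
                             rng_seed = 1L, n_lambda = 100L,
                             lambda_min_ratio = 1e-3,
                             family = "gaussian") {
  stopifnot(all(k_values >= 1), n_lambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(k_values = as.integer(k_values), standardize = standardize,
                 rng_seed = as.integer(rng_seed),
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio, family = family),
            class = "selection_config")
}

#' Select (about) k features by walking the penalty path
#'
#' Walks a geometric penalty path from `lambda_max` downward with warm
#' starts and returns the fit at the largest penalty whose active set
#' reaches size `k`. When the active set overshoots `k`, the coefficients
#' are truncated to the `k` of largest magnitude, ties broken
#' deterministically by feature order. If the path never reaches `k`
#' active features the largest achievable fit is returned with
#' `reached_k = FALSE`.
#'
#' @param X samples x features matrix; column names are the feature ids.
#' @param y +1/-1 labels.
#' @param k target active-set size, `1 <= k <= ncol(X)`.
#' @param config a [selection_config()].
#' @return list with `active` (feature ids), `coefficients`, `intercept`,
#'   `lambda`, `achieved_k`, `reached_k`.
#' @export
select_k_features <- function(X, y, k, config = selection_config()) {
  X <- as.matrix(X)
  stopifnot(k >= 1, k <= ncol(X))
  lmax <- lasso_lambda_max(X, y, config$standardize)
  if (lmax == 0)
    stop("select_k_features: response is uncorrelated with every feature")
  lambdas <- lmax * exp(seq(0, log(config$lambda_min_ratio),
                            length.out = config$n_lambda))
  warm <- NULL
  best <- NULL
  for (lam in lambdas) {
    fit <- lasso_fit(X, y, lam, standardize = config$standardize,
                     family = config$family, init = warm)
    warm <- fit$std_coef
    nnz <- sum(fit$coefficients != 0)
    best <- fit
    if (nnz >= k) break
  }
  coef <- best$coefficients
  active_idx <- which(coef != 0)
  if (length(active_idx) > k) {
    keep <- order(-abs(coef), seq_along(coef))[seq_len(k)]
    coef[setdiff(seq_along(coef), keep)] <- 0
    active_idx <- sort(keep)
  }
  list(active = colnames(X)[active_idx],
       coefficients = coef,
       intercept = best$intercept,
       lambda = best$lambda,
       achieved_k = length(active_idx),
       reached_k = length(active_idx) == k)
}

#' Balanced leave-one-out LASSO voting over metastatic samples
#'
#' One round per metastatic sample M: training uses all other metastatic
#' samples plus an equal-size uniform random draw (without replacement,
#' seeded) of non-metastatic samples; validation uses M plus every
#' non-metastatic sample not drawn for training (training and validation
#' are disjoint by construction). Per round and per target size k,
#' [select_k_features()] picks the markers, the sign of the linear
#' prediction classifies, and accuracy (correct/total on validation) and
#' recall (1 if M is classified metastatic, else 0) are recorded. All
#' random draws happen up front from `config$rng_seed`, so adding k
#' values does not perturb the sampling.
#'
#' @param X samples x features matrix of normalized reactivities,
#'   restricted to the selection universe; rownames are sample ids.
#' @param groups named character vector (`crc_nonmet` / `crc_met`) for
#'   every row of `X`.
#' @param config a [selection_config()].
#' @return object of class `selection_report`: list with `rounds`,
#'   `k_values`, `vote_histogram` (features x k matrix of round counts),
#'   `n_rounds`.
#' @export
balanced_loocv <- function(X, groups, config = selection_config()) {
  X <- as.matrix(X)
  stopifnot(!is.null(rownames(X)), !is.null(colnames(X)),
            all(names(groups) %in% rownames(X)))
  met_ids <- names(groups)[groups == "crc_met"]
  nonmet_ids <- names(groups)[groups == "crc_nonmet"]
  n_met <- length(met_ids)
  if (n_met < 2)
    stop("balanced_loocv: need at least 2 metastatic samples")
  if (length(nonmet_ids) <= n_met - 1)
    stop("balanced_loocv: need more than ", n_met - 1,
         " non-metastatic samples")
  set.seed(config$rng_seed)
  draws <- lapply(met_ids, function(m) sample(nonmet_ids, n_met - 1))

  y_all <- setNames(ifelse(groups == "crc_met", 1, -1), names(groups))
  votes <- matrix(0L, ncol(X), length(config$k_values),
                  dimnames = list(colnames(X), paste0("k", config$k_values)))
  rounds <- vector("list", n_met)
  for (i in seq_len(n_met)) {
    m <- met_ids[i]
    train_ids <- c(setdiff(met_ids, m), draws[[i]])
    validation_ids <- c(m, setdiff(nonmet_ids, draws[[i]]))
    stopifnot(length(intersect(train_ids, validation_ids)) == 0)
    per_k <- lapply(config$k_values, function(k) {
      sel <- select_k_features(X[train_ids, , drop = FALSE],
                               y_all[train_ids], k, config)
      pred <- lasso_predict(sel, X[validation_ids, , drop = FALSE])
      predicted_met <- pred > 0  # exact zero classifies non-metastatic
      truth_met <- y_all[validation_ids] > 0
      list(active = sel$active, coefficients = sel$coefficients,
           lambda = sel$lambda, reached_k = sel$reached_k,
           accuracy = mean(predicted_met == truth_met),
           recall = as.numeric(predicted_met[1]))
    })
    names(per_k) <- paste0("k", config$k_values)
    for (ki in seq_along(config$k_values))
      votes[per_k[[ki]]$active, ki] <- votes[per_k[[ki]]$active, ki] + 1L
    rounds[[i]] <- list(round_index = i, held_out_met = m,
                        train_ids = train_ids,
                        validation_ids = validation_ids, per_k = per_k)
  }
  structure(list(rounds = rounds, k_values = config$k_values,
                 vote_histogram = votes, n_rounds = n_met),
            class = "selection_report")
}

#' Accuracy and recall curves versus number of selected markers
#'
#' @param report a [balanced_loocv()] result with at least one round.
#' @return list with `summary` (data frame: k, mean_accuracy,
#'   mean_recall) and `per_round` (data frame of per-round values).
#' @export
accuracy_recall_curves <- function(report) {
  stopifnot(inherits(report, "selection_report"), report$n_rounds >= 1)
  per_round <- do.call(rbind, lapply(report$rounds, function(r)
    do.call(rbind, lapply(seq_along(report$k_values), function(ki)
      data.frame(round_index = r$round_index,
                 held_out_met = r$held_out_met,
                 k = report$k_values[ki],
                 accuracy = r$per_k[[ki]]$accuracy,
                 recall = r$per_k[[ki]]$recall,
                 stringsAsFactors = FALSE)))))
  rownames(per_round) <- NULL
  summary <- do.call(rbind, lapply(split(per_round, per_round$k), function(d)
    data.frame(k = d$k[1], mean_accuracy = mean(d$accuracy),
               mean_recall = mean(d$recall))))
  summary <- summary[order(summary$k), ]
  rownames(summary) <- NULL
  list(summary = summary, per_round = per_round)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report:", x$n_rounds, "balanced leave-one-out rounds, k =",
      paste(x$k_values, collapse = ", "), "\n")
  cur <- accuracy_recall_curves(x)$summary
  print(cur, row.names = FALSE)
  top <- x$vote_histogram[, 1]
  top <- sort(top[top > 0], decreasing = TRUE)
  if (length(top))
    cat("  top k=1 votes:", paste(sprintf("%s (%d)", names(top)[seq_len(min(3, length(top)))],
                                          top[seq_len(min(3, length(top)))]),
                                  collapse = ", "), "\n")
  invisible(x)
}
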