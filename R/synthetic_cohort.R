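# Synthetic cohorts with the statistical structure the analysis assumes:
# lognormal right-skewed intensities, sparse group-dependent seroreactivity,
# planted differential TAAs and per-array multiplicative scale jitter.

#' Configuration for the synthetic-cohort generator
#'
#' The defaults mirror the reference screening study: 7 healthy donors,
#' 38 non-metastatic and 12 metastatic sCRC patients, 2023 TAA features,
#' and 50 each of the two control classes. Intensities follow a lognormal
#' model (array fluorescence is right-skewed and strictly positive);
#' `reactive_fold` is the raw-scale multiplicative signal of a seropositive
#' spot, and `array_scale_sd` the log-scale spread of a per-array
#' multiplicative factor that the empty-vector normalization is designed to
#' cancel. Seroreactivity is Bernoulli(`background_prevalence`) everywhere,
#' overridden by Bernoulli(`planted_crc_prevalence`) for `planted_crc_taa`
#' in sCRC samples and by Bernoulli(`planted_met_prevalence`) for
#' `planted_met_taa` in metastatic samples; planted TAAs are forced
#' non-reactive in healthy samples.
#'
#' @param n_healthy,n_crc_nonmet,n_crc_met group sizes.
#' @param n_taa number of TAA features.
#' @param n_empty_vector,n_nonspot number of control spots of each class.
#' @param n_positive_control number of constant high-intensity QC spots.
#' @param baseline_log_mean,baseline_log_sd log-scale location and spread
#'   of the non-reactive intensity distribution.
#' @param nonspot_attenuation multiplicative attenuation (0,1] of nonspot
#'   positions relative to printed spots.
#' @param array_scale_sd log-scale SD of the per-array scale factor.
#' @param reactive_fold raw-scale fold of a seropositive spot (> 0).
#' @param background_prevalence probability any TAA is seroreactive in any
#'   sample.
#' @param planted_crc_taa,planted_met_taa character vectors of planted
#'   feature ids (subsets of the TAA universe; they may overlap).
#' @param planted_crc_prevalence,planted_met_prevalence override
#'   probabilities for the planted sets.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_healthy = 7, n_crc_nonmet = 38, n_crc_met = 12,
                          n_taa = 2023, n_empty_vector = 50, n_nonspot = 50,
                          n_positive_control = 4,
                          baseline_log_mean = log(200), baseline_log_sd = 0.4,
                          nonspot_attenuation = 0.3, array_scale_sd = 0.15,
                          reactive_fold = 8, background_prevalence = 0.25,
                          planted_crc_taa = character(),
                          planted_crc_prevalence = 0.9,
                          planted_met_taa = character(),
                          planted_met_prevalence = 0.9,
                          seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(background_prevalence, planted_crc_prevalence,
             planted_met_prevalence)
  stopifnot(n_taa >= 1, n_empty_vector >= 1, n_nonspot >= 1,
            baseline_log_sd > 0, nonspot_attenuation > 0,
            nonspot_attenuation <= 1, array_scale_sd >= 0,
            reactive_fold > 0, all(probs >= 0 & probs <= 1))
  universe <- taa_feature_ids(n_taa)
  for (set in c("planted_crc_taa", "planted_met_taa")) {
    extra <- setdiff(cfg[[set]], universe)
    if (length(extra))
      stop(set, " outside the TAA feature universe: ",
           paste(extra, collapse = ", "))
  }
  structure(cfg, class = "cohort_config")
}

taa_feature_ids <- function(n_taa) sprintf("TAA_%04d", seq_len(n_taa))

# Fixed feature layout shared by every array of a cohort: TAAs first, then
# empty-vector, nonspot and positive-control spots, on a square-ish grid.
cohort_layout <- function(config) {
  ids <- c(taa_feature_ids(config$n_taa),
           sprintf("EMPTY_%03d", seq_len(config$n_empty_vector)),
           sprintf("NONSPOT_%03d", seq_len(config$n_nonspot)),
           sprintf("POSCTRL_%02d", seq_len(config$n_positive_control)))
  roles <- rep(SPOT_ROLES,
               c(config$n_taa, config$n_empty_vector, config$n_nonspot,
                 config$n_positive_control))
  n <- length(ids)
  ncol <- ceiling(sqrt(n))
  data.frame(
    block = 1L,
    row = as.integer((seq_len(n) - 1L) %/% ncol) + 1L,
    column = as.integer((seq_len(n) - 1L) %% ncol) + 1L,
    feature_id = ids,
    feature_name = ids,
    role = roles,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort with planted differential TAAs
#'
#' Draws one array per sample under the generative model of
#' [cohort_config()] and returns the cohort together with the ground
#' truth: the sample-by-feature seropositivity table and the planted
#' feature sets. Intensities: nonspot positions are lognormal with
#' location `baseline_log_mean + log(nonspot_attenuation)`; empty-vector
#' and non-reactive TAA spots are lognormal at `baseline_log_mean`; each
#' reactive TAA spot is multiplied by `reactive_fold`; every spot of one
#' array is additionally multiplied by that array's scale factor,
#' lognormal(0, `array_scale_sd`). Positive-control spots are constant
#' high-intensity features (20x the baseline median), carried through I/O
#' but ignored by the analysis.
#'
#' @param config a [cohort_config()].
#' @return list with elements `cohort` (named list of [array_sample()])
#'   and `truth` (list: `seropositive` logical samples x TAA matrix,
#'   `planted_crc_taa`, `planted_met_taa`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_samples <- config$n_healthy + config$n_crc_nonmet + config$n_crc_met
  if (n_samples == 0)
    stop("cohort_config: zero samples in all groups")
  set.seed(config$seed)
  layout <- cohort_layout(config)
  taa_ids <- taa_feature_ids(config$n_taa)
  groups <- rep(c("healthy", "crc_nonmet", "crc_met"),
                c(config$n_healthy, config$n_crc_nonmet, config$n_crc_met))
  sample_ids <- sprintf("S%02d_%s",
                        seq_len(n_samples),
                        c(healthy = "H", crc_nonmet = "N", crc_met = "M")[groups])
  crc_idx <- match(config$planted_crc_taa, taa_ids)
  met_idx <- match(config$planted_met_taa, taa_ids)
  planted_idx <- union(crc_idx, met_idx)
  pos_level <- exp(config$baseline_log_mean) * 20

  scale_factors <- rlnorm(n_samples, 0, config$array_scale_sd)
  seropos <- matrix(FALSE, n_samples, config$n_taa,
                    dimnames = list(sample_ids, taa_ids))
  cohort <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    g <- groups[i]
    reactive <- rbinom(config$n_taa, 1, config$background_prevalence) == 1
    if (g %in% c("crc_nonmet", "crc_met") && length(crc_idx))
      reactive[crc_idx] <-
        rbinom(length(crc_idx), 1, config$planted_crc_prevalence) == 1
    if (g == "crc_met" && length(met_idx))
      reactive[met_idx] <-
        rbinom(length(met_idx), 1, config$planted_met_prevalence) == 1
    if (g == "healthy" && length(planted_idx))
      reactive[planted_idx] <- FALSE
    seropos[i, ] <- reactive

    n_spots <- nrow(layout)
    meanlog <- rep(config$baseline_log_mean, n_spots)
    meanlog[layout$role == "nonspot"] <-
      config$baseline_log_mean + log(config$nonspot_attenuation)
    intensity <- rlnorm(n_spots, meanlog, config$baseline_log_sd)
    taa_rows <- which(layout$role == "taa")
    intensity[taa_rows[reactive]] <-
      intensity[taa_rows[reactive]] * config$reactive_fold
    intensity[layout$role == "positive_control"] <- pos_level
    intensity <- intensity * scale_factors[i]

    spots <- layout
    spots$intensity_532 <- intensity
    cohort[[i]] <- array_sample(sample_ids[i], g, spots)
  }
  names(cohort) <- sample_ids
  list(cohort = cohort,
       truth = list(seropositive = seropos,
                    planted_crc_taa = config$planted_crc_taa,
                    planted_met_taa = config$planted_met_taa))
}

#' Write a cohort to spot-table files plus a manifest
#'
#' One tab-separated spot table per sample and a 3-column manifest, in the
#' dialect read back by [read_cohort()]; the write/read round trip
#' reproduces the cohort.
#'
#' @param cohort named list of [array_sample()] (e.g.
#'   `generate_cohort(cfg)$cohort`).
#' @param directory writable output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
cohort_to_files <- function(cohort, directory) {
  if (!length(cohort)) stop("cohort is empty; nothing to write")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(cohort, function(a) {
    f <- paste0(a$sample_id, ".tsv")
    write_spot_table(a, file.path(directory, f))
    f
  }, character(1))
  manifest <- data.frame(sample_id = vapply(cohort, `[[`, character(1), "sample_id"),
                         file = files,
                         group = vapply(cohort, `[[`, character(1), "group"),
                         stringsAsFactors = FALSE)
  mpath <- file.path(directory, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}
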