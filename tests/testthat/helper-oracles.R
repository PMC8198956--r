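# Shared helpers: independent oracles and small object builders.

# Full-permutation Mann-Whitney oracle: enumerates every assignment of the
# pooled values to the two group sizes and returns the exact two-sided
# p-value of the U statistic (ties credited 0.5), independently of
# stats::wilcox.test.
perm_mw_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_stat <- function(a, b)
    sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b), numeric(1)))
  u_obs <- u_stat(x, y)
  combos <- combn(length(pooled), m)
  us <- apply(combos, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  min(1, 2 * min(mean(us <= u_obs + 1e-12), mean(us >= u_obs - 1e-12)))
}

# Build a reactivity_matrix + positivity_matrix pair directly from a values
# matrix, with chosen per-sample empty-vector control summaries. Used where
# a test needs exact control over normalized values and thresholds.
make_rm <- function(values, groups, ev_mean = 1, ev_sd = 0.1) {
  ids <- rownames(values)
  ev_mean <- rep_len(ev_mean, length(ids))
  ev_sd <- rep_len(ev_sd, length(ids))
  rm_ <- structure(list(
    values = values,
    controls = data.frame(sample_id = ids, background_q1 = 0,
                          empty_vector_median = 1,
                          empty_vector_norm_mean = ev_mean,
                          empty_vector_norm_sd = ev_sd,
                          stringsAsFactors = FALSE),
    groups = setNames(groups, ids),
    dropped = character()),
    class = "reactivity_matrix")
  list(rm = rm_, calls = call_positives(rm_))
}

# A small array built spot-by-spot; intensities in the order given.
make_array <- function(sample_id, group, roles, intensities,
                       feature_ids = NULL) {
  n <- length(roles)
  if (is.null(feature_ids)) feature_ids <- sprintf("F%02d", seq_len(n))
  array_sample(sample_id, group, data.frame(
    block = 1L, row = 1L, column = seq_len(n),
    feature_id = feature_ids, feature_name = feature_ids,
    role = roles, intensity_532 = intensities,
    stringsAsFactors = FALSE))
}

# Generator settings used by the end-to-end recovery checks: a scaled-down
# cohort with strong planted effects. The tenth planted CRC antigen is also
# the metastasis marker: near-saturated reactivity in non-metastatic sCRC
# (CRC override) and rare reactivity in metastatic sCRC (met override), a
# reactivity-loss marker.
recovery_config <- function(seed) {
  cohort_config(
    n_healthy = 7, n_crc_nonmet = 26, n_crc_met = 12, n_taa = 300,
    n_empty_vector = 50, n_nonspot = 50,
    reactive_fold = 10, background_prevalence = 0.1,
    planted_crc_taa = sprintf("TAA_%04d", 1:10),
    planted_crc_prevalence = 0.95,
    planted_met_taa = "TAA_0010", planted_met_prevalence = 0.15,
    seed = seed)
}
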