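# Packaged reference-cohort tables: per-sample reactivity counts and the
# 67-TAA differential immunome, shipped as plain TSV under inst/extdata.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "seroscreen")
  if (p == "") p <- file.path("inst", "extdata", name)  # pre-install fallback
  if (!file.exists(p)) stop("packaged fixture not found: ", name)
  p
}

#' Reference cohort per-sample reactivity table
#'
#' Per-sample positive autoantibody counts against the 2023 unique TAA
#' features of the reference screening cohort: 57 plasma samples, 50 with
#' sCRC and 7 healthy donors. The table is shipped verbatim; a self-check
#' recomputes each printed percentage as round-half-up of
#' `n_positive / 2023 * 100` and flags (never corrects) inconsistent rows
#' in the `pct_consistent` column. The narrative range quoted alongside
#' the original table (maximum 1288, 64%) disagrees with the tabulated
#' maximum (1310, 65%); the table is kept as printed.
#'
#' @param n_features size of the feature universe behind the percentages
#'   (default 2023).
#' @return data frame with columns `sample_id`, `diagnosis`, `n_positive`,
#'   `pct_positive`, `pct_consistent`.
#' @export
load_table2_fixture <- function(n_features = 2023) {
  tab <- read.delim(fixture_path("table2_reactivity.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 57L)
  tab$sample_id <- as.character(tab$sample_id)
  tab$pct_consistent <-
    round_half_up(tab$n_positive / n_features * 100) == tab$pct_positive
  if (any(!tab$pct_consistent))
    message("load_table2_fixture: ", sum(!tab$pct_consistent),
            " row(s) fail the round-half-up percentage self-check: ",
            paste(tab$sample_id[!tab$pct_consistent], collapse = ", "))
  tab
}

#' Reference cohort differential immunome table (p < 0.01 subset)
#'
#' The 67 tumor-associated antigens of the reference immunome whose
#' healthy-vs-sCRC Mann-Whitney p-value was below 0.01, with the number of
#' positive sCRC samples (out of 50), the median per-case fold change and
#' the percent of sCRC cases with fold change above 1. None of these TAAs
#' had a positive call in any healthy donor.
#'
#' @return data frame with columns `taa_id`, `p_value`, `n_positive`,
#'   `n_group`, `median_fc`, `pct_cases_fc_gt1`.
#' @export
load_table3_fixture <- function() {
  tab <- read.delim(fixture_path("table3_immunome.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(tab$p_value > 0 & tab$p_value < 0.01),
            all(tab$n_positive >= 2))
  tab
}
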