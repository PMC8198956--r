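# Reading and writing the GenePix-results-like spot-table dialect, sample
# manifests, and cohort containers.

#' Construct an array sample
#'
#' An `array_sample` holds one scanned array: a sample identifier, its
#' clinical group, and a data frame of spots with 1-based block/row/column
#' coordinates, feature identity, role, and the raw 532 nm intensity.
#'
#' @param sample_id single string, unique within a cohort.
#' @param group one of `"healthy"`, `"crc_nonmet"`, `"crc_met"`, or `NA`.
#' @param spots data frame with columns `block`, `row`, `column`,
#'   `feature_id`, `feature_name`, `role`, `intensity_532`.
#' @return an object of class `array_sample`.
#' @export
array_sample <- function(sample_id, group = NA_character_, spots) {
  obj <- structure(
    list(sample_id = as.character(sample_id),
         group = as.character(group),
         spots = spots),
    class = "array_sample"
  )
  validate_array_sample(obj)
  obj
}

#' Validate an array sample
#'
#' Checks the invariants of the container: required spot columns, positive
#' 1-based coordinates unique within the array, roles drawn from the four
#' spot classes, non-negative intensities, and presence of at least one
#' spot of each of the taa / empty_vector / nonspot classes.
#'
#' @param x an `array_sample`.
#' @return `x`, invisibly; errors describe the violated invariant.
#' @export
validate_array_sample <- function(x) {
  stopifnot(inherits(x, "array_sample"))
  spots <- x$spots
  needed <- c("block", "row", "column", "feature_id", "feature_name",
              "role", "intensity_532")
  missing_cols <- setdiff(needed, names(spots))
  if (length(missing_cols))
    stop("array_sample '", x$sample_id, "': missing spot columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(spots) == 0L)
    stop("array_sample '", x$sample_id, "': spot table is empty")
  if (!is.na(x$group) && !x$group %in% SAMPLE_GROUPS)
    stop("array_sample '", x$sample_id, "': unknown group '", x$group, "'")
  coords <- spots[c("block", "row", "column")]
  if (any(unlist(coords) < 1))
    stop("array_sample '", x$sample_id, "': coordinates must be 1-based positive")
  key <- paste(coords$block, coords$row, coords$column)
  if (anyDuplicated(key))
    stop("array_sample '", x$sample_id,
         "': duplicate (block,row,column) coordinates: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  bad_role <- setdiff(unique(spots$role), SPOT_ROLES)
  if (length(bad_role))
    stop("array_sample '", x$sample_id, "': unknown roles: ",
         paste(bad_role, collapse = ", "))
  for (r in c("taa", "empty_vector", "nonspot"))
    if (!any(spots$role == r))
      stop("array_sample '", x$sample_id, "': no spots with role '", r, "'")
  if (any(!is.finite(spots$intensity_532)) || any(spots$intensity_532 < 0))
    stop("array_sample '", x$sample_id,
         "': intensities must be finite and non-negative")
  invisible(x)
}

#' @export
print.array_sample <- function(x, ...) {
  cat("array_sample '", x$sample_id, "' (group: ", x$group, ")\n", sep = "")
  cat("  ", nrow(x$spots), " spots: ",
      paste(sprintf("%s=%d", names(table(x$spots$role)),
                    as.integer(table(x$spots$role))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Default feature-name to role mapping
#'
#' Named character vector of regular-expression patterns mapped to spot
#' roles, matching the naming scheme of [generate_cohort()]. Patterns are
#' tried in order; the first match assigns the role. Control naming varies
#' across array designs, so real data will usually need a custom map.
#'
#' @return named character vector: `names` are regex patterns, values roles.
#' @export
default_role_map <- function() {
  c("^EMPTY"   = "empty_vector",
    "^NONSPOT" = "nonspot",
    "^POSCTRL" = "positive_control",
    "."        = "taa")
}

assign_roles <- function(feature_names, role_map) {
  roles <- rep(NA_character_, length(feature_names))
  for (pat in names(role_map)) {
    hit <- is.na(roles) & grepl(pat, feature_names)
    roles[hit] <- role_map[[pat]]
  }
  if (anyNA(roles)) {
    offenders <- unique(feature_names[is.na(roles)])
    stop("role_map does not cover feature names: ",
         paste(utils::head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) sprintf(" (and %d more)", length(offenders) - 10))
  }
  bad <- setdiff(unique(roles), SPOT_ROLES)
  if (length(bad))
    stop("role_map assigns unknown roles: ", paste(bad, collapse = ", "))
  roles
}

#' Read a spot quantification table
#'
#' Reads one tab-separated GenePix-results-like file into an
#' [array_sample()]. The reader skips any ATF-style preamble lines that
#' begin with a double quote, then expects a header naming at least
#' `Block`, `Row`, `Column`, `ID`, `Name` and a 532 nm intensity column
#' (the single-channel foreground median, `F532 Median`; the scanner's
#' local background column is ignored because background correction is
#' defined from nonspot features downstream). Rows whose intensity does
#' not parse as a number are rejected (dropped with a message).
#'
#' @param path path to the file.
#' @param role_map feature-name pattern to role mapping; see
#'   [default_role_map()]. Must cover every feature name in the file.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @param group clinical group, or `NA` if unknown at read time.
#' @return an `array_sample` whose spots preserve file order.
#' @export
read_spot_table <- function(path, role_map = default_role_map(),
                            sample_id = NULL, group = NA_character_) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  skip <- 0L
  while (skip < length(lines) && startsWith(lines[skip + 1L], "\""))
    skip <- skip + 1L
  tab <- read.delim(path, skip = skip, check.names = FALSE,
                    stringsAsFactors = FALSE)
  required <- c("Block", "Row", "Column", "ID", "Name")
  for (col in required)
    if (!col %in% names(tab))
      stop("spot table '", path, "': missing required column '", col, "'")
  int_col <- grep("532", names(tab), value = TRUE)
  if (!length(int_col))
    stop("spot table '", path, "': missing required column 'F532 Median' ",
         "(no 532 nm intensity column found)")
  int_col <- int_col[[1L]]
  intensity <- suppressWarnings(as.numeric(tab[[int_col]]))
  bad <- is.na(intensity)
  if (any(bad)) {
    message("read_spot_table: rejecting ", sum(bad),
            " row(s) with non-numeric intensity in ", basename(path))
    tab <- tab[!bad, , drop = FALSE]
    intensity <- intensity[!bad]
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  spots <- data.frame(
    block = as.integer(tab$Block),
    row = as.integer(tab$Row),
    column = as.integer(tab$Column),
    feature_id = as.character(tab$ID),
    feature_name = as.character(tab$Name),
    role = assign_roles(as.character(tab$Name), role_map),
    intensity_532 = intensity,
    stringsAsFactors = FALSE
  )
  array_sample(sample_id, group, spots)
}

#' Write a spot quantification table
#'
#' Emits the same dialect read by [read_spot_table()], with an ATF-style
#' preamble line and full-precision intensities, so that a write/read
#' round trip reproduces the array field for field.
#'
#' @param array an `array_sample`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(array, path) {
  validate_array_sample(array)
  s <- array$spots
  header <- c(sprintf("\"Sample=%s\"", array$sample_id),
              paste("Block", "Row", "Column", "ID", "Name", "F532 Median",
                    sep = "\t"))
  body <- paste(s$block, s$row, s$column, s$feature_id, s$feature_name,
                sprintf("%.17g", s$intensity_532), sep = "\t")
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) {
    stop("cannot write spot table to '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

#' Read a sample manifest
#'
#' A manifest is a 3-column tab-separated file with header
#' `sample_id`, `file`, `group` mapping each array file to its clinical
#' group (`healthy`, `crc_nonmet`, `crc_met`).
#'
#' @param path manifest path.
#' @return data frame with columns `sample_id`, `file`, `group`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "file", "group")
  missing_cols <- setdiff(needed, names(m))
  if (length(missing_cols))
    stop("manifest '", path, "': missing columns: ",
         paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(m$group), SAMPLE_GROUPS)
  if (length(bad))
    stop("manifest '", path, "': unknown group label(s): ",
         paste(bad, collapse = ", "),
         " (expected: ", paste(SAMPLE_GROUPS, collapse = ", "), ")")
  if (anyDuplicated(m$sample_id))
    stop("manifest '", path, "': duplicate sample_id(s): ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  m[needed]
}

#' Read a whole cohort from a manifest
#'
#' @param manifest_path path to a manifest (see [read_manifest()]); file
#'   paths in the manifest are resolved relative to its directory.
#' @param role_map passed to [read_spot_table()].
#' @return list of `array_sample`, named by sample id.
#' @export
read_cohort <- function(manifest_path, role_map = default_role_map()) {
  m <- read_manifest(manifest_path)
  dir <- dirname(manifest_path)
  cohort <- lapply(seq_len(nrow(m)), function(i) {
    p <- m$file[i]
    if (!file.exists(p)) p <- file.path(dir, m$file[i])
    read_spot_table(p, role_map, sample_id = m$sample_id[i],
                    group = m$group[i])
  })
  names(cohort) <- m$sample_id
  check_shared_layout(cohort)
  cohort
}

# All arrays of a cohort must share one feature layout.
check_shared_layout <- function(cohort) {
  if (!length(cohort)) stop("cohort is empty")
  ref <- cohort[[1L]]$spots[c("feature_id", "role")]
  for (a in cohort[-1L]) {
    cur <- a$spots[c("feature_id", "role")]
    if (!identical(ref, cur))
      stop("array '", a$sample_id, "' does not share the feature layout of '",
           cohort[[1L]]$sample_id, "'")
  }
  invisible(cohort)
}

cohort_groups <- function(cohort) {
  setNames(vapply(cohort, `[[`, character(1), "group"),
           vapply(cohort, `[[`, character(1), "sample_id"))
}
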