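# CSV reading/writing and validation for the pipeline's tables.
#
# All tables are plain CSV with a header row, UTF-8, "." decimal separator.
# Column names are mapped through a user-supplied schema so tables from
# different sources can be read without renaming; units are fixed (hr, mg,
# pg/mg) and never converted here. Validation never silently drops rows:
# non-pupariating larvae are retained and flagged, and every malformed row is
# reported with its row number.

read_checked_csv <- function(path, schema, required) {
  if (!file.exists(path))
    stop_cw(sprintf("file not found: %s", path), "cw_io_error")
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  missing <- setdiff(unname(schema[required]), names(raw))
  if (length(missing))
    stop_cw(sprintf("missing column(s) in %s: %s", path,
                    paste(missing, collapse = ", ")), "cw_schema_error")
  raw
}

parse_numeric_col <- function(values, column, allow_na = FALSE) {
  num <- suppressWarnings(as.numeric(values))
  sentinel <- is.na(values) | toupper(trimws(values)) %in% c("NA", "", "NAN")
  bad <- which(is.na(num) & !sentinel)
  if (length(bad))
    stop_cw(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                    values[bad[1L]], column, bad[1L]), "cw_parse_error")
  if (!allow_na && any(is.na(num)))
    stop_cw(sprintf("missing value in column '%s' at data row %d",
                    column, which(is.na(num))[1L]), "cw_parse_error")
  num
}

#' Read a starvation-response table
#'
#' Reads per-larva records of (group, age at starvation, time to pupariation)
#' from CSV. A missing/`NA` time to pupariation is taken to mean the larva
#' died before pupariating and is retained with `pupariated = FALSE` (fits
#' exclude such larvae but report their count).
#'
#' @param path CSV file with a header row.
#' @param schema named character vector mapping the canonical fields
#'   `larva_id`, `group`, `age`, `ttp` (and optionally `pupariated`) to the
#'   file's column names. Fields absent from the file (`larva_id`, `group`,
#'   `pupariated`) are filled with defaults.
#' @param age_grid optional numeric vector declaring the collection grid
#'   (e.g. `seq(0, 24, 2)` for a 2-hr design); when given, ages off the grid
#'   are an error. When `NULL` (default) any non-negative age is accepted.
#' @return data frame with columns `larva_id`, `group`, `age` (hr AL3E),
#'   `ttp` (hr), `pupariated` (logical).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,group,age,ttp", "L1,w1118,0,48", "L2,w1118,8,34"), f)
#' read_starvation_table(f)
#' @export
read_starvation_table <- function(path,
                                  schema = c(larva_id = "id", group = "group",
                                             age = "age", ttp = "ttp",
                                             pupariated = "pupariated"),
                                  age_grid = NULL) {
  schema <- check_schema(schema, c("larva_id", "group", "age", "ttp", "pupariated"))
  raw <- read_checked_csv(path, schema, required = c("age", "ttp"))
  n <- nrow(raw)
  age <- parse_numeric_col(raw[[schema[["age"]]]], schema[["age"]])
  ttp <- parse_numeric_col(raw[[schema[["ttp"]]]], schema[["ttp"]], allow_na = TRUE)
  pup <- if (schema[["pupariated"]] %in% names(raw)) {
    toupper(trimws(raw[[schema[["pupariated"]]]])) %in% c("TRUE", "T", "1", "YES")
  } else rep(TRUE, n)
  pup <- pup & !is.na(ttp)   # NA time-to-pupariation => died before pupariation
  out <- data.frame(
    larva_id = col_or_default(raw, schema[["larva_id"]], paste0("larva_", seq_len(n)),
                              canonical = "larva_id"),
    group = col_or_default(raw, schema[["group"]], "unknown"),
    age = age, ttp = ttp, pupariated = pup,
    stringsAsFactors = FALSE
  )
  if (any(out$age < 0))
    stop_cw(sprintf("negative age at data row %d", which(out$age < 0)[1L]),
            "cw_validation_error")
  bad_ttp <- which(out$pupariated & out$ttp <= 0)
  if (length(bad_ttp))
    stop_cw(sprintf("non-positive time to pupariation at data row %d", bad_ttp[1L]),
            "cw_validation_error")
  if (!is.null(age_grid)) {
    off <- which(!vapply(out$age, function(a) any(abs(a - age_grid) < 1e-8), logical(1)))
    if (length(off))
      stop_cw(sprintf("age %g at data row %d is off the declared collection grid",
                      out$age[off[1L]], off[1L]), "cw_validation_error")
  }
  if (any(!out$pupariated))
    message(sprintf("%d larva(e) died before pupariation (retained, flagged pupariated = FALSE)",
                    sum(!out$pupariated)))
  out
}

#' Read a larval growth table
#'
#' @param path CSV with header row.
#' @param schema named map for fields `larva_id`, `group`, `age`, `mass`.
#' @return data frame with columns `larva_id`, `group`, `age` (hr AL3E),
#'   `mass` (mg, positive).
#' @export
read_growth_table <- function(path,
                              schema = c(larva_id = "id", group = "group",
                                         age = "age", mass = "mass")) {
  schema <- check_schema(schema, c("larva_id", "group", "age", "mass"))
  raw <- read_checked_csv(path, schema, required = c("age", "mass"))
  n <- nrow(raw)
  out <- data.frame(
    larva_id = col_or_default(raw, schema[["larva_id"]], paste0("larva_", seq_len(n)),
                              canonical = "larva_id"),
    group = col_or_default(raw, schema[["group"]], "unknown"),
    age = parse_numeric_col(raw[[schema[["age"]]]], schema[["age"]]),
    mass = parse_numeric_col(raw[[schema[["mass"]]]], schema[["mass"]]),
    stringsAsFactors = FALSE
  )
  if (any(out$age < 0))
    stop_cw("negative age in growth table", "cw_validation_error")
  if (any(out$mass <= 0))
    stop_cw(sprintf("non-positive mass at data row %d", which(out$mass <= 0)[1L]),
            "cw_validation_error")
  out
}

#' Read a qPCR Ct table
#'
#' One row per (gene, time, replicate): the target gene's Ct and the internal
#' control's Ct (the reference gene, e.g. *RpL3*) measured on the same sample.
#' Ct values far outside the usual 5–40 cycle range are flagged with a
#' warning, not an error.
#'
#' @param path CSV with header row.
#' @param schema named map for `gene`, `time`, `replicate`, `ct_target`,
#'   `ct_reference`, `group`.
#' @return data frame with those canonical columns.
#' @export
read_ct_table <- function(path,
                          schema = c(gene = "gene", time = "time",
                                     replicate = "replicate",
                                     ct_target = "ct_target",
                                     ct_reference = "ct_reference",
                                     group = "group")) {
  schema <- check_schema(schema, c("gene", "time", "replicate",
                                   "ct_target", "ct_reference", "group"))
  raw <- read_checked_csv(path, schema,
                          required = c("gene", "time", "ct_target", "ct_reference"))
  n <- nrow(raw)
  out <- data.frame(
    gene = raw[[schema[["gene"]]]],
    group = col_or_default(raw, schema[["group"]], "unknown"),
    time = parse_numeric_col(raw[[schema[["time"]]]], schema[["time"]]),
    replicate = col_or_default(raw, schema[["replicate"]], as.character(seq_len(n))),
    ct_target = parse_numeric_col(raw[[schema[["ct_target"]]]], schema[["ct_target"]]),
    ct_reference = parse_numeric_col(raw[[schema[["ct_reference"]]]], schema[["ct_reference"]]),
    stringsAsFactors = FALSE
  )
  ct <- c(out$ct_target, out$ct_reference)
  if (any(ct < 5 | ct > 40))
    warn_cw("Ct value(s) outside the typical 5-40 cycle range", "cw_ct_range_warning")
  out
}

#' Read a time-course table (hormone titres or relative expression)
#'
#' @param path CSV with header row.
#' @param schema named map for `time`, `replicate`, `value`, `group`.
#' @return data frame with columns `group`, `time` (hr AL3E), `replicate`,
#'   `value` (non-negative; e.g. 20E in pg/mg, or fold change).
#' @export
read_timecourse_table <- function(path,
                                  schema = c(time = "time", replicate = "replicate",
                                             value = "value", group = "group")) {
  schema <- check_schema(schema, c("time", "replicate", "value", "group"))
  raw <- read_checked_csv(path, schema, required = c("time", "value"))
  n <- nrow(raw)
  out <- data.frame(
    group = col_or_default(raw, schema[["group"]], "unknown"),
    time = parse_numeric_col(raw[[schema[["time"]]]], schema[["time"]]),
    replicate = col_or_default(raw, schema[["replicate"]], as.character(seq_len(n))),
    value = parse_numeric_col(raw[[schema[["value"]]]], schema[["value"]]),
    stringsAsFactors = FALSE
  )
  if (any(out$value < 0))
    stop_cw(sprintf("negative value at data row %d", which(out$value < 0)[1L]),
            "cw_validation_error")
  out
}

check_schema <- function(schema, fields) {
  defaults <- setNames(fields, fields)
  if ("larva_id" %in% fields) defaults[["larva_id"]] <- "id"
  for (f in names(schema)) {
    if (!f %in% fields)
      stop_cw(sprintf("unknown schema field '%s'", f), "cw_schema_error")
    defaults[[f]] <- schema[[f]]
  }
  defaults
}

# look up the schema-mapped column, falling back to the canonical field name
# so tables the package itself writes always round-trip
col_or_default <- function(raw, col, default, canonical = NULL) {
  for (nm in c(col, canonical))
    if (!is.null(nm) && nm %in% names(raw)) return(as.character(raw[[nm]]))
  default
}

#' Write / read a critical-weight estimate as flat JSON
#'
#' Serialises a [bootstrap_critical_weight()] result to a flat key-value JSON
#' file (age, age CI, mass, mass CI, replicate counts, seed, group) and reads
#' it back losslessly.
#'
#' @param estimate a `critical_weight_estimate`.
#' @param path output file path.
#' @return `write_estimate` invisibly returns `path`; `read_estimate` returns
#'   the reconstructed `critical_weight_estimate`.
#' @export
write_estimate <- function(estimate, path) {
  stopifnot(inherits(estimate, "critical_weight_estimate"))
  flat <- estimate[c("group", "age", "age_ci_low", "age_ci_high",
                     "mass", "mass_ci_low", "mass_ci_high",
                     "n_boot", "n_failed_boot", "level", "seed")]
  num <- unlist(flat[c("age", "age_ci_low", "age_ci_high")])
  if (!all(is.finite(num)))
    stop_cw("estimate contains non-finite age values", "cw_validation_error")
  if (estimate$age_ci_low > estimate$age || estimate$age > estimate$age_ci_high)
    stop_cw("age CI bounds do not bracket the estimate (reversed bounds?)",
            "cw_validation_error")
  if (!is.na(estimate$mass) &&
      (estimate$mass_ci_low > estimate$mass || estimate$mass > estimate$mass_ci_high))
    stop_cw("mass CI bounds do not bracket the estimate (reversed bounds?)",
            "cw_validation_error")
  ok <- tryCatch({
    suppressWarnings(jsonlite::write_json(flat, path, auto_unbox = TRUE,
                                          digits = NA, null = "null",
                                          na = "null"))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_cw(sprintf("cannot write estimate to '%s': %s", path,
                    conditionMessage(ok)), "cw_io_error")
  invisible(path)
}

#' @rdname write_estimate
#' @export
read_estimate <- function(path) {
  if (!file.exists(path))
    stop_cw(sprintf("file not found: %s", path), "cw_io_error")
  flat <- jsonlite::read_json(path, simplifyVector = TRUE)
  flat[vapply(flat, is.null, logical(1))] <- NA
  new_cw_estimate(flat)
}

#' Write a summary CSV of several critical-weight estimates
#'
#' One row per group: age at critical weight with its CI, mass with its CI.
#'
#' @param estimates list of `critical_weight_estimate` objects.
#' @param path output CSV path.
#' @export
write_cw_summary <- function(estimates, path) {
  if (inherits(estimates, "critical_weight_estimate")) estimates <- list(estimates)
  tab <- do.call(rbind, lapply(estimates, as.data.frame))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
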