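#' Canonical column schema of a country-year financing panel
#'
#' The package works on a single long-format interchange table: one row per
#' (country, year). Financing shares are percentages of total health
#' expenditure (THE); outcomes cover expenditure, service coverage, health
#' status and financial risk protection; controls and contextual factors are
#' the covariates commonly used in the cross-country public-expenditure
#' literature.
#'
#' @return Named list of character vectors: `keys`, `shares`, `outcomes`,
#'   `controls`, `contextual`.
#' @export
panel_schema <- function() {
  list(
    keys       = c("country_id", "year"),
    shares     = c("gov_pct", "shi_pct", "oop_pct", "other_pct"),
    outcomes   = c("the_pc", "imm_idx", "le", "u5m", "mm", "cat10"),
    controls   = c("log_gdp_pc", "educ_enroll", "water_pct", "urban_pct",
                   "gini", "pop65_pct", "pop14_pct", "gov_eff", "corr_ctrl"),
    contextual = c("informal_pct", "payroll_rev_pct", "gge_gdp_pct")
  )
}

# percent-valued columns (bounded [0, 100]); log_* and index columns are not
.percent_cols <- function() {
  # educ_enroll is a gross rate and may legitimately exceed 100
  c("gov_pct", "shi_pct", "oop_pct", "other_pct",
    "imm_idx", "cat10", "water_pct", "urban_pct",
    "pop65_pct", "pop14_pct", "informal_pct", "payroll_rev_pct",
    "gge_gdp_pct")
}

# outcomes with strictly positive support (logged downstream)
.positive_cols <- function() c("the_pc", "u5m", "mm")

#' Validate a country-year panel
#'
#' Enforces the structural invariants of the interchange format:
#' unique (country, year) keys, integer years, percent fields in
#' \eqn{[0, 100]}, strictly positive support for outcomes that are logged
#' downstream, and financing shares summing to 100 within a tolerance where
#' all four are present (accounting data rarely sums exactly).
#'
#' @param panel data.frame in the long country-year format.
#' @param share_tol allowed absolute deviation of the four financing shares
#'   from 100, in percentage points. Default 0.5.
#' @return The validated panel (invisibly classed `hfs_panel`), sorted by
#'   (country_id, year).
#' @export
validate_panel <- function(panel, share_tol = 0.5) {
  stopifnot(is.data.frame(panel))
  need <- panel_schema()$keys
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing key columns: ", paste(miss, collapse = ", "))
  if (anyNA(panel$country_id) || anyNA(panel$year))
    stop("key columns country_id/year must not be missing")
  if (!is.numeric(panel$year) || any(panel$year != as.integer(panel$year)))
    stop("year must be integer-valued")

  key <- paste(panel$country_id, panel$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- unique(key[duplicated(key)])
    stop("duplicate (country_id, year) rows: ",
         paste(gsub("\r", " ", utils::head(d, 5)), collapse = "; "))
  }

  for (col in intersect(.percent_cols(), names(panel))) {
    v <- panel[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad))
      stop(sprintf("column %s outside [0, 100] in %d row(s), e.g. row %d (%s)",
                   col, length(bad), bad[1], format(v[bad[1]])))
  }

  sh <- panel_schema()$shares
  if (all(sh %in% names(panel))) {
    s <- rowSums(panel[, sh])
    bad <- which(!is.na(s) & abs(s - 100) > share_tol)
    if (length(bad))
      stop(sprintf(paste0("financing shares must sum to 100 (+/- %g); ",
                          "%d row(s) violate, e.g. %s year %d (sum %.2f)"),
                   share_tol, length(bad),
                   panel$country_id[bad[1]], panel$year[bad[1]], s[bad[1]]))
  }

  panel <- panel[order(panel$country_id, panel$year), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- unique(c("hfs_panel", class(panel)))
  invisible(panel)
}

#' Read a country-year panel from CSV
#'
#' @param path CSV file path, UTF-8, header row, missing values as empty
#'   cells (or `NA`).
#' @param schema optional named character vector mapping canonical column
#'   names (names) to the column names used in the file (values), for files
#'   whose headers differ from [panel_schema()].
#' @param share_tol passed to [validate_panel()].
#' @return A validated `hfs_panel` data.frame sorted by (country_id, year).
#' @export
read_panel <- function(path, schema = NULL, share_tol = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    stopifnot(is.character(schema), !is.null(names(schema)))
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop("schema maps ", canon, " to missing column ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  validate_panel(df, share_tol = share_tol)
}

#' Write a panel to CSV
#'
#' Inverse of [read_panel()]: the written file reads back to an identical
#' panel (missing cells as empty strings).
#'
#' @param panel an `hfs_panel` or compatible data.frame.
#' @param path output CSV path.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Add natural-log columns for positive-support outcomes
#'
#' Mortality and expenditure outcomes enter the regressions in natural
#' logs. Adds `log_<name>` columns; originals are retained.
#'
#' @param panel panel data.frame.
#' @param names outcome columns to log; default the per-capita expenditure
#'   and mortality outcomes.
#' @return panel with `log_*` columns appended.
#' @export
log_transform_outcomes <- function(panel, names = c("the_pc", "u5m", "mm")) {
  for (nm in names) {
    if (!nm %in% base::names(panel)) stop("no such outcome column: ", nm)
    v <- panel[[nm]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop(sprintf("%s must be strictly positive before log; row %d (%s, %d) has %s",
                   nm, bad[1], panel$country_id[bad[1]], panel$year[bad[1]],
                   format(v[bad[1]])))
    panel[[paste0("log_", nm)]] <- log(v)
  }
  panel
}

#' Bundle model results for serialization
#'
#' A flat, serializable summary of one fitted model: coefficient table,
#' test results, sample sizes and fit statistics.
#'
#' @param model_name,outcome_name identifying strings.
#' @param coefficients data.frame with columns `name`, `estimate`, `se`,
#'   `statistic`, `p_value` (may have zero rows).
#' @param tests optional data.frame of test results (`test`, `statistic`,
#'   `p_value`, ...).
#' @param n_obs,n_countries sample sizes.
#' @param r2_within,r2_adj fit statistics (may be `NA`).
#' @return object of class `hfs_result_bundle`.
#' @export
result_bundle <- function(model_name, outcome_name, coefficients,
                          tests = NULL, n_obs = NA_integer_,
                          n_countries = NA_integer_,
                          r2_within = NA_real_, r2_adj = NA_real_) {
  stopifnot(is.data.frame(coefficients))
  need <- c("name", "estimate", "se", "statistic", "p_value")
  miss <- setdiff(need, names(coefficients))
  if (length(miss))
    stop("coefficient table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(coefficients)) {
    if (any(!is.finite(coefficients$se) | coefficients$se <= 0))
      stop("coefficient SEs must be finite and > 0 (clean upstream)")
    if (any(coefficients$p_value < 0 | coefficients$p_value > 1, na.rm = TRUE))
      stop("p-values must lie in [0, 1]")
  }
  n_obs <- if (length(n_obs)) n_obs else NA_integer_
  n_countries <- if (length(n_countries)) n_countries else NA_integer_
  if (isTRUE(n_countries > n_obs))
    stop("n_countries cannot exceed n_obs")
  structure(list(model_name = model_name, outcome_name = outcome_name,
                 coefficients = coefficients, tests = tests,
                 n_obs = as.integer(n_obs),
                 n_countries = as.integer(n_countries),
                 r2_within = r2_within, r2_adj = r2_adj),
            class = "hfs_result_bundle")
}

#' Write a result bundle to disk
#'
#' Writes a JSON file with the full bundle plus a flat CSV coefficient
#' table next to it (same path with extension `.csv`). The JSON round-trips
#' through [read_results()] losslessly.
#'
#' @param bundle an `hfs_result_bundle`.
#' @param path output path for the JSON file.
#' @export
write_results <- function(bundle, path) {
  stopifnot(inherits(bundle, "hfs_result_bundle"))
  if (nrow(bundle$coefficients) &&
      any(!is.finite(bundle$coefficients$se)))
    stop("cannot serialize non-finite SEs")
  jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  csv <- sub("\\.json$", "", path)
  utils::write.csv(bundle$coefficients, paste0(csv, ".csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a result bundle written by [write_results()]
#' @param path JSON path.
#' @return `hfs_result_bundle`.
#' @export
read_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- x$coefficients
  if (is.null(co) || (is.list(co) && !length(co)))
    co <- data.frame(name = character(), estimate = numeric(),
                     se = numeric(), statistic = numeric(),
                     p_value = numeric())
  tests <- x$tests
  if (!is.null(tests) && is.list(tests) && !is.data.frame(tests) && !length(tests))
    tests <- NULL
  result_bundle(x$model_name, x$outcome_name, as.data.frame(co),
                tests = if (is.null(tests)) NULL else as.data.frame(tests),
                n_obs = x$n_obs, n_countries = x$n_countries,
                r2_within = if (is.null(x$r2_within)) NA_real_ else x$r2_within,
                r2_adj = if (is.null(x$r2_adj)) NA_real_ else x$r2_adj)
}

#' @export
print.hfs_result_bundle <- function(x, ...) {
  cat(sprintf("<%s on %s>  n = %s obs, %s countries\n", x$model_name,
              x$outcome_name, x$n_obs, x$n_countries))
  if (nrow(x$coefficients)) print(x$coefficients, digits = 4)
  invisible(x)
}
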