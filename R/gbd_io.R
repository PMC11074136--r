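# Column-name aliases across GBD results-tool export versions (all matched
# case-insensitively).
GBD_ALIASES <- list(
  location = c("location", "location_name"),
  year = c("year", "year_id"),
  metric = c("metric", "metric_name"),
  val = c("val", "value"),
  measure = c("measure", "measure_name"),
  sex = c("sex", "sex_name"),
  age = c("age", "age_name", "age_group_name"),
  cause_or_rei = c("cause", "cause_name", "rei", "rei_name"),
  upper = "upper",
  lower = "lower"
)

#' Read a GBD results-tool CSV extract
#'
#' Parses one CSV in the layout of the public GBD results tool
#' (one row per location/year/measure with `val`, `upper`, `lower`), tolerant
#' of the column-name dialects the portal has used (`location` vs
#' `location_name`, `val` vs `value`, any letter case). Rows are filtered to
#' the requested metric, and — when the columns are present — to both-sex,
#' age-standardized rows by default, matching the usual analysis of
#' age-standardized both-population rates. Rows whose value fails numeric
#' parsing are dropped with a warning stating the count.
#'
#' @param path CSV file path.
#' @param expected_metric Metric to keep, e.g. `"Rate"` for burden measures or
#'   the portal's label for summary exposure values; matched
#'   case-insensitively.
#' @param sex Keep only rows with this sex label (default `"Both"`); `NULL`
#'   disables the filter.
#' @param age Keep only rows with this age label (default
#'   `"Age-standardized"`); `NULL` disables the filter.
#' @return Tibble of raw rows with canonical column names (`location`, `year`,
#'   `metric`, `val`, plus whichever of `measure`, `sex`, `age`,
#'   `cause_or_rei`, `upper`, `lower` the file carried).
#' @export
read_gbd_csv <- function(path, expected_metric,
                         sex = "Both", age = "Age-standardized") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  lc <- tolower(names(raw))
  out <- tibble::tibble(.rows = nrow(raw))
  for (canon in names(GBD_ALIASES)) {
    hit <- which(lc %in% GBD_ALIASES[[canon]])
    if (length(hit)) out[[canon]] <- raw[[hit[1]]]
  }
  for (col in c("location", "year", "metric", "val")) {
    if (is.null(out[[col]])) {
      stop("mandatory column missing from ", path, ": ", col,
           " (accepted names: ", paste(GBD_ALIASES[[col]], collapse = ", "), ")")
    }
  }

  out$year <- suppressWarnings(as.integer(out$year))
  val_num <- suppressWarnings(as.numeric(out$val))
  bad <- !is.finite(val_num) | is.na(out$year)
  if (any(bad)) {
    warning(sum(bad), " row(s) dropped: value or year failed numeric parse")
    out <- out[!bad, , drop = FALSE]
    val_num <- val_num[!bad]
  }
  out$val <- val_num
  for (col in c("upper", "lower")) {
    if (!is.null(out[[col]])) out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }

  out <- out[tolower(out$metric) == tolower(expected_metric), , drop = FALSE]
  if (!is.null(sex) && !is.null(out$sex)) {
    out <- out[tolower(out$sex) == tolower(sex), , drop = FALSE]
  }
  if (!is.null(age) && !is.null(out$age)) {
    out <- out[tolower(out$age) == tolower(age), , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    stop("no rows left after filtering ", path, " to metric '", expected_metric, "'")
  }
  out
}

#' Assemble a two-period analysis panel from GBD rows
#'
#' Inner-joins the outcome rows with every covariate source on
#' (location, year) and keeps only complete cases across both years: a
#' location missing the outcome or any covariate in either year is excluded
#' entirely (the decomposition compares the same covariate set across
#' periods). Covariate values outside their declared range are rejected, not
#' clamped.
#'
#' @param rate_rows Outcome rows from [read_gbd_csv()] (rates per 100,000).
#' @param covariate_rows Named list of row tibbles, one per covariate; names
#'   become panel column names.
#' @param years Length-2 integer vector of the two analysis years.
#' @param covariate_ranges Optional named list of `c(lower, upper)` ranges
#'   used to validate covariate values (e.g. `c(0, 100)` for summary exposure
#'   values, `c(0, 1)` for the socio-demographic index).
#' @return Analysis panel tibble (`location`, `year`, `outcome`, covariates in
#'   alphabetical order), with an attribute `excluded` listing dropped
#'   locations.
#' @export
build_panel <- function(rate_rows, covariate_rows, years,
                        covariate_ranges = NULL) {
  stopifnot(length(years) == 2, years[1] != years[2])
  if (is.null(names(covariate_rows)) || any(names(covariate_rows) == "")) {
    stop("covariate_rows must be a named list")
  }

  take <- function(rows, value_name, source) {
    rows <- rows[rows$year %in% years, c("location", "year", "val")]
    dup <- duplicated(rows[, c("location", "year")])
    if (any(dup)) {
      stop("duplicate (location, year) in source '", source, "': ",
           rows$location[dup][1], " ", rows$year[dup][1])
    }
    names(rows)[3] <- value_name
    rows
  }

  panel <- take(rate_rows, "outcome", "outcome")
  if (!all(years %in% panel$year)) {
    stop("outcome rows must contain both years ", years[1], " and ", years[2])
  }
  for (nm in names(covariate_rows)) {
    cv <- take(covariate_rows[[nm]], nm, nm)
    rng <- covariate_ranges[[nm]]
    if (!is.null(rng)) {
      off <- cv[[nm]] < rng[1] | cv[[nm]] > rng[2]
      if (any(off)) {
        stop("covariate '", nm, "' has ", sum(off), " value(s) outside [",
             rng[1], ", ", rng[2], "]; rejecting, not clamping")
      }
    }
    panel <- dplyr::inner_join(panel, cv, by = c("location", "year"))
  }

  all_locs <- unique(rate_rows$location[rate_rows$year %in% years])
  keep <- names(which(table(panel$location) == 2L))
  excluded <- setdiff(all_locs, keep)
  if (length(excluded)) {
    message(length(excluded), " location(s) excluded (incomplete data): ",
            paste(utils::head(excluded, 10), collapse = ", "),
            if (length(excluded) > 10) ", ...")
  }
  panel <- panel[panel$location %in% keep, , drop = FALSE]
  if (nrow(panel) == 0L) stop("zero locations with complete data in both years")

  covs <- sort(names(covariate_rows))
  panel <- panel[order(panel$year, panel$location),
                 c("location", "year", "outcome", covs)]
  attr(panel, "excluded") <- excluded
  check_panel(panel)
  panel
}

#' Write / read a tidy analysis panel
#'
#' Panels are written at full precision (shortest round-trip representation),
#' so writing and re-reading reproduces finite doubles bit-exactly.
#'
#' @param panel Analysis panel tibble.
#' @param path CSV path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns the panel tibble.
#' @export
write_panel_csv <- function(panel, path) {
  check_panel(panel)
  out <- panel
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      # 17 significant digits: lossless round-trip for IEEE doubles
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # base read.csv: strtod parsing is correctly rounded, preserving the
  # 17-digit round-trip guarantee of write_panel_csv
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(location = "character"))
  raw$year <- as.integer(raw$year)
  panel <- tibble::as_tibble(raw)
  check_panel(panel)
  panel
}
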