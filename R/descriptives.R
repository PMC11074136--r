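#' Per-location change in a burden measure between two years
#'
#' Computes, for every location in a two-period panel, the end-year minus
#' start-year difference in the outcome (for example, Latvia's age-standardized
#' incidence rate rising from 3.48 to 12.09 gives a change of 8.61). Rows are
#' sorted by the change, largest first, ties broken alphabetically by location.
#'
#' @param panel Analysis panel tibble with both years for every location.
#' @param year_start,year_end The two years; default to the panel's minimum
#'   and maximum year.
#' @return Tibble with columns `location`, `value_start`, `value_end`, `delta`.
#' @export
delta_change <- function(panel, year_start = min(panel$year),
                         year_end = max(panel$year)) {
  check_panel(panel)
  a <- panel[panel$year == year_start, c("location", "outcome")]
  b <- panel[panel$year == year_end, c("location", "outcome")]
  if (!setequal(a$location, b$location)) {
    stop("every location must appear in both years")
  }
  out <- dplyr::inner_join(
    dplyr::rename(a, value_start = "outcome"),
    dplyr::rename(b, value_end = "outcome"),
    by = "location"
  )
  out$delta <- out$value_end - out$value_start
  out[order(-out$delta, out$location), ]
}

#' Top or bottom locations by value
#'
#' @param values Named numeric vector (names are locations) or a two-column
#'   data frame (`location`, `value`).
#' @param k Number of locations to return (<= length of input).
#' @param direction `"lowest"` or `"highest"`.
#' @return Tibble `location`, `value`, ties broken alphabetically; stable
#'   across runs.
#' @export
rank_extremes <- function(values, k, direction = c("lowest", "highest")) {
  direction <- match.arg(direction)
  if (is.data.frame(values)) {
    df <- tibble::tibble(location = as.character(values[[1]]),
                         value = as.numeric(values[[2]]))
  } else {
    if (is.null(names(values))) stop("values must be named by location")
    df <- tibble::tibble(location = names(values), value = as.numeric(values))
  }
  if (nrow(df) == 0L) stop("empty input")
  if (k > nrow(df)) stop("k exceeds the number of locations")
  ord <- if (direction == "lowest") order(df$value, df$location)
         else order(-df$value, df$location)
  df[ord, ][seq_len(k), ]
}

#' Standardized mean difference between two samples
#'
#' Cohen's d with the pooled sample standard deviation:
#' \deqn{(\bar x_{end} - \bar x_{start}) / s_p,\quad
#'   s_p = \sqrt{\frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}}}
#' Used to summarize how much a risk-factor exposure distribution moved
#' between periods (e.g. high body-mass index SEVs shifting by about one
#' pooled SD over three decades).
#'
#' @param values_start,values_end Numeric vectors with at least 2 finite
#'   values each.
#' @return The signed standardized mean difference; 0 when both means and the
#'   pooled SD are zero-difference degenerate.
#' @export
standardized_mean_difference <- function(values_start, values_end) {
  for (v in list(values_start, values_end)) {
    if (length(v) < 2 || any(!is.finite(v))) {
      stop("each sample needs at least 2 finite values")
    }
  }
  n1 <- length(values_start); n2 <- length(values_end)
  s1 <- stats::var(values_start); s2 <- stats::var(values_end)
  sp <- sqrt(((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2))
  dm <- mean(values_end) - mean(values_start)
  if (sp == 0) {
    if (dm == 0) return(0)
    stop("pooled SD is zero with unequal means: standardized mean difference is infinite")
  }
  dm / sp
}

#' Between-period summary of every covariate
#'
#' @param panel Analysis panel tibble.
#' @param year_start,year_end The two years (default panel min/max).
#' @return Tibble `covariate`, `mean_start`, `sd_start`, `mean_end`, `sd_end`,
#'   `smd`, ordered alphabetically by covariate.
#' @export
covariate_summary <- function(panel, year_start = min(panel$year),
                              year_end = max(panel$year)) {
  check_panel(panel)
  covs <- sort(panel_covariates(panel))
  rows <- lapply(covs, function(cv) {
    a <- panel[[cv]][panel$year == year_start]
    b <- panel[[cv]][panel$year == year_end]
    tibble::tibble(
      covariate = cv,
      mean_start = mean(a), sd_start = stats::sd(a),
      mean_end = mean(b), sd_end = stats::sd(b),
      smd = standardized_mean_difference(a, b)
    )
  })
  dplyr::bind_rows(rows)
}
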