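#' Covariate columns of an analysis panel
#'
#' An analysis panel is a tidy tibble with one row per (location, year): the
#' columns `location`, `year`, `outcome`, and one numeric column per covariate.
#' This accessor returns the covariate column names in panel order.
#'
#' @param panel Analysis panel tibble.
#' @return Character vector of covariate column names.
#' @export
panel_covariates <- function(panel) {
  setdiff(names(panel), c("location", "year", "outcome"))
}

# Design matrix (intercept + covariates) and outcome for one year of a panel.
panel_design <- function(panel, year) {
  rows <- panel[panel$year == year, , drop = FALSE]
  if (nrow(rows) == 0L) stop("panel has no rows for year ", year)
  covs <- panel_covariates(panel)
  x <- cbind(`(Intercept)` = rep(1, nrow(rows)),
             as.matrix(rows[, covs, drop = FALSE]))
  list(x = x, y = rows$outcome, location = rows$location)
}

check_panel <- function(panel) {
  need <- c("location", "year", "outcome")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(panel)) stop("panel contains missing values; build it complete-case")
  if (any(panel$outcome < 0)) stop("panel outcome must be non-negative")
  dup <- duplicated(panel[, c("location", "year")])
  if (any(dup)) {
    stop("duplicate (location, year) in panel: ",
         paste(panel$location[dup][1], panel$year[dup][1]))
  }
  invisible(panel)
}
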