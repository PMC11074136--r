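# Shared fixture builders; everything is generated in code.

# Small hand-assembled two-period panel with given outcome values.
make_panel <- function(locations, y_start, y_end, covs_start, covs_end,
                       years = c(1990L, 2019L)) {
  stopifnot(length(y_start) == length(locations))
  dplyr::bind_rows(
    tibble::tibble(location = locations, year = years[1], outcome = y_start,
                   tibble::as_tibble(covs_start)),
    tibble::tibble(location = locations, year = years[2], outcome = y_end,
                   tibble::as_tibble(covs_end))
  )
}

# Random synthetic spec with n_cov covariates and modest effect sizes,
# for property-style loops.
random_spec <- function(n_cov = 5, n_locations = 200L, seed = 1L,
                        sigma = 0.25) {
  set.seed(seed)
  covs <- list()
  beta_s <- c(`(Intercept)` = stats::runif(1, -0.5, 0.5))
  beta_e <- c(`(Intercept)` = beta_s[[1]] + stats::runif(1, -0.2, 0.2))
  for (k in seq_len(n_cov)) {
    nm <- paste0("x", k)
    m1 <- stats::runif(1, 5, 20)
    covs[[nm]] <- covariate_spec(m1, m1 + stats::runif(1, -4, 6),
                                 sd = stats::runif(1, 2, 8), lower = 0,
                                 upper = 100)
    b <- stats::runif(1, -0.03, 0.03)
    beta_s[nm] <- b
    beta_e[nm] <- b + stats::runif(1, -0.01, 0.01)
  }
  synthetic_spec(n_locations, covs, beta_s, beta_e,
                 noise = list(type = "lognormal", sigma = sigma),
                 seed = seed)
}

# Write a small GBD-results-tool-style CSV and return its path.
write_gbd_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile("gbd", tmpdir = dir, fileext = ".csv")
  writeLines(lines, path)
  path
}

# CSV lines in the GBD results-tool layout (vectorized over rows).
gbd_lines <- function(location, year, val, metric = "Rate", sex = "Both",
                      age = "Age-standardized", location_col = "location_name") {
  header <- paste(location_col, "sex_name", "age_name", "metric_name",
                  "year", "val", sep = ",")
  c(header, paste(location, sex, age, metric, year, val, sep = ","))
}
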