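#' Build a pipeline run configuration
#'
#' Collects everything one end-to-end run needs: where the data come from
#' (GBD-style CSV extracts, or the synthetic generator), which burden measures
#' to analyze, the covariate set, the two analysis years, and the inference
#' method. In real mode `measures` maps measure names to rate CSV paths and
#' `covariates` maps covariate names to SEV/SDI CSV paths. In synthetic mode a
#' [synthetic_spec()] (or a YAML file describing one) replaces the inputs, and
#' a panel is generated per measure from consecutive sub-seeds.
#'
#' When `sdi_covariate` names one of the covariates, each measure is
#' decomposed twice: once with the risk-factor set excluding it
#' (model `"base"`) and once with the full set (model `"with_sdi"`), so the
#' contrast between the two models is reported side by side.
#'
#' @param mode `"real"` or `"synthetic"`.
#' @param out_dir Output directory (created if needed).
#' @param measures Real mode: named list of rate CSV paths. Synthetic mode:
#'   character vector of measure names (default `"ASIR"`).
#' @param covariates Real mode: named list of covariate CSV paths.
#' @param covariate_ranges Optional named list of `c(lower, upper)` validation
#'   ranges forwarded to [build_panel()].
#' @param spec Synthetic mode: a `synthetic_spec`, or path to a YAML file, or
#'   `NULL` for [gbd_like_spec()].
#' @param reference_year,comparison_year Analysis years (2019 vs 1990 by
#'   default).
#' @param inference `"delta"` or `"bootstrap"`.
#' @param bootstrap_reps,seed Inference settings.
#' @param sdi_covariate Name of the development-index covariate used for the
#'   two-model contrast, or `NULL` to run a single model.
#' @param reverse Also run the group-swap diagnostic (reference and comparison
#'   years exchanged) and write it alongside, labelled `"reversed"`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "real"), out_dir,
                       measures = "ASIR", covariates = NULL,
                       covariate_ranges = NULL, spec = NULL,
                       reference_year = 2019, comparison_year = 1990,
                       inference = c("delta", "bootstrap"),
                       bootstrap_reps = 1000L, seed = 1L,
                       sdi_covariate = NULL, reverse = FALSE) {
  mode <- match.arg(mode)
  inference <- match.arg(inference)
  if (reference_year == comparison_year) {
    stop("config invalid: reference_year must differ from comparison_year")
  }
  if (length(measures) == 0L) stop("config invalid: measures is empty")
  if (mode == "real") {
    if (is.null(names(measures)) || any(names(measures) == "")) {
      stop("config invalid: in real mode 'measures' must map names to CSV paths")
    }
    if (is.null(covariates) || is.null(names(covariates))) {
      stop("config invalid: in real mode 'covariates' must map names to CSV paths")
    }
  } else {
    if (is.character(spec)) spec <- read_synthetic_spec(spec)
    if (is.null(spec)) spec <- gbd_like_spec(seed = seed)
    stopifnot(inherits(spec, "synthetic_spec"))
  }
  structure(
    list(mode = mode, out_dir = out_dir, measures = measures,
         covariates = covariates, covariate_ranges = covariate_ranges,
         spec = spec, reference_year = reference_year,
         comparison_year = comparison_year, inference = inference,
         bootstrap_reps = as.integer(bootstrap_reps), seed = as.integer(seed),
         sdi_covariate = sdi_covariate, reverse = isTRUE(reverse)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Read a synthetic spec from YAML
#'
#' @param path YAML file with fields `n_locations`, `covariates` (each a map
#'   with `mean_start`, `mean_end`, `sd`, `lower`, `upper`), `beta_start`,
#'   `beta_end` (maps including `intercept`), `noise`, `years`, `seed`.
#' @return A `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path)
  y <- yaml::read_yaml(path)
  covs <- lapply(y$covariates, function(cs) {
    covariate_spec(cs$mean_start, cs$mean_end, cs$sd,
                   cs$lower %||% -Inf, cs$upper %||% Inf)
  })
  to_beta <- function(b) {
    v <- unlist(b)
    names(v)[names(v) == "intercept"] <- "(Intercept)"
    v
  }
  synthetic_spec(
    n_locations = y$n_locations, covariates = covs,
    beta_start = to_beta(y$beta_start), beta_end = to_beta(y$beta_end),
    noise = y$noise %||% list(type = "lognormal", sigma = 0.3),
    years = unlist(y$years) %||% c(1990L, 2019L),
    seed = y$seed %||% 1L
  )
}

# Overall-table rows (Table-1 shape) for one decomposition.
overall_rows <- function(measure, model, res) {
  tibble::tibble(
    measure = measure,
    model = model,
    component = c("Endowments", "Coefficients", "Mean difference"),
    coefficient = c(res$E, res$C, res$total_difference),
    ci_low = c(res$ci_E[1], res$ci_C[1], res$ci_total[1]),
    ci_high = c(res$ci_E[2], res$ci_C[2], res$ci_total[2]),
    p_value = c(res$p_E, res$p_C, res$p_total),
    percent = c(res$pct_E, res$pct_C, NA_real_),
    mean_reference = res$mean_reference,
    mean_comparison = res$mean_comparison
  )
}

detail_rows <- function(measure, model, res) {
  d <- res$detail
  tibble::tibble(measure = measure, model = model, d)
}

#' Run the full decomposition pipeline
#'
#' Executes, per measure: data ingest (or synthetic generation), descriptive
#' statistics, per-period quasi-Poisson fits with adjusted rate ratios, and
#' the endowment/coefficient decomposition with inference — once on the
#' risk-factor covariate set and once adding the development-index covariate
#' when configured. Writes deterministic CSVs to `config$out_dir`:
#' `panel_<measure>.csv`, `delta_change_<measure>.csv`,
#' `covariate_summary_<measure>.csv`, `adjusted_effects_<measure>.csv`,
#' `decomposition_overall.csv`, `decomposition_detail.csv`, and `run_log.txt`.
#' Identical configuration and seed produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the panels, decomposition objects, and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("ratedecomp ", as.character(utils::packageVersion("ratedecomp"))),
    paste0("R ", getRversion()),
    paste0("mode: ", config$mode),
    paste0("seed: ", config$seed),
    paste0("inference: ", config$inference),
    paste0("years: ", config$comparison_year, " -> ", config$reference_year)
  )

  measure_names <- if (config$mode == "real") names(config$measures) else config$measures
  panels <- list()
  for (i in seq_along(measure_names)) {
    m <- measure_names[i]
    if (config$mode == "real") {
      rate_rows <- read_gbd_csv(config$measures[[m]], "Rate")
      cov_rows <- lapply(config$covariates, function(p) {
        read_gbd_csv(p, expected_metric = "Rate")
      })
      panel <- build_panel(rate_rows, cov_rows,
                           years = c(config$comparison_year, config$reference_year),
                           covariate_ranges = config$covariate_ranges)
      log_lines <- c(log_lines, paste0("excluded_", m, ": ",
                                       length(attr(panel, "excluded"))))
    } else {
      panel <- generate_panel(config$spec, seed = config$seed + i - 1L)
    }
    panels[[m]] <- panel
    log_lines <- c(log_lines,
                   paste0("locations_", m, ": ", length(unique(panel$location))))
  }

  overall <- list()
  detail <- list()
  results <- list()
  for (m in measure_names) {
    panel <- panels[[m]]
    write_panel_csv(panel, file.path(config$out_dir, paste0("panel_", m, ".csv")))
    readr::write_csv(delta_change(panel),
                     file.path(config$out_dir, paste0("delta_change_", m, ".csv")))
    readr::write_csv(covariate_summary(panel),
                     file.path(config$out_dir, paste0("covariate_summary_", m, ".csv")))

    covs <- panel_covariates(panel)
    model_sets <- list()
    if (!is.null(config$sdi_covariate) && config$sdi_covariate %in% covs) {
      model_sets$base <- setdiff(covs, config$sdi_covariate)
      model_sets$with_sdi <- covs
    } else {
      model_sets$base <- covs
    }

    effects <- list()
    for (model in names(model_sets)) {
      sub <- panel[, c("location", "year", "outcome", sort(model_sets[[model]]))]
      res <- decompose(sub,
                       reference_year = config$reference_year,
                       comparison_year = config$comparison_year,
                       inference = config$inference,
                       bootstrap_reps = config$bootstrap_reps,
                       seed = config$seed)
      results[[paste(m, model, sep = ".")]] <- res
      overall[[paste(m, model)]] <- overall_rows(m, model, res)
      detail[[paste(m, model)]] <- detail_rows(m, model, res)
      for (side in c("reference", "comparison")) {
        yr <- if (side == "reference") config$reference_year else config$comparison_year
        effects[[paste(model, yr)]] <- tibble::tibble(
          model = model, year = yr, rate_ratios(res$fits[[side]])
        )
      }
      if (config$reverse) {
        rev_res <- decompose(sub,
                             reference_year = config$comparison_year,
                             comparison_year = config$reference_year,
                             inference = config$inference,
                             bootstrap_reps = config$bootstrap_reps,
                             seed = config$seed)
        overall[[paste(m, model, "reversed")]] <-
          overall_rows(m, paste0(model, "_reversed"), rev_res)
        detail[[paste(m, model, "reversed")]] <-
          detail_rows(m, paste0(model, "_reversed"), rev_res)
      }
    }
    readr::write_csv(dplyr::bind_rows(effects),
                     file.path(config$out_dir, paste0("adjusted_effects_", m, ".csv")))
  }

  overall_path <- file.path(config$out_dir, "decomposition_overall.csv")
  detail_path <- file.path(config$out_dir, "decomposition_detail.csv")
  readr::write_csv(dplyr::bind_rows(overall), overall_path)
  readr::write_csv(dplyr::bind_rows(detail), detail_path)
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(panels = panels, results = results,
                 paths = list(overall = overall_path, detail = detail_path,
                              out_dir = config$out_dir)))
}

#' Rounded Table-1-style summary of an overall decomposition table
#'
#' @param overall Tibble from `decomposition_overall.csv` / [run_pipeline()].
#' @param digits Decimal places (default 2, matching the usual presentation).
#' @return Tibble with rounded coefficient, CI, percentage, and a formatted
#'   p-value column.
#' @export
format_overall_table <- function(overall, digits = 2) {
  tibble::tibble(
    measure = overall$measure,
    model = overall$model,
    component = overall$component,
    coefficient = round(overall$coefficient, digits),
    ci = sprintf("%.*f, %.*f", digits, overall$ci_low, digits, overall$ci_high),
    p_value = ifelse(is.na(overall$p_value), "",
                     format.pval(overall$p_value, digits = 2, eps = 1e-3)),
    percent = round(overall$percent, digits)
  )
}
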