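#' Decompose a between-period rate difference into endowment and coefficient parts
#'
#' Splits the difference in mean rates between a reference period and a
#' comparison period into an endowment component E (differences in covariate
#' distributions, the "explained" part) and a coefficient component C
#' (differences in covariate-outcome associations, the "unexplained" part),
#' using the counterfactual means of the log-link Poisson model fitted
#' separately to each period:
#' \deqn{E = \overline{F(X_{ref}\beta_{ref})} - \overline{F(X_{cmp}\beta_{ref})}}
#' \deqn{C = \overline{F(X_{cmp}\beta_{ref})} - \overline{F(X_{cmp}\beta_{cmp})}}
#' with \eqn{F = \exp} and each mean taken over the locations observed in that
#' period. Because the Poisson score equations force the fitted mean to match
#' the observed mean in each period, \eqn{E + C} telescopes exactly to the
#' difference of observed mean rates.
#'
#' Each component is then attributed to individual covariates through the
#' normalized weight linearization (see [detailed_weights()]), which is
#' invariant to the order in which covariates enter the model. The intercept
#' carries its own line in the coefficient part (its mean covariate value is 1)
#' and contributes nothing to the endowment part.
#'
#' Percentages of the total may legitimately exceed 100 or be negative when E
#' and C have opposite signs; they are never clipped. When `|E + C|` is
#' indistinguishable from zero the percentages are undefined and reported as
#' `NA` with `degenerate_percentages = TRUE`.
#'
#' @param panel Analysis panel tibble (columns `location`, `year`, `outcome`,
#'   covariates) containing exactly the two requested years.
#' @param reference_year Year whose coefficients anchor the endowment
#'   counterfactual (default 2019).
#' @param comparison_year Year whose covariate distribution anchors the
#'   coefficient counterfactual (default 1990).
#' @param inference `"delta"` (default), `"bootstrap"`, or `"none"`. Passed to
#'   [decomposition_inference()].
#' @param dispersion Dispersion mode for the per-period fits; see
#'   [fit_poisson_glm()].
#' @param bootstrap_reps,seed Bootstrap settings when `inference = "bootstrap"`.
#'
#' @return An object of class `rate_decomposition`: a list holding
#'   `mean_reference`, `mean_comparison`, `total_difference`, `E`, `C`,
#'   `pct_E`, `pct_C`, standard errors / CIs / p-values (when inference was
#'   run), a `detail` tibble with one row per term (intercept and covariates:
#'   weights, `E_k`, `C_k`, their uncertainty, and percentages of the total),
#'   and the two period fits under `fits`.
#' @seealso [detailed_weights()], [decomposition_inference()]
#' @export
decompose <- function(panel, reference_year = 2019, comparison_year = 1990,
                      inference = c("delta", "bootstrap", "none"),
                      dispersion = c("pearson", "fixed"),
                      bootstrap_reps = 1000L, seed = NULL) {
  inference <- match.arg(inference)
  dispersion <- match.arg(dispersion)
  check_panel(panel)
  if (reference_year == comparison_year) {
    stop("reference_year and comparison_year must differ")
  }
  years <- sort(unique(panel$year))
  if (!all(c(reference_year, comparison_year) %in% years)) {
    stop("panel must contain both ", reference_year, " and ", comparison_year)
  }

  ref <- panel_design(panel, reference_year)
  cmp <- panel_design(panel, comparison_year)
  if (!identical(colnames(ref$x), colnames(cmp$x))) {
    stop("the two periods must share the same covariate columns")
  }

  fit_ref <- fit_poisson_glm(ref$x, ref$y, dispersion = dispersion)
  fit_cmp <- fit_poisson_glm(cmp$x, cmp$y, dispersion = dispersion)
  if (!fit_ref$converged || !fit_cmp$converged) {
    stop("period regression did not converge; decomposition aborted")
  }

  terms <- decomp_point(fit_ref$beta, fit_cmp$beta, ref$x, cmp$x)

  res <- structure(
    list(
      reference_year = reference_year,
      comparison_year = comparison_year,
      mean_reference = mean(ref$y),
      mean_comparison = mean(cmp$y),
      total_difference = terms$E + terms$C,
      E = terms$E, C = terms$C,
      pct_E = terms$pct_E, pct_C = terms$pct_C,
      degenerate_percentages = terms$degenerate_percentages,
      se_E = NA_real_, se_C = NA_real_, se_total = NA_real_,
      ci_E = c(NA_real_, NA_real_), ci_C = c(NA_real_, NA_real_),
      ci_total = c(NA_real_, NA_real_),
      p_E = NA_real_, p_C = NA_real_, p_total = NA_real_,
      detail = terms$detail,
      fits = list(reference = fit_ref, comparison = fit_cmp),
      design = list(reference = ref, comparison = cmp),
      inference = "none"
    ),
    class = "rate_decomposition"
  )
  if (inference != "none") {
    res <- decomposition_inference(res, method = inference,
                                   bootstrap_reps = bootstrap_reps, seed = seed)
  }
  res
}

# Point decomposition given coefficients and the two design matrices.
# Returns E, C, percentages, and the per-term detail tibble.
decomp_point <- function(beta_ref, beta_cmp, x_ref, x_cmp) {
  t_rr <- mean(exp(drop(x_ref %*% beta_ref)))
  t_cr <- mean(exp(drop(x_cmp %*% beta_ref)))
  t_cc <- mean(exp(drop(x_cmp %*% beta_cmp)))
  E <- t_rr - t_cr
  C <- t_cr - t_cc
  total <- E + C

  degenerate <- abs(total) < 1e-12 * max(1, abs(E) + abs(C))
  pct_E <- if (degenerate) NA_real_ else 100 * E / total
  pct_C <- if (degenerate) NA_real_ else 100 * C / total

  xbar_ref <- colMeans(x_ref)
  xbar_cmp <- colMeans(x_cmp)
  w <- tryCatch(
    detailed_weights(beta_ref, xbar_ref, beta_cmp, xbar_cmp),
    error = function(e) {
      tibble::tibble(term = names(beta_ref),
                     weight_E = NA_real_, weight_C = NA_real_)
    }
  )
  detail <- tibble::tibble(
    term = w$term,
    weight_E = w$weight_E,
    weight_C = w$weight_C,
    E_k = w$weight_E * E,
    C_k = w$weight_C * C,
    se_Ek = NA_real_, se_Ck = NA_real_,
    ci_Ek_low = NA_real_, ci_Ek_high = NA_real_,
    ci_Ck_low = NA_real_, ci_Ck_high = NA_real_,
    p_Ek = NA_real_, p_Ck = NA_real_,
    pct_Ek = if (degenerate) NA_real_ else 100 * w$weight_E * E / total,
    pct_Ck = if (degenerate) NA_real_ else 100 * w$weight_C * C / total
  )
  list(E = E, C = C, pct_E = pct_E, pct_C = pct_C,
       degenerate_percentages = degenerate, detail = detail,
       terms = c(t_rr = t_rr, t_cr = t_cr, t_cc = t_cc))
}

#' Normalized attribution weights for the detailed decomposition
#'
#' Linearizes the endowment and coefficient components over covariates:
#' \deqn{W_{\Delta X_k} = \beta_{ref,k}(\bar X_{ref,k} - \bar X_{cmp,k})
#'   \big/ \sum_j \beta_{ref,j}(\bar X_{ref,j} - \bar X_{cmp,j})}
#' \deqn{W_{\Delta\beta_k} = \bar X_{ref,k}(\beta_{ref,k} - \beta_{cmp,k})
#'   \big/ \sum_j \bar X_{ref,j}(\beta_{ref,j} - \beta_{cmp,j})}
#' Each weight set sums to one, and the attribution does not depend on the
#' order in which covariates enter the model. The intercept (mean value 1 in
#' both periods) contributes zero to the endowment weights and enters the
#' coefficient weights like any other term.
#'
#' @param beta_ref,beta_cmp Named coefficient vectors (intercept first) from
#'   the reference- and comparison-period fits.
#' @param xbar_ref,xbar_cmp Mean design rows for the two periods (the intercept
#'   entry is 1).
#' @return A tibble with columns `term`, `weight_E`, `weight_C`.
#' @export
detailed_weights <- function(beta_ref, xbar_ref, beta_cmp, xbar_cmp) {
  k <- length(beta_ref)
  if (length(beta_cmp) != k || length(xbar_ref) != k || length(xbar_cmp) != k) {
    stop("coefficient and mean-covariate vectors must have equal length")
  }
  num_e <- beta_ref * (xbar_ref - xbar_cmp)
  num_c <- xbar_ref * (beta_ref - beta_cmp)
  den_e <- sum(num_e)
  den_c <- sum(num_c)
  scale_e <- max(1, sum(abs(num_e)))
  scale_c <- max(1, sum(abs(num_c)))
  if (abs(den_e) < 1e-12 * scale_e) {
    stop("degenerate decomposition direction: endowment weight denominator is zero")
  }
  if (abs(den_c) < 1e-12 * scale_c) {
    stop("degenerate decomposition direction: coefficient weight denominator is zero")
  }
  tibble::tibble(
    term = names(beta_ref) %||% paste0("term", seq_len(k)),
    weight_E = unname(num_e / den_e),
    weight_C = unname(num_c / den_c)
  )
}

#' Attach uncertainty to a decomposition
#'
#' Fills the standard errors, 95% confidence intervals and p-values of the
#' overall components (E, C, total) and of every per-covariate contribution
#' (`E_k`, `C_k`).
#'
#' With `method = "delta"` the sampling variance of every component is
#' assembled from per-location influence functions: each location's influence
#' on its period's coefficient vector (empirical-residual sandwich form, so
#' overdispersion is absorbed) is mapped through the beta-gradient of the
#' decomposition, and its direct influence on the empirical counterfactual
#' and covariate means enters at fixed coefficients. Gradients are evaluated
#' numerically by central differences. This targets the same variance as
#' resampling locations; `design_variation = FALSE` instead propagates only
#' the model-based coefficient covariances with covariates held fixed.
#' P-values are two-sided normal. With `method = "bootstrap"`
#' locations are resampled with replacement independently within each period,
#' the full decomposition is recomputed per replicate, and percentile CIs with
#' bootstrap-SE normal p-values are reported. Replicates with a non-convergent
#' fit are dropped (more than 10% dropped is an error).
#'
#' @param result A `rate_decomposition` from [decompose()].
#' @param method `"delta"` or `"bootstrap"`.
#' @param bootstrap_reps Number of bootstrap replicates.
#' @param seed Integer seed for the bootstrap resampling.
#' @param design_variation Delta method only: include the within-period
#'   sampling variability of the covariate distributions (influence-function
#'   form, the default, which targets the same variance as the location
#'   bootstrap), or `FALSE` to propagate only the model-based coefficient
#'   covariances with covariate values treated as fixed.
#' @return The input object with uncertainty fields filled and
#'   `inference` set to the method used.
#' @export
decomposition_inference <- function(result, method = c("delta", "bootstrap"),
                                    bootstrap_reps = 1000L, seed = NULL,
                                    design_variation = TRUE) {
  stopifnot(inherits(result, "rate_decomposition"))
  method <- match.arg(method)
  if (method == "delta") {
    result <- delta_inference(result, design_variation = design_variation)
  } else {
    result <- bootstrap_inference(result, bootstrap_reps, seed)
  }
  result$inference <- method
  result
}

# Delta method for the decomposition components.
#
# With design_variation = TRUE (default) the variance is assembled from
# per-location influence functions, independent across the two periods:
# each location contributes (a) its influence on that period's coefficient
# vector (empirical-residual / sandwich form, so overdispersion is absorbed)
# mapped through the beta-gradient of the decomposition, and (b) its direct
# influence on the empirical counterfactual means and covariate means at
# fixed coefficients. This targets the same sampling variance as resampling
# locations within each period. With design_variation = FALSE the classic
# fixed-covariate propagation of the two model-based coefficient covariance
# matrices is used instead.
delta_inference <- function(result, design_variation = TRUE) {
  x_ref <- result$design$reference$x
  x_cmp <- result$design$comparison$x
  y_ref <- result$design$reference$y
  y_cmp <- result$design$comparison$y
  p <- ncol(x_ref)
  n_ref <- nrow(x_ref)
  n_cmp <- nrow(x_cmp)
  b_ref <- result$fits$reference$beta
  b_cmp <- result$fits$comparison$beta
  mu_ref <- result$fits$reference$fitted
  mu_cmp <- result$fits$comparison$fitted
  have_detail <- !anyNA(result$detail$weight_E)

  xbar_r <- colMeans(x_ref)
  xbar_c <- colMeans(x_cmp)
  f_r_br <- exp(drop(x_ref %*% b_ref))
  f_c_br <- exp(drop(x_cmp %*% b_ref))
  f_c_bc <- exp(drop(x_cmp %*% b_cmp))
  m_rr <- mean(f_r_br)
  m_cr <- mean(f_c_br)
  m_cc <- mean(f_c_bc)

  # decomposition map from means and coefficients to the reported components
  core <- function(br, bc, mrr, mcr, mcc, xr, xc) {
    E <- mrr - mcr
    C <- mcr - mcc
    out <- c(E, C, E + C)
    if (have_detail) {
      num_e <- br * (xr - xc)
      num_c <- xr * (br - bc)
      out <- c(out, num_e / sum(num_e) * E, num_c / sum(num_c) * C)
    }
    out
  }

  # beta-gradient with the empirical distributions held fixed
  g_beta <- function(theta) {
    br <- theta[seq_len(p)]
    bc <- theta[p + seq_len(p)]
    core(br, bc,
         mean(exp(drop(x_ref %*% br))),
         mean(exp(drop(x_cmp %*% br))),
         mean(exp(drop(x_cmp %*% bc))),
         xbar_r, xbar_c)
  }
  j_beta <- pracma::jacobian(g_beta, c(b_ref, b_cmp))
  jb_r <- j_beta[, seq_len(p), drop = FALSE]
  jb_c <- j_beta[, p + seq_len(p), drop = FALSE]

  if (design_variation) {
    # distribution-gradient with the coefficients held fixed
    g_dist <- function(v) {
      core(b_ref, b_cmp, v[1], v[2], v[3],
           v[3 + seq_len(p)], v[3 + p + seq_len(p)])
    }
    j_dist <- pracma::jacobian(g_dist, c(m_rr, m_cr, m_cc, xbar_r, xbar_c))

    # coefficient influence per location, empirical residuals
    ainv_r <- chol2inv(chol(crossprod(x_ref * sqrt(mu_ref))))
    ainv_c <- chol2inv(chol(crossprod(x_cmp * sqrt(mu_cmp))))
    infl_br <- n_ref * (x_ref * (y_ref - mu_ref)) %*% ainv_r
    infl_bc <- n_cmp * (x_cmp * (y_cmp - mu_cmp)) %*% ainv_c

    psi_ref <- infl_br %*% t(jb_r) +
      cbind(f_r_br - m_rr, sweep(x_ref, 2, xbar_r)) %*%
        t(j_dist[, c(1, 3 + seq_len(p)), drop = FALSE])
    psi_cmp <- infl_bc %*% t(jb_c) +
      cbind(f_c_br - m_cr, f_c_bc - m_cc, sweep(x_cmp, 2, xbar_c)) %*%
        t(j_dist[, c(2, 3, 3 + p + seq_len(p)), drop = FALSE])
    variance <- colSums(psi_ref^2) / n_ref^2 + colSums(psi_cmp^2) / n_cmp^2
    se <- sqrt(pmax(0, variance))
  } else {
    v <- matrix(0, 2 * p, 2 * p)
    v[seq_len(p), seq_len(p)] <- result$fits$reference$covariance
    v[p + seq_len(p), p + seq_len(p)] <- result$fits$comparison$covariance
    se <- sqrt(pmax(0, diag(j_beta %*% v %*% t(j_beta))))
  }

  est <- core(b_ref, b_cmp, m_rr, m_cr, m_cc, xbar_r, xbar_c)
  z <- ifelse(se > 0, est / se, 0)
  pval <- 2 * stats::pnorm(-abs(z))
  lo <- est - 1.96 * se
  hi <- est + 1.96 * se

  result$se_E <- se[[1]]; result$se_C <- se[[2]]; result$se_total <- se[[3]]
  result$ci_E <- c(lo[[1]], hi[[1]])
  result$ci_C <- c(lo[[2]], hi[[2]])
  result$ci_total <- c(lo[[3]], hi[[3]])
  result$p_E <- pval[[1]]; result$p_C <- pval[[2]]; result$p_total <- pval[[3]]
  if (have_detail) {
    idx_e <- 3 + seq_len(p)
    idx_c <- 3 + p + seq_len(p)
    result$detail$se_Ek <- se[idx_e]
    result$detail$se_Ck <- se[idx_c]
    result$detail$ci_Ek_low <- lo[idx_e]
    result$detail$ci_Ek_high <- hi[idx_e]
    result$detail$ci_Ck_low <- lo[idx_c]
    result$detail$ci_Ck_high <- hi[idx_c]
    result$detail$p_Ek <- pval[idx_e]
    result$detail$p_Ck <- pval[idx_c]
  }
  result
}

bootstrap_inference <- function(result, bootstrap_reps, seed) {
  if (!is.null(seed)) set.seed(seed)
  ref <- result$design$reference
  cmp <- result$design$comparison
  p <- ncol(ref$x)
  n_ref <- nrow(ref$x)
  n_cmp <- nrow(cmp$x)
  have_detail <- !anyNA(result$detail$weight_E)
  n_out <- 3L + if (have_detail) 2L * p else 0L

  reps <- matrix(NA_real_, bootstrap_reps, n_out)
  dropped <- 0L
  for (b in seq_len(bootstrap_reps)) {
    i <- sample.int(n_ref, replace = TRUE)
    j <- sample.int(n_cmp, replace = TRUE)
    est <- tryCatch({
      fr <- suppressWarnings(fit_poisson_glm(ref$x[i, , drop = FALSE], ref$y[i]))
      fc <- suppressWarnings(fit_poisson_glm(cmp$x[j, , drop = FALSE], cmp$y[j]))
      if (!fr$converged || !fc$converged) stop("non-convergent replicate")
      pt <- decomp_point(fr$beta, fc$beta,
                         ref$x[i, , drop = FALSE], cmp$x[j, , drop = FALSE])
      out <- c(pt$E, pt$C, pt$E + pt$C)
      if (have_detail) {
        if (anyNA(pt$detail$weight_E)) stop("degenerate replicate")
        out <- c(out, pt$detail$E_k, pt$detail$C_k)
      }
      out
    }, error = function(e) NULL)
    if (is.null(est)) dropped <- dropped + 1L else reps[b, ] <- est
  }
  if (dropped > 0L) {
    message(dropped, " bootstrap replicate(s) dropped (non-convergent or degenerate)")
  }
  if (dropped > 0.1 * bootstrap_reps) {
    stop("more than 10% of bootstrap replicates failed (", dropped, " of ",
         bootstrap_reps, ")")
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]

  se <- apply(reps, 2, stats::sd)
  lo <- apply(reps, 2, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(reps, 2, stats::quantile, probs = 0.975, names = FALSE)
  est <- c(result$E, result$C, result$total_difference,
           if (have_detail) c(result$detail$E_k, result$detail$C_k))
  z <- ifelse(se > 0, est / se, 0)
  pval <- 2 * stats::pnorm(-abs(z))

  result$se_E <- se[[1]]; result$se_C <- se[[2]]; result$se_total <- se[[3]]
  result$ci_E <- c(lo[[1]], hi[[1]])
  result$ci_C <- c(lo[[2]], hi[[2]])
  result$ci_total <- c(lo[[3]], hi[[3]])
  result$p_E <- pval[[1]]; result$p_C <- pval[[2]]; result$p_total <- pval[[3]]
  if (have_detail) {
    idx_e <- 3 + seq_len(p)
    idx_c <- 3 + p + seq_len(p)
    result$detail$se_Ek <- se[idx_e]
    result$detail$se_Ck <- se[idx_c]
    result$detail$ci_Ek_low <- lo[idx_e]
    result$detail$ci_Ek_high <- hi[idx_e]
    result$detail$ci_Ck_low <- lo[idx_c]
    result$detail$ci_Ck_high <- hi[idx_c]
    result$detail$p_Ek <- pval[idx_e]
    result$detail$p_Ck <- pval[idx_c]
  }
  result$bootstrap_dropped <- dropped
  result
}

#' @export
print.rate_decomposition <- function(x, digits = 2, ...) {
  cat("Non-linear multivariate decomposition of mean rate difference\n")
  cat(sprintf("  Reference %d (mean %.*f) vs comparison %d (mean %.*f)\n",
              x$reference_year, digits, x$mean_reference,
              x$comparison_year, digits, x$mean_comparison))
  fmt <- function(est, ci, p, pct) {
    sprintf("%8.*f  [%.*f, %.*f]  p=%s  %s", digits, est, digits, ci[1],
            digits, ci[2],
            ifelse(is.na(p), "NA", format.pval(p, digits = 2, eps = 1e-3)),
            ifelse(is.na(pct), "", sprintf("%6.2f%%", pct)))
  }
  cat("  Endowments  ", fmt(x$E, x$ci_E, x$p_E, x$pct_E), "\n", sep = "")
  cat("  Coefficients", fmt(x$C, x$ci_C, x$p_C, x$pct_C), "\n", sep = "")
  cat("  Difference  ", fmt(x$total_difference, x$ci_total, x$p_total, NA), "\n",
      sep = "")
  cat("  Inference:", x$inference, "\n")
  invisible(x)
}

#' Tidy per-covariate decomposition detail
#'
#' @param result A `rate_decomposition`.
#' @return The `detail` tibble: one row per term with weights, contributions,
#'   uncertainty and percentages of the total difference.
#' @export
decomposition_detail <- function(result) {
  stopifnot(inherits(result, "rate_decomposition"))
  result$detail
}
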