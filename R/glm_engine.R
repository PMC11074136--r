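#' Fit a log-link quasi-Poisson regression by IRLS
#'
#' Fits the rate model \eqn{E[Y \mid X] = \exp(X\beta + o)} by iteratively
#' reweighted least squares on the Poisson quasi-likelihood score. The outcome
#' may be any non-negative real vector (age-standardized rates per 100,000 are
#' the intended use), not only counts: the score equations are identical and
#' the point estimates are those of a Poisson GLM.
#'
#' The covariance of the coefficients is \eqn{\hat\phi (X^T W X)^{-1}} with the
#' dispersion \eqn{\hat\phi} estimated as Pearson chi-square over residual
#' degrees of freedom (`dispersion = "pearson"`, the default) or fixed at 1 for
#' strict-Poisson standard errors (`dispersion = "fixed"`). The choice affects
#' standard errors and p-values only, never the point estimates.
#'
#' @param x Design matrix; the first column must be an intercept of ones.
#'   Column names are used to label coefficients.
#' @param y Non-negative outcome vector, one value per row of `x`.
#' @param offset Optional offset on the log scale; defaults to zero for every
#'   observation (rates modelled directly, no exposure term).
#' @param tolerance Convergence tolerance on the relative deviance change.
#' @param max_iterations Maximum IRLS iterations before giving up.
#' @param dispersion `"pearson"` (quasi-Poisson) or `"fixed"` (dispersion 1).
#'
#' @return An object of class `poisson_fit`: a list with elements `beta`
#'   (named coefficient vector), `covariance`, `fitted` (vector of
#'   \eqn{\exp(X\hat\beta + o)}), `dispersion`, `converged`, `iterations`,
#'   `deviance`, `n`, and `df_residual`.
#' @export
#' @examples
#' x <- cbind(`(Intercept)` = 1, exposure = rnorm(50, 10, 2))
#' y <- exp(0.5 + 0.05 * x[, 2]) * exp(rnorm(50, 0, 0.2))
#' fit <- fit_poisson_glm(x, y)
#' rate_ratios(fit)
fit_poisson_glm <- function(x, y, offset = NULL, tolerance = 1e-10,
                            max_iterations = 100L,
                            dispersion = c("pearson", "fixed")) {
  dispersion <- match.arg(dispersion)
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- c("(Intercept)", paste0("x", seq_len(ncol(x) - 1L)))
  }
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (any(!is.finite(y)) || any(!is.finite(x))) {
    stop("design matrix and outcome must be finite")
  }
  if (any(y < 0)) stop("outcome must be non-negative")
  if (n <= p) stop("need more observations than coefficients (n > p)")
  if (any(x[, 1L] != 1)) stop("first column of the design must be an intercept of ones")
  if (is.null(offset)) offset <- rep(0, n)

  qx <- qr(x)
  if (qx$rank < p) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  # deviance of the (quasi-)Poisson model; y log y terms vanish at y = 0
  dev_fun <- function(mu) {
    tt <- rep(0, n)
    pos <- y > 0
    tt[pos] <- y[pos] * log(y[pos] / mu[pos])
    2 * sum(tt - (y - mu))
  }

  beta <- rep(0, p)
  names(beta) <- colnames(x)
  beta[1L] <- log(mean(y) + 1e-8)
  eta <- pmin(drop(x %*% beta) + offset, 700)
  mu <- exp(eta)
  dev <- dev_fun(mu)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iterations)) {
    w <- mu
    z <- (eta - offset) + (y - mu) / mu
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(x * sw), z * sw)
    eta <- pmin(drop(x %*% beta_new) + offset, 700)
    mu <- exp(eta)
    dev_new <- dev_fun(mu)
    rel <- abs(dev_new - dev) / (abs(dev_new) + 0.1)
    beta <- beta_new
    dev <- dev_new
    if (rel < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("IRLS did not converge in ", max_iterations, " iterations")
  names(beta) <- colnames(x)

  xtwx <- crossprod(x * sqrt(mu))
  phi <- if (dispersion == "pearson") sum((y - mu)^2 / mu) / (n - p) else 1
  vcov <- phi * chol2inv(chol(xtwx))
  dimnames(vcov) <- list(colnames(x), colnames(x))

  structure(
    list(beta = beta, covariance = vcov, fitted = mu, dispersion = phi,
         converged = converged, iterations = it, deviance = dev,
         n = n, df_residual = n - p),
    class = "poisson_fit"
  )
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat("Quasi-Poisson log-link fit:", length(x$beta), "coefficients,",
      x$n, "observations\n")
  cat("Converged:", x$converged, "in", x$iterations,
      "iterations; dispersion:", format(x$dispersion, digits = 4), "\n")
  se <- sqrt(diag(x$covariance))
  print(cbind(estimate = x$beta, se = se), ...)
  invisible(x)
}

#' Adjusted effects as rate ratios
#'
#' Exponentiates the slope coefficients of a fitted quasi-Poisson model into
#' rate ratios per unit of each covariate, with Wald 95% confidence intervals
#' \eqn{\exp(\hat\beta_k \pm 1.96\, se_k)} and two-sided normal p-values. The
#' intercept is omitted: it is the log baseline rate, not an effect.
#'
#' @param fit A `poisson_fit` from [fit_poisson_glm()].
#' @return A tibble with columns `covariate`, `rate_ratio`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
rate_ratios <- function(fit) {
  stopifnot(inherits(fit, "poisson_fit"))
  if (!fit$converged) stop("fit did not converge; rate ratios not reported")
  keep <- names(fit$beta) != "(Intercept)"
  covariate <- names(fit$beta)[keep]
  b <- unname(fit$beta[keep])
  se <- unname(sqrt(diag(fit$covariance))[keep])
  z <- ifelse(se > 0, b / se, 0)
  tibble::tibble(
    covariate = covariate,
    rate_ratio = exp(b),
    ci_low = exp(b - 1.96 * se),
    ci_high = exp(b + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z))
  )
}
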