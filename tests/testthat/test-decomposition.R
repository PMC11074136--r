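test_that("identical periods decompose to zero everywhere", {
  set.seed(1)
  x <- list(a = runif(30, 5, 15), b = runif(30, 0, 1))
  y <- exp(0.2 + 0.05 * x$a + 0.5 * x$b)
  panel <- make_panel(sprintf("L%02d", 1:30), y, y, x, x)
  res <- decompose(panel)
  expect_equal(res$E, 0, tolerance = 1e-8)
  expect_equal(res$C, 0, tolerance = 1e-8)
  expect_equal(res$total_difference, 0, tolerance = 1e-8)
  expect_true(res$degenerate_percentages)
  expect_true(is.na(res$pct_E))
  # null effects carry p-values near 1
  expect_gt(res$p_E, 0.99)
  expect_gt(res$p_C, 0.99)
})

test_that("identical covariates with different outcomes put everything in C", {
  set.seed(2)
  x <- list(a = runif(40, 5, 15))
  y1 <- exp(0.1 + 0.05 * x$a) * exp(rnorm(40, 0, 0.1))
  y2 <- y1 * 1.8
  panel <- make_panel(sprintf("L%02d", 1:40), y1, y2, x, x)
  res <- decompose(panel, inference = "none")
  expect_equal(res$E, 0, tolerance = 1e-8)
  expect_equal(res$C, res$total_difference, tolerance = 1e-8)
})

test_that("decompose equals a literal transcription of the counterfactual means", {
  panel <- generate_panel(random_spec(2, 120, seed = 33))
  res <- decompose(panel, inference = "none")

  # independent transcription: four counterfactual mean terms and the two
  # weight formulas, written out directly from the fitted coefficients
  d_ref <- list(x = cbind(1, as.matrix(panel[panel$year == 2019, 4:5])),
                y = panel$outcome[panel$year == 2019])
  d_cmp <- list(x = cbind(1, as.matrix(panel[panel$year == 1990, 4:5])),
                y = panel$outcome[panel$year == 1990])
  b_ref <- res$fits$reference$beta
  b_cmp <- res$fits$comparison$beta
  m_rr <- mean(exp(d_ref$x %*% b_ref))
  m_cr <- mean(exp(d_cmp$x %*% b_ref))
  m_cc <- mean(exp(d_cmp$x %*% b_cmp))
  E <- m_rr - m_cr
  C <- m_cr - m_cc
  expect_equal(res$E, E, tolerance = 1e-10)
  expect_equal(res$C, C, tolerance = 1e-10)

  xbar_ref <- colMeans(d_ref$x)
  xbar_cmp <- colMeans(d_cmp$x)
  we <- b_ref * (xbar_ref - xbar_cmp)
  we <- we / sum(we)
  wc <- xbar_ref * (b_ref - b_cmp)
  wc <- wc / sum(wc)
  expect_equal(res$detail$weight_E, unname(we), tolerance = 1e-10)
  expect_equal(res$detail$weight_C, unname(wc), tolerance = 1e-10)
  expect_equal(res$detail$E_k, unname(we * E), tolerance = 1e-10)
  expect_equal(res$detail$C_k, unname(wc * C), tolerance = 1e-10)
})

test_that("fits agree with the reference GLM inside the decomposition", {
  panel <- generate_panel(random_spec(3, 100, seed = 8))
  res <- decompose(panel, inference = "none")
  sub <- panel[panel$year == 2019, ]
  ref <- suppressWarnings(stats::glm(
    outcome ~ x1 + x2 + x3, data = sub,
    family = stats::quasipoisson(link = "log")
  ))
  expect_equal(unname(res$fits$reference$beta), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("detailed weights: normalization, hand case, and formula oracle", {
  # single covariate: its endowment weight is 1 by normalization
  w <- detailed_weights(c(`(Intercept)` = 0.5, a = 0.2),
                        c(`(Intercept)` = 1, a = 4),
                        c(`(Intercept)` = 0.3, a = 0.1),
                        c(`(Intercept)` = 1, a = 2))
  expect_equal(w$weight_E, c(0, 1))

  # K = 2 hand arithmetic: beta_ref slopes (1, 1), delta xbar (3, 1)
  w2 <- detailed_weights(c(`(Intercept)` = 0.2, a = 1, b = 1),
                         c(`(Intercept)` = 1, a = 8, b = 3),
                         c(`(Intercept)` = 0.1, a = 1, b = 0.5),
                         c(`(Intercept)` = 1, a = 5, b = 2))
  expect_equal(w2$weight_E, c(0, 0.75, 0.25))
  expect_equal(sum(w2$weight_C), 1, tolerance = 1e-12)

  # random 5-covariate vectors against a termwise transcription
  for (s in 1:5) {
    set.seed(400 + s)
    k <- 6
    br <- rnorm(k); bc <- rnorm(k)
    xr <- c(1, runif(k - 1, 1, 10)); xc <- c(1, runif(k - 1, 1, 10))
    names(br) <- names(bc) <- c("(Intercept)", paste0("v", 1:5))
    w <- detailed_weights(br, xr, bc, xc)
    expect_equal(w$weight_E, br * (xr - xc) / sum(br * (xr - xc)),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(w$weight_C, xr * (br - bc) / sum(xr * (br - bc)),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(sum(w$weight_E), 1, tolerance = 1e-12)
    expect_equal(sum(w$weight_C), 1, tolerance = 1e-12)
  }

  expect_error(
    detailed_weights(c(`(Intercept)` = 1, a = 1), c(1, 5), c(`(Intercept)` = 1, a = 1), c(1, 5)),
    "degenerate decomposition direction"
  )
})

test_that("additivity identities hold on random panels", {
  for (s in 1:5) {
    panel <- generate_panel(random_spec(4, 150, seed = 40 + s))
    res <- decompose(panel, inference = "none")
    scale <- abs(res$mean_reference - res$mean_comparison)
    expect_equal(res$E + res$C, res$mean_reference - res$mean_comparison,
                 tolerance = 1e-8 * max(1, scale))
    expect_equal(sum(res$detail$weight_E), 1, tolerance = 1e-12)
    expect_equal(sum(res$detail$weight_C), 1, tolerance = 1e-12)
    expect_equal(sum(res$detail$E_k), res$E, tolerance = 1e-10)
    expect_equal(sum(res$detail$C_k), res$C, tolerance = 1e-10)
    expect_equal(res$pct_E + res$pct_C, 100, tolerance = 1e-8)
  }
})

test_that("permuting covariate columns permutes but does not change detail", {
  panel <- generate_panel(random_spec(4, 120, seed = 77))
  res1 <- decompose(panel, inference = "none")
  covs <- panel_covariates(panel)
  panel2 <- panel[, c("location", "year", "outcome", rev(covs))]
  res2 <- decompose(panel2, inference = "none")
  expect_equal(res1$E, res2$E, tolerance = 1e-10)
  expect_equal(res1$C, res2$C, tolerance = 1e-10)
  d1 <- res1$detail[order(res1$detail$term), ]
  d2 <- res2$detail[order(res2$detail$term), ]
  expect_equal(d1$E_k, d2$E_k, tolerance = 1e-10)
  expect_equal(d1$C_k, d2$C_k, tolerance = 1e-10)
})

test_that("a covariate identical in both periods contributes nearly nothing", {
  spec <- random_spec(3, 5000, seed = 55, sigma = 0.1)
  spec$covariates$x2 <- covariate_spec(10, 10, 3, 0, 100)
  spec$beta_end["x2"] <- spec$beta_start["x2"]
  panel <- generate_panel(spec)
  res <- decompose(panel, inference = "none")
  i <- which(res$detail$term == "x2")
  expect_lt(abs(res$detail$E_k[i]), 0.05 * abs(res$total_difference))
  expect_lt(abs(res$detail$C_k[i]), 0.05 * abs(res$total_difference))
})

test_that("scaling all outcomes by 10 scales components and SEs by 10", {
  panel <- generate_panel(random_spec(2, 150, seed = 21))
  r1 <- decompose(panel, inference = "delta")
  panel10 <- panel
  panel10$outcome <- panel$outcome * 10
  r10 <- decompose(panel10, inference = "delta")
  expect_equal(r10$E, 10 * r1$E, tolerance = 1e-7)
  expect_equal(r10$C, 10 * r1$C, tolerance = 1e-7)
  expect_equal(r10$se_E, 10 * r1$se_E, tolerance = 1e-6)
  expect_equal(r10$se_C, 10 * r1$se_C, tolerance = 1e-6)
  expect_equal(r10$pct_E, r1$pct_E, tolerance = 1e-7)
})

test_that("bootstrap inference is reproducible and close to the delta method", {
  panel <- generate_panel(gbd_like_spec(n_locations = 150), seed = 4)
  rd <- decompose(panel, inference = "delta")
  rb1 <- decompose(panel, inference = "bootstrap", bootstrap_reps = 400, seed = 9)
  rb2 <- decompose(panel, inference = "bootstrap", bootstrap_reps = 400, seed = 9)
  expect_equal(rb1$se_E, rb2$se_E)
  expect_equal(rb1$ci_C, rb2$ci_C)
  # same order of magnitude on a modest replicate count
  expect_lt(abs(rd$se_E - rb1$se_E) / rb1$se_E, 0.5)
  expect_lt(abs(rd$se_total - rb1$se_total) / rb1$se_total, 0.5)
  # point estimates are untouched by inference
  expect_equal(rb1$E, rd$E)
})

test_that("fixed-covariate delta propagation is available and smaller for E", {
  panel <- generate_panel(gbd_like_spec(n_locations = 150), seed = 4)
  res <- decompose(panel, inference = "none")
  full <- decomposition_inference(res, method = "delta")
  fixed <- decomposition_inference(res, method = "delta",
                                   design_variation = FALSE)
  expect_lt(fixed$se_E, full$se_E)
  expect_gt(fixed$se_E, 0)
})

test_that("configuration errors are caught", {
  panel <- generate_panel(random_spec(2, 30, seed = 1))
  expect_error(decompose(panel, reference_year = 1990, comparison_year = 1990),
               "differ")
  expect_error(decompose(panel, reference_year = 2020), "2020")
})
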