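# Nonlinear least-squares estimation, adjusted R-squared, model comparison.

test_that("noiseless hormetic data is recovered to high precision", {
  truth <- hormetic_params(a = 0.2, m = 1.0, s = 0.5, skew = 1, c = 0,
                           d = 0.005)
  d <- noiseless_hormetic_data(truth)
  fit <- fit_hormetic(d)
  expect_true(fit$converged)
  expect_lt(fit$sse, 1e-8)
  est <- coef(fit)
  for (nm in c("a", "m", "s", "skew", "d")) {
    expect_lt(abs(est[[nm]] - truth[[nm]]) / abs(truth[[nm]]), 1e-4)
  }
  expect_lt(abs(est[["c"]]), 1e-6)  # truth c = 0: absolute scale
  # optimizer never worsens any multi-start initialization
  expect_true(all(fit$sse <= fit$start_sse + 1e-12))
})

test_that("constrained parameters are held exactly and excluded from p", {
  truth <- hormetic_params(a = 0.2, m = 1.0, s = 0.5, skew = 1, c = 0,
                           d = 0.005)
  d <- noiseless_hormetic_data(truth)
  fit <- fit_hormetic(d, fix = list(c = 0))
  expect_identical(fit$params$c, 0)
  expect_lt(fit$sse, 1e-8)
  expect_equal(fit$n_free, 5)
  expect_true("c" %in% fit$fixed)
})

test_that("fitting errors on insufficient or degenerate data", {
  expect_error(
    fit_hormetic(dose_response_data(c(1, 2, 5, 10, 20),
                                    c(0.1, 0.2, 0.3, 0.2, 0.1))),
    "insufficient")
  d <- dose_response_data(c(0.5, 1, 2, 5, 10, 20, 50, 100),
                          rep(0.2, 8))
  expect_error(fit_hormetic(d), "degenerate")
  expect_error(
    fit_cedergreen(dose_response_data(c(1, 2, 5, 10, 20),
                                      c(0.1, 0.2, 0.3, 0.2, 0.1)),
                   fix = list()),
    "insufficient")
})

test_that("noiseless Cedergreen data is recovered to high precision", {
  truth <- cedergreen_params(a = 1, b = 3, c = 0, d = 0.05, e = 50, f = 0.4)
  doses <- c(0.5, 1, 2, 5, 10, 15, 20, 30, 50, 100, 200, 400)
  d <- dose_response_data(doses, cedergreen_response(doses, truth))
  fit <- fit_cedergreen(d)
  expect_true(fit$satisfactory)
  expect_lt(fit$sse, 1e-10)
  est <- coef(fit)
  for (nm in c("b", "d", "e", "f")) {
    expect_lt(abs(est[[nm]] - truth[[nm]]) / abs(truth[[nm]]), 1e-3)
  }
  expect_lt(abs(est[["c"]]), 1e-5)
})

test_that("monotone-decline data yields a nested Cedergreen fit with f near 0", {
  truth <- cedergreen_params(a = 1, b = 2, c = 0.01, d = 0.3, e = 20, f = 0)
  doses <- c(0.5, 1, 2, 5, 10, 20, 40, 80, 160, 320)
  d <- dose_response_data(doses, cedergreen_response(doses, truth))
  fit <- fit_cedergreen(d)
  expect_lt(fit$sse, 1e-8)
  expect_lt(fit$params$f, 1e-4)
  expect_true(fit$satisfactory)  # f at bound but SSE beats the flat model
})

test_that("adjusted R-squared matches direct arithmetic and decreases in p", {
  # perfect fit
  expect_equal(adjusted_r2(rep(0, 10), rnorm(10) + 5, 6)$r2_adjusted, 1.0)
  # R2 = 0.9, n = 10, p = 6  ->  1 - 0.1 * 9 / 3 = 0.7
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  sstot <- sum((y - mean(y))^2)
  res <- rep(sqrt(0.1 * sstot / 10), 10)
  out <- adjusted_r2(res, y, 6)
  expect_equal(out$r2, 0.9)
  expect_equal(out$r2_adjusted, 0.7)
  # R2 = 0 gives a negative adjustment: 1 - 1 * 9 / 3 = -2
  res0 <- rep(sqrt(sstot / 10), 10)
  expect_equal(adjusted_r2(res0, y, 6)$r2_adjusted, -2.0)
  # strictly decreasing in the free-parameter count
  adj <- vapply(1:7, function(p) adjusted_r2(res, y, p)$r2_adjusted,
                numeric(1))
  expect_true(all(diff(adj) < 0))
  expect_error(adjusted_r2(res, y, 9), "undefined")
})

test_that("stochastic recovery: peak location M within 15% median error", {
  truth <- hormetic_params(a = 0.2, m = 1.0, s = 0.5, skew = 1, c = 0,
                           d = 0.005)
  rec <- run_recovery(truth,
                      doses = c(0, 0.5, 1, 2, 5, 10, 15, 20, 30, 50, 100,
                                300),
                      replicates = 1, cv = 0.05, n_seeds = 100, seed = 1)
  m_row <- rec$summary[rec$summary$parameter == "M", ]
  expect_lt(m_row$median_rel_error, 0.15)
})

test_that("each free parameter recovers within 20% median error at 5% noise", {
  # c constrained to zero (its truth), mirroring the constraint interface;
  # a relative error against a zero truth is not meaningful
  truth <- hormetic_params(a = 0.2, m = 1.0, s = 0.5, skew = 2, c = 0,
                           d = 0.005)
  rec <- run_recovery(truth,
                      doses = c(0, 0.5, 1, 2, 5, 10, 15, 20, 30, 50, 100,
                                300),
                      replicates = 3, cv = 0.05, n_seeds = 100, seed = 1,
                      fix = list(c = 0))
  s <- rec$summary
  free <- s$parameter %in% c("a", "m", "s", "skew", "d")
  expect_true(all(s$median_rel_error[free] < 0.2))
})

test_that("model comparison prefers the skewed-Gaussian truth under noise", {
  truth <- hormetic_params(a = 0.2, m = 1.0, s = 0.5, skew = 2, c = 0,
                           d = 0.005)
  wins <- 0L; decided <- 0L
  for (i in 1:50) {
    d <- simulate_hormetic_data(
      truth, doses = c(0, 0.5, 1, 2, 5, 10, 15, 20, 30, 50, 100, 300),
      replicates = 1, cv = 0.05, seed = 1000 + i)
    cmp <- compare_models(d)
    if (cmp$winner != "undecided") {
      decided <- decided + 1L
      if (cmp$winner == "hormetic") wins <- wins + 1L
    }
  }
  expect_gt(decided, 25)
  expect_gt(wins / decided, 0.5)
})

test_that("both families capture noiseless monotone logistic decline", {
  # the steepness-10 log-logistic decline lies in BOTH families exactly:
  # hormetic with a = 0, and Cedergreen with f = 0, b = 10/ln(10), e = 10^m
  truth <- hormetic_params(a = 0, m = 1.2, s = 1, c = 0.005, d = 0.3)
  doses <- c(0.5, 1, 2, 5, 10, 20, 40, 80, 160, 320)
  d <- dose_response_data(doses, hormetic_response(log10(doses), truth))
  cmp <- compare_models(d)
  expect_gte(cmp$hormetic$r2, 0.999)
  expect_gte(cmp$cedergreen$r2, 0.999)
})

test_that("a Cedergreen failure is recorded without losing the hormetic fit", {
  # an interior one-dose spike the monotone-skeleton Cedergreen family
  # cannot express sends its best fit to an unsatisfactory state
  doses <- c(0.5, 1, 2, 5, 10, 15, 20, 30, 50, 100)
  y <- rep(0.01, length(doses))
  y[doses == 10] <- 5
  d <- dose_response_data(doses, y)
  cmp <- compare_models(d)
  expect_s3_class(cmp$hormetic, "hormetic_fit")
  expect_true(is.character(cmp$winner))
  # graceful degradation: comparison object exists whatever the verdict
  expect_true(!is.null(cmp$cedergreen) || cmp$cedergreen_failed)
})
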