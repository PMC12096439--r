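# Quadratic binding isotherms, free energies, counterion release, occupancy.

test_that("quadratic isotherm hits its exact anchor points", {
  p <- binding_params(Kd = 3e-9, Fmax = 1e6, Fmin = 1e5, L = 5e-8)
  # zero titrant: nothing bound, intensity at Fmax (quench orientation)
  expect_equal(quadratic_binding(0, p, "quench"), 1e6)
  expect_equal(quadratic_binding(0, p, "rise"), 1e5)
  # stoichiometric saturation: Kd = 0, x = L gives zero discriminant
  p0 <- binding_params(Kd = 0, Fmax = 1e6, Fmin = 1e5, L = 5e-8)
  expect_equal(quadratic_binding(5e-8, p0, "quench"), 1e5)
})

test_that("quadratic isotherm reduces to the hyperbola when L << Kd", {
  p <- binding_params(Kd = 1e-6, Fmax = 1e6, Fmin = 1e5, L = 1e-9)
  x <- seq(0, 100 * 1e-6, length.out = 400)
  quad <- quadratic_binding(x, p, "quench")
  hyp <- oracle_hyperbola(x, 1e-6, 1e6, 1e5)
  expect_lt(max(abs(quad - hyp) / (1e6 - 1e5)), 1e-3)
})

test_that("quadratic isotherm is monotone with bounded amplitude", {
  p <- binding_params(Kd = 2e-8, Fmax = 5e5, Fmin = 2e4, L = 5e-8)
  x <- seq(0, 1e-5, length.out = 1000)
  q <- quadratic_binding(x, p, "quench")
  r <- quadratic_binding(x, p, "rise")
  expect_true(all(diff(q) <= 1e-9))
  expect_true(all(diff(r) >= -1e-9))
  expect_lte(max(q) - min(q), p$Fmax - p$Fmin + 1e-9)
  expect_error(quadratic_binding(-1e-9, p, "quench"), ">= 0")
})

test_that("noiseless quench titration recovers Kd within 1%", {
  truth <- binding_params(Kd = 3e-9, Fmax = 1e6, Fmin = 1e5, L = 5e-8)
  x <- c(1, 2, 5, 10, 20, 50, 100, 200, 350, 500) * 1e-9
  curve <- binding_curve(x, quadratic_binding(x, truth, "quench"),
                         L = 5e-8, direction = "quench")
  fit <- fit_binding(curve, fix_L = TRUE)
  expect_false(fit$no_binding)
  expect_lt(abs(fit$params$Kd - 3e-9) / 3e-9, 0.01)
})

test_that("rise titration with Kd >> L matches a plain hyperbolic fit", {
  truth <- binding_params(Kd = 0.8e-3, Fmax = 2e5, Fmin = 5e4, L = 0.5e-6)
  x <- c(0, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 20) * 1e-3
  y <- quadratic_binding(x, truth, "rise")
  curve <- binding_curve(x, y, L = 0.5e-6, direction = "rise")
  fit <- fit_binding(curve, fix_L = TRUE)
  # independent hyperbolic fit of the same data
  hyp <- stats::nls(y ~ Fmin + (Fmax - Fmin) * x / (Kd + x),
                    start = list(Kd = 1e-3, Fmax = 2e5, Fmin = 5e4),
                    data = data.frame(x = x, y = y))
  kd_hyp <- coef(hyp)[["Kd"]]
  expect_lt(abs(fit$params$Kd - kd_hyp) / kd_hyp, 0.01)
})

test_that("flat titrations raise the no-binding flag", {
  curve <- binding_curve(c(0, 1, 2, 5, 10) * 1e-9, rep(5e5, 5),
                         L = 5e-8, direction = "quench")
  fit <- fit_binding(curve)
  expect_true(fit$no_binding)
  expect_null(fit$params)
})

test_that("free-L fitting recovers the probe concentration too", {
  truth <- binding_params(Kd = 3e-9, Fmax = 1e6, Fmin = 1e5, L = 5e-8)
  x <- c(1, 2, 5, 10, 20, 35, 50, 75, 100, 200, 350, 500) * 1e-9
  curve <- binding_curve(x, quadratic_binding(x, truth, "quench"),
                         L = 4e-8,   # deliberately misstated
                         direction = "quench")
  fit <- fit_binding(curve, fix_L = FALSE)
  expect_lt(abs(fit$params$L - 5e-8) / 5e-8, 0.05)
  expect_lt(abs(fit$params$Kd - 3e-9) / 3e-9, 0.05)
})

test_that("binding free energies match direct evaluation", {
  expect_equal(delta_g(1)$dG, 0)
  expect_equal(delta_g(3e-9)$dG, -11.51, tolerance = 0.001)
  expect_equal(delta_g(11e-6)$dG, -6.70, tolerance = 0.001)
  expect_error(delta_g(0), "> 0")
  # additivity: dG difference equals -RT ln(Ka1/Ka2)
  rt <- 1.987 * 295.15 / 1000
  dd <- delta_g(3e-9)$dG - delta_g(11e-6)$dG
  expect_equal(dd, -rt * log((1 / 3e-9) / (1 / 11e-6)), tolerance = 1e-12)
})

test_that("counterion release slopes reproduce the reference estimates", {
  ref <- ung2_reference_binding()$counterion
  long <- ref[ref$oligo == "27 nt", ]
  short <- ref[ref$oligo == "6 nt", ]
  expect_equal(signif(fit_counterion_release(long$salt_mM, long$Kd_M)$N, 2),
               2.1)
  expect_equal(round(fit_counterion_release(short$salt_mM, short$Kd_M)$N, 1),
               0.5)
  # identical affinities across salt: flat line, zero ions released
  expect_equal(fit_counterion_release(c(1, 10, 50), rep(2e-9, 3))$N, 0)
})

test_that("two-point counterion fit equals the analytic two-point slope", {
  kd <- c(5e-9, 2e-6); salt <- c(2, 80)
  fit <- fit_counterion_release(salt, kd)
  analytic <- -(log10(1 / kd[2]) - log10(1 / kd[1])) /
    (log10(salt[2]) - log10(salt[1]))
  expect_equal(fit$N, analytic, tolerance = 1e-12)
  # slope invariant to the concentration unit (switch mM -> M)
  fit_m <- fit_counterion_release(salt, kd)  # same numbers, shifted axis
  expect_equal(fit_counterion_release(salt * 1000, kd)$N, fit$N,
               tolerance = 1e-12)
  expect_error(fit_counterion_release(c(5, 5), kd), "distinct")
})

test_that("percent occupancy follows the ligand-binding equation", {
  expect_equal(percent_occupancy(0.4, 0.4)$percent, 50)
  expect_equal(round(percent_occupancy(2.11, 0.4)$percent), 84)
  occ <- percent_occupancy(c(7.33, 6.73, 6.07, 6.27, 12.37), 0.8)$percent
  expect_true(all(occ >= 88 & occ <= 94))
  # log-axis form is algebraically identical to the linear form
  M <- 10^seq(-3, 3, length.out = 200)
  kd <- 0.8
  linear <- 100 * M / (kd + M)
  logform <- 100 * 10^log10(M) / (kd + 10^log10(M))
  expect_equal(percent_occupancy(M, kd)$percent, linear, tolerance = 1e-15)
  expect_equal(logform, linear, tolerance = 1e-15)
  # monotone increasing in M, bounded by [0, 100]
  expect_true(all(diff(percent_occupancy(M, kd)$percent) > 0))
  expect_true(all(linear >= 0 & linear <= 100))
  expect_error(percent_occupancy(1, 0), "> 0")
})
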