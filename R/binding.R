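# Quadratic (ligand-depletion) binding isotherms, binding free energies,
# counterion-condensation slopes and ion-site occupancy.
#
# The quadratic isotherm is required whenever the probe concentration L is
# comparable to Kd (free-ligand depletion); it reduces to the hyperbolic
# isotherm when L << Kd. Both orientations are supported: "quench"
# (intensity falls as titrant binds, e.g. a fluorescein-labelled protein
# titrated with dark-quencher DNA) and "rise" (intensity grows, e.g.
# 2-aminopurine DNA titrated with Mg2+).

GAS_CONSTANT_CAL <- 1.987   # cal K^-1 mol^-1
DEFAULT_T_K <- 295.15       # 22 degrees C

#' Parameters of the quadratic binding isotherm
#'
#' @param Kd dissociation constant (molar, >= 0).
#' @param Fmax maximum fluorescence intensity (arbitrary units).
#' @param Fmin minimum fluorescence intensity; must be < `Fmax`.
#' @param L probe (fixed species) concentration, molar, > 0.
#' @return An object of class `binding_params`.
#' @export
binding_params <- function(Kd, Fmax, Fmin, L) {
  vals <- c(Kd = Kd, Fmax = Fmax, Fmin = Fmin, L = L)
  if (any(!is.finite(vals))) stop("binding parameters must be finite",
                                  call. = FALSE)
  if (Kd < 0) stop("Kd must be >= 0", call. = FALSE)
  if (L <= 0) stop("probe concentration L must be > 0", call. = FALSE)
  if (Fmax <= Fmin) stop("Fmax must exceed Fmin", call. = FALSE)
  structure(as.list(vals), class = "binding_params")
}

#' Evaluate the quadratic (ligand-depletion) binding isotherm
#'
#' With \eqn{b = K_d + x + L}, the bound fraction of the probe is
#' \eqn{(b - \sqrt{b^2 - 4 x L}) / (2L)} (the physical root of the binding
#' quadratic). Orientation `"quench"` maps zero titrant to `Fmax` and
#' saturation to `Fmin`; `"rise"` is the mirror image, starting at `Fmin`.
#'
#' @param x titrant concentrations (molar, >= 0).
#' @param params a [binding_params()] object or coercible named list.
#' @param direction `"quench"` or `"rise"`.
#' @return Fluorescence intensities at each `x`.
#' @examples
#' p <- binding_params(Kd = 3e-9, Fmax = 1e6, Fmin = 1e5, L = 5e-8)
#' quadratic_binding(c(0, 1e-8, 1e-7, 5e-7), p, "quench")
#' @export
quadratic_binding <- function(x, params, direction = c("quench", "rise")) {
  direction <- match.arg(direction)
  if (!inherits(params, "binding_params"))
    params <- do.call(binding_params, as.list(params))
  if (any(!is.finite(x)) || any(x < 0))
    stop("titrant concentrations must be finite and >= 0", call. = FALSE)
  with(params, {
    b <- Kd + x + L
    disc <- pmax(b^2 - 4 * x * L, 0)   # analytically >= 0; guard rounding
    bound <- (b - sqrt(disc)) / (2 * L)
    if (direction == "quench") Fmax - (Fmax - Fmin) * bound
    else Fmin + (Fmax - Fmin) * bound
  })
}

#' Construct a binding titration curve
#'
#' @param x titrant concentrations (molar, >= 0); at least 5 points.
#' @param intensity fluorescence intensities (arbitrary units).
#' @param L probe concentration (molar, > 0).
#' @param direction `"quench"` (intensity falls with titrant) or `"rise"`.
#' @param label free-text label.
#' @return A data.frame of class `binding_curve`.
#' @export
binding_curve <- function(x, intensity, L,
                          direction = c("quench", "rise"), label = "") {
  direction <- match.arg(direction)
  if (length(x) != length(intensity))
    stop("x and intensity lengths differ", call. = FALSE)
  if (length(x) < 5) stop("at least 5 titration points required",
                          call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("titrant concentrations must be >= 0", call. = FALSE)
  if (!is.numeric(L) || L <= 0) stop("probe concentration L must be > 0",
                                     call. = FALSE)
  structure(data.frame(x = as.numeric(x), intensity = as.numeric(intensity)),
            class = c("binding_curve", "data.frame"),
            L = L, direction = direction, label = label)
}

#' Fit the quadratic binding isotherm to a titration curve
#'
#' Least-squares estimation of `Fmax`, `Fmin`, `Kd` (constrained >= 0) and,
#' unless `fix_L`, the probe concentration `L` from a fluorescence
#' titration. `fix_L = FALSE` suits protein-titration curves where the
#' active probe concentration is itself uncertain; `fix_L = TRUE` suits
#' assays where the probe concentration is known (e.g. 0.5 uM
#' 2-aminopurine DNA).
#'
#' A curve whose intensities do not change beyond noise carries no binding
#' information: the fit returns a no-binding flag with `Kd = NA` rather
#' than an arbitrary number.
#'
#' @param curve a [binding_curve()].
#' @param fix_L hold the probe concentration at its stated value.
#' @return An object of class `binding_fit` with elements `params`
#'   ([binding_params()]), `no_binding`, `sse`, `r2`, `converged`,
#'   `standard_errors`, `direction`.
#' @export
fit_binding <- function(curve, fix_L = FALSE) {
  stopifnot(inherits(curve, "binding_curve"))
  x <- curve$x; y <- curve$intensity
  L <- attr(curve, "L"); direction <- attr(curve, "direction")

  rng <- diff(range(y))
  if (rng <= 1e-8 * max(abs(y), 1)) {
    return(structure(list(params = NULL, no_binding = TRUE, sse = 0,
                          r2 = NA_real_, converged = TRUE,
                          standard_errors = NULL, direction = direction,
                          L = L),
                     class = "binding_fit"))
  }

  Fmax0 <- max(y); Fmin0 <- min(y)
  half <- (Fmax0 + Fmin0) / 2
  x_half <- x[which.min(abs(y - half))]
  Kd0 <- max(x_half - L / 2, max(x) * 1e-4, 1e-12)
  free <- c(Kd = Kd0, Fmax = Fmax0, Fmin = Fmin0,
            if (!fix_L) c(L = L))
  lower <- c(Kd = 0, Fmax = -Inf, Fmin = -Inf, if (!fix_L) c(L = 1e-15))
  resid_fun <- function(par) {
    p <- as.list(par)
    if (fix_L) p$L <- L
    b <- p$Kd + x + p$L
    bound <- (b - sqrt(pmax(b^2 - 4 * x * p$L, 0))) / (2 * p$L)
    if (direction == "quench") y - (p$Fmax - (p$Fmax - p$Fmin) * bound)
    else y - (p$Fmin + (p$Fmax - p$Fmin) * bound)
  }
  fit <- run_lm(free, lower, rep(Inf, length(free)), resid_fun)
  est <- as.list(fit$par)
  if (fix_L) est$L <- L
  n <- length(y); p_n <- length(free)
  res <- resid_fun(fit$par)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  # amplitude indistinguishable from residual noise: no binding signal
  sigma <- sqrt(fit$sse / max(n - p_n, 1))
  no_binding <- abs(est$Fmax - est$Fmin) < 2 * sigma
  params <- if (est$Fmax > est$Fmin)
    binding_params(est$Kd, est$Fmax, est$Fmin, est$L) else NULL
  structure(list(params = params, no_binding = no_binding,
                 sse = fit$sse, r2 = r2, converged = fit$converged,
                 standard_errors = param_std_errors(fit$hessian, fit$sse,
                                                    n, p_n, names(free)),
                 residuals = res, direction = direction, L = est$L,
                 fixed_L = fix_L, n_points = n),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, digits = 4, ...) {
  if (x$no_binding || is.null(x$params)) {
    cat("Binding fit: no binding signal detected (Kd unbounded)\n")
    return(invisible(x))
  }
  cat("Quadratic binding isotherm fit (", x$direction, "):\n", sep = "")
  cat(sprintf("  Kd   = %s M%s\n", signif(x$params$Kd, digits),
              if (!is.null(x$standard_errors) &&
                  is.finite(x$standard_errors[["Kd"]]))
                paste0(" (SE ", signif(x$standard_errors[["Kd"]], 2), ")")
              else ""))
  cat(sprintf("  Fmax = %s, Fmin = %s, L = %s M%s\n",
              signif(x$params$Fmax, digits), signif(x$params$Fmin, digits),
              signif(x$params$L, digits),
              if (x$fixed_L) " (fixed)" else " (estimated)"))
  cat(sprintf("  R2 = %.5f over %d points\n", x$r2, x$n_points))
  invisible(x)
}

#' Binding free energy from a dissociation constant
#'
#' \eqn{\Delta G_{bind} = -RT \ln(K_a)} with \eqn{K_a = 1/K_d}, the gas
#' constant R = 1.987 cal K^-1 mol^-1 and the result converted to
#' kcal/mol.
#'
#' @param Kd dissociation constant (molar, > 0); vectorized.
#' @param temperature temperature in kelvin (default 295.15 K, i.e. 22 C).
#' @return List of class `thermo_result` with `Ka` (M^-1), `dG` (kcal/mol),
#'   `R` and `T`.
#' @examples
#' delta_g(3e-9)$dG    # about -11.5 kcal/mol
#' @export
delta_g <- function(Kd, temperature = DEFAULT_T_K) {
  if (any(!is.finite(Kd)) || any(Kd <= 0))
    stop("Kd must be > 0", call. = FALSE)
  Ka <- 1 / Kd
  dG <- -GAS_CONSTANT_CAL * temperature * log(Ka) / 1000
  structure(list(Ka = Ka, dG = dG, R = GAS_CONSTANT_CAL, T = temperature),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, digits = 4, ...) {
  cat("Binding thermodynamics at", x$T, "K:\n")
  cat("  Ka =", signif(x$Ka, digits), "M^-1;  dG_bind =",
      signif(x$dG, digits), "kcal/mol\n")
  invisible(x)
}

#' Counterion-condensation salt dependence of binding affinity
#'
#' Ordinary least-squares regression of log10(Ka) on log10([salt]):
#' \eqn{\log K_a = \log K_a^0 - N \log[\mathrm{salt}]}. The slope magnitude
#' `N` estimates the number of counterions released from the DNA ion cloud
#' upon protein binding; the intercept estimates the intrinsic (1 mM
#' reference) affinity. The slope is invariant to the concentration unit;
#' the intercept is unit-dependent and should be interpreted with care,
#' especially for short oligonucleotides that violate polyelectrolyte
#' assumptions.
#'
#' @param salt_mM salt concentrations (mM, > 0), at least 2 distinct.
#' @param Kd dissociation constants (molar, > 0) measured at each salt
#'   concentration.
#' @return An object of class `counterion_fit`: `N`, `logKa0`,
#'   `standard_errors` (NA with only two points), `n_points` and the
#'   underlying `lm` fit.
#' @examples
#' fit_counterion_release(c(1, 50), c(3e-9, 11e-6))$N   # about 2.1
#' @export
fit_counterion_release <- function(salt_mM, Kd) {
  if (length(salt_mM) != length(Kd))
    stop("salt_mM and Kd lengths differ", call. = FALSE)
  if (any(!is.finite(salt_mM)) || any(salt_mM <= 0))
    stop("salt concentrations must be > 0", call. = FALSE)
  if (any(!is.finite(Kd)) || any(Kd <= 0))
    stop("Kd values must be > 0", call. = FALSE)
  if (length(unique(salt_mM)) < 2)
    stop("insufficient data: need >= 2 distinct salt concentrations",
         call. = FALSE)
  df <- data.frame(log_salt = log10(salt_mM), log_Ka = log10(1 / Kd))
  fit <- stats::lm(log_Ka ~ log_salt, data = df)
  cf <- stats::coef(fit)
  # a perfect (zero-residual) line makes summary() warn; SEs are then 0
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) c(NA_real_, NA_real_))
  if (length(se) < 2) se <- c(se, NA_real_)
  structure(list(N = -unname(cf[2]), logKa0 = unname(cf[1]),
                 standard_errors = c(logKa0 = unname(se[1]),
                                     N = unname(se[2])),
                 n_points = nrow(df), lm = fit),
            class = "counterion_fit")
}

#' @export
print.counterion_fit <- function(x, digits = 3, ...) {
  cat("Counterion-condensation analysis (log10 Ka vs log10 [salt]):\n")
  cat(sprintf("  N (ions released) = %s%s\n", signif(x$N, digits),
              if (is.finite(x$standard_errors[["N"]]))
                paste0(" +/- ", signif(x$standard_errors[["N"]], 2)) else ""))
  cat(sprintf("  log10 Ka0 (intercept, unit-dependent) = %s over %d points\n",
              signif(x$logKa0, digits), x$n_points))
  invisible(x)
}

#' Percent occupancy of ion binding sites on DNA
#'
#' The fraction of ion sites occupied at the salt concentration `M` that
#' maximizes enzyme activity, given the apparent affinity of the ion for
#' the DNA: \eqn{100 \cdot M / (K_{d,app} + M)} — the basic ligand binding
#' equation, identical whether the concentration is handled linearly or as
#' \eqn{10^{\log_{10} M}} for plotting on a log axis.
#'
#' @param M salt concentration of maximal activity (mM, >= 0); vectorized.
#' @param Kd_apparent apparent dissociation constant of the ion for its DNA
#'   sites (mM, > 0).
#' @return An object of class `occupancy_result` with `percent` in
#'   \[0, 100\].
#' @examples
#' percent_occupancy(10.04, 0.4)   # dsDNA sites nearly saturated at peak
#' @export
percent_occupancy <- function(M, Kd_apparent) {
  if (any(!is.finite(M)) || any(M < 0))
    stop("M must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(Kd_apparent)) || any(Kd_apparent <= 0))
    stop("Kd_apparent must be > 0", call. = FALSE)
  structure(list(M = M, Kd_apparent = Kd_apparent,
                 percent = 100 * M / (Kd_apparent + M)),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, digits = 3, ...) {
  cat("Ion-site occupancy at peak-activity concentration(s):\n")
  print(data.frame(M_mM = x$M, Kd_apparent_mM = x$Kd_apparent,
                   percent = signif(x$percent, digits)))
  invisible(x)
}
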