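# Nonlinear least-squares estimation of the hormetic and Cedergreen models.
# Levenberg-Marquardt (minpack.lm::nls.lm) with box constraints; unweighted
# residuals, replicate points entering individually.

HORMETIC_PAR_NAMES <- c("a", "m", "s", "skew", "c", "d")
CEDERGREEN_PAR_NAMES <- c("a", "b", "c", "d", "e", "f")

lm_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-12, maxfev = 10000,
                             maxiter = 1000)
}

# Shared L-M driver over a named free-parameter subset with box bounds.
run_lm <- function(start_free, lower, upper, resid_fun) {
  # convergence state is read from the info code, not the warning text
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par = start_free, lower = lower, upper = upper,
                       fn = resid_fun, control = lm_control()))
  list(par = fit$par, sse = fit$deviance, info = fit$info,
       hessian = fit$hessian, converged = fit$info %in% 1:4)
}

param_std_errors <- function(hessian, sse, n, p, names_free) {
  se <- rep(NA_real_, p)
  if (n > p && p > 0) {
    cv <- tryCatch(solve(hessian) * sse / (n - p), error = function(e) NULL)
    if (!is.null(cv)) {
      dg <- diag(cv)
      se <- ifelse(dg >= 0, sqrt(dg), NA_real_)
    }
  }
  stats::setNames(se, names_free)
}

#' Adjusted coefficient of determination
#'
#' Computes \eqn{R^2 = 1 - SSE/SS_{tot}} (total sum of squares about the
#' mean) and its adjustment for the number of free model parameters,
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-p-1)}. Used to compare the
#' six-parameter hormetic model against the five-free-parameter Cedergreen
#' model on equal footing.
#'
#' @param residuals numeric vector of fit residuals (observed - fitted).
#' @param observations numeric vector of observed responses (same length).
#' @param n_free_params number of parameters that were free during fitting;
#'   constrained parameters and the fixed sigmoid steepness are excluded.
#' @return List with elements `r2` and `r2_adjusted` (may be negative).
#' @examples
#' adjusted_r2(rep(0, 10), rnorm(10), 6)$r2_adjusted   # perfect fit: 1
#' @export
adjusted_r2 <- function(residuals, observations, n_free_params) {
  n <- length(observations)
  if (length(residuals) != n)
    stop("residuals and observations lengths differ", call. = FALSE)
  if (n <= n_free_params + 1)
    stop("adjusted R^2 undefined: n <= p + 1", call. = FALSE)
  sse <- sum(residuals^2)
  sstot <- sum((observations - mean(observations))^2)
  r2 <- 1 - sse / sstot
  list(r2 = r2,
       r2_adjusted = 1 - (1 - r2) * (n - 1) / (n - n_free_params - 1))
}

#' Fit the skewed-Gaussian hormetic model to dose-response data
#'
#' Least-squares estimation of the parameters of [hormetic_response()] on
#' the log10-concentration axis. Initialization is heuristic (baseline from
#' the lowest dose, peak position from the dose of maximal response, width
#' from the span) with a multi-start over skew in {-2, 0, +2}; the start
#' with the lowest final SSE wins, ties going to the smallest fitted |skew|.
#' Zero-dose points are substituted by the dataset's pseudo-zero
#' concentration (default 0.01 mM) before taking logs.
#'
#' Bounds keep the fit physical: `s > 0` and the asymptotes `c, d >= 0`
#' (rates are non-negative); `a` and `skew` are unbounded. Any parameter can
#' be held at a fixed value via `fix`, e.g. `fix = list(c = 0)`; fixed
#' parameters are excluded from the free-parameter count used for adjusted
#' R-squared.
#'
#' @param data a [dose_response_data()] dataset (or a data.frame with
#'   `concentration` and `response` columns).
#' @param fix named list of parameters to hold constant during fitting.
#' @param pseudo_zero optionally override the dataset's pseudo-zero (mM).
#' @return An object of class `hormetic_fit`: fitted [hormetic_params()],
#'   the fixed-parameter set, per-free-parameter standard errors, `r2`,
#'   `r2_adjusted`, residuals, `sse`, `converged` flag, and the pseudo-zero
#'   actually used.
#' @examples
#' truth <- hormetic_params(a = 0.2, m = 1, s = 0.5, skew = 1, d = 0.005)
#' d <- simulate_hormetic_data(truth, cv = 0, seed = 1)
#' fit <- fit_hormetic(d)
#' coef(fit)
#' @export
fit_hormetic <- function(data, fix = list(), pseudo_zero = NULL) {
  data <- as_dose_response(data)
  if (!is.null(pseudo_zero)) attr(data, "pseudo_zero") <- pseudo_zero
  fix <- validate_fix(fix, HORMETIC_PAR_NAMES, "hormetic")
  steepness <- fix$steepness %||% 10
  fix$steepness <- NULL
  free_names <- setdiff(HORMETIC_PAR_NAMES, names(fix))
  prep <- prepare_doses(data, length(free_names))
  x <- prep$x; y <- prep$y

  # initialization heuristic
  y_lo <- mean(y[prep$conc == min(prep$conc)])
  y_hi <- mean(y[prep$conc == max(prep$conc)])
  init <- list(d = y_lo, c = min(y_hi, y_lo), m = x[which.max(y)],
               s = max(diff(range(x)) / 4, 0.05), a = max(y) - y_lo)
  lower_all <- c(a = -Inf, m = -Inf, s = 1e-6, skew = -Inf, c = 0, d = 0)
  upper_all <- c(a = Inf, m = Inf, s = Inf, skew = Inf, c = Inf, d = Inf)

  make_resid <- function(par_free) {
    p <- c(as.list(par_free), fix)
    p$steepness <- steepness
    y - hormetic_response(x, as_hormetic_params(p))
  }
  clamp <- function(v, nm) pmin(pmax(v, lower_all[nm]), upper_all[nm])

  # second m candidate at the half-drop midpoint: positions the sigmoid
  # correctly when the data are monotone rather than peaked
  ord <- order(x)
  xs_o <- x[ord]; ys_o <- y[ord]
  half <- (init$d + init$c) / 2
  past_peak <- which(xs_o >= init$m & ys_o < half)
  m_cands <- init$m
  if (length(past_peak)) {
    j <- past_peak[1]
    if (j > 1) m_cands <- unique(c(m_cands, (xs_o[j - 1] + xs_o[j]) / 2))
  }
  starts <- expand.grid(m0 = m_cands, skew0 = c(-2, 0, 2))
  runs <- lapply(seq_len(nrow(starts)), function(k) {
    ini <- init
    ini$m <- starts$m0[k]
    start <- unlist(c(ini, skew = starts$skew0[k]))[free_names]
    start <- clamp(start, free_names)
    run_lm(start, lower_all[free_names], upper_all[free_names], make_resid)
  })
  sses <- vapply(runs, `[[`, numeric(1), "sse")
  best_sse <- min(sses)
  cand <- which(sses <= best_sse * (1 + 1e-9) + 1e-300)
  if (length(cand) > 1 && "skew" %in% free_names) {
    cand <- cand[which.min(abs(vapply(
      runs[cand], function(r) r$par[["skew"]], numeric(1))))]
  }
  best <- runs[[cand[1]]]

  par_full <- c(as.list(best$par), fix)
  par_full$steepness <- steepness
  params <- as_hormetic_params(par_full[c(HORMETIC_PAR_NAMES, "steepness")])
  res <- y - hormetic_response(x, params)
  n <- length(y); p <- length(free_names)
  r2s <- adjusted_r2(res, y, p)
  structure(list(
    params = params, fixed = names(fix), fixed_values = fix,
    free = free_names,
    standard_errors = param_std_errors(best$hessian, best$sse, n, p,
                                       free_names),
    r2 = r2s$r2, r2_adjusted = r2s$r2_adjusted,
    n_points = n, n_free = p, sse = best$sse,
    converged = best$converged, residuals = res,
    fitted = y - res, x = x, y = y,
    pseudo_zero = prep$pseudo_zero, label = attr(data, "label") %||% "",
    start_sse = vapply(runs, `[[`, numeric(1), "sse")
  ), class = "hormetic_fit")
}

#' @export
print.hormetic_fit <- function(x, digits = 4, ...) {
  cat("Hormetic (skewed-Gaussian) dose-response fit",
      if (nzchar(x$label)) paste0("'", x$label, "'") else "", "\n")
  est <- unlist(x$params)[HORMETIC_PAR_NAMES]
  se <- x$standard_errors[HORMETIC_PAR_NAMES]
  names(se) <- HORMETIC_PAR_NAMES
  tab <- data.frame(estimate = signif(est, digits),
                    std.error = signif(se, digits),
                    fixed = HORMETIC_PAR_NAMES %in% x$fixed)
  print(tab)
  cat(sprintf("R2 = %.5f, adjusted R2 = %.5f (n = %d, free params = %d)\n",
              x$r2, x$r2_adjusted, x$n_points, x$n_free))
  if (!x$converged) cat("warning: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.hormetic_fit <- function(object, ...) {
  unlist(object$params)[HORMETIC_PAR_NAMES]
}

#' Fit the Cedergreen hormesis model to dose-response data
#'
#' Least-squares fit of [cedergreen_response()] on the linear concentration
#' axis (the model is written in the dose itself, not its log). The
#' pre-peak exponent `a` is fixed at 1 by default — the common dose-response
#' usage — but can be freed or set via `fix`. Zero-dose points receive the
#' dataset's pseudo-zero concentration, since the model is undefined at 0.
#'
#' A fit is flagged unsatisfactory when the optimizer fails to converge, or
#' when the hormetic term is pinned at its bound (`f = 0`) while fitting
#' worse than a flat mean-only model — the situations in which this family
#' cannot describe the data.
#'
#' @inheritParams fit_hormetic
#' @param fix named list of parameters to hold constant; defaults to
#'   `list(a = 1)`. Supply `fix = list()` to free all six parameters.
#' @return An object of class `cedergreen_fit` with the same diagnostic
#'   fields as [fit_hormetic()] plus a `satisfactory` flag.
#' @export
fit_cedergreen <- function(data, fix = list(a = 1), pseudo_zero = NULL) {
  data <- as_dose_response(data)
  if (!is.null(pseudo_zero)) attr(data, "pseudo_zero") <- pseudo_zero
  fix <- validate_fix(fix, CEDERGREEN_PAR_NAMES, "Cedergreen")
  free_names <- setdiff(CEDERGREEN_PAR_NAMES, names(fix))
  prep <- prepare_doses(data, length(free_names))
  conc <- prep$conc; y <- prep$y

  y_lo <- mean(y[conc == min(conc)])
  y_hi <- mean(y[conc == max(conc)])
  d0 <- y_lo
  c0 <- max(min(y_hi, y_lo), 0)
  f0 <- max(max(y) - d0, 0)
  conc_peak <- conc[which.max(y)]
  e_cands <- unique(pmax(c(stats::median(conc), 2 * conc_peak,
                           max(conc) / 2), 1e-3))
  lower_all <- c(a = 1e-6, b = -Inf, c = 0, d = 0, e = 1e-9, f = 0)
  upper_all <- c(a = Inf, b = Inf, c = Inf, d = Inf, e = Inf, f = Inf)

  make_resid <- function(par_free) {
    p <- c(as.list(par_free), fix)
    y - cedergreen_response(conc, do.call(cedergreen_params,
                                          p[CEDERGREEN_PAR_NAMES]))
  }
  starts <- list()
  for (e0 in e_cands) for (b0 in c(1, 3, 8)) {
    starts[[length(starts) + 1L]] <-
      c(a = 1, b = b0, c = c0, d = d0, e = e0, f = f0)
  }
  runs <- lapply(starts, function(s0) {
    start <- pmin(pmax(s0[free_names], lower_all[free_names]),
                  upper_all[free_names])
    tryCatch(
      run_lm(start, lower_all[free_names], upper_all[free_names], make_resid),
      error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0)
    stop("Cedergreen fit failed from every start", call. = FALSE)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "sse"))]]

  par_full <- c(as.list(best$par), fix)
  params <- do.call(cedergreen_params, par_full[CEDERGREEN_PAR_NAMES])
  res <- y - cedergreen_response(conc, params)
  n <- length(y); p <- length(free_names)
  r2s <- adjusted_r2(res, y, p)
  sse_flat <- sum((y - mean(y))^2)
  f_pinned <- ("f" %in% free_names) && params$f <= 1e-10
  satisfactory <- best$converged && !(f_pinned && best$sse > sse_flat)
  structure(list(
    params = params, fixed = names(fix), fixed_values = fix,
    free = free_names,
    standard_errors = param_std_errors(best$hessian, best$sse, n, p,
                                       free_names),
    r2 = r2s$r2, r2_adjusted = r2s$r2_adjusted,
    n_points = n, n_free = p, sse = best$sse,
    converged = best$converged, satisfactory = satisfactory,
    residuals = res, fitted = y - res, concentration = conc, y = y,
    pseudo_zero = prep$pseudo_zero, label = attr(data, "label") %||% ""
  ), class = "cedergreen_fit")
}

#' @export
print.cedergreen_fit <- function(x, digits = 4, ...) {
  cat("Cedergreen hormesis model fit",
      if (nzchar(x$label)) paste0("'", x$label, "'") else "", "\n")
  est <- unlist(x$params)[CEDERGREEN_PAR_NAMES]
  tab <- data.frame(estimate = signif(est, digits),
                    fixed = CEDERGREEN_PAR_NAMES %in% x$fixed)
  print(tab)
  cat(sprintf("R2 = %.5f, adjusted R2 = %.5f (n = %d, free params = %d)\n",
              x$r2, x$r2_adjusted, x$n_points, x$n_free))
  if (!x$satisfactory) cat("fit flagged UNSATISFACTORY\n")
  invisible(x)
}

#' @export
coef.cedergreen_fit <- function(object, ...) {
  unlist(object$params)[CEDERGREEN_PAR_NAMES]
}

#' Compare the hormetic and Cedergreen models on one dataset
#'
#' Fits both model families to the same dataset and compares them by
#' adjusted R-squared, each adjustment using that model's own free-parameter
#' count. A Cedergreen fit that errors or is flagged unsatisfactory is
#' recorded as a failure without aborting; the hormetic fit is always
#' returned.
#'
#' @inheritParams fit_hormetic
#' @param fix_hormetic,fix_cedergreen fixed-parameter maps passed through to
#'   the respective fitters.
#' @return An object of class `model_comparison` with elements `hormetic`,
#'   `cedergreen` (or NULL on failure), `cedergreen_failed`, and `winner`
#'   (`"hormetic"`, `"cedergreen"`, or `"undecided"` when the comparison
#'   cannot be made).
#' @export
compare_models <- function(data, fix_hormetic = list(),
                           fix_cedergreen = list(a = 1),
                           pseudo_zero = NULL) {
  hfit <- fit_hormetic(data, fix = fix_hormetic, pseudo_zero = pseudo_zero)
  cfit <- tryCatch(
    fit_cedergreen(data, fix = fix_cedergreen, pseudo_zero = pseudo_zero),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "cedergreen_failure"))
  failed <- inherits(cfit, "cedergreen_failure") || !cfit$satisfactory
  winner <- if (failed) "undecided"
            else if (hfit$r2_adjusted >= cfit$r2_adjusted) "hormetic"
            else "cedergreen"
  structure(list(hormetic = hfit,
                 cedergreen = if (inherits(cfit, "cedergreen_failure")) NULL
                              else cfit,
                 cedergreen_failed = failed,
                 failure_message = if (inherits(cfit, "cedergreen_failure"))
                   cfit$error else NULL,
                 winner = winner),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (adjusted R2):\n")
  cat(sprintf("  hormetic:   %.5f\n", x$hormetic$r2_adjusted))
  if (!is.null(x$cedergreen))
    cat(sprintf("  Cedergreen: %.5f%s\n", x$cedergreen$r2_adjusted,
                if (x$cedergreen_failed) " (unsatisfactory)" else ""))
  else cat("  Cedergreen: failed —", x$failure_message, "\n")
  cat("  winner:", x$winner, "\n")
  invisible(x)
}

as_dose_response <- function(data) {
  if (inherits(data, "dose_response")) return(data)
  if (is.data.frame(data) &&
      all(c("concentration", "response") %in% names(data)))
    return(dose_response_data(data$concentration, data$response,
                              replicate = data$replicate))
  stop("expected a dose_response dataset or a data.frame with ",
       "'concentration' and 'response' columns", call. = FALSE)
}

validate_fix <- function(fix, par_names, model) {
  if (length(fix) == 0) return(list())
  allowed <- c(par_names, if (model == "hormetic") "steepness")
  bad <- setdiff(names(fix), allowed)
  if (length(bad))
    stop("unknown ", model, " parameter(s) in fix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(!vapply(fix, function(v) is.numeric(v) && is.finite(v), logical(1))))
    stop("fixed parameter values must be finite numbers", call. = FALSE)
  lapply(fix, as.numeric)
}
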