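# Synthetic dose-response and binding-titration data with known ground
# truth. Defaults mirror the assay designs the analysis targets:
# MgCl2-like series 0-50 mM and monovalent series 0-1000 mM, triplicate
# rate measurements with proportional Gaussian noise (cv 5%).

#' Default dose designs for synthetic dose-response series
#'
#' `"divalent"` mirrors a MgCl2-style titration (0-50 mM), `"monovalent"` a
#' KCl/NaCl-style titration (0-1000 mM). Both include an explicit zero-dose
#' (no salt) control.
#'
#' @param type `"divalent"` or `"monovalent"`.
#' @return Numeric vector of doses in mM.
#' @export
default_doses <- function(type = c("divalent", "monovalent")) {
  switch(match.arg(type),
         divalent = c(0, 0.5, 1, 2, 5, 10, 15, 20, 30, 50),
         monovalent = c(0, 10, 30, 100, 300, 1000))
}

#' Simulate a hormetic dose-response dataset with known truth
#'
#' Evaluates the skewed-Gaussian hormetic model at each dose (zero doses
#' substituted by `pseudo_zero` before taking logs, exactly as at fit time)
#' and adds Gaussian noise with standard deviation
#' `sd_additive + cv * |model value|`. Negative draws are truncated at zero
#' — rates are non-negative — which introduces a small upward bias only
#' where the true rate is within a couple of noise SDs of zero.
#'
#' @param truth a [hormetic_params()] object: the generating parameters.
#' @param doses dose grid in mM, may include 0; default the divalent design.
#' @param replicates measurements per dose (default 3, emulating triplicate
#'   assays).
#' @param cv proportional noise coefficient of variation (default 0.05).
#' @param sd_additive additive noise SD in response units (default 0).
#' @param pseudo_zero concentration substituted for zero doses (mM).
#' @param seed integer seed; the output is fully reproducible given it.
#' @param label dataset label.
#' @return A [dose_response_data()] dataset with the generating parameters
#'   attached as attribute `"truth"`.
#' @examples
#' truth <- hormetic_params(a = 0.2, m = 1, s = 0.5, skew = 1, d = 0.005)
#' d <- simulate_hormetic_data(truth, seed = 42)
#' fit_hormetic(d)
#' @export
simulate_hormetic_data <- function(truth, doses = default_doses("divalent"),
                                   replicates = 3, cv = 0.05,
                                   sd_additive = 0, pseudo_zero = 0.01,
                                   seed = NULL, label = "synthetic") {
  truth <- as_hormetic_params(truth)
  if (cv < 0 || sd_additive < 0)
    stop("noise magnitudes must be >= 0", call. = FALSE)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  conc <- rep(doses, each = replicates)
  conc_eff <- ifelse(conc == 0, pseudo_zero, conc)
  mu <- hormetic_response(log10(conc_eff), truth)
  sdv <- sd_additive + cv * abs(mu)
  y <- mu + stats::rnorm(length(mu), 0, sdv)
  y <- pmax(y, 0)
  out <- dose_response_data(conc, y,
                            replicate = rep(seq_len(replicates),
                                            times = length(doses)),
                            label = label, pseudo_zero = pseudo_zero)
  attr(out, "truth") <- truth
  out
}

#' Simulate a binding titration curve with known truth
#'
#' @param truth a [binding_params()] object.
#' @param x titrant concentrations (molar); default 10 points spanning
#'   roughly 0 to 10 Kd.
#' @param direction `"quench"` or `"rise"`.
#' @param cv proportional Gaussian noise on intensities (default 0).
#' @param seed integer seed.
#' @return A [binding_curve()] with attribute `"truth"`.
#' @export
simulate_binding_curve <- function(truth, x = NULL,
                                   direction = c("quench", "rise"),
                                   cv = 0, seed = NULL) {
  direction <- match.arg(direction)
  if (!inherits(truth, "binding_params"))
    truth <- do.call(binding_params, as.list(truth))
  if (is.null(x)) {
    top <- 10 * max(truth$Kd, truth$L)
    x <- c(0, top * c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 0.7, 0.85, 1))
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- quadratic_binding(x, truth, direction)
  y <- mu * (1 + stats::rnorm(length(mu), 0, cv))
  out <- binding_curve(x, y, L = truth$L, direction = direction,
                       label = "synthetic")
  attr(out, "truth") <- truth
  out
}

#' Parameter-recovery study: generate, fit, derive, aggregate
#'
#' Runs `n_seeds` independent simulate-fit-derive cycles from one ground
#' truth and aggregates per-parameter bias, RMSE and median relative error,
#' plus recovery of the derived peak summaries `y_max` and `M`. Fit
#' failures are counted, not fatal. Fully deterministic given the master
#' seed (per-replicate seeds are `seed + 1 ... seed + n_seeds`).
#'
#' @inheritParams simulate_hormetic_data
#' @param n_seeds number of simulation replicates (>= 2).
#' @param seed master seed (default 1).
#' @param fix fixed-parameter map forwarded to [fit_hormetic()].
#' @return An object of class `recovery_report`: a summary data.frame
#'   (`bias`, `rmse`, `median_rel_error` per quantity), `n_seeds`,
#'   `n_failures`, and the per-seed estimates.
#' @examples
#' truth <- hormetic_params(a = 0.2, m = 1, s = 0.5, skew = 1, d = 0.005)
#' run_recovery(truth, n_seeds = 5, cv = 0.05, seed = 7)
#' @export
run_recovery <- function(truth, doses = default_doses("divalent"),
                         replicates = 3, cv = 0.05, sd_additive = 0,
                         n_seeds = 100, seed = 1, fix = list(),
                         pseudo_zero = 0.01) {
  truth <- as_hormetic_params(truth)
  if (n_seeds < 2) stop("n_seeds must be >= 2", call. = FALSE)
  true_pk <- locate_peak(truth)
  true_vals <- c(unlist(truth)[HORMETIC_PAR_NAMES],
                 y_max = true_pk$y_max, M = true_pk$M)
  per_seed <- vector("list", n_seeds)
  n_fail <- 0L
  for (i in seq_len(n_seeds)) {
    est <- tryCatch({
      d <- simulate_hormetic_data(truth, doses = doses,
                                  replicates = replicates, cv = cv,
                                  sd_additive = sd_additive,
                                  pseudo_zero = pseudo_zero,
                                  seed = seed + i)
      fit <- fit_hormetic(d, fix = fix)
      if (!fit$converged) stop("fit did not converge")
      pk <- locate_peak(fit)
      c(coef(fit), y_max = pk$y_max, M = pk$M)
    }, error = function(e) NULL)
    if (is.null(est)) n_fail <- n_fail + 1L else per_seed[[i]] <- est
  }
  est_mat <- do.call(rbind, per_seed)
  if (is.null(est_mat)) {
    # every replicate failed: still report, with an empty summary
    return(structure(list(
      summary = data.frame(parameter = character(), truth = numeric(),
                           bias = numeric(), rmse = numeric(),
                           median_rel_error = numeric()),
      n_seeds = n_seeds, n_failures = n_fail, estimates = NULL,
      truth = truth, cv = cv, doses = doses, replicates = replicates,
      seed = seed), class = "recovery_report"))
  }
  err <- sweep(est_mat, 2, true_vals[colnames(est_mat)])
  denom <- pmax(abs(true_vals[colnames(est_mat)]), 1e-12)
  rel <- abs(err) / rep(denom, each = nrow(err))
  summary <- data.frame(
    parameter = colnames(est_mat),
    truth = unname(true_vals[colnames(est_mat)]),
    bias = colMeans(err, na.rm = TRUE),
    rmse = sqrt(colMeans(err^2, na.rm = TRUE)),
    median_rel_error = apply(rel, 2, stats::median, na.rm = TRUE),
    row.names = NULL)
  structure(list(summary = summary, n_seeds = n_seeds,
                 n_failures = n_fail, estimates = est_mat,
                 truth = truth, cv = cv, doses = doses,
                 replicates = replicates, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Parameter-recovery study: %d seeds, cv = %s, %d doses x %d replicates\n",
    x$n_seeds, format(x$cv), length(x$doses), x$replicates))
  if (x$n_failures > 0)
    cat("  fit failures:", x$n_failures, "of", x$n_seeds, "\n")
  df <- x$summary
  df$truth <- signif(df$truth, digits)
  df$bias <- signif(df$bias, digits)
  df$rmse <- signif(df$rmse, digits)
  df$median_rel_error <- signif(df$median_rel_error, digits)
  print(df)
  invisible(x)
}
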