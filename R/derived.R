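# Biologically meaningful summaries of a fitted hormetic curve: peak height
# y_max, peak concentration M, fold-stimulation y_max/d, inflection slopes
# and the stimulatory concentration range. The skewed model has no
# closed-form mode, so the peak is found by dense-grid search plus bounded
# refinement on the log10 axis.

GRID_PER_DECADE <- 1e4

hcurve <- function(fit_or_params) {
  p <- if (inherits(fit_or_params, "hormetic_fit")) fit_or_params$params
       else as_hormetic_params(fit_or_params)
  list(params = p, f = function(x) hormetic_response(x, p))
}

default_span <- function(fit_or_params) {
  if (inherits(fit_or_params, "hormetic_fit")) {
    rng <- range(fit_or_params$x)
    c(rng[1] - 1, rng[2] + 1)          # data span plus one decade each side
  } else {
    p <- as_hormetic_params(fit_or_params)
    c(p$m - 6 * max(p$s, 0.5), p$m + 6 * max(p$s, 0.5))
  }
}

#' Locate the hormetic peak (y_max, M)
#'
#' Numerically maximizes the fitted hormetic curve over a log10
#' concentration span — by default the data span extended one decade either
#' side. The argmax of a dense grid (10^4 points per decade) seeds a bounded
#' golden-section/parabolic refinement to better than 1e-6 log10 units.
#' `y_max` is the peak response and `M` the corresponding concentration in
#' mM (linear scale). When the curve is monotone over the span (no interior
#' maximum), a no-peak result is returned instead.
#'
#' @param fit a converged [fit_hormetic()] result, or a
#'   [hormetic_params()] object.
#' @param span optional log10-mM interval `c(lo, hi)` to search.
#' @return List with `has_peak`, `y_max`, `M` (mM), and `log10_M`.
#' @examples
#' locate_peak(hormetic_params(a = 0.15, m = 1, s = 0.5))  # M = 10 mM
#' @export
locate_peak <- function(fit, span = NULL) {
  if (inherits(fit, "hormetic_fit") && !fit$converged)
    stop("cannot derive parameters from a non-converged fit", call. = FALSE)
  cur <- hcurve(fit)
  span <- span %||% default_span(fit)
  n_grid <- max(201L, ceiling(GRID_PER_DECADE * diff(span)))
  xs <- seq(span[1], span[2], length.out = n_grid)
  ys <- cur$f(xs)
  i <- which.max(ys)
  if (i == 1L || i == n_grid) {
    # argmax on the boundary: monotone over the span, no interior peak
    return(list(has_peak = FALSE, y_max = NA_real_, M = NA_real_,
                log10_M = NA_real_))
  }
  opt <- stats::optimize(cur$f, lower = xs[i - 1L], upper = xs[i + 1L],
                         maximum = TRUE, tol = 1e-9)
  # a flat interior (e.g. a = 0, c = d) has no genuine peak
  edge_max <- max(ys[1], ys[n_grid])
  if (opt$objective <= edge_max + 1e-15 * max(1, abs(edge_max)))
    return(list(has_peak = FALSE, y_max = NA_real_, M = NA_real_,
                log10_M = NA_real_))
  list(has_peak = TRUE, y_max = opt$objective, M = 10^opt$maximum,
       log10_M = opt$maximum)
}

#' Fold-stimulation of activity over the zero-salt baseline
#'
#' The ratio `y_max / d`: how many times faster the enzyme runs at its
#' optimal salt concentration than with no salt at all. When the baseline
#' `d` has been constrained to zero (within 1e-12), the stimulation is
#' unbounded and `Inf` is returned rather than an error.
#'
#' @param y_max peak response (s^-1).
#' @param d baseline response at zero dose (s^-1, >= 0).
#' @return `y_max / d`, or `Inf` when `d` is zero within tolerance.
#' @examples
#' fold_stimulation(0.1576, 0.0044)  # 35.8-fold
#' @export
fold_stimulation <- function(y_max, d) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
    stop("undefined baseline: d must be finite and >= 0", call. = FALSE)
  ifelse(abs(d) < 1e-12, Inf, y_max / d)
}

# first/second derivative of the curve by central differences
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
num_deriv2 <- function(f, x, h = 1e-4) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

bisect_sign_change <- function(g, lo, hi, tol = 1e-10) {
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  flo <- g(lo)
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    fm <- g(mid)
    if (hi - lo < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Inflection-point slopes and the stimulatory concentration range
#'
#' Characterizes the steepness of the hormetic peak and its reach: the
#' first derivatives (response units per log10 mM) at the two inflection
#' points flanking the peak, and the maximal concentration interval around
#' the peak over which the fitted curve stays at or above the zero-salt
#' baseline `d`. Inflection points are located as sign changes of the
#' numerical second derivative on a dense grid, refined by bisection; range
#' endpoints are roots of `curve(x) = d`, reported in mM. An endpoint is 0
#' or `Inf` mM when the curve never drops below the baseline on that side
#' of the search window.
#'
#' @inheritParams locate_peak
#' @return List with `ascending_slope`, `descending_slope`,
#'   `ascending_x`/`descending_x` (log10 mM positions of the inflections)
#'   and `stimulatory_range` (low mM, high mM).
#' @export
slopes_and_range <- function(fit, span = NULL) {
  pk <- locate_peak(fit, span)
  if (!pk$has_peak)
    stop("curve has no interior peak; slopes undefined", call. = FALSE)
  cur <- hcurve(fit)
  p <- cur$params
  xm <- pk$log10_M
  w <- 100 * max(p$s, 1)
  d2 <- function(x) num_deriv2(cur$f, x)

  find_inflection <- function(from, to) {
    xs <- seq(from, to, length.out = 2000L)
    v <- d2(xs)
    flips <- which(v[-1] * v[-length(v)] < 0)
    if (!length(flips)) return(NA_real_)
    j <- flips[1]  # xs starts at the peak, so the first flip is nearest it
    bisect_sign_change(d2, xs[j], xs[j + 1])
  }
  asc_x <- find_inflection(xm, xm - 6 * max(p$s, 0.5))
  des_x <- find_inflection(xm, xm + 6 * max(p$s, 0.5))

  # curve(x) - d computed subtraction-free: the peak term against the
  # sigmoid's deficit below d. Resolves baseline crossings far into the
  # tails, where both terms underflow relative to d itself.
  gap <- function(x) {
    dx <- x - p$m
    p$a * exp(-0.5 * (dx / p$s)^2) * (1 + erf(p$skew * dx)) -
      (p$d - p$c) * stats::plogis(p$steepness * dx)
  }
  root_below <- {
    xs <- seq(xm, xm - w, length.out = 4000L)
    below <- which(gap(xs) < 0)
    if (!length(below)) 0 else {
      j <- below[1]
      10^bisect_sign_change(gap, xs[j - 1], xs[j])
    }
  }
  root_above <- {
    xs <- seq(xm, xm + w, length.out = 4000L)
    below <- which(gap(xs) < 0)
    if (!length(below)) Inf else {
      j <- below[1]
      10^bisect_sign_change(gap, xs[j - 1], xs[j])
    }
  }
  list(ascending_slope = num_deriv(cur$f, asc_x),
       descending_slope = num_deriv(cur$f, des_x),
       ascending_x = asc_x, descending_x = des_x,
       stimulatory_range = c(low_mM = root_below, high_mM = root_above))
}

#' Derive all summary parameters from a hormetic fit
#'
#' Convenience wrapper combining [locate_peak()], [fold_stimulation()] and
#' [slopes_and_range()] into one record mirroring the columns of a
#' dose-response summary table: baseline rate `d`, maximum rate `y_max`,
#' fold-stimulation, and the peak concentration `M`.
#'
#' @inheritParams locate_peak
#' @return An object of class `derived_params`.
#' @export
derive_params <- function(fit, span = NULL) {
  pk <- locate_peak(fit, span)
  p <- hcurve(fit)$params
  out <- list(has_peak = pk$has_peak, y_max = pk$y_max, M = pk$M,
              d = p$d, c = p$c,
              fold_stimulation = if (pk$has_peak)
                fold_stimulation(pk$y_max, p$d) else NA_real_,
              ascending_slope = NA_real_, descending_slope = NA_real_,
              stimulatory_range = c(low_mM = NA_real_, high_mM = NA_real_))
  if (pk$has_peak) {
    sl <- slopes_and_range(fit, span)
    out$ascending_slope <- sl$ascending_slope
    out$descending_slope <- sl$descending_slope
    out$stimulatory_range <- sl$stimulatory_range
  }
  structure(out, class = "derived_params")
}

#' @export
print.derived_params <- function(x, digits = 4, ...) {
  if (!x$has_peak) {
    cat("No interior hormetic peak detected.\n")
    return(invisible(x))
  }
  cat("Derived hormetic parameters:\n")
  cat(sprintf("  baseline rate d:      %s s^-1\n", signif(x$d, digits)))
  cat(sprintf("  maximum rate y_max:   %s s^-1\n", signif(x$y_max, digits)))
  cat(sprintf("  fold-stimulation:     %s\n",
              signif(x$fold_stimulation, digits)))
  cat(sprintf("  peak concentration M: %s mM\n", signif(x$M, digits)))
  cat(sprintf("  slopes at inflections: +%s / %s per log10 mM\n",
              signif(x$ascending_slope, digits),
              signif(x$descending_slope, digits)))
  cat(sprintf("  stimulatory range:    %s – %s mM\n",
              signif(x$stimulatory_range[1], digits),
              signif(x$stimulatory_range[2], digits)))
  invisible(x)
}
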