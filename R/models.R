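# Closed-form hormetic model family and the Cedergreen hormesis model.
# All hormetic-model math runs on x = log10(concentration in mM); conversion
# from/to the linear mM axis happens only at I/O boundaries.

# Gauss error function; exact via the normal CDF, no series approximation.
erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

#' Parameters of the skewed-Gaussian hormetic model
#'
#' Bundles and validates the six parameters of the biphasic (hormetic)
#' dose-response model used throughout the package, plus the fixed sigmoid
#' steepness. The model evaluated by [hormetic_response()] is
#' \deqn{y = a\,e^{-\tfrac12((x-m)/s)^2}\,(1 + \mathrm{erf}(skew\,(x-m)))
#'       + d + \frac{c-d}{1 + e^{-steepness\,(x-m)}}}
#' with \eqn{x = \log_{10}} (concentration in mM).
#'
#' With `skew = 0` and `c = d = 0` the model collapses to a symmetric
#' Gaussian of amplitude `a` centred at `m` with width `s`. The sigmoid term
#' lets the two tails sit on independent baselines: `d` is the asymptote as
#' \eqn{x \to -\infty} (activity with no salt) and `c` the asymptote as
#' \eqn{x \to +\infty} (activity at very high salt).
#'
#' @param a amplitude scale (response units, e.g. s^-1). Scales the peak
#'   height but — once `skew` is nonzero — is not itself the peak height.
#' @param m peak reference position on the log10-concentration axis
#'   (log10 mM). The skew displaces the true mode away from `m`.
#' @param s width parameter (log10 mM); must be > 0.
#' @param skew dimensionless asymmetry factor; 0 gives a symmetric peak,
#'   positive values bias mass to the high-concentration side.
#' @param c lower asymptote as log10(conc) grows (response units, >= 0).
#' @param d upper asymptote at vanishing concentration (response units, >= 0);
#'   the zero-salt baseline rate.
#' @param steepness sigmoid transition constant; fixed at 10 by convention
#'   and never free during fitting.
#' @return An object of class `hormetic_params` (a validated named list).
#' @examples
#' p <- hormetic_params(a = 0.2, m = 1, s = 0.5, skew = 1, d = 0.005)
#' hormetic_response(log10(c(0.01, 1, 10, 50)), p)
#' @export
hormetic_params <- function(a, m, s, skew = 0, c = 0, d = 0, steepness = 10) {
  vals <- c(a = a, m = m, s = s, skew = skew, c = c, d = d,
            steepness = steepness)
  if (any(!is.finite(vals)))
    stop("hormetic parameters must all be finite", call. = FALSE)
  if (s <= 0)
    stop("width parameter 's' must be > 0", call. = FALSE)
  structure(as.list(vals), class = "hormetic_params")
}

#' @export
print.hormetic_params <- function(x, ...) {
  cat("Skewed-Gaussian hormetic model parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Evaluate the skewed-Gaussian hormetic model
#'
#' @param x numeric vector of log10(concentration in mM) values.
#' @param params a [hormetic_params()] object (or coercible named list).
#' @return Numeric vector of model responses, finite for all finite `x`.
#' @seealso [hormetic_params()], [fit_hormetic()]
#' @export
hormetic_response <- function(x, params) {
  params <- as_hormetic_params(params)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  with(params, {
    g <- a * exp(-0.5 * ((x - m) / s)^2) * (1 + erf(skew * (x - m)))
    g + d + (c - d) / (1 + exp(-steepness * (x - m)))
  })
}

as_hormetic_params <- function(p) {
  if (inherits(p, "hormetic_params")) return(p)
  p <- as.list(p)
  if (is.null(p$steepness)) p$steepness <- 10
  if (is.null(p$skew)) p$skew <- 0
  if (is.null(p$c)) p$c <- 0
  if (is.null(p$d)) p$d <- 0
  do.call(hormetic_params, p)
}

#' Parameters of the Cedergreen hormesis model
#'
#' The Cedergreen model is the established reference family for hormetic
#' dose-response data. Unlike the skewed-Gaussian model it is written on the
#' linear concentration axis and is undefined at zero dose:
#' \deqn{y = c + \frac{(d - c) + f e^{-1/x^{a}}}{1 + e^{b \ln(x/e)}}}
#'
#' @param a rate of increase before the hormetic peak (> 0); fixed at 1 by
#'   default during fitting, the common dose-response usage.
#' @param b steepness of the post-peak decline.
#' @param c lower asymptote as the dose grows without bound (response units).
#' @param d upper asymptote as the dose approaches zero (response units).
#' @param e reference dose for the halfway transition between `d` and `c`
#'   (same units as the dose, > 0).
#' @param f hormetic peak height factor (response units, >= 0); `f = 0`
#'   reduces the model to a monotone log-logistic decline from `d` to `c`.
#' @return An object of class `cedergreen_params`.
#' @examples
#' p <- cedergreen_params(a = 1, b = 3, c = 0, d = 0.05, e = 50, f = 0.4)
#' cedergreen_response(c(1, 10, 50, 200), p)
#' @export
cedergreen_params <- function(a = 1, b, c, d, e, f) {
  vals <- c(a = a, b = b, c = c, d = d, e = e, f = f)
  if (any(!is.finite(vals)))
    stop("Cedergreen parameters must all be finite", call. = FALSE)
  if (a <= 0) stop("'a' must be > 0", call. = FALSE)
  if (e <= 0) stop("'e' must be > 0", call. = FALSE)
  structure(as.list(vals), class = "cedergreen_params")
}

#' @export
print.cedergreen_params <- function(x, ...) {
  cat("Cedergreen hormesis model parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Evaluate the Cedergreen hormesis model
#'
#' @param x numeric vector of doses on the linear concentration scale
#'   (e.g. mM); must be strictly positive, the model is undefined at zero.
#' @param params a [cedergreen_params()] object (or coercible named list).
#' @return Numeric vector of model responses.
#' @seealso [cedergreen_params()], [fit_cedergreen()]
#' @export
cedergreen_response <- function(x, params) {
  if (!inherits(params, "cedergreen_params"))
    params <- do.call(cedergreen_params, as.list(params))
  if (any(!is.finite(x)) || any(x <= 0))
    stop("Cedergreen model is undefined at dose <= 0", call. = FALSE)
  with(params, c + ((d - c) + f * exp(-1 / x^a)) / (1 + exp(b * log(x / e))))
}
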