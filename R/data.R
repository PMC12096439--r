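# Dose-response container. Concentrations stay in mM on the linear scale;
# the log10 transform and pseudo-zero substitution happen at fit time.

#' Construct a dose-response dataset
#'
#' Holds (concentration, response) observations for one enzyme/substrate/salt
#' series. Replicate points are kept as individual rows and are never
#' pre-averaged. A single zero-dose (no-salt control) point is allowed; it is
#' retained as 0 mM until fitting, when it is substituted by the
#' `pseudo_zero` concentration so it can live on a log10 axis.
#'
#' @param concentration numeric vector of doses in mM (>= 0).
#' @param response numeric vector of observed rates (s^-1), finite and >= 0.
#' @param replicate optional replicate identifier per row.
#' @param label free-text label (enzyme/substrate/salt).
#' @param pseudo_zero positive concentration (mM) substituted for 0-dose
#'   points at fit time; 0.01 by default, conventionally 0.001 or 0.01.
#' @return A data.frame of class `dose_response` with attributes `label` and
#'   `pseudo_zero`.
#' @examples
#' d <- dose_response_data(c(0, 1, 5, 10, 20, 30, 50),
#'                         c(0.005, 0.02, 0.1, 0.15, 0.12, 0.05, 0.01))
#' d
#' @export
dose_response_data <- function(concentration, response, replicate = NULL,
                               label = "", pseudo_zero = 0.01) {
  if (length(concentration) != length(response))
    stop("concentration and response lengths differ", call. = FALSE)
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(response)) || any(response < 0))
    stop("responses must be finite and >= 0", call. = FALSE)
  if (!is.numeric(pseudo_zero) || length(pseudo_zero) != 1 || pseudo_zero <= 0)
    stop("pseudo_zero must be a single positive concentration (mM)",
         call. = FALSE)
  df <- data.frame(concentration = as.numeric(concentration),
                   response = as.numeric(response))
  if (!is.null(replicate)) df$replicate <- replicate
  structure(df, class = c("dose_response", "data.frame"),
            label = label, pseudo_zero = pseudo_zero)
}

#' @export
print.dose_response <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Dose-response dataset",
      if (nzchar(lab)) paste0("'", lab, "'") else "", "\n")
  cat(" ", nrow(x), "observations,",
      length(unique(x$concentration)), "distinct concentrations (mM);",
      sum(x$concentration == 0), "zero-dose point(s), pseudo-zero =",
      attr(x, "pseudo_zero"), "mM\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

# Substitute the pseudo-zero concentration and validate fitting preconditions.
prepare_doses <- function(data, n_free) {
  conc <- data$concentration
  pz <- attr(data, "pseudo_zero") %||% 0.01
  conc[conc == 0] <- pz
  n_distinct <- length(unique(conc))
  if (n_distinct <= n_free)
    stop("insufficient data: ", n_distinct, " distinct concentrations for ",
         n_free, " free parameters", call. = FALSE)
  if (stats::sd(data$response) == 0)
    stop("degenerate data: all responses identical", call. = FALSE)
  list(conc = conc, x = log10(conc), y = data$response, pseudo_zero = pz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
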