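# Tabular I/O, k_obs computation from assay primitives, JSON reports, and
# the reference parameter tables for human nuclear uracil DNA glycosylase
# (UNG2) distributed with the package.

REPORT_FORMAT_VERSION <- "1.0"

#' Observed rate constant from uracil-excision assay primitives
#'
#' Gel-based excision assays quantify the fraction of substrate processed
#' after a fixed time. The observed rate is the substrate turnover per
#' second normalized by the enzyme concentration:
#' `k_obs = (fraction * substrate_conc / time) / enzyme_conc`, in s^-1.
#'
#' @param fraction_processed fraction of substrate converted, in \[0, 1\].
#' @param substrate_conc substrate concentration (uM).
#' @param time reaction time (s, > 0).
#' @param enzyme_conc enzyme concentration (uM, > 0).
#' @return k_obs in s^-1; vectorized over all arguments.
#' @examples
#' compute_kobs(0.5, 0.5, 100, 0.0025)   # 1 s^-1
#' @export
compute_kobs <- function(fraction_processed, substrate_conc, time,
                         enzyme_conc) {
  if (any(!is.finite(fraction_processed)) || any(fraction_processed < 0) ||
      any(fraction_processed > 1))
    stop("fraction_processed must be in [0, 1]", call. = FALSE)
  if (any(!is.finite(substrate_conc)) || any(substrate_conc < 0))
    stop("substrate_conc must be >= 0", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("time must be > 0", call. = FALSE)
  if (any(!is.finite(enzyme_conc)) || any(enzyme_conc <= 0))
    stop("enzyme_conc must be > 0", call. = FALSE)
  (fraction_processed * substrate_conc / time) / enzyme_conc
}

#' Read a dose-response dataset from delimited text
#'
#' Expects a header with columns `concentration_mM` and `response`
#' (optionally `replicate`); the in-file concentration unit is fixed at mM
#' to avoid silent unit bugs. Zero-dose rows are preserved as 0 until
#' pseudo-zero substitution at fit time.
#'
#' @param path file path.
#' @param sep field separator (`","` by default; use `"\t"` for TSV).
#' @param label dataset label; defaults to the file name.
#' @param pseudo_zero pseudo-zero concentration (mM) recorded on the
#'   dataset.
#' @return A [dose_response_data()] dataset.
#' @export
read_dose_response <- function(path, sep = ",", label = basename(path),
                               pseudo_zero = 0.01) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("concentration_mM", "response")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) stop("empty dataset: no data rows in ", path,
                          call. = FALSE)
  for (col in required) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric or missing '", col, "' at data row ", bad[1],
           call. = FALSE)
    df[[col]] <- vals
  }
  if (any(df$concentration_mM < 0))
    stop("negative concentration at data row ",
         which(df$concentration_mM < 0)[1], call. = FALSE)
  dose_response_data(df$concentration_mM, df$response,
                     replicate = df$replicate, label = label,
                     pseudo_zero = pseudo_zero)
}

#' Write a dose-response dataset to delimited text
#'
#' @param data a [dose_response_data()] dataset.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(data, path, sep = ",") {
  data <- as_dose_response(data)
  df <- data.frame(concentration_mM = data$concentration,
                   response = data$response)
  if (!is.null(data$replicate)) df$replicate <- data$replicate
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a binding titration curve from delimited text
#'
#' Expects columns `titrant_M` and `intensity` (titrant concentration in
#' molar).
#'
#' @inheritParams read_dose_response
#' @param L probe concentration (molar).
#' @param direction `"quench"` or `"rise"`.
#' @return A [binding_curve()].
#' @export
read_binding_curve <- function(path, L, direction = c("quench", "rise"),
                               sep = ",", label = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("titrant_M", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  binding_curve(df$titrant_M, df$intensity, L = L,
                direction = match.arg(direction), label = label)
}

#' Assemble a structured analysis report
#'
#' Collects fit, derived-parameter, model-comparison, binding and occupancy
#' results into one versioned record that serializes losslessly to JSON
#' with deterministic key order.
#'
#' @param ... named report sections: any of `hormetic_fit`,
#'   `cedergreen_fit`, `model_comparison`, `derived_params`, `binding_fit`,
#'   `counterion_fit`, `occupancy_result`, or plain lists/data.frames.
#' @return An object of class `analysis_report`.
#' @export
analysis_report <- function(...) {
  sections <- list(...)
  if (length(sections) && is.null(names(sections)))
    stop("report sections must be named", call. = FALSE)
  structure(list(format_version = REPORT_FORMAT_VERSION,
                 sections = lapply(sections, report_section)),
            class = "analysis_report")
}

report_section <- function(x) {
  if (inherits(x, "hormetic_fit")) {
    list(type = "hormetic_fit", label = x$label,
         params = as.list(unlist(x$params)[c(HORMETIC_PAR_NAMES,
                                             "steepness")]),
         fixed = x$fixed, standard_errors = as.list(x$standard_errors),
         r2 = x$r2, r2_adjusted = x$r2_adjusted, sse = x$sse,
         n_points = x$n_points, n_free = x$n_free,
         converged = x$converged, pseudo_zero = x$pseudo_zero)
  } else if (inherits(x, "cedergreen_fit")) {
    list(type = "cedergreen_fit", label = x$label,
         params = as.list(unlist(x$params)[CEDERGREEN_PAR_NAMES]),
         fixed = x$fixed, r2 = x$r2, r2_adjusted = x$r2_adjusted,
         sse = x$sse, n_points = x$n_points, n_free = x$n_free,
         converged = x$converged, satisfactory = x$satisfactory)
  } else if (inherits(x, "model_comparison")) {
    list(type = "model_comparison", winner = x$winner,
         cedergreen_failed = x$cedergreen_failed,
         failure_message = x$failure_message,
         hormetic = report_section(x$hormetic),
         cedergreen = if (!is.null(x$cedergreen))
           report_section(x$cedergreen))
  } else if (inherits(x, "derived_params")) {
    list(type = "derived_params", has_peak = x$has_peak,
         d = x$d, y_max = x$y_max, M = x$M,
         fold_stimulation = x$fold_stimulation,
         ascending_slope = x$ascending_slope,
         descending_slope = x$descending_slope,
         stimulatory_range = as.list(x$stimulatory_range))
  } else if (inherits(x, "binding_fit")) {
    list(type = "binding_fit", no_binding = x$no_binding,
         params = if (!is.null(x$params)) as.list(unlist(x$params)),
         standard_errors = as.list(x$standard_errors), r2 = x$r2,
         direction = x$direction, converged = x$converged)
  } else if (inherits(x, "counterion_fit")) {
    list(type = "counterion_fit", N = x$N, logKa0 = x$logKa0,
         standard_errors = as.list(x$standard_errors),
         n_points = x$n_points)
  } else if (inherits(x, "occupancy_result")) {
    list(type = "occupancy", M = x$M, Kd_apparent = x$Kd_apparent,
         percent = x$percent)
  } else if (inherits(x, "thermo_result")) {
    list(type = "thermo", Ka = x$Ka, dG = x$dG, R = x$R, T = x$T)
  } else x
}

#' Write an analysis report to versioned JSON
#'
#' Keys are emitted in a deterministic order so reports are diffable;
#' special values (Inf for unbounded fold-stimulation) are encoded as
#' strings per JSON convention and restored by [read_report()].
#'
#' @param report an [analysis_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "string", pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' @param path path written by [write_report()].
#' @return The deserialized report (lists; numeric specials restored).
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  restore_specials <- function(x) {
    if (is.list(x)) return(lapply(x, restore_specials))
    if (is.character(x)) {
      y <- suppressWarnings(
        ifelse(x == "Inf", Inf,
               ifelse(x == "-Inf", -Inf, ifelse(x == "NA", NA, x))))
      numeric_like <- all(is.na(x) | x %in% c("Inf", "-Inf", "NA"))
      if (numeric_like && length(x)) return(as.numeric(y))
      return(y)
    }
    x
  }
  restore_specials(rep)
}

#' Summary-table formatting for derived parameters
#'
#' Formats derived parameters with the display conventions of a
#' dose-response summary table: rates to 4 significant digits,
#' fold-stimulation to 1 decimal place, peak concentration M to 2 decimals.
#'
#' @param derived a [derive_params()] result or list of them.
#' @param labels optional column labels.
#' @return A data.frame with one column per dataset.
#' @export
format_summary_table <- function(derived, labels = NULL) {
  if (inherits(derived, "derived_params")) derived <- list(derived)
  cols <- lapply(derived, function(dp) {
    c(`baseline rate (d) (s-1)` = signif(dp$d, 4),
      `maximum rate (y_max) (s-1)` = signif(dp$y_max, 4),
      `fold-stimulation (y_max/d)` =
        if (is.finite(dp$fold_stimulation))
          round(dp$fold_stimulation, 1) else Inf,
      `M (mM)` = round(dp$M, 2))
  })
  out <- as.data.frame(cols)
  names(out) <- labels %||% paste0("dataset_", seq_along(cols))
  out
}

#' Reference hormetic parameters for UNG2 activity
#'
#' Fitted dose-response summary parameters for human nuclear uracil DNA
#' glycosylase (UNG2) and variants acting on dsDNA and ssDNA substrates
#' across salt titrations: the zero-salt baseline rate `d`, the peak rate
#' `y_max`, the printed fold-stimulation, and the peak salt concentration
#' `M`. Distributed with the package as reference inputs for the
#' downstream occupancy and potency calculations and as ground-truth-like
#' scenarios for simulation studies.
#'
#' @return A data.frame with columns `substrate_class` (dsDNA/ssDNA),
#'   `enzyme`, `salt`, `substrate`, `d`, `y_max`, `fold_stimulation`, `M_mM`.
#' @examples
#' ref <- ung2_reference_params()
#' with(ref[ref$substrate == "55 bp" & ref$salt == "MgCl2", ],
#'      y_max / d)   # ~35.8
#' @export
ung2_reference_params <- function() {
  ds <- data.frame(
    substrate_class = "dsDNA",
    enzyme = c("UNG2", "UNG2", "UNG2", "catalytic domain", "UNG2(N215A)",
               "UNG2(Q144A)", "UNG2", "UNG2"),
    salt = c(rep("MgCl2", 6), "KCl", "NaCl"),
    substrate = c("13 bp", "27 bp", "55 bp", "55 bp", "55 bp", "55 bp",
                  "55 bp", "55 bp"),
    d = c(0.1246, 0.0805, 0.0044, 0.012, 0.0044, 0.0015, 0.007, 0.0057),
    y_max = c(0.5124, 0.4457, 0.1576, 0.3595, 0.2242, 0.0383, 0.2061,
              0.1962),
    fold_stimulation = c(4.1, 5.5, 35.8, 30.0, 51.0, 25.5, 29.4, 34.4),
    M_mM = c(6.77, 6.92, 10.04, 2.11, 8.45, 3.13, 74.25, 106.73))
  ss <- data.frame(
    substrate_class = "ssDNA",
    enzyme = "UNG2",
    salt = "MgCl2",
    substrate = c("5 nt", "7 nt", "13 nt", "27 nt", "55 nt"),
    d = c(0.3872, 0.5681, 0.1210, 0.0603, 0.0133),
    y_max = c(0.8949, 1.9591, 2.7439, 1.3633, 0.5718),
    fold_stimulation = c(2.3, 3.4, 22.7, 22.6, 43.0),
    M_mM = c(7.33, 6.73, 6.07, 6.27, 12.37))
  rbind(ds, ss)
}

#' Reference binding measurements for UNG2-ssDNA interactions
#'
#' Dissociation constants for fluorescein-labelled UNG2 binding dark-
#' quencher ssDNA at two MgCl2 concentrations (27 nt and 6 nt oligos), and
#' the apparent affinities of Mg2+ for its sites on ssDNA and dsDNA from
#' 2-aminopurine titrations. Inputs for the counterion-condensation and
#' occupancy reference calculations.
#'
#' @return A list with `counterion` (data.frame: oligo, salt_mM, Kd_M) and
#'   `Kd_apparent_mM` (named vector: ssDNA, dsDNA).
#' @export
ung2_reference_binding <- function() {
  list(
    counterion = data.frame(
      oligo = c("27 nt", "27 nt", "6 nt", "6 nt"),
      salt_mM = c(1, 50, 1, 50),
      Kd_M = c(3e-9, 11e-6, 1e-6, 8e-6)),
    Kd_apparent_mM = c(ssDNA = 0.8, dsDNA = 0.4))
}
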