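# Independent oracle transcriptions of the model formulas, kept separate
# from the package implementation (different erf source, scalar arithmetic)
# so agreement checks are genuinely two-path.

oracle_hormetic <- function(a, m, s, skew, c, d, x, steepness = 10) {
  vapply(x, function(xi) {
    gauss <- a * exp(-0.5 * ((xi - m) / s)^2)
    asym <- 1 + pracma::erf(skew * (xi - m))
    sig <- (c - d) / (1 + exp(-steepness * (xi - m)))
    gauss * asym + d + sig
  }, numeric(1))
}

oracle_cedergreen <- function(a, b, c, d, e, f, x) {
  vapply(x, function(xi) {
    c + ((d - c) + f * exp(-1 / xi^a)) / (1 + exp(b * log(xi / e)))
  }, numeric(1))
}

oracle_hyperbola <- function(x, Kd, Fmax, Fmin) {
  Fmax - (Fmax - Fmin) * x / (Kd + x)
}

# noiseless dataset straight from the hormetic truth on a 12-dose design
noiseless_hormetic_data <- function(truth,
                                    doses = c(0, 0.5, 1, 2, 5, 10, 15, 20,
                                              30, 50, 100, 300),
                                    pseudo_zero = 0.01) {
  conc_eff <- ifelse(doses == 0, pseudo_zero, doses)
  dose_response_data(doses, hormetic_response(log10(conc_eff), truth),
                     pseudo_zero = pseudo_zero)
}
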