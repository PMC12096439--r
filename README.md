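# hormetica

Biphasic (hormetic) dose–response modeling for salt-dependent enzyme
kinetics, with the downstream biophysics: binding isotherms under ligand
depletion, counterion-condensation slopes, and DNA ion-site occupancy.

## Who this is for

Enzymologists and biophysicists analyzing rate measurements (`k_obs`, s⁻¹)
collected across salt concentrations that show the classic hormetic
signature — detectable activity with no salt, strong stimulation at
moderate salt, near-complete inhibition at high salt. The motivating system
is human nuclear uracil DNA glycosylase (UNG2), whose uracil-excision
activity is stimulated up to ~50-fold by low-millimolar Mg²⁺ and abolished
at high salt, but nothing in the machinery is specific to that enzyme.

## The model

Rates are modeled on the log₁₀ concentration axis (in mM) as a skewed
Gaussian riding on a two-level baseline:

    y(x) = a · exp(−½((x−m)/s)²) · (1 + erf(skew·(x−m)))
           + d + (c−d) / (1 + exp(−10·(x−m)))

`d` is the zero-salt baseline rate, `c` the high-salt asymptote, and the
error-function factor lets the peak be asymmetric. From a fit the package
derives the biologically meaningful summaries: peak rate `y_max`, peak
concentration `M` (mM), fold-stimulation `y_max/d`, inflection-point
slopes, and the stimulatory concentration range. The established Cedergreen
hormesis model is available as the comparison family, ranked by adjusted
R². Companion tools implement the quadratic (ligand-depletion) binding
isotherm, ΔG = −RT·ln(Ka), the counterion-condensation regression
log₁₀(Ka) = log₁₀(Ka⁰) − N·log₁₀[salt], and percent ion-site occupancy
100·M/(K_d,app + M).

See `vignettes/hormetic-modeling.Rmd` for the full methods account.

## Worked example

A synthetic MgCl₂-style titration with known ground truth
(`a = 0.16, m = 1, s = 0.45, skew = 1.2, c = 0, d = 0.0044`; true peak
`y_max = 0.184` s⁻¹ at `M = 15.8` mM, 41.8-fold stimulation) ships in
`inst/extdata/`:

```r
library(hormetica)
d <- read_dose_response(system.file("extdata", "synthetic_mgcl2_series.csv",
                                    package = "hormetica"))
fit <- fit_hormetic(d, fix = list(c = 0))
derive_params(fit)
#> Derived hormetic parameters:
#>   baseline rate d:      0.004061 s^-1
#>   maximum rate y_max:   0.1855 s^-1
#>   fold-stimulation:     45.67
#>   peak concentration M: 16.3 mM
#>   slopes at inflections: +0.2794 / -0.2946 per log10 mM
#>   stimulatory range:    0.00165 – 182.3 mM
```

The fitted baseline (0.0041 vs 0.0044 s⁻¹), peak rate (0.186 vs 0.184 s⁻¹)
and peak position (16.3 vs 15.8 mM) recover the truth to within a few
percent from 5%-noise triplicates; the derived summaries are much better
determined than the raw `(m, skew)` pair, which trades position against
asymmetry. Comparing model families and asking how occupied the Mg²⁺ sites
are at the optimum (dsDNA affinity `K_d,app = 0.4` mM):

```r
compare_models(d, fix_hormetic = list(c = 0))
#> Model comparison (adjusted R2):
#>   hormetic:   0.99385
#>   Cedergreen: 0.83571
#>   winner: hormetic
percent_occupancy(derive_params(fit)$M, 0.4)
#> Ion-site occupancy at peak-activity concentration(s):
#>       M_mM Kd_apparent_mM percent
#> 1 16.30468            0.4    97.6
```

A thin command-line wrapper over the same functions lives at
`inst/cli/hormetica.R` (verbs: `fit`, `binding`, `counterions`,
`occupancy`, `simulate`, `recover`).

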