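---
title: "Modeling biphasic salt dependence of enzyme activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling biphasic salt dependence of enzyme activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hormetica)
```

## The problem

Many DNA-modifying enzymes — uracil DNA glycosylase (UNG2) is the motivating
case — show a *biphasic* (hormetic) response to salt: activity is detectable
but low with no salt, rises steeply to a maximum at moderate cation
concentrations, and collapses toward zero at high salt. A dose–response
analysis of such data has to answer four questions: What is the zero-salt
baseline rate? How high is the peak and at what concentration does it occur?
How steep are the flanks? Over what concentration window is the enzyme
actually stimulated? `hormetica` provides the model family, the fitting
machinery and the downstream biophysical calculations to answer them.

## The skewed-Gaussian hormetic model

With $x = \log_{10}(\text{concentration in mM})$ the fitted curve is

$$y(x) = a\,e^{-\frac{1}{2}\left(\frac{x-m}{s}\right)^2}
\bigl(1 + \operatorname{erf}(skew\,(x-m))\bigr)
+ d + \frac{c-d}{1+e^{-10\,(x-m)}}.$$

The first factor is a Gaussian peak; the error-function factor skews it
(positive $skew$ pushes mass toward higher concentrations, and displaces the
true mode away from the reference point $m$); the logistic term gives the two
tails *independent baselines*: $d$ is the asymptote at vanishing salt (the
no-salt rate, which is experimentally nonzero) and $c$ the asymptote at very
high salt (near zero). The sigmoid steepness is fixed at 10, which makes the
baseline hand-off essentially complete within about $\pm 0.5$ of a decade of
$m$; it is stored on the parameter object but never free during fitting.
Setting $skew = 0$ and $c = d = 0$ recovers an exact symmetric Gaussian —
that reduction, and the two asymptote identities, are enforced by tests.

Parameters and units:

| parameter | meaning | units | default bound |
|---|---|---|---|
| `a` | amplitude scale | s⁻¹ | free, either sign |
| `m` | peak reference on log axis | log₁₀ mM | free |
| `s` | width | log₁₀ mM | > 0 |
| `skew` | asymmetry | — | free |
| `d` | zero-salt baseline | s⁻¹ | ≥ 0 |
| `c` | high-salt asymptote | s⁻¹ | ≥ 0 |

`a` is left unbounded in sign so that U-shaped (inverted-hormetic) data stay
fittable; the asymptotes are kept non-negative because they are rates.

## Fitting

`fit_hormetic()` minimizes the unweighted residual sum of squares with the
Levenberg–Marquardt algorithm (`minpack.lm::nls.lm`, box constraints,
relative SSE tolerance $10^{-10}$, at most $10^4$ evaluations). Replicates
enter as individual points and are never pre-averaged. Weighting is
deliberately plain least squares: gel-quantified rates carry no reliable
per-point error estimate.

Initialization is heuristic: $d_0$ from the lowest dose, $c_0$ from the
highest, $m_0$ at the dose of maximal response, $s_0$ a quarter of the
log-concentration span, $a_0$ the max-minus-baseline. Because the peak
heuristic mis-places $m_0$ when the data are monotone, a second $m_0$
candidate is placed at the half-drop midpoint. Each $m_0$ is crossed with
$skew_0 \in \{-2, 0, +2\}$; the lowest final SSE wins, ties going to the
smallest fitted $|skew|$. The final SSE can never exceed any start's SSE, a
property the test suite asserts.

**Zero-dose convention.** A 0 mM control cannot sit on a log axis; it is
assigned a pseudo-concentration of 0.01 mM by default (0.001 mM is the other
conventional choice, settable per dataset). The substitution happens at fit
time; files and datasets keep the honest 0. The choice is recorded on the
fit object.

**Constraints.** Any parameter can be fixed via `fix = list(c = 0)` etc.
Fixed parameters are excluded from the free-parameter count $p$ used in
adjusted $R^2 = 1 - (1-R^2)(n-1)/(n-p-1)$, as is the fixed steepness.

## The Cedergreen comparison

The established alternative for hormesis is the Cedergreen model, written on
the *linear* dose axis:

$$y = c + \frac{(d-c) + f e^{-1/x^{a}}}{1 + e^{b \ln(x/e)}},$$

with $f = 0$ collapsing to a monotone log-logistic decline. `fit_cedergreen()`
fixes the pre-peak exponent $a = 1$ by default — the value is not critical
for the comparison and $a=1$ is the common dose–response usage — and frees
$b, c, d, e, f$ ($f \ge 0$, $e > 0$). `compare_models()` fits both families
and ranks them by adjusted $R^2$; a Cedergreen fit that does not converge, or
that is pinned at $f = 0$ while fitting worse than a flat mean, is flagged
unsatisfactory and the comparison records a failure rather than aborting.
Note the two families intersect but neither contains the other: the hormetic
sigmoid has fixed steepness 10 per log₁₀ unit, which equals a Cedergreen
decline with $b = 10/\ln 10 \approx 4.34$.

## Derived parameters

The skewed model has no closed-form mode, so `locate_peak()` maximizes the
curve on a dense grid ($10^4$ points per decade over the data span extended
one decade each side) and refines the argmax with bounded scalar
optimization to better than $10^{-6}$ log units. `M` is reported in mM. A
grid argmax on the span boundary means the curve is monotone there: a
no-peak result, not an error.

Fold-stimulation is the plain ratio $y_{\max}/d$. When $d$ has been
constrained to 0 (within $10^{-12}$) the ratio is reported as `Inf` rather
than an error, since constraining $c$ or $d$ to zero is a legitimate
modeling move.

`slopes_and_range()` finds the inflection points flanking the peak as sign
changes of the numerical second derivative (central differences, refined by
bisection) and reports the first derivative there, in response units per
log₁₀ mM. The *stimulatory range* is the maximal concentration interval
around the peak where the curve stays at or above the baseline $d$. Its
endpoints are roots of $y(x) = d$; the gap is evaluated in a
subtraction-free form (peak term minus $(d-c)\cdot\text{plogis}$) because
near the lower crossing both terms can sit dozens of orders of magnitude
below $d$, where the naive difference underflows. An endpoint is reported as
0 or `Inf` mM when no crossing exists within $m \pm 100\cdot\max(s,1)$ log
units.

## Binding analyses

Fluorescence titrations in which the probe concentration $L$ is comparable
to $K_d$ need the quadratic (ligand-depletion) isotherm. With
$b = K_d + x + L$, the bound probe fraction is
$(b - \sqrt{b^2 - 4xL})/(2L)$, and the two orientations map it to intensity
from `Fmax` downward (quench) or from `Fmin` upward (rise). When
$L \ll K_d$ this converges to the familiar hyperbola, a limit the tests
check at 0.1%. `fit_binding()` estimates `Fmax`, `Fmin`, `Kd` and optionally
`L`; a titration whose intensity change is indistinguishable from its
residual noise returns a no-binding flag instead of a meaningless $K_d$.

Binding free energy: $\Delta G_{\text{bind}} = -RT\ln K_a$, with
$K_a = 1/K_d$, $R = 1.987$ cal K⁻¹ mol⁻¹ and $T = 295.15$ K (22 °C) by
default, reported in kcal/mol.

Counterion condensation: `fit_counterion_release()` regresses
$\log_{10} K_a$ on $\log_{10}[\text{salt}]$; the slope magnitude $N$
estimates the number of cations released from the DNA ion cloud on protein
binding. The slope is invariant to the concentration unit; the intercept is
not, and for oligonucleotides too short to behave as polyelectrolytes both
the slope and the extrapolated intercept deserve caution.

Ion-site occupancy: $\%\text{occ} = 100\,M/(K_{d,\text{app}} + M)$, the
basic ligand-binding equation; the log-axis form used for plotting is
algebraically identical, which the tests assert to machine precision.

## Synthetic data and what it shows

`simulate_hormetic_data()` emulates the assay design this analysis targets:
a divalent-salt grid $\{0, 0.5, 1, 2, 5, 10, 15, 20, 30, 50\}$ mM (or a
monovalent grid to 1000 mM), triplicate measurements, and Gaussian noise on
the rate scale with a proportional CV of 5% by default — assays quantified
from gel band intensities plausibly carry multiplicative error, and no
empirical error model is available. Negative draws are truncated at zero,
a small upward bias only where the true rate is within a couple of noise
SDs of zero.

What the generator does *not* emulate: day effects or other replicate
correlation, dose-dependent error structure, pipetting error in the dose
itself, and departure of real curves from the model family. Passing
recovery tests therefore demonstrate that the estimation machinery is
correct and well-conditioned under the stated noise model — not that real
assay data obey it.

`run_recovery()` aggregates bias, RMSE and median relative error over
seeded simulate–fit–derive cycles. Two facts from these studies are worth
knowing before fitting real data. First, the *derived* summaries
($y_{\max}$, $M$) are far better determined than the raw parameters: at 5%
noise on a 12-dose design the median relative error of $\hat M$ is about
3%, while $m$ and $skew$ individually can wander (they trade off against
each other; a skew/position ridge is intrinsic to the family at small
$|skew|$). Second, constraining what is known — e.g. $c = 0$ when the
high-salt rate is indistinguishable from zero — markedly improves the
identifiability of everything else. The study sizes used in the shipped
tests (100 seeds for the stochastic checks, 25 per noise level for the
noise-monotonicity property) keep the whole suite comfortably fast while
leaving the medians stable.

## Numerical choices

* erf comes from the normal CDF identity
  $\operatorname{erf}(z) = 2\Phi(z\sqrt 2) - 1$ — exact, no series
  approximation.
* The model is evaluated directly; the only guarded operations are the
  binding discriminant (clamped at 0 against rounding) and the
  stimulatory-range gap (subtraction-free form, above).
* Optimizer: relative SSE change $< 10^{-10}$ or $10^4$ evaluations;
  convergence is read from the information code, and a stalled fit returns
  `converged = FALSE` rather than throwing.
* Asymptote identities hold to $10^{-8}$ at $m \pm 50s$ only where
  $50\,s\cdot\text{steepness} \gg 1$; with the default steepness this is
  any $s \gtrsim 0.4$, the physically relevant regime for these data.

## Limitations

* Confidence intervals are asymptotic standard errors from the Jacobian;
  no profile likelihood or bootstrap.
* No heteroscedastic weighting or shared-parameter global fits.
* The Cedergreen exponent $a$ is fixed at 1 by default; data demanding
  $a \ne 1$ must free it explicitly.
* The reference parameter tables shipped with the package
  (`ung2_reference_params()`, `ung2_reference_binding()`) are summary
  values; the underlying raw rate data are not distributed here, so the
  package validates its fitting machinery on synthetic data with known
  truth rather than on the original measurements.
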