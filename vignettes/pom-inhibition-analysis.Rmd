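---
title: "Models and methods: quantifying polyoxometalate inhibition of amyloid formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying polyoxometalate inhibition of amyloid formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amypom)
```

amypom analyses the biophysical readouts by which small polyoxyanion
clusters (polyoxometalates, POMs, such as decaniobate Nb10 and
monotitanoniobate TiNb9) are characterised as inhibitors of S100A9
amyloid formation: thioflavin-T (ThT) aggregation kinetics, fluorescence
titrations, acrylamide quenching, circular dichroism (CD) spectra and
AFM fibril cross-sections. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices made where
the analysis was genuinely open.

## Isodesmic aggregation kinetics

S100A9 self-assembles without a significant lag phase: ThT traces rise
steeply from time zero and approach a plateau hyperbolically. That shape
is the signature of isodesmic (step-growth) polymerization, in which
every monomer-addition step has the same rate constant — in contrast to
nucleation–elongation mechanisms, which produce sigmoidal traces with a
lag. The extent of reaction (the fraction of reacted groups, which the
normalized ThT signal tracks) obeys

$$\frac{dp}{dt} = k_f c_0 (1-p)^2 - k_b\, p, \qquad p(0)=0,$$

with forward and backward step rates $k_f$ (per concentration per hour)
and $k_b$ (per hour) and total monomer concentration $c_0$. This is a
Riccati equation with constant coefficients; with $a = k_f c_0$,
$s = \sqrt{k_b(k_b + 4a)}$ and smaller root
$p_- = (2a + k_b - s)/2a$, its solution is

$$p(t) = \frac{1 - e^{-st}}{s/a + p_-\,(1 - e^{-st})},$$

implemented in `isodesmic_extent_reversible()` (the numerator uses
`expm1` so the $k_b \to 0$ limit is numerically stable). Because the
two Riccati roots have product one, $p$ rises monotonically to the
equilibrium extent $p_{eq} = p_- < 1$.

Depolymerization of S100A9 fibrils is not measurable on the assay
timescale, so the traces are fitted with the $k_b = 0$ limit,

$$p(t) = \frac{k t}{1 + k t},$$

where $k = k_f c_0$ is the single apparent polymerization rate constant
(`isodesmic_extent()`). Both forms are verified in the test suite
against direct numerical integration of the rate equation (tolerance
1e-5 over 0–150 h for random parameter draws).

`fit_kinetic_trace()` fits `baseline + amplitude * p(t; k)` by bounded
Levenberg–Marquardt least squares ($k > 0$, amplitude $\ge 0$). The
starting rate is data driven — $p = 1/2$ at $kt = 1$, so $k_0$ is the
reciprocal of the time at which the signal crosses half of its total
change — with five log-spaced restarts of $k_0$ on non-convergence
(cost tolerance 1e-10, at most 2000 evaluations per start). Constant or
monotonically decreasing traces are rejected as fit failures rather
than returned as meaningless rates. Standard errors come from the
covariance of the converged fit.

Because the model is linear in the signal scale, the fitted $k$ is
invariant to any positive rescaling of a trace; panel normalization
(`normalize_panel()`, which divides every trace by the
replicate-averaged maximum of the inhibitor-free reference so the
reference peak maps to 1.0) therefore changes amplitudes but never
rates. Normalization is idempotent.

### Dose response of the apparent rate

The apparent rate falls roughly exponentially with POM concentration.
`fit_rate_concentration()` fits

$$k(c) = \alpha\, e^{-\beta c} + \gamma,$$

with $\alpha$ the inhibitable rate amplitude, $\beta$ (1/µM) the
susceptibility of the rate to the inhibitor, and $\gamma$ the residual
rate at saturating inhibitor. The functional layout of the published
exponential is not printed anywhere, so two standard parameterizations
are supported: the default above, and a scale form
$\alpha e^{-c/\beta} + \gamma$ (`parameterization = "scale"`), which is
the same family with $\beta$ inverted. Both $\alpha$ and $\beta$ are
bounded at zero — the model describes an inhibitor — so rates that do
not decay with concentration drive one of them to its bound; the fit is
then flagged (`beta_at_bound`) instead of reporting a spurious
susceptibility. Replicates are fitted individually and summarized as
mean ± SD per condition (a pooled fit of replicate-averaged traces is
possible by averaging before fitting); the per-replicate default
propagates between-well variability into the dose–response stage.

## One-site binding isotherms

Fluorescence titrations (intrinsic tryptophan or ANS probe) are fitted
with the single-site binding fraction

$$\theta(c) = \frac{c}{K_d + c}, \qquad
S(c) = S_0 + (S_\infty - S_0)\,\theta(c),$$

which handles the observed decreasing signals ($S_\infty < S_0$) as
well as increasing ones. $c$ is the *total* titrated POM concentration.
When $K_d$ is comparable to the protein concentration (a few µM of
protein against $K_d \approx$ 0.5–3 µM), ligand depletion by the bound
complex is not negligible; `fit_titration(depletion = TRUE, P = ...)`
uses the exact quadratic solution

$$\theta = \frac{(P + c + K_d) - \sqrt{(P + c + K_d)^2 - 4 P c}}{2P}$$

with $P$ defaulting to 4 µM, the protein concentration of the intrinsic
fluorescence experiments. The simple isotherm remains the default
because it is what the published $K_d$ values were obtained with; the
two agree as $P \to 0$.

Starting values are data driven ($K_d$ from the concentration at half
the signal change; endpoints from the first and last points). A curve
whose fitted signal change is smaller than twice the residual standard
deviation is flagged `unidentifiable` — a $K_d$ from a flat curve is
noise. Uncertainties are covariance-based by default; a seeded residual
bootstrap (`bootstrap = n`) is available because the error convention
of the published estimates is not stated.

## Sphere-of-action quenching

Acrylamide quenching of tryptophan fluorescence produces Stern–Volmer
plots that curve upward, which indicates a static contribution:
quenchers adjacent to the fluorophore at the moment of excitation
quench instantly. The sphere-of-action model multiplies the dynamic
Stern–Volmer law by an exponential static factor:

$$\frac{F_0}{F} = (1 + K_{SV} Q)\, e^{V Q},$$

with $K_{SV}$ (1/M) the dynamic constant and $V$ (1/M) the effective
action volume. `fit_quenching()` takes $F_0$ from the measured $Q = 0$
point (it is not a fit parameter — matching the convention in which
plotted ratios are anchored at 1), and fits $(K_{SV}, V)$ with both
bounded at zero; $V = 0$ recovers the linear law exactly.

The action volume converts to an equivalent radius with the litre-based
convention

$$V \,[\mathrm{M}^{-1}] = N_A \cdot \tfrac{4}{3}\pi r^3 \,[\mathrm{L}],$$

i.e. Avogadro's number times the per-molecule sphere volume in litres
(`radius_to_action_volume()` / `action_volume_to_radius()`). A radius
of 7.7 Å corresponds to $V = 1.152$ 1/M under this convention, which
reproduces radii of the observed 7–9 Å magnitude from Stern–Volmer-scale
volumes. The convention lives in one pair of functions so an
alternative (e.g. a cm³-based constant) can be swapped without touching
the fitters. The radius standard error is propagated to first order,
$\mathrm{se}(r) = r\,\mathrm{se}(V)/(3V)$, and is undefined at $V = 0$.

## Weighted spectral difference for CD spectra

To decide whether two CD spectra differ beyond replicate noise, spectra
are compared by a weighted spectral difference,

$$\mathrm{WSD} = \sqrt{\frac{1}{n}\sum_i w_i\,(\mathrm{ref}_i - \mathrm{test}_i)^2},
\qquad w_i = \frac{|\mathrm{ref}_i|}{\frac{1}{n}\sum_j |\mathrm{ref}_j|},$$

squared pointwise differences weighted by the reference magnitude, with
weights normalized to average one so WSD keeps the units of the spectra.
The exact weighting convention of the original WSD definition is not
publicly printed; this reference-magnitude form is adopted and isolated
in a single internal function (`wsd_weights()`) so it can be swapped.
Its defining properties — WSD = 0 iff the spectra are identical, WSD
scales linearly with a uniform scaling of the difference at fixed
reference, and WSD is *asymmetric* because the weights come from the
reference — are what the tests pin down. An all-zero reference leaves
the weights undefined and is a degenerate-input error.

`wsd_uncertainty()` computes the WSD of the repeat-mean spectra and
estimates its standard deviation from all pairings of individual repeat
scans (5 × 5 = 25 pairs for the standard five CD repeats), the same way
replicate scans put error bars on published WSD traces.

`spectral_maximum()` implements the first-derivative method for peak
positions: Savitzky–Golay smoothing (default window 9 points, polynomial
order 2 — both configurable), then the positive-to-negative zero
crossing of the first difference quotient, refined by linear
interpolation between the bracketing midpoints. Monotone spectra raise a
no-peak error. For background subtraction on mismatched grids the
background is linearly interpolated onto the sample grid over the
overlap only; extrapolation is forbidden.

## AFM height statistics

Fibril cross-sectional heights are summarized as they are reported with
height histograms: the sample median, the *median deviation* — the
unscaled median absolute deviation from the median, with no 1.4826
consistency factor, since it is used descriptively, not as a robust
sigma — and the number of measurements (`height_summary()`).

`compare_height_distributions()` is an addition beyond the descriptive
summaries: a median difference with a seeded bootstrap confidence
interval and a two-sided permutation p-value for the null of a common
generating distribution. The p-value uses the mid-p convention
(permutations tied with the observed statistic count one half) because
the median statistic is discrete in small samples and the conventional
rule would be noticeably conservative; with mid-p the null distribution
of p is close to uniform, which the test suite checks over 500 seeded
runs.

## What the synthetic generators emulate

The generators provide every input the pipeline consumes, with the
statistical structure the analysis assumes:

* `gen_kinetic_panel()` — a plate of lag-free hyperbolic ThT traces at
  75 µM protein, inhibitor:protein molar ratios
  {0, 0.5, 1, 2, 4, 8, 10}, 150 h sampled every 10 minutes, in
  triplicate, with 2% multiplicative Gaussian noise (plate-reader-like:
  the error scales with the signal). The apparent rate follows the
  exponential dose response; the plateau amplitude decays with the same
  exponential family, because the phenomenon (plateaus fall with
  inhibitor) is observed but no functional form is reported for it.
  Default shapes — rate α = 0.2 1/h, β = 0.01 1/µM, γ = 0.005 1/h;
  plateau α = 0.9, β = 0.004 1/µM, γ = 0.1; baseline 0.02 — were chosen
  once as realistic for S100A9: an uninhibited half-time of ~5 h,
  plateau well within 150 h, and strong but incomplete suppression of
  both rate and plateau at the highest (750 µM) inhibitor concentration.
* `gen_titration_curve()` / `gen_quenching_curve()` — exact model curves
  plus multiplicative noise; the quenching grid always includes Q = 0.
* `gen_spectrum()` — sums of Gaussian bands with independent additive
  noise per repeat scan.
* `gen_heights()` — log-normal heights (log-normality guarantees
  positivity, unlike a Gaussian) parameterized so the *population*
  median and median deviation equal the requested targets; the sdlog is
  solved numerically from the target median deviation.

Every generator is a deterministic function of its parameters and seed.

What passing tests on these data do **not** show about real data: the
generators have no well-position or edge effects, no signal drift or
photobleaching, no evaporation late in a 150 h run, Gaussian rather than
heavy-tailed noise, and exactly the fitted model as the truth — so
recovery studies here measure estimator correctness and precision, not
model adequacy for a real instrument. Model adequacy must come from
residual inspection on measured curves.

## Numerical choices and problem sizes

* Optimizer: bounded Levenberg–Marquardt, cost tolerance 1e-10, max
  2000 evaluations per start, five log-spaced restarts of the leading
  parameter on failure.
* Degenerate inputs are flagged or rejected, never silently fitted:
  constant/decreasing kinetic traces (error), flat titrations
  (`unidentifiable`), non-decaying dose–response (`beta_at_bound`),
  increasing quenching curves (error), all-zero WSD references (error).
* The parameter-recovery studies use 100 seeded replicate curves of
  20–25 points each (titrations) or 11 points (quenching), and the
  kinetic panel uses 21 traces of 901 points — sizes at which the whole
  suite runs in well under a minute while medians over replicates are
  stable to a few percent.
* Seeds: every stochastic routine takes an explicit integer seed and
  restores the caller's RNG state afterwards.

## Known limitations

* The isodesmic fit reports a single apparent rate; it cannot detect
  secondary nucleation or fragmentation, which would need sigmoidal
  master-equation models (out of scope by design).
* The one-site isotherm assumes a single class of independent sites;
  cooperative or multi-site binding will bias $K_d$.
* WSD weighting is one defensible convention among several; comparisons
  across software should check the weight definition.
* The sphere-of-action radius depends on the volume convention; use the
  documented conversion when comparing radii between analyses.
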