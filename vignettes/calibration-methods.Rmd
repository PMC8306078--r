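---
title: "Hyperspectral PLS calibration: models, rules and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral PLS calibration: models, rules and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Internal quality attributes of intact fruit — vitamin C, total phenols,
soluble solids content (SSC), titratable acidity (TA) — are routinely
assayed by destructive wet chemistry. Hyperspectral imaging offers a
non-destructive alternative: a push-broom scanner records a reflectance
spectrum for every pixel, and a multivariate calibration maps spectra to
constituent concentrations. `hyperpls` implements the full calibration
workflow for two common sensor regions, VIS-NIR (400–1000 nm) and NIR
(900–1700 nm), both on a 5 nm grid (121 and 161 variables respectively):
spectral pretreatment, PLS1 regression with leave-one-out
cross-validation, parsimonious latent-variable selection, backward
interval-wise wavelength elimination, cross-validation outlier removal,
stratified 70/30 evaluation, and pixel-wise concentration mapping.

Because reference data sets of fruit spectra with paired chemistry are
rarely public, the package ships a synthetic data generator that
reproduces the statistical structure such a study assumes. Every
claim the test suite makes is a claim about this generator; the section
on its limitations below spells out what that does and does not imply
about real fruit.

## The calibration model

For one constituent, let $X$ be the $I \times p$ matrix of pretreated
calibration spectra and $y$ the concentration vector. PLS1 extracts
latent variables sequentially (NIPALS deflation): at step $a$ the weight
vector is $w_a \propto X_{a-1}^{\top} y_{a-1}$ (normalised), the score
is $t_a = X_{a-1} w_a$, loadings are
$p_a = X_{a-1}^{\top} t_a / t_a^{\top} t_a$ and
$q_a = y_{a-1}^{\top} t_a / t_a^{\top} t_a$, and both blocks are
deflated by $t_a$. The regression vector in the pretreated variable
space is $b = W (P^{\top} W)^{-1} q$, with intercept
$\bar y - \bar x^{\top} b$. Both blocks are centered inside the fit, so
the model applies unchanged to uncentered inputs, and with $k$ equal to
the rank of $X$ the fit coincides with ordinary least squares — a
property the test suite checks against a normal-equations oracle.

### Choosing the number of latent variables

Leave-one-out cross-validation refits the model $I$ times — including
the centering statistics, which are recomputed from each fold's
training rows so no information leaks from the held-out sample — and
accumulates $\mathrm{PRESS}(k) = \sum_i (\hat y_{(i),k} - y_i)^2$ for
every candidate count $k$. The selection rule is the classical
parsimony criterion: the ratio $\mathrm{PRESS}(k)/\min_k \mathrm{PRESS}$
is treated as a variance ratio with $(I, I)$ degrees of freedom, and the
chosen $k$ is the smallest one at or below the PRESS minimiser whose
ratio is *not* significantly greater than 1 — concretely, whose
F-distribution probability falls below 0.75. The threshold is
configurable, and a raw-ratio variant (`method = "ratio"` in
`select_lv()`) is provided for toolbox compatibility. When every PRESS
value ties, parsimony wins and one latent variable is selected.

`loo_cv()` is implemented as a literal refit — no rank-one update
shortcuts — and the suite separately re-implements the refit loop as a
brute-force oracle; the two must agree to $10^{-8}$ relative. The
maximum candidate count defaults to $\min(20, I-2, p)$.

### Wavelength elimination

`modified_ipls()` divides the grid into contiguous, near-equal
intervals (default 20 per region, i.e. roughly 6–8 variables each;
earlier intervals absorb the remainder when the count does not divide).
Elimination is greedy and backward: each round tentatively removes every
retained interval in turn, re-runs the cross-validation *with the
latent-variable count re-selected* (the optimal complexity shrinks as
variables disappear), and permanently discards the single interval whose
removal improves RMSECV the most. Ties break toward the interval
starting at the lower wavelength, making the trace deterministic. The
procedure stops when no removal helps, so the final RMSECV can never
exceed the full-spectrum RMSECV; with a single interval it is a no-op.
Exhaustive subset search was rejected as intractable ($2^{20}$ subsets)
and unnecessary for contiguous spectral structure.

### Outlier diagnosis

With left-out predictions in hand, each sample's deviation is scored as

$$F_y(i) = \frac{(I-1)\,(\hat y_{\mathrm{pred},i} - y_{\mathrm{nom},i})^2}
{\sum_{j \ne i} (\hat y_{\mathrm{pred},j} - y_{\mathrm{nom},j})^2},$$

referred to an F distribution with $(1, I-1)$ degrees of freedom.
Samples with upper-tail probability below `alpha` (default 0.01) are
flagged; `remove_outliers_refit()` drops the single most extreme
flagged sample, refits the cross-validation, and repeats. Two guards
bound the loop: `max_rounds`, and a sample floor of 80% of the initial
count — iterative outlier hunts on small calibration sets can otherwise
delete their way to optimism. Under the null (no outliers, approximately
i.i.d. residuals) the flag rate is close to `alpha`; the acceptance
suite verifies this over 200 simulated data sets, and verifies that a
sample spiked by ten standard deviations is always caught.

## Pretreatment chains

Chains are written exactly as practitioners log them —
`"SM + Log + 1st Dev + MC"` — and applied in the printed order:

* **SM** — Savitzky–Golay polynomial smoothing (`signal::sgolayfilt`).
* **Log** — decadic absorbance, $A = -\log_{10} R$, the conventional
  linearising transform for reflectance; a natural-log option exists.
* **1st/2nd Dev** — Savitzky–Golay derivatives. The derivative *is* the
  local-polynomial filter's analytic derivative (one pass), not a
  finite difference of smoothed values, and is scaled by the 5 nm grid
  step so units are per nm and per nm². Edge values come from the
  polynomial fit itself, so no wavelengths are trimmed and the
  121/161-variable counts are preserved through any chain.
* **MC** — mean centering, constrained to be the last step. Fitting a
  chain stores the calibration column means; `chain_apply()` reuses
  them verbatim on prediction spectra and image pixels.

Window 7 and polynomial order 2 are the defaults — conventional for a
5 nm grid, wide enough to suppress sensor noise without flattening the
~12–45 nm-wide absorption features the generator produces — and both
are exposed. A chain may contain at most one derivative step. On an
exact quadratic spectrum the second-derivative chain returns the
analytic constant at every band to $10^{-9}$, which the suite asserts.

## The synthetic generator

The generator is the package's test bed and its null model. Its forward
model is additive Beer–Lambert mixing in decadic absorbance:

$$A(\lambda) = \sum_k c_k\, \varepsilon_k(\lambda) + B(\lambda) + d(\lambda),
\qquad R = 10^{-A} + \epsilon,$$

where $\varepsilon_k$ sums Gaussian bands for constituent $k$,
$B$ is a fixed background (broad water bands at 970 and 1450 nm,
amplitude 0.4, on a 0.25 pedestal), $d$ is a per-sample smooth baseline
drift (quadratic in wavelength, coefficient scale 0.005 absorbance),
and $\epsilon$ is i.i.d. Gaussian sensor noise with standard deviation
0.005 reflectance units. Band positions follow the assignment
literature: vitamin C features at 850, 1000, 1210, 1360, 1460, 1580 and
1650 nm; phenolics (ferulic-acid dominated) near 450 nm; carbohydrate
features near 880–920 nm; organic-acid information in 900–1000 nm. Band
strengths were fixed once so that each constituent's absorbance
contribution is a realistic fraction (0.1–0.2 AU) of the background,
and are user-editable. A constituent with no band inside the simulated
region is rejected at generation time — it would be unlearnable by
construction, and silently generating such data would make downstream
recovery failures uninterpretable.

Concentrations are drawn per maturity stage from truncated normal
distributions on the published ranges. The ripeness effect is a linear
mean shift of one within-stage standard deviation per stage for vitamin
C, SSC and TA (direction is documented for these constituents; the
magnitude is a package convention). Because truncation and stage
spread both distort moments, the latent mean and within-stage sd are
calibrated by a fixed-point iteration on the analytic truncated-normal
moments so that the pooled population reproduces the target mean and sd;
the suite checks both to within 10% at $n = 1000$.

`noise_equivalent_error()` propagates the reflectance noise through the
forward model to the best achievable per-sample concentration error:
the generalised least-squares standard error of an estimator that knows
the true absorptivities and fits the baseline nuisance jointly. It is
the yardstick for end-to-end recovery: on the default 100-sample batch
the full pipeline's RMSEP must land within a factor 2 of this floor and
reach $R^2_{pred} \ge 0.9$ for every in-region constituent.

**What the generator does not emulate** — and therefore what passing
tests do not demonstrate about real fruit: multiplicative scatter and
path-length variation (no SNV/MSC correction is implemented, matching
the modelled workflow), detector response curves and wavelength-dependent
noise, chemical correlations beyond the shared stage effect,
non-linearity between absorbance and concentration at high optical
densities, and spatial texture beyond a smooth radial gradient. Results
on real cubes will be worse than the synthetic recovery numbers, and
the package makes no claim otherwise.

## Workflow conventions

* **Split** — stratified by maturity stage; the calibration total is
  `ceiling(0.70 * n)` ("around 30%" held out, rounding toward
  calibration) apportioned by largest remainder, so 97 samples split
  68/29 and 100 samples over four stages split 70/30. Stratified is the
  default because acquisition-interval replicates are the natural
  stratum; a single-stratum call gives the global split.
* **Per-constituent sample bases** — each constituent uses the samples
  with a measured value (missing entries drop rows per-constituent
  rather than globally), since real studies assay different subsets.
* **Refinement scope** — interval elimination and outlier removal are
  applied to the best full-spectrum chain per constituent by default
  (`refine = "best"`), mirroring how such studies narrow a model grid;
  `refine = "all"` is available.
* **Best-model rule** — lowest RMSEP, ties broken by highest
  $R^2_{pred}$, then fewest latent variables, then fewest variables,
  then stable order.
* **Reports** — one row per configuration with the standard column set
  (`LVs, R2_Cal, RMSEC, R2_CV, RMSECV, R2_pred, RMSEP`); retained
  wavelengths are printed as inclusive nm ranges. $R^2$ is
  $1 - SS_{res}/SS_{tot}$ throughout; the squared correlation is also
  computed (`r2_corr`) because some toolboxes report it for
  cross-validation, which can exceed the calibration value on skewed
  splits.
* **Mapping** — every masked pixel is pretreated with the *fitted*
  chain and pushed through the model; for linear chains the mean of
  pixel predictions equals the prediction of the mean spectrum exactly,
  a property the suite asserts. For chains containing the Log step the
  equality is only approximate and is not asserted.

## Problem sizes and determinism

The suite and the acceptance script run entirely on generated data:
100-sample batches for end-to-end recovery, 25–45-sample batches for
unit-level checks, 200 replicates for the null calibration of the
outlier statistic, and 30–50 pixel frames for cube tests. These sizes
were chosen as the smallest at which the statistical assertions are
stable across seeds. All randomness flows from explicit integer seeds;
two runs with the same configuration produce byte-identical report
CSVs, which the suite checks at the file level.

## Known limitations

* The PRESS-ratio threshold 0.75 and its $(I, I)$ degrees of freedom
  follow the classical rule; other toolboxes use different conventions,
  so selected latent-variable counts need not match any particular
  software.
* Greedy backward elimination can keep a locally useful interval whose
  joint removal with another would help; the audit trace records every
  candidate evaluation so such cases are inspectable.
* The outlier statistic assumes roughly i.i.d. cross-validation
  residuals; with strong leverage structure its null rate drifts above
  the nominal level.
* ENVI support covers BSQ/BIL/BIP interleaves with float32/float64/
  uint16 payloads and little-endian byte order; big-endian files are
  not handled.
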