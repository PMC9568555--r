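---
title: "Tolerance-interval reference ranges for middle ear transfer functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tolerance-interval reference ranges for middle ear transfer functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metfref)
```

## The measurement and its model

A middle ear transfer function (METF) is the frequency-domain ratio of stapes
footplate motion to sound pressure at the tympanic membrane, measured on
cadaveric temporal bone (TB) specimens with a laser Doppler vibrometer (LDV)
and a probe microphone. In discrete form the magnitude at frequency bin $k$ is

$$\mathrm{METF}_k = \frac{a_k\,V_k^{LDV}}{b_k\,V_k^{Probe}},$$

where $V_k$ are FFT magnitudes of the recorded voltages and $a_k, b_k$
calibration factors. All analysis in this package happens on dB magnitudes:
displacement in dB re 1 µm/Pa, velocity in dB re 1 µm/s/Pa, connected by the
exact affine map $\mathrm{vel} = \mathrm{disp} + 20\log_{10}(2\pi f)$. Because
the laser usually meets the footplate at an incidence angle $\theta$ from its
normal, the measured motion is underestimated by $\cos\theta$;
`apply_angle_correction()` adds $-20\log_{10}\cos\theta$ dB (2.6 dB at the
typical 42°).

The statistical model underlying everything downstream treats the dB
magnitude of specimen $i$ at frequency $f$ as

$$y_{i}(f) = \sum_{q=0}^{3}\beta_q\,z(f)^q + u_{\mathrm{group}} +
u_{\mathrm{method}} + u_{\mathrm{tb},i} + \varepsilon_{i}(f),$$

a cubic in standardized log-frequency plus crossed random intercepts for
research group, measurement method and specimen, plus residual noise. The
cubic captures the canonical METF shape — resonance near 1 kHz, roll-off
above. The random effects are *crossed*, not nested, because the same
measurement method is used by several groups.

## Signal-level estimation

`estimate_transfer()` implements the H1 estimator
$|S_{xy}|/S_{xx}$ (scaled by $a_k/b_k$) from unwindowed per-block FFTs.
Two deliberate choices:

* **H1, not H2 or Hv.** With a synthesized excitation the input channel is
  effectively noise-free, which is the regime H1 is optimal for.
* **No windowing or overlap.** Excitation tones are constrained to exact FFT
  bins of the acquisition block (`excitation_spec()` refuses anything else),
  so rectangular blocks are leakage-free and the bins between tones carry
  background noise only. That is also what makes the adjacent-bin SNR
  estimate meaningful: each tone's magnitude is divided by the mean magnitude
  of its six nearest non-excited bins.

Quality gating follows the three laboratory conventions: coherence
$\gamma^2 = |S_{xy}|^2/(S_{xx}S_{yy})$ strictly above 0.8 (`dresden`), SNR
above 12 dB (`hannover`), or SNR above 10 dB below 1 kHz and above 20 dB at
and above it (`shanghai` — the 1 kHz boundary is assigned to the stricter
rule). A whole curve is rejected if any point needed to interpolate the
1000–4000 Hz grid targets is invalid (`enforce_core_validity()`).

## Preprocessing

Acquisition grids vary, so curves are linearly interpolated onto the
audiological grid {125, 250, 500, 1000, 2000, 3000, 4000, 6000} Hz. Linear
interpolation avoids the bias of higher-order schemes toward one bracket. The
axis is linear in Hz by default; because "linear" is ambiguous between a Hz
and a log-frequency axis, both are implemented (`axis = "log"`) and the
choice is recorded on the result. Extrapolation is never performed — a target
without valid brackets is simply missing, represented as an absent row.
The pipeline order is fixed: quality gate → core-band validity →
interpolation → outlier screening.

## Outlier screening

Per frequency, Tukey fences $Q_1 - k\cdot IQR$, $Q_3 + k\cdot IQR$ with
$k = 1.75$ — more lenient than the textbook 1.5 because the METF magnitude
distributions are slightly left-skewed (the middle ear has a hard physical
ceiling on transfer but a long tail of attenuation). Quartiles use linear
interpolation of order statistics (R type 7, the spreadsheet default); the
convention is an explicit argument because exclusion counts are sensitive to
it. Values exactly on a fence are kept (strict comparison).

Exclusion logic: an outlier anywhere in 500–4000 Hz discards the whole curve,
since a single outlier may be the tip of a wider peak whose neighbors are
biased without being flagged themselves; outliers only at the spectral edges
truncate the curve at the most medial flagged frequency (everything outward
goes, unflagged medial points stay). Screening runs twice: within each
(group, method) cell, so between-cell offsets cannot mask within-cell
outliers, and once more on the pooled single-point-LDV data from which the
reference is built. The two passes are independent branches by default
(pass 2 starts from the raw pooled rows); `chain = TRUE` feeds pass-1
survivors into pass 2 instead.

## Inference

Between-group differences are tested per frequency with Welch t-tests (the
data sets are heteroscedastic across laboratories) and Holm-adjusted. The
Holm family is the set of pairwise tests *within one frequency*: the
scientific question is frequency-wise equality of groups, and pooling
families across frequencies would couple unrelated questions. A `family =
"global"` switch exists for the conservative alternative.

The variance decomposition is fitted by REML with `lme4` (random intercepts
for specimen, method, group; singular fits are reported with a boundary flag,
never errored; single-level factors are dropped with variance 0).
$R^2$ follows Nakagawa–Schielzeth:
$R^2_m = \sigma^2_f / (\sigma^2_f + \sum\sigma^2_r + \sigma^2_\varepsilon)$
with $\sigma^2_f$ the population variance of the fixed-effect predictions,
and $R^2_c$ adding the random components to the numerator. The frequency
covariate is standardized log10-frequency, $z = (\log_{10} f - \bar{\ell}) /
s_\ell$ over the distinct frequencies — the cubic design matrix on raw
log-frequency (values ~2.1–3.8) is poorly conditioned, and standardization
makes the generator and the fitter agree on one scale. Polynomial orders 4–5
add less than one percentage point of marginal $R^2$ on generator data, which
is why order 3 is the default.

## Reference construction

Per frequency, independently (no cross-frequency pooling — the reference is
a per-frequency table, and a joint band would change its meaning):

* mean and its 95% CI, $\bar{x} \pm t_{1-\alpha/2,\,n-1}\, s/\sqrt{n}$;
* two-sided $(p, 1-\alpha)$ tolerance intervals $\bar{x} \pm k_2 s$ for
  $p \in \{0.90, 0.95, 0.99\}$, $\alpha = 0.05$.

The default $k_2$ is Howe's closed form
$z_{(1+p)/2}\sqrt{\nu(1+1/n)/\chi^2_{\nu;\alpha}}$; the exact two-sided
factor is also implemented, solving numerically for the $k$ whose confidence

$$\int 2\sqrt{n}\,\varphi(\sqrt{n}u)\,
P\!\left(\chi^2_\nu \ge \nu\,r(u)^2/k^2\right)\,du = 1-\alpha,
\qquad \Phi(u+r)-\Phi(u-r)=p,$$

equals the nominal level. The two agree within 0.01% at $n = 366$ and within
1% even at $n = 20$ (Howe is very slightly anti-conservative at small $n$:
its true confidence at $n=20$ is ≈ 0.948). Normality of the per-frequency dB
values is assumed, which the screened data supports (|skewness| and excess
kurtosis below 2, large $n$); a nonparametric interval is out of scope.

The published multicenter reference (366 single-point-LDV curves, 2321
points after screening) ships as `packaged_reference()`, carrying the mean,
95% CI and 95% TI panels for both units. Its 90%/99% TI columns were
published only in supplementary material and are stored as `NA`; consumers
fall back to the 95% TI. The source also states "362 measurements" in one
passage; the packaged metadata records 366 (the reference-figure caption's
count) and documents the discrepancy rather than guessing.

## Validation protocol

`validate_curve()` checks per-frequency containment in the reference TI.
Violations only at the edges ($f < 500$ or $f > 4000$ Hz) yield
`valid_after_truncation`; a violation in the core band yields `flagged` —
never auto-exclusion, because only the researcher can distinguish an
undetected pathology from a measurement error from a genuinely unusual but
normal ear. Single-frequency violations are annotated as possible narrow-band
resonances. `compare_study_mean()` applies the 6 dB advisory (the plausible
ceiling for a between-laboratory offset), and `guideline_report()` adds the
sample-size rules (strong warning below $n=5$, soft below $n=10$).

`impact_of_extreme()` quantifies the leverage of one measurement at the edge
of the range on a study of size $n$: the deterministic surrogate places one
observation at $\mu + k_2\sigma$ next to $n-1$ observations with mean $\mu$
and sample SD $\sigma$, giving a mean shift of exactly $k_2\sigma/n$ and an
SD of $\sqrt{\sigma^2(n-2)/(n-1) + (k_2\sigma)^2/n}$. This surrogate is a
modeling choice, labeled as such in the output: it *augments* the study with
the edge observation rather than conditioning on an extreme draw. The
Monte-Carlo mode (drawing the $n-1$ companions from the reference normal)
is the cross-check; the two agree within a few percent at $n \ge 3$.

## The synthetic-data generator

`sample_population()` draws from the model above with the reference study's
parameters as defaults: SDs of 4.2 dB (specimen), 3.4 dB (method), 1.4 dB
(group); residual SD 3.0 dB, chosen so the implied total SD
$\sqrt{4.2^2+1.4^2+3^2} \approx 5.4$ dB matches the published 95% TI
half-width at 1 kHz (≈10.4 dB) divided by the large-$n$ tolerance factor
≈2.0; and a cubic mean curve fitted to the packaged displacement means (that
cubic tracks the eight published means to within 2.8 dB — the residual is
largest at the spectral edges, consistent with a cubic being a good but not
perfect description of the mean shape). The default design — 4 groups ×
1 method × 100 specimens — mirrors the scale of the pooled single-point-LDV
set the reference was built from. An optional `design` argument supports
sparse crossed designs (each group using a subset of methods), which is both
how the real multicenter data looks and what the parameter-recovery harness
needs.

Determinism: one RNG stream per entity class (groups, methods, per-cell
specimens, per-cell residuals), each derived from the master seed, so
enlarging one cell does not perturb the draws of others. The optional left
skew is a variance-preserving skew-normal transform applied to the residuals
only — random intercepts stay Gaussian — the simplest structure consistent
with per-frequency left skew in the real data.

What the generator does *not* emulate: method-specific physics (footplate
rocking modes, µCT-derived volume displacement differ by more than an
intercept), frequency-dependent variance and skew, within-curve correlation
of residuals across frequency, and laboratory-specific acquisition grids.
Passing tests on generator data therefore demonstrate the statistical
machinery, not fidelity to every feature of real laboratory data.

## Numerical choices and problem sizes

* Quantile convention: R type 7 everywhere, exposed as an argument.
* Fence comparison strict; on-fence values kept.
* Interpolation axis: Hz (log-frequency available, recorded in output).
* The exact $k_2$ solver brackets the root at 0.7–1.3 × Howe and uses
  `uniroot`/`integrate` at 1e-8/1e-9 tolerances; it is deterministic.
* Mixed models: REML, lme4 defaults; convergence messages other than
  singular-boundary are surfaced as warnings with `converged = FALSE`.
* The test suite's empirical checks use moderate sizes chosen for stable
  sampling error: 2000 replicates for TI confidence and type-I error
  (binomial SE ≈ 0.5 points), $10^5$ draws for the Gaussian fence rate,
  50 000 replicates for the Monte-Carlo impact expectation, and 20
  replicates of a 100-group × 100-method sparse crossed design (2 methods
  per group, 30 specimens per cell) for variance-component recovery — that
  design size comes from a power analysis: the sampling error of an SD
  estimated from $k$ levels is roughly $\chi^2_{k-1}$-shaped, and holding a
  1.4 dB SD to 25% relative error in ≥90% of replicates needs on the order
  of a hundred levels once the extra uncertainty from the crossed structure
  is accounted for.

## Known limitations

* Phase is not modeled anywhere; the analysis is magnitude-only.
* The packaged reference carries no per-frequency $n$ (not published) and no
  90/99% TI columns.
* Tolerance intervals are normal-theory; heavy deviations from normality in
  a user's data would call for a nonparametric interval the package does not
  provide.
* The validation verdicts implement a reporting protocol, not a clinical
  classifier: `flagged` means "look at this", nothing more.
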