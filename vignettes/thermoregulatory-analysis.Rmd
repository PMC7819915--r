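---
title: "Methods: steady-state respirometry and the segmented thermoregulatory profile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state respirometry and the segmented thermoregulatory profile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnz)
```

`tnz` implements the computational chain of a flow-through respirometry
study of endotherm thermoregulation: converting analyzer readings into
gas-exchange rates, extracting steady-state values from multiplexed
traces, fitting the segmented Scholander–Irving profile, partitioning
evaporative heat loss between its respiratory and cutaneous avenues, and
estimating among-individual repeatability. This vignette documents the
models, the numerical choices, and what the synthetic-data verification
does and does not demonstrate.

## Gas-exchange mass balance

Open-flow calorimetry measures an animal's exchange rates indirectly:
dry, CO₂-free air flows through a chamber (or is pulled through a mask)
and the analyzers read the excurrent O₂ and CO₂ fractions (on dried gas)
and the water-vapour partial pressure (on wet gas). At steady state each
gas species is conserved, so the rates can be recovered exactly by
inverting the balance. With dry-basis incurrent fractions
$F_iO_2, F_iCO_2$, excurrent fractions $F_eO_2, F_eCO_2$ and dry flows
$F_i$ (incurrent), $F_e$ (excurrent), nitrogen conservation gives

$$F_e = F_i\,\frac{1 - F_iO_2 - F_iCO_2}{1 - F_eO_2 - F_eCO_2},$$

and then
$\dot V O_2 = F_i F_iO_2 - F_e F_eO_2$ and
$\dot V CO_2 = F_e F_eCO_2 - F_i F_iCO_2$.
The `mode` flag records where the flow meter sits: `push_chamber` meters
$F_i$ upstream on the dry supply, the pull modes meter $F_e$ downstream
after drying; the same balance is solved for the unmetered flow. Water
is carried on the wet stream as the mole fraction $w = P_{H_2O}/BP$,
giving $\dot V H_2O = F_e\,w_e/(1-w_e) - F_i\,w_i/(1-w_i)$ ml of vapour
per minute, converted at 0.803 mg ml⁻¹ (STP). These closed forms are
derived from species conservation rather than transcribed from a
textbook; the test suite verifies that they invert an independent
forward simulator (`simulate_excurrent()`) to below 10⁻⁶ relative error
across all three modes, including humid incurrent air and CO₂ bleed.

Derived quantities follow the field's standard conversions:

* **Metabolic rate**: the RER-dependent oxyjoule equivalent,
  $MR\,(\mathrm{W}) = \dot V O_2\,(16 + 5.164\,\mathrm{RER})/60$ with
  $\dot V O_2$ in ml min⁻¹. At RER 0.85 one ml O₂ min⁻¹ is ≈ 0.34 W; a
  small passerine's basal rate of 0.24 W corresponds to ≈ 0.7 ml O₂
  min⁻¹.
* **Evaporative heat loss**: latent heat 2.4 J mg⁻¹, so
  $EHL = EWL \cdot 2.4/60$ W.
* **Surface area**: $A_s = 10\,m_b^{0.667}$ cm² (mass in g).
* **Dry thermal conductance**:
  $C = (MR - EHL)/((T_b - T_a)\,A_s)$, meaningful only below the lower
  critical temperature where the body–air gradient is positive; the
  function refuses $T_b \le T_a$.

Negative computed rates are never silently clamped: magnitudes below
0.01 ml min⁻¹ (analyzer noise around a true zero) are zeroed with a
warning, anything larger is kept and flagged so the record can be
inspected.

## Trace processing

A multiplexer cycles the analyzer chain over up to ten chambers in
5-minute dwells, sampling a reference (incurrent) line at least every 20
minutes. `demultiplex()` splits a 0.5 Hz trace at the switches, masks
the first 60 s of every dwell, and attaches the nearest preceding and
following reference summaries to each animal dwell. The washout discard
of 60 s is a configurable compromise: a 0.85 L chamber at 500 ml min⁻¹
has a ~1.7 min time constant, but since the steady-state selection
downstream picks the flattest/lowest part of the dwell anyway, masking
only the sharpest transient preserves usable data. Each reference dwell
is summarized by the mean of its final 3 minutes (its own washout
discarded).

`baseline_correct()` models analyzer drift as affine in time: the
incurrent composition assigned to each sample is the linear
interpolation between the bracketing reference summaries, so any drift
that is linear over the ~20 min between references is removed exactly
(a property the tests assert with zero-noise traces). With only one
reference available the correction degenerates to a constant with a
warning.

`select_steady_state()` implements the two selection rules used for
resting measurements: the window (step one sample) minimizing mean
$\dot V O_2$ (`lowest_mean`, width 2 min) for resting metabolism, and
the window minimizing the within-window variance of $\dot V O_2$
(`most_stable`, width 5 min) for mask sessions. "Most unchanging" is
deliberately interpreted as minimum variance; a minimum-slope criterion
is a reasonable alternative but ranks a slow steady ramp as perfectly
"stable", which is not what a plateau search wants. Ties break to the
earliest window. The implementation is vectorized with cumulative sums
and is checked against exhaustive window enumeration.

## Segmented Scholander–Irving fitting

The thermoregulatory profile is estimated by continuous piecewise-linear
least squares of each response against ambient temperature, pooling
birds (per-individual random variation is handled by the bootstrap, not
the point estimate):

* MR: three segments with a **horizontal middle plateau** — the two
  breakpoints are the lower and upper critical temperatures
  ($T_{LC}$, $T_{UC}$) and the plateau level is BMR;
* $T_b$, EHL and the per-observation ratio EHL/MR: two segments with a
  horizontal first segment — the breakpoint is the hyperthermia
  threshold, the EHL inflection, and the evaporative-efficiency
  inflection respectively.

For fixed breakpoints the fit is linear: the design uses one
"covered-length" basis column per free-slope segment, which enforces
continuity at every breakpoint by construction and makes a horizontal
constraint a simple column drop. Breakpoints are located by exhaustive
search over the midpoints between adjacent sorted unique predictor
values (all feasible pairs for two breakpoints, each segment keeping at
least 5 observations), refined by golden-section search to 10⁻⁴ °C. The
SSE profile has a kink at every data point, so the one-breakpoint search
brackets every inter-point cell separately — making it effectively
exhaustive — while the two-breakpoint search refines the best grid pairs
coordinate-wise. The unit tests require the SSE to match an independent
0.01 °C brute-force grid.

The EHL/MR inflection is fitted directly on the per-observation ratio
rather than derived from the MR and EHL fits: the ratio of two fitted
piecewise functions is not piecewise-linear and its apparent inflection
would not be an estimated parameter with a standard error.

**Model selection** (`select_model_type()`) walks a ladder of candidate
shapes ordered by parameter count (straight line → plateau-then-rise →
free one-breakpoint → three-segment plateau) and adopts a more complex
shape only when the nested F-test against the currently held model is
significant at α = 0.05, counting each breakpoint as one parameter.
This is a documented stand-in for the published software's selection
cascade (maximize R² and test model significance), which is not fully
specified anywhere; on data simulated with a true breakpoint and 10%
noise it selects the correct shape in ≥ 95% of replicates.

**Standard errors** come from a nonparametric cluster bootstrap that
resamples *birds*, not rows, and re-runs the entire breakpoint search on
each resample (default B = 1000; the analysis scripts use B = 200,
which stabilizes the SE to well under its own Monte-Carlo error at a
fraction of the cost). Resampling individuals respects the repeated
measures per bird; a row bootstrap would understate breakpoint
uncertainty. Whether the published ± SE values were analytic or
resampled is unstated; the cluster bootstrap is the defensible choice
for clustered data and reproduces their order of magnitude (± 0.3–0.7 °C
on the critical temperatures at 36 birds).

## Partitioning of evaporative heat loss

Mask respirometry separates the two evaporative avenues with two pull
lines: the mask line (500 ml min⁻¹) carries the respiratory water signal
plus the breath gases, the chamber line (200 ml min⁻¹) carries the
cutaneous signal. `partition_ehl()` inverts each line with the same
mass balance, converts to heat, and reports REHL, CEHL, their total,
the REHL/CEHL ratio and the cutaneous share CEHL/TEHL. Because the mask
covers the whole head, "respiratory" water includes evaporation from
head skin and eyes; no correction is applied, and none is attempted for
metabolic water. Summaries report the cutaneous share both as the mean
of per-bird fractions and as the ratio of summed means, since the two
differ whenever birds vary in total loss and the published contribution
figures do not say which was used.

## Repeatability

`repeatability_anova()` is the classical one-way ANOVA intraclass
correlation: $s^2_A = (MS_A - MS_W)/n_0$ with
$n_0 = (N - \sum n_i^2/N)/(a-1)$, $\tau = s^2_A/(s^2_A + MS_W)$, and the
ANOVA F-test p-value. Negative variance estimates are truncated to zero
and flagged. `adjusted_repeatability()` removes fixed effects (ambient
temperature, body mass, design factors) by ordinary least squares and
estimates $\tau$ on the residuals, with a cluster bootstrap over
individuals re-running both stages for the SE. The published analysis
used a mixed-model package for this adjustment; the residual-ANOVA
stand-in is dependency-free and deterministic, and the test suite shows
it agrees with the REML variance-components estimator (`lme4`) to within
0.02 on balanced designs. On unbalanced designs with strong covariate
effects the two can diverge more; that is a known limitation.

## The synthetic-data generator

No raw data accompany the study design this package is verified
against, so every stage is validated by parameter recovery on synthetic
data whose ground truth is set to the published profile:
$T_{LC} = 34.87$, $T_{UC} = 37.47$ °C, BMR 0.24 W, MR slopes 0.015
(below) and 0.013 (above) W °C⁻¹, $T_b$ plateau 40.98 °C with threshold
35.94 °C and slope 0.43, EHL plateau 0.061 W with inflection 37.45 °C
and slope 0.045 W °C⁻¹.

`generate_steady_state()` emulates the study design: 36 birds in four
acclimation groups (8/10/9/9), each measured at two randomly chosen
temperatures from the 22–44 °C grid (0.5 °C steps) per day. The number
of measurement days is not part of the published design; six days (12
steady-state points per bird, 432 rows) is a realistic campaign for
mapping a Scholander curve at this resolution and is the fixed default.
Noise parameters are invented — the study reports only SEs of fitted
parameters — and were chosen once so that recovered parameter SEs are of
the same order as the published ones: residual SDs 0.020 W (MR), 0.30 °C
($T_b$), 0.008 W (EHL), among-individual SDs 0.016 W (MR) and 0.25 °C
($T_b$). The MR variance components deliberately give a true intraclass
correlation of $0.016^2/(0.016^2+0.020^2) = 0.390$, matching the
published adjusted repeatability, so the repeatability module can be
tested against a known truth. RER is drawn uniform on 0.75–0.95, a
plausible post-absorptive span that affects only the back-computed
$\dot V O_2$. Noisy MR and EHL are drawn first and the gas columns are
back-computed from them, so every generated table satisfies the
calorimetric identities exactly row by row.

The mask-session truths set the cutaneous share of total evaporative
heat loss to 0.61 at 25 °C and 0.21 at 40 °C with cutaneous loss 25%
higher at 40 °C (REWL/CEWL of 1.01/1.58 and 7.43/1.98 mg min⁻¹), with
log-normal among-bird variation (CV 0.15); mask-line oxygen consumption
runs above resting rates, as restrained measurements do.

What the generator does **not** emulate: washout dynamics within a
dwell (dwells are steady by construction, so the recovery tests exercise
selection and correction, not the instantaneous-correction problem);
activity bursts and non-resting records; acclimation-induced group
differences (supported via per-group truth overrides but off by
default); analyzer calibration error, which baseline correction cannot
see. Passing recovery tests therefore demonstrates that the estimation
chain is unbiased under the stated noise model, not that it is robust to
every pathology of real traces.

## Problem sizes and reproducibility

The analysis scripts and the verification suite use the default study
size (36 birds, 432 steady-state rows), 200 cluster-bootstrap resamples
per fit, 20 replicate studies for the repeatability recovery and a
500-point randomized grid for the mass-balance inversion check. Every
stochastic step takes an explicit integer seed, and generation is
byte-identical for identical seeds. `scripts/acceptance.R --seed N
--out results/acceptance.json` re-runs the whole chain from scratch and
writes the recovered profile and repeatability as JSON.
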