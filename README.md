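# tnz — flow-through respirometry and the thermoneutral zone

`tnz` is an R package for the computational chain of open-flow
respirometry studies of endotherm thermoregulation — the kind of study
that maps a bird's metabolic rate (MR), body temperature (T_b) and
evaporative heat loss (EHL) across ambient temperature (T_a) and asks
where the thermoneutral zone lies, how evaporative cooling is
partitioned, and how consistently individuals differ.

It provides, as tested package functions:

* **Calorimetry** — exact steady-state mass-balance inversion of
  excurrent gas fractions into V̇O₂, V̇CO₂ (ml min⁻¹) and evaporative
  water loss (mg min⁻¹), for push-chamber and pull (mask/chamber)
  configurations; conversions to watts via the oxyjoule equivalent
  MR = V̇O₂·(16 + 5.164·RER)/60 and the latent heat 2.4 J mg⁻¹; surface
  area A_s = 10·m_b^0.667 and dry thermal conductance
  C = (MR − EHL)/((T_b − T_a)·A_s).
* **Trace processing** — demultiplexing of 0.5 Hz multichannel traces,
  baseline correction of analyzer drift against bracketing reference
  readings, and steady-state window selection (lowest 2-min mean V̇O₂,
  or most stable 5-min window).
* **Segmented regression** — continuous piecewise-linear fits with 0–2
  breakpoints, horizontal-segment constraints, grid + golden-section
  breakpoint search, nested-F model selection, and cluster-bootstrap
  standard errors that resample birds. The three-segment MR fit yields
  T_LC, T_UC and BMR; the two-segment T_b and EHL fits yield the
  hyperthermia threshold and the EHL inflection.
* **Partitioning** — respiratory vs cutaneous evaporative heat loss
  from two-line mask respirometry, with per-stratum summaries.
* **Repeatability** — one-way ANOVA intraclass correlation
  (τ = s²_A/(s²_A + MS_W)) with covariate adjustment and
  cluster-bootstrap SEs.
* **Synthetic data** — generators for steady-state tables, raw
  multiplexed traces and mask sessions with known ground truth, so the
  entire chain is verifiable end to end without proprietary raw data.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (seed 42). `analysis/01_simulate_study.R` generates 432
steady-state observations of 36 birds whose true profile is the
published zebra-finch estimate; `analysis/03_fit_profile.R` then fits
the segmented profile with 200 cluster-bootstrap resamples and prints:

```
Thermoregulatory profile
  TNZ: 34.389 ± 0.355 to 37.604 ± 0.631 °C
  BMR: 0.243 ± 0.005 W
  MR slope below/above TNZ: 0.0158 / 0.0135 W °C⁻¹
  Tb plateau: 40.98 °C; hyperthermia above 35.903 ± 0.212 °C (slope 0.425)
  EHL plateau: 0.0608 W; inflection at 37.489 ± 0.039 °C (slope 0.0456 W °C⁻¹)
  EHL/MR inflection: 36.627 ± 0.157 °C; ratio at max Ta 1.13
Dry thermal conductance below T_LC (n = 254): 0.368 ± 0.065 mW/degC/cm2
```

Read against the generating truth (T_LC 34.87, T_UC 37.47 °C, BMR
0.24 W, slopes 0.015/0.013, T_b threshold 35.94 °C and slope 0.43, EHL
plateau 0.061 W, inflection 37.45 °C, slope 0.045): every breakpoint is
recovered within half a degree and every plateau within a few percent,
with the bootstrap SEs quantifying the remaining uncertainty.
`analysis/04_partition_ehl.R` recovers the evaporative partition
(cutaneous share ≈ 60% at 25 °C, ≈ 20% at 40 °C), and
`analysis/05_repeatability.R` the adjusted repeatability of MR above
the zone (true intraclass correlation 0.390).

In code, the core loop is three calls:

```r
library(tnz)
ss <- generate_steady_state(scholander_truth(), generator_config(seed = 42))
fits <- fit_thermoreg_profile(ss, bootstrap = 200, seed = 42)
fits$profile
```

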