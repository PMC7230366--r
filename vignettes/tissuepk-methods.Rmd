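---
title: "Methods: target-site pharmacokinetics from microdialysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-site pharmacokinetics from microdialysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuepk)
```

`tissuepk` analyses antibiotic exposure at the infection target site —
the interstitial fluid (ISF) of subcutaneous tissue sampled by
microdialysis — alongside plasma, for cohorts of obese and non-obese
patients given a single intravenous antibiotic infusion. This vignette
documents the models, the conventions behind every numerical choice,
and what the synthetic cohort generator does and does not emulate.

## The measurement problem

A microdialysis catheter perfused at a constant flow (here 2 µL/min)
recovers only a fraction of the true ISF concentration, because
equilibration across the membrane is incomplete. Each catheter is
calibrated in vivo by retrodialysis: the perfusate is spiked with drug
at concentration $C_{RP}$ and the fraction lost to the tissue measures
the same membrane transfer in reverse,

$$\text{relative recovery} = \left(1 - \frac{C_{RD}}{C_{RP}}\right)
\times 100\%, \qquad
C_{ISF} = C_{\mu D} \times \frac{100}{\text{relative recovery}}.$$

A recovery at or below zero means the catheter did not exchange with
the tissue; `relative_recovery()` signals a classed error
(`tpk_calibration_failure`) and the pipeline excludes that catheter and
logs the exclusion, keeping the subject. Each catheter uses its own
single calibration; recovery is assumed constant over the 8 h
experiment (one retrodialysis per catheter).

Dialysate collections are interval averages, not point samples. The
package assigns each interval to its midpoint time. The alternative —
accumulating mean × width directly into an AUC — differs only through
the trapezoidal interpolation between midpoints; on simulated profiles
the two agree within about 2%, and the midpoint convention keeps a
point-profile representation that the terminal fit and Cmax/Tmax
operations can share.

Catheters are averaged on the arithmetic concentration scale before any
log-scale analysis: concentrations, not their logarithms, are the
physical quantity being duplicated by the two probes. Times where only
one catheter is quantifiable pass through; a below-quantification (BLQ)
value is excluded from the average when the partner is quantifiable.

## Non-compartmental analysis

NCA follows the standard conventions for a constant-rate infusion:

* **AUC** uses the linear-up/log-down trapezoidal rule: rising or
  zero-bounded segments contribute $\tfrac{1}{2}(C_1 + C_2)\Delta t$,
  declining segments with both ends positive contribute
  $(C_1 - C_2)\Delta t / \ln(C_1/C_2)$. A partial AUC ending between
  samples interpolates the bracketing segment with the same rule
  (log-interpolation on declining segments), so AUC is exactly additive
  over interior cut points.
* **λ~z~** comes from ordinary least squares of $\ln C$ on $t$ over the
  best terminal window: all suffixes of at least three quantifiable
  points strictly after T~max~ (T~max~ itself excluded) are fitted, and
  the window with the largest adjusted R² wins; ties within 10⁻⁴ go to
  the longer window. A slope that is not negative (beyond numerical
  zero, 10⁻¹⁰) disqualifies a window; if no window qualifies the
  parameter is reported missing and the subject retained. On the 8 h
  schedule this selector typically starts the window at 3–5 h,
  consistent with elimination-phase onset after the distribution phase.
  Whether a Phoenix-style selector that can drop interior points would
  choose differently is unknowable from the published rules; the
  suffix-window convention is the documented stand-in.
* **Extrapolation** uses the *predicted* (not observed) concentration
  at the last quantifiable time: tail $= \hat C_{last}/\lambda_z$,
  $AUC_\infty = AUC_{0-t_{last}} + \text{tail}$, with the extrapolated
  percentage reported relative to $AUC_\infty$.
* **Moments**: AUMC applies the same segment rules to $t \cdot C(t)$
  (the literal product series, integrated with the same linear-up/
  log-down decision on the transformed values), with tail
  $\hat C_{last} t_{last}/\lambda_z + \hat C_{last}/\lambda_z^2$. This
  convention is exact on exponentials for AUC but carries a small
  discretisation error for AUMC on sparse schedules (≈0.5% on the 8 h
  design); tests that assert closed-form equality therefore use dense
  grids. MRT $= AUMC_\infty/AUC_\infty - t_{inf}/2$ for the infusion.
* **CL and V~ss~** are plasma-only: CL $=$ dose$/AUC_\infty$ and
  V~ss~ $=$ CL × MRT; requesting them from an ISF profile is a contract
  violation, not a silent answer.
* **Daily exposure**: for twice-daily dosing of the same dose,
  $AUC_{24} = 2 \times AUC_\infty$.

**BLQ rules** (LLOQ 0.1 mg/L by default): a BLQ baseline at $t = 0$
counts as concentration zero; any other BLQ record is excluded from
both the trapezoids and the terminal fit. ISF profiles have no $t = 0$
record (the first midpoint is 0.25 h), so a zero anchor at $t = 0$ is
inserted before integration.

## fAUC~24~/MIC targets

The efficacy index is the daily unbound AUC divided by the MIC, with
the therapeutic target fAUC~24~/MIC > 80 evaluated on a grid of 0.5, 1,
2 and 4 mg/L. The comparison is strict: a ratio of exactly 80 is not
attained (the published target is stated as an inequality without an
equality case; strictness is the conservative reading). ISF
concentrations are treated as entirely unbound — microdialysis samples
protein-free fluid — and plasma fAUC uses measured unbound
concentrations when available, otherwise total × f~u~ (default 0.86).
Ratios halve exactly across doubling MICs, so group medians commute
with the MIC scaling; both facts are asserted by tests.

## Statistical layer

* **Exposure–size regression**: OLS of AUC on sex and *either* weight
  or BMI (never both; they are collinear), slope reported per 10 kg
  with a Wald 95% CI.
* **Correlations**: Pearson's r with the Fisher-Z interval
  $\tanh(\operatorname{atanh} r \pm z_{0.975}/\sqrt{n-3})$. With
  `robust = TRUE` the percentage-bend correlation (bend fraction 0.2)
  serves as the outlier-resistant sensitivity analysis; it is a
  documented stand-in, not a reproduction of any specific published
  robust estimator.
* **Longitudinal mixed model**: maximum-likelihood `lme4` fit of log
  concentration on group, time, group × time and catheter, with a
  per-subject random intercept and slope. Fixed effects are
  exponentiated into ratios with Wald CIs, matching the
  ratio-and-interval reporting style of clinical PK papers. The
  decline-rate ratio is the ratio of group-specific slopes,
  $(\beta_t + \beta_{g \times t})/\beta_t$, with a delta-method CI on
  the ratio scale (the log-scale delta method is undefined when slopes
  could cross zero). A singular random-effects fit falls back to a
  random intercept only, with a warning.
* **Group comparisons**: Welch's t-test by default — on the log scale
  (reported as a ratio) for concentrations and AUCs, on the natural
  scale for V~ss~ — with a rank-based alternative available. Degenerate
  inputs are handled explicitly: identical constant groups give a
  difference of 0 with p = 1.
* **Sample size for a correlation**:
  $n = \lceil ((z_{1-\alpha/2} + z_{power})/\operatorname{atanh} r)^2 +
  3 \rceil$, floored at 4 (also when the requested power is so low that
  the normal quantile sum is non-positive). For r = 0.52, power 0.80,
  α = 0.05 this gives n = 27. The formula is defined on the Fisher-Z
  approximation; Monte-Carlo under that approximation brackets 27 as
  the smallest adequate n, while exact bivariate-normal simulation with
  the correlation t-test shows the formula is conservative by about one
  subject (empirical power ≈0.80 already at n = 26). No multiplicity
  adjustment is applied anywhere; all tests are two-sided at α = 0.05.

## The synthetic cohort generator

The generator exists so that every stage above is testable without
patient-level data. It emulates the study design: a single 600 mg /
0.5 h infusion; blood samples at 0, 0.5, 1, 2, 3, 4, 5, 6, 8 h;
dialysate intervals 0–0.5, …, 6–7, 7–8 h on two catheters; 15 subjects
per group; 87% female; obese weights ~N(134.3, 34.3²) kg and non-obese
~N(67.9, 8.8²) kg with heights making the group BMI definitions hold
(obese ≥ 35; non-obese 18.5–30, enforced by rejection sampling).

**Disposition** is a two-compartment model with constant-rate infusion,
evaluated by its closed-form bi-exponential solution (verified against
an ODE integrator to < 0.1%). Group parameters anchor to the reported
medians — CL 8.2 / 7.0 L/h and V~ss~ 41.0 / 30.8 L (obese / non-obese).
Only CL and V~ss~ are reported quantities, so the split into V₁, V₂ and
Q is a package calibration: V₁ = V₂ = 0.5 V~ss~ and Q = 2 CL were
chosen, once, on a grid so that the *measured* NCA half-life on the 8 h
schedule lands in the reported 3.0–3.8 h range (a deeper, slower
peripheral compartment inflates the measured t½ well beyond 4 h). The
split is configurable (`v1_frac`, `q_frac`, or V₁/V₂/Q directly).

**Tissue link**: ISF follows first-order equilibration with unbound
plasma, $dC_{ISF}/dt = k_{isf}(p \cdot f_u C_p - C_{ISF})$, scaled so
the steady-state ISF/unbound-plasma AUC ratio equals the penetration
$p$ (0.53 obese, 0.62 non-obese) by construction. The rate
$k_{isf} = 2$ h⁻¹ puts the simulated ISF T~max~ about 30–60 min after
the plasma peak, matching the reported T~max~ categories; its 30%
inter-individual variability spreads subjects across the categories.
Dialysate intervals receive the *analytic* time-average of this curve
times the catheter recovery — no integrator error enters the simulator.

**Variability**: lognormal inter-individual variability with a common
30% CV on CL, V₁, V₂ and k~isf~ (a typical pharmacometric default; the
study reports only group medians and IQRs, not variances). Proportional
residual error of 10% (plasma) and 15% (dialysate) — the assay CVs were
below 3%, so these represent assay plus biological noise; both are
assumptions, not reported values. Setting `iiv_cv = 0` collapses every
draw, including covariates, to its central value, which gives the fully
deterministic profiles the exactness tests rely on. Per-catheter
recovery is drawn from a Beta distribution on (0, 1) quartile-matched
to the reported median 0.48 and IQR (0.34, 0.58). Values below the
LLOQ are reported as BLQ flags with the LLOQ recorded, never as zeros.

**Weight coupling**: by default weight acts only through the group
parameter sets, which reproduces the group contrasts but dilutes the
continuous exposure–weight correlation. The optional allometric mode
(exponent 0.75 on CL, 1 on volumes, centred on the group median weight)
generates the continuous trends needed for the regression and
correlation analyses; the acceptance script reports both modes.

**A separate log-linear longitudinal generator**
(`simulate_longitudinal()`) builds data with a *known* group ratio
(default 0.52), decline-rate ratio (1.06) and catheter ratio directly
on the log scale, with random intercepts/slopes (SD 0.30 / 0.05) and
residual SD 0.15. It exists because the mixed model's estimands must be
tested against exactly known truth, which the PK simulator — whose
group ratio is an emergent property of CL and penetration — cannot
provide.

**What the generator does not emulate**: real elimination-phase tails
are heavier than a clean bi-exponential, so simulated extrapolated-AUC
fractions run a few points below the reported ones (about 19% vs 24%
in plasma — the ISF fraction, about 21–23%, falls inside the reported
band); no covariance between CL and V beyond the allometric mode; no
time-varying recovery, catheter drift, or sampling-time deviations; no
renal-function or anesthesia effects on clearance; single dose only
(the AUC~24~ doubling rule stands in for steady state).

## Numerical conventions and edge cases

* Degenerate tie-break: if k~isf~ coincides with a disposition
  eigenvalue the convolution coefficient diverges; the rate is nudged
  by a relative 10⁻⁷, far below any other error source.
* Cmax ties resolve to the earliest time.
* A correlation of |r| = 1 returns the degenerate interval at ±1
  rather than failing on the singular atanh.
* CSV round-trip uses `%.17g` so written concentrations re-read
  bit-identically; BLQ cells are stored as the literal `"BLQ"`.
* Seeds: `draw_cohort()`, `simulate_plasma()`,
  `simulate_microdialysate()` and `simulate_calibration()` each derive
  a deterministic offset of the config seed, so a full
  `simulate_cohort()` is bit-stable and each stage is independently
  reproducible.

## Problem sizes used by the test suite

Exactness tests run on single subjects or dense noiseless grids.
Stochastic checks use 200 subjects per group over 10 seeds for NCA
parameter recovery (median CL within 10% of truth, V~ss~ ordering
between groups), 100 replicates of 15 subjects per group for
mixed-model CI coverage of the built-in group ratio, and 40,000–200,000
Monte-Carlo replicates for the sample-size power bracketing. These
sizes keep the full suite around three minutes on one CPU while leaving
Monte-Carlo error well below the asserted margins.

## Known limitations

* The NCA terminal-window selector is the suffix convention described
  above; published analyses using commercial software may select
  slightly different windows on the same data.
* The robust correlation is a sensitivity analysis with a documented
  estimator choice, not a reproduction of any specific reference
  implementation. One published interval (r = −0.68, CI −0.84 to
  −0.43) differs in the last digit from the plain Fisher formula
  (−0.42); the package reports the formula value and does not force
  agreement.
* Mixed-model inference uses Wald intervals on the ML fit; profile or
  Kenward-Roger intervals would widen slightly at n = 15 per group.
* Group medians at n = 15 carry substantial sampling noise; simulated
  summary tables should be compared to reported ones only at the
  cohort-median level, not subject by subject.
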