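---
title: "Methods: the NR index, the cohort simulator, and the trial analysis layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the NR index, the cohort simulator, and the trial analysis layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nociguard)
```

## The nociceptive response index

Intraoperative nociception — the afferent barrage from surgical trauma that
persists under general anesthesia — leaves a sympathetic signature in
routinely monitored vitals: heart rate (HR) and systolic blood pressure
(SBP) rise, and the plethysmographic perfusion index (PI) falls as skin
vessels constrict. The NR index condenses these into a single score. A
stimulus term

$$S = 0.01\,\mathrm{HR} + 0.02\,\mathrm{SBP} - 0.17\,\mathrm{PI}$$

(HR in beats·min⁻¹, SBP in mmHg, PI in percent) is mapped through the
logistic response curve

$$\mathrm{NR} = \frac{2}{1 + e^{-S}} - 1,$$

the solution of a logistic differential equation in which the physiological
response saturates under feedback regulation (descending pain inhibition and
the baroreflex). The weights of $S$ are fixed constants of the index, fitted
upstream to discriminate procedures of graded invasiveness; the rate and
ceiling constants of the underlying differential equation are absorbed into
the fitted logistic and are not run-time quantities here.

Numerical conventions in `compute_nr()` / `nr_from_vitals()`:

* **Clamp at zero.** The index is defined on $[0, 1]$, but the raw logistic
  is negative for $S < 0$ (attainable under profound vasodilation, i.e.
  very high PI). We clamp at 0 from below and keep the unclamped $S$ in the
  trace, so no information is lost and the identity
  $\mathrm{NR} = \max(2/(1+e^{-S})-1,\, 0)$ is testable per minute.
* **PI scale.** PI is on the usual pulse-oximeter percent scale
  (≈ 0.2–20 %); the −0.17 weight is only meaningful on that scale.
* **1-minute grid, LOCF pressure.** The index is computed once per minute.
  Under non-invasive monitoring the cuff cycles every 5 minutes, so the
  most recent earlier SBP is carried forward (never backward, never
  interpolated) and every carried minute is flagged. The index is undefined
  before the first pressure observation rather than assuming a default.
* **Closed surgical window.** Per-patient highest/mean/lowest NR and the
  exceedance fraction are computed over the closed interval
  [surgery start, surgery end]; the mean is the unweighted per-minute mean.
* **Exceedance is NR ≥ 0.85**, the complement of the guidance target of
  holding NR below 0.85.
* Sub-minute input must be pre-binned (mean within minute) by the reader;
  mean blood pressure, used only for the hypotension flags (< 55 / < 65
  mmHg), is accepted as an external trace and never derived from SBP.

## The cohort simulator

`simulate_trial()` generates a two-arm trial (default 52 patients per arm)
without any external data. Each patient carries a latent nociceptive drive
$u(t)$ on the minute grid:

* an awake plateau before induction (awake patients score high on the NR
  scale),
* exponential-decay pulses at tracheal intubation, skin incision and wound
  closure,
* a sustained pneumoperitoneum/dissection plateau between incision and
  surgery end (per-patient intensity drawn once per patient),
* an emergence rise after surgery end, and
* mean-reverting AR(1) noise (stationary SD 0.4 drive units, 8-minute
  correlation time).

Vitals are affine in the drive (per unit: +8 beats·min⁻¹, +15 mmHg,
−1.5 % PI), so $S$ is affine in the drive with slope
$0.01 \cdot 8 + 0.02 \cdot 15 + 0.17 \cdot 1.5 = 0.635$ per unit. Surgery
duration is drawn normal (230 ± 45 min, truncated to 120–340), straddling
the two arms' published mean durations. A quarter (control) or roughly a
fifth (guided arm) of patients are invasively monitored and emit SBP every
minute; the rest follow the 5-minute cuff cadence, which exercises the
carry-forward path end to end — the controller, like the real monitor, sees
the NR computed from the carried pressure.

**The controller.** The guided arm emulates NR-guided multimodal care with
a first-order lagged rule acting on the *measured* NR:

* a *prophylactic* component (`baseline_effect`, 0.26 drive units) active
  throughout anesthesia, reflecting the deeper continuous analgesia that
  guided care runs from the start (the trial's guided arm received a
  higher continuous remifentanil rate overall, not only after alarms);
* a *reactive* effect that rises toward a ceiling with a 3-minute lag while
  NR ≥ 0.85 and decays slowly (120-minute time constant — an increased
  infusion rate is rarely dialled straight back down) with gain 0.95;
* a *secondary* (landiolol-like) stage that engages only after 8
  consecutive minutes of exceedance, mirroring rescue beta-blockade; with
  the default configuration about 10 % of guided-arm patients engage it,
  matching the published 5/52;
* a per-patient multiplicative *titration-vigour* factor
  (SD 0.62, truncated at 0) on all three effects, representing
  between-clinician variability.

All effect components are non-negative and subtractive, so with a shared
stimulus stream a controlled trajectory can never exceed its uncontrolled
twin at any minute — a property the test suite checks pairwise.

**Calibration.** The defaults were calibrated once, against the published
arm-level intraoperative summaries, and then frozen: across large simulated
cohorts the control arm's per-patient mean NR averages ≈ 0.808
(between-patient SD ≈ 0.046) versus the published 0.809 ± 0.047, and the
guided arm ≈ 0.754 (SD ≈ 0.051) versus 0.753 ± 0.060. The guided arm's
between-patient spread is somewhat narrower than the trial's (0.05 vs
0.06): threshold feedback compresses the upper tail, and we chose not to
inflate the vigour heterogeneity further to chase the second moment.

**Outcome models.** Outcomes depend on the arm only through the patient's
mean NR (plus, for the grade split, the arm's conditional grade-III
share):

* POD-1 CRP (mg·dL⁻¹): $\max(0,\; -12.81 + 20.27\,\overline{\mathrm{NR}} +
  \varepsilon)$, $\varepsilon \sim N(0, 2.35^2)$. The residual SD is taken
  from the observational study underlying the trial's power calculation
  (≈ 2.34–2.37); intercept and slope were solved so the *truncated* means
  match the published arm means (3.66 and 2.70) under the calibrated mean-NR
  distributions. Linearity is the minimal assumption — the trial
  demonstrates an association, not a functional form.
* Complication (Clavien–Dindo ≥ II): Bernoulli with
  $\mathrm{logit}\,p = -34.84 + 42.06\,\overline{\mathrm{NR}}$, solved so the
  *marginal* arm rates are 38.5 % and 11.5 % after averaging the logistic
  over each arm's mean-NR distribution (plugging the arm mean into the
  logit directly would miss the flattening from between-patient spread).
* Conditional grade split: grade III with probability 0.30 in the control
  arm and 0 in the guided arm, mirroring the published 14 II / 6 III versus
  6 II / 0 III structure; grades IV–V are never generated (none were
  observed).
* POD-1 pain (NRS 0–10): a rounded, clamped latent Gaussian
  $-28.3 + 40\,\overline{\mathrm{NR}} + N(0, 1.2^2)$, giving medians near
  4 (control) and 2 (guided) against the published 4 and 1 — a loose,
  deliberately simple ordinal stand-in; NRS is not a calibration target.

**Randomness.** One root seed; each patient's stream is seeded by a fixed
arithmetic hash of (root, arm, index), so identical configs give
byte-identical datasets and enlarging `n_per_arm` never reshuffles earlier
patients.

**What the generator does *not* emulate.** Artifacted waveforms, drug
pharmacokinetics, fluid/temperature physiology, demographic covariates, and
any real correlation structure between baseline characteristics and
outcomes. Passing calibration tests therefore shows that the analysis layer
recovers the published arm-level contrasts *under the generating model*,
not that the model captures real intraoperative dynamics.

## The statistics layer

Every estimator carries a method tag in the reports so the dialect is
auditable:

* **Wilson score interval** for proportions. The trial does not name its
  interval method; the Wilson score interval reproduces every printed
  complication CI to the digit (6/52 → 5.4–23.0 %, 20/52 → 26.5–52.0 %,
  14/52 → 16.8–40.3 %), which identifies it. It also has near-nominal
  coverage at n ≈ 52 (the suite checks 0.93–0.97 empirically).
* **Katz log-method** relative-risk CI, which reproduces the printed
  0.30 [0.13–0.69] exactly.
* **Uncorrected Pearson χ²** on 2 × 2 tables: the uncorrected statistic
  reproduces the printed p = 0.002 and 0.047; the Yates-corrected one does
  not.
* **Student's pooled-variance t** by default (the trial says only
  "unpaired t-test"); Welch selectable.
* **Mann–Whitney U** with mid-ranks; exact permutation p when both n ≤ 8
  and no ties, otherwise the tie- and continuity-corrected normal
  approximation.
* **Sample sizes**: the uncorrected two-proportion normal-approximation
  formula (it returns exactly 49 per group at 12 % vs 36 %, α = 0.05,
  power 0.8) and the two-means normal approximation with optional
  t-quantile iteration. Results are always rounded *up*. At the published
  CRP inputs (2.6 vs 3.9, SDs 2.34/2.37) the formula gives 52 per group
  while the trial reports 50; the exact values entered into the original
  power software are not recoverable, so we document the discrepancy and
  return the formula value.
* **Bonferroni thresholds**: 0.05/2 = 0.025 for the co-primary endpoints;
  for the seven perioperative timepoints the published adjustment divides
  by 6 (0.05/6 ≈ 0.008). The divisor is an explicit argument; the pipeline
  follows the published choice.

Degenerate inputs are conventions, not crashes: two identical constant
samples give p = 1 with a `degenerate` flag; a count contrast with no
events (or events in everyone) is reported `chi2_not_estimable` with
p = 1; a zero-numerator relative risk returns the point estimate with the
CI flagged unavailable.

## Pipeline and power harness

`run_trial()` chains simulate → per-minute NR → per-patient summaries →
reports, writes everything as fixed-column CSVs plus a JSON manifest with a
config hash, and is byte-reproducible under a fixed config.
`power_experiment()` estimates empirical power by repeated simulation at
arm-level generating parameters (event rates or means/SDs), analyzing each
replicate with the same test functions the pipeline uses. Generation at
arm-level rates — rather than re-running the per-minute simulator per
replicate — is what makes a 1,000-replicate grid a minutes-scale
computation and is the direct simulation twin of the analytic sample-size
formulas it is checked against: at rates 0.36/0.12 and n = 49 the exact
enumeration of the uncorrected χ² rejection probability is 0.8165, slightly
above the 0.80 normal-approximation design value, and the empirical power
matches the enumeration within Monte-Carlo error while the null
configuration holds the 5 % level.

## Problem sizes used in the checks

The routine suite runs full-scale (52/arm) simulations only where the
published calibration is being checked, and small, short-surgery
configurations (4–8 per arm, ~60-minute surgeries) for structural and
determinism properties; parameter recovery uses 5,000-patient outcome-level
cohorts; the power twin uses 1,000 replicates. These sizes were chosen as
the smallest that leave the Monte-Carlo bands decisive.

## Known limitations

* The guided-arm between-patient SD of mean NR is under-dispersed relative
  to the trial (≈ 0.05 vs 0.060).
* CRP truncation at 0 is handled by `max(0, ·)` rather than a log-normal;
  published arm means are far from 0 relative to noise, and the calibration
  solves for the truncated means, but the lower tail is a point mass at 0.
* The NRS model is a convenience stand-in (guided-arm median 2 vs the
  published 1).
* T3 ("before start of surgery") is placed 1–5 minutes before T4 ("start
  of surgery"); the published timeline does not state the gap. Timepoint
  calibration is shape-only: no per-timepoint values are targeted.
* Whether clinical NR software clamps or rescales negative raw values is
  not documented anywhere we know of; the clamp is this package's decision.
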