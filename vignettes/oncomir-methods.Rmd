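---
title: "Methods: the oncomiR index pipeline and its synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the oncomiR index pipeline and its synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncomir)
library(dplyr)
```

## The problem

Secondary CNS involvement of aggressive B-cell non-Hodgkin lymphoma (DLBCL,
MCL, Burkitt, B-NHL-NOS) is hard to detect: CSF cytology and flow cytometry
miss parenchymal disease, and imaging only finds established tumours. Five
circulating oncogenic microRNAs (miR-21, miR-19a, miR-20a, miR-92a, miR-155)
measured by qPCR in cerebrospinal fluid and plasma are markedly elevated when
the CNS is involved. This package implements the complete analysis chain for
such data: quantification of raw Ct values, the composite "oncomiR index"
classifier, ROC threshold selection, nonparametric group comparison, and
survival-based risk stratification — together with a synthetic-cohort
generator so that every stage is testable without patient data.

## Quantification model

Relative expression is estimated by the 2^−ΔCt method against the endogenous
reference miR-let-7a:

$$\mathrm{expression} = 2^{-(Ct_\mathrm{target} - Ct_\mathrm{let\text{-}7a})}.$$

Choices a user should know about:

* **Replicates are averaged on the Ct scale** (`average_duplicates()`),
  where replicate noise is approximately Gaussian in cycles. A spread above
  `tolerance` (default 1.0 cycle) flags the pair as discordant.
* **Undetermined Ct values are missing, never a pseudo-Ct of 40.** Treating
  non-amplification as Ct 40 fabricates signal at the detection limit;
  instead missingness propagates with QC flags and panel scoring refuses to
  impute.
* **Spike-in QC** (`spike_in_qc()`): a sample fails when its cel-miR-39 Ct
  deviates from the batch median by more than 2 cycles (configurable),
  indicating poor RNA recovery. Failed samples are excluded from
  equalization statistics but kept, flagged, in the output.
* **Equalization** (`equalize_to_reference()`) divides each value by the
  mean of the reference group per miRNA and compartment, so the reference
  mean is exactly 1. The reference defaults to the non-lymphoma control
  group; it can be set to the systemic-lymphoma group instead, which is the
  scale on which index coefficients are usually fitted. Both conventions
  appear in the literature for this assay family and the package supports
  either; neither is hard-coded as the single truth. The **mean** (not the
  median) is used as the denominator because the equalization is defined as
  division by the group average.

Equalized values are scale-free: multiplying all abundances by a constant
(equivalently shifting all target Cts) leaves them unchanged, which the test
suite checks exactly.

## The oncomiR index

The index is a weighted sum of equalized abundances,
$\mathrm{index} = \sum_i c_i \, a_i$ with $c_i \ge 0$, optionally passed
through a logistic link

$$P(\mathrm{CNS}) = \frac{1}{1 + \exp(X - \mathrm{index})},$$

which is strictly increasing in the index with $P = 0.5$ at
$\mathrm{index} = X$. Because the link is monotone, the score and the
probability generate identical ROC curves; thresholds can therefore be
stated on the raw index scale. A sample is called CNS-involved when its
index is **greater than or equal to** the threshold — the published
thresholds are cut-offs *for* involvement, so the boundary counts as
positive.

Eight published coefficient presets (four diagnoses × CSF/plasma) ship in a
versioned JSON resource (`oncomir_presets()`), together with their decision
thresholds. Two caveats are inherited from the published models and are
deliberate:

* The logistic intercept $X$ was never published; presets carry
  `intercept = NA` and `cns_probability()` on a preset requires an explicit
  intercept.
* The prose of the original report mentions a DLBCL-CSF threshold of 8.2 in
  one place while its summary table prints 8.42; the presets follow the
  table and the discrepancy is documented rather than resolved.

### Fitting new coefficients

`fit_index()` maximises the difference of average class probabilities,
$\max \; \overline{P}_\mathrm{CNS} - \overline{P}_\mathrm{systemic}$ — the
objective the published coefficients were derived with. This objective is
**scale-degenerate**: multiplying all coefficients and $X$ by a large factor
approaches a 0/1 step function, so the unconstrained problem has no finite
optimum. The fitter therefore requires finite boxes (defaults: each
coefficient in $[0, 10]$, $X \in [-20, 20]$) and refuses unbounded searches.

Numerical design:

* multi-start bounded quasi-Newton (L-BFGS-B with an analytic gradient;
  probabilities via `plogis` to avoid overflow at steep optima), starting
  from a deterministic grid of coefficient levels plus seeded random starts
  — results are reproducible given `seed`;
* near-equal optima (within `tie_tol`) are resolved toward the smallest L2
  norm of the coefficient vector;
* the same preference is applied to the panel by **backward pruning**: a
  coefficient whose removal (after re-optimising the rest) costs at most
  `prune_tol = 1e-3` of the objective is set to zero, and zero-weight
  miRNAs are dropped from the panel, mirroring the published convention
  that a zero coefficient excludes the oncomiR.

A known limitation, measured on synthetic data: when classes overlap
substantially (biological log2 SD near 1 at a 8× fold-change), the training
optimum of this objective genuinely assigns a small positive weight to a
pure-noise miRNA in roughly a third of random cohorts — gains of
0.005–0.013 in the objective, i.e. real overfitting rather than optimizer
error. With a clearly separating marker the pruning step removes the noise
weight essentially always. Users fitting on small noisy cohorts should
treat small fitted coefficients with suspicion and validate on held-out
samples (`fit_index` is intentionally *not* wrapped in any cross-validated
model search).

After fitting, the decision threshold is selected on the training scores by
the closest-to-corner rule below and stored on the model.

## ROC construction and threshold selection

`roc_curve()` uses candidate cut-offs at the midpoints between consecutive
distinct scores plus ±∞ sentinels — a finite, deterministic set that is
decision-equivalent to all real thresholds — and the `score ≥ cutoff`
positive-call convention, consistent with classification. The AUC is the
Mann-Whitney concordance probability with ties credited 0.5, which for this
construction equals trapezoidal integration exactly (asserted in tests to
1e−12) and ties the AUC to the U statistic via $U = \mathrm{AUC}\,n_x n_y$.

The operating threshold minimises the squared distance to the ideal corner,
$(1-\mathrm{sens})^2 + (\mathrm{spec}-1)^2$ on the fractional scale, with
ties broken toward higher Youden index, then higher specificity, then lower
cut-off (for reproducibility). The Youden index is reported in percentage
points, $\mathrm{sens}\% + \mathrm{spec}\% - 100$; the corner rule selects
the maximum-Youden point on most curves, and `select_threshold(method =
"youden")` is available where the distinction matters.

## Group comparison

Mann-Whitney U uses mid-ranks; the two-sided p-value is computed by exact
enumeration of the permutation distribution when both groups have ≤ 8
observations (exactness is cheap there) and by the tie-corrected normal
approximation otherwise. Kruskal-Wallis (tie-corrected, χ² reference) comes
from `stats::kruskal.test`; Dunn's post hoc z statistics use the pooled
tie-corrected variance with Bonferroni adjustment by default — the most
common companion of Dunn's test; Holm or no adjustment are switches, since
the adjustment convention is rarely stated in clinical reports. Summaries
are medians with Tukey-hinge quartiles (`fivenum`), matching common
clinical-stats software output.

## Survival and risk stratification

Kaplan-Meier estimation, the log-rank (Mantel-Cox) test and univariate Cox
proportional-hazards fits (Efron tie handling, Wald CI from the observed
information, p-value from the likelihood-ratio test) are delegated to the
survival package behind this package's tabular interface. Cumulative
incidence at a horizon is reported as $1 - S(\mathrm{horizon})$ in percent
— the convention of the emulated analyses, which treats death as censoring
when estimating CNS-relapse risk. Because death is in truth a competing
risk, `cumulative_incidence_at(method = "aalen-johansen")` provides the
competing-risk estimator as a sensitivity analysis; on synthetic data with
equal hazards the 1−KM estimate visibly overestimates incidence, as
expected.

Risk stratification: patients are split into oncomiR high/low at a cut-off.
The published high/low cut-off procedure is not public; the default is the
closest-to-corner ROC threshold computed from the diagnosis-time scores —
the one cut-off rule stated anywhere in the source analyses — with an
explicit override. CNS-IPI is dichotomized high vs not-high (low and
intermediate collapse) for the combined model, whose three strata are
"both risks" (oncomiR high and CNS-IPI high), "one risk", "no risk".

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not the biology of any real cohort:

* **Cohort composition** defaults to the emulated study: 22 controls, 108
  systemic and 54 CNS-involving lymphoma patients across four diagnoses,
  with paired CSF/plasma samples.
* **Abundances are log-normal** on the 2^−ΔCt scale: Gaussian on the log2
  scale, where qPCR replicate noise is also Gaussian. The original report
  plots medians with interquartile ranges on a log2 scale; log-normal is
  the natural generative match, but it is an assumption, not a reported
  fact. The default spread `sd_log2 = 1` reproduces single-miRNA
  CNS-vs-systemic AUCs near 0.9 at the default fold-changes, the magnitude
  such cohorts report.
* **Fold-changes** (vs control): CSF 2× systemic / 8× CNS-involving
  (i.e. 4× CNS-vs-systemic); plasma 4× systemic / 8× CNS-involving —
  systemic disease runs higher in plasma than CSF, and the CNS adds a
  further ~2×, within the 1.5–4× plasma-increase window reported around
  CNS relapse.
* **Ct synthesis inverts 2^−ΔCt exactly**: `Ct_target = Ct_let-7a −
  log2(abundance)`, plus Gaussian replicate noise in cycles; at
  `ct_noise_sd = 0` quantification recovers the latent truth to machine
  precision (tested).
* **Outcomes** follow a proportional-hazards link on the log2 latent
  plasma index: hazard `h0 · exp(β · log2 score)`, with independent relapse
  and death processes (no competing-risk coupling — matching the 1−KM
  analysis convention; death can be switched off to isolate relapse).
  Default `h0 = 0.0005`/month and `β = 0.5` give 4-year relapse risks in
  the 10–35% range typical of CNS-relapse cohorts; `death_baseline_hazard
  = 0.002` yields a moderate OS event rate. Early censoring affects a
  `censor_rate` fraction of patients uniformly before the administrative
  horizon (60 months).
* **Longitudinal trajectories** (`generate_longitudinal()`) encode the
  three observed monitoring shapes — responder (decline to control level),
  refractory (steady rise), pre-relapse (flat, then rising from 1–4 months
  — median 3 — before the recorded relapse). The monitoring rule
  `flag_rising_trajectory()` alerts on k = 2 consecutive strict rises
  totalling ≥ 1.5× — a deliberately simple operationalisation of the
  pre-relapse rise.

What passing tests on these cohorts does **not** show: robustness to
hemolysis or serum-coagulation artifacts, non-log-normal abundance tails,
informative censoring, or correlated miRNA co-regulation (miRNAs are
generated independently given the group). Conclusions about real patient
data require validation on real patient data.

### Problem sizes used in the shipped checks

The packaged checks run at sizes where each property is informative yet
quick: ROC/AUC oracle equivalence on 1,000 random instances up to n = 200;
coefficient recovery on 20 cohorts of 100 + 100 patients; Cox
hazard-ratio recovery on 50 cohorts of 400 patients; null calibration on an
800-patient no-signal cohort and 1,000-replicate type-I-error simulations.

## Reproducibility

Every generator takes an integer seed and restores the caller's RNG state;
a fixed seed makes all emitted tables byte-identical, which the test suite
verifies, and `run_pipeline()` records the seed and a configuration hash in
its output manifest. CSV outputs are UTF-8 with "." decimals; the tokens
"", "NA" and "Undetermined" parse as missing on input.
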