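# oncomir

Analysis toolkit for circulating oncogenic microRNAs (oncomiRs) as liquid-biopsy
markers of secondary CNS involvement in aggressive B-cell non-Hodgkin lymphoma
(DLBCL, MCL, Burkitt lymphoma, B-NHL-NOS).

Detecting CNS spread of systemic lymphoma is hard: CSF cytology and flow
cytometry miss parenchymal disease, imaging only finds established tumours.
Five oncomiRs — miR-21, miR-19a, miR-20a, miR-92a, miR-155 — measured by qPCR
in cerebrospinal fluid and plasma are strongly elevated when the CNS is
involved, and their weighted combination separates CNS-involving from
systemic-only disease with high sensitivity and specificity. This package
implements that analysis chain end to end, for biostatisticians and
translational researchers working with such panels:

* **Quantification** — duplicate Ct averaging, cel-miR-39 spike-in QC,
  relative expression by the 2^−ΔCt method against miR-let-7a
  (`expression = 2^−(Ct_target − Ct_let-7a)`), and equalization to a
  reference group so the control mean is 1 per miRNA and compartment.
* **The oncomiR index** — the composite score
  `index = Σ cᵢ · abundanceᵢ`, its logistic CNS-involvement probability
  `p = 1 / (1 + exp(X − index))`, the eight published coefficient presets
  with their decision thresholds, and a fitter (`fit_index()`) that
  maximises the difference of average class probabilities inside a bounded,
  reproducible multi-start search.
* **ROC machinery** — concordance AUC (= Mann-Whitney U / nₓn_y), the
  closest-to-corner threshold rule `min (1−sens)² + (spec−1)²`, and the
  Youden index `sens% + spec% − 100`.
* **Group comparison** — Mann-Whitney U (exact for small groups),
  Kruskal-Wallis with Dunn post hoc, median ± IQR summaries.
* **Survival risk models** — Kaplan-Meier, log-rank, univariate Cox hazard
  ratios, 4-year cumulative incidence, oncomiR high/low stratification, and
  the combined oncomiR + CNS-IPI risk model.
* **Synthetic cohorts** — a seeded generator (`generate_cohort()`,
  `generate_longitudinal()`, `generate_survival()`) that emulates the
  statistical structure of such studies (log-normal abundances, paired
  CSF/plasma samples, proportional-hazards outcomes, responder / refractory
  / pre-relapse trajectories), so the whole pipeline is testable without
  patient data.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; fitted objects have `tidy()` / `glance()`
methods and result objects have `autoplot()`.

## Worked example

Generate a synthetic cohort, quantify expression, score the DLBCL-CSF index
preset and measure how well it separates CNS-involving from systemic disease:

```r
library(oncomir)
library(dplyr)

cohort <- generate_cohort(synthetic_config(seed = 7))
cohort
#> <oncomir_cohort> 368 samples / 184 patients; 5152 Ct records; seed 7

expr <- quantify_expression(cohort$ct, cohort$metadata)
wide <- expression_wide(expr) |>
  filter(compartment == "CSF", diagnosis == "DLBCL", group != "control")

scored <- classify_samples(wide, oncomir_presets("DLBCL-CSF"))
roc <- roc_curve(scored, index, group, positive = "SCNSL")
roc
#> <oncomir_roc> 25 positive / 72 negative samples
#>   AUC 0.990; threshold 18.74 (sens 96.0%, spec 94.4%, Youden 90.4)
```

Reading this: of 97 synthetic DLBCL patients (25 with CNS involvement), the
preset index ranks a CNS-involving sample above a systemic one 99% of the
time (AUC 0.990). The closest-to-corner rule picks the cut-off 18.74 on this
cohort's scale, where 96% of CNS-involving samples are called positive
(sensitivity) and 94.4% of systemic samples negative (specificity); the
Youden index is 96.0 + 94.4 − 100 = 90.4 percentage points. Note the
selected threshold lives on the synthetic cohort's expression scale — the
preset's published threshold (8.42, log2 3.07) applies to the original
assay's scale:

```r
oncomir_presets("DLBCL-CSF")
#> <index_model> DLBCL-CSF (CSF)
#>   index = 1.83 x miR-21 + 1.31 x miR-20a + 1.78 x miR-155
#>   threshold 8.42 (log2 3.07)
```

`run_pipeline(synthetic = synthetic_config(seed = 7), out_dir = "out")`
runs the whole chain — quantification, all eight presets, ROC summaries,
group tests, and oncomiR/CNS-IPI survival stratification — and writes CSVs
plus a seed-stamped manifest; reruns under the same seed are byte-identical.

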