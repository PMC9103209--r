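#' Default per-group cohort composition
#'
#' The default cohort mirrors the clinical study population this generator
#' emulates: 22 non-lymphoma controls and 162 B-NHL patients (108 systemic,
#' 54 with secondary CNS involvement) across four diagnoses.
#'
#' @return A tibble with columns `diagnosis`, `group`, `n`.
#' @export
default_group_sizes <- function() {
  tibble(
    diagnosis = c("control", "DLBCL", "DLBCL", "MCL", "MCL", "BL", "BL",
                  "B-NHL-NOS", "B-NHL-NOS"),
    group = c("control", "systemic", "SCNSL", "systemic", "SCNSL",
              "systemic", "SCNSL", "systemic", "SCNSL"),
    n = c(22L, 72L, 25L, 19L, 15L, 13L, 5L, 4L, 9L)
  )
}

#' Default fold-changes of latent oncomiR abundance versus controls
#'
#' Multiplicative shifts of the latent (noise-free) abundance per group and
#' compartment, applied uniformly across the five-miRNA panel. Defaults
#' encode the qualitative structure of the emulated study: CNS-involving
#' disease raises CSF oncomiRs strongly (8x vs control, i.e. 4x vs systemic
#' disease at 2x), while in plasma systemic disease itself runs higher
#' (4x vs control, roughly twice its CSF elevation) and CNS involvement
#' adds a further 2x (8x vs control) - the same 1.5-4x plasma-increase
#' magnitude reported around CNS relapse.
#'
#' @param csf_systemic,csf_scnsl,plasma_systemic,plasma_scnsl Fold-changes
#'   vs control for each (compartment, group) cell.
#' @param mirnas miRNA panel the fold-changes apply to.
#' @return A tibble `group` x `compartment` x `mirna` x `fold_change`.
#' @export
default_fold_changes <- function(csf_systemic = 2, csf_scnsl = 8,
                                 plasma_systemic = 4, plasma_scnsl = 8,
                                 mirnas = ONCOMIR_PANEL) {
  grid <- tidyr::expand_grid(
    group = c("control", "systemic", "SCNSL"),
    compartment = c("CSF", "plasma"),
    mirna = mirnas
  )
  grid$fold_change <- dplyr::case_when(
    grid$group == "control" ~ 1,
    grid$group == "systemic" & grid$compartment == "CSF" ~ csf_systemic,
    grid$group == "SCNSL" & grid$compartment == "CSF" ~ csf_scnsl,
    grid$group == "systemic" & grid$compartment == "plasma" ~ plasma_systemic,
    grid$group == "SCNSL" & grid$compartment == "plasma" ~ plasma_scnsl
  )
  grid
}

#' Configuration of the synthetic liquid-biopsy cohort generator
#'
#' Bundles every knob of the generator: cohort composition, the latent
#' log-normal abundance model, the Ct synthesis parameters, and the
#' proportional-hazards link used for outcome generation. Latent abundances
#' are log-normal on the relative-expression (2^-dCt) scale - Gaussian on
#' the log2 scale where replicate noise is also Gaussian in cycles - and Ct
#' values are back-computed by exactly inverting the 2^-dCt relation:
#' Ct_target = Ct_reference - log2(abundance), plus replicate noise.
#'
#' @param seed Integer seed; a fixed seed makes every generated table
#'   byte-identical across runs.
#' @param group_sizes Tibble `diagnosis`/`group`/`n` ([default_group_sizes()]).
#' @param compartments Compartments sampled per patient (paired).
#' @param mirnas Target miRNA panel.
#' @param base_log2_abundance Named per-miRNA control mean of log2 abundance
#'   (default 0: the control-relative scale).
#' @param sd_log2 Spread of log2 abundance (biological variation), in log2
#'   units; scalar or named per-miRNA. The default of 1 reproduces
#'   single-miRNA CNS-vs-systemic AUCs near 0.9 at the default 4x CSF
#'   separation, the magnitude such cohorts report.
#' @param fold_changes Tibble `group`/`compartment`/`mirna`/`fold_change`
#'   ([default_fold_changes()]); all values must be positive.
#' @param ct_reference_mean,ct_reference_sd Mean/SD of the per-sample
#'   miR-let-7a reference Ct (cycles).
#' @param ct_noise_sd Replicate noise SD in cycles (0 = noise-free Ct).
#' @param spike_ct_mean,spike_ct_sd Spike-in (cel-miR-39) Ct distribution.
#' @param n_replicates qPCR replicates per assay (default duplicate).
#' @param baseline_hazard Baseline CNS-relapse hazard per month (> 0).
#' @param hazard_beta Log hazard-ratio per unit log2 index score.
#' @param death_baseline_hazard Baseline death hazard per month; set 0 to
#'   switch deaths off and isolate relapse analyses.
#' @param death_hazard_beta Log hazard-ratio of death per unit log2 score.
#' @param censor_rate Fraction of patients with random early (uniform)
#'   censoring in addition to administrative censoring at `followup_months`.
#' @param followup_months Administrative censoring horizon (months).
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1L,
                             group_sizes = default_group_sizes(),
                             compartments = c("CSF", "plasma"),
                             mirnas = ONCOMIR_PANEL,
                             base_log2_abundance = setNames(rep(0, length(mirnas)), mirnas),
                             sd_log2 = 1,
                             fold_changes = default_fold_changes(mirnas = mirnas),
                             ct_reference_mean = 25, ct_reference_sd = 1,
                             ct_noise_sd = 0.25,
                             spike_ct_mean = 20, spike_ct_sd = 0.5,
                             n_replicates = 2L,
                             baseline_hazard = 0.0005, hazard_beta = 0.5,
                             death_baseline_hazard = 0.002,
                             death_hazard_beta = 0.3,
                             censor_rate = 0.2, followup_months = 60) {
  assert_number(seed, "seed")
  assert_data_frame(group_sizes, "group_sizes")
  assert_columns(group_sizes, c("diagnosis", "group", "n"), "group_sizes")
  if (nrow(group_sizes) == 0) abort("`group_sizes` must not be empty.")
  if (any(group_sizes$n < 0)) abort("Group counts must be >= 0.")
  if (any(sd_log2 < 0) || ct_reference_sd < 0 || ct_noise_sd < 0 ||
      spike_ct_sd < 0) {
    abort("All standard deviations must be >= 0.")
  }
  assert_data_frame(fold_changes, "fold_changes")
  assert_columns(fold_changes, c("group", "compartment", "mirna", "fold_change"),
                 "fold_changes")
  if (any(!is.finite(fold_changes$fold_change) | fold_changes$fold_change <= 0)) {
    abort("All fold-changes must be positive and finite.")
  }
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be positive.")
  if (death_baseline_hazard < 0) abort("`death_baseline_hazard` must be >= 0.")
  if (!is.finite(hazard_beta)) abort("`hazard_beta` must be finite.")
  assert_number(censor_rate, "censor_rate", min = 0, max = 1)
  assert_number(followup_months, "followup_months", min = 0)
  structure(
    list(
      seed = as.integer(seed), group_sizes = as_tibble(group_sizes),
      compartments = compartments, mirnas = mirnas,
      base_log2_abundance = base_log2_abundance, sd_log2 = sd_log2,
      fold_changes = as_tibble(fold_changes),
      ct_reference_mean = ct_reference_mean, ct_reference_sd = ct_reference_sd,
      ct_noise_sd = ct_noise_sd,
      spike_ct_mean = spike_ct_mean, spike_ct_sd = spike_ct_sd,
      n_replicates = as.integer(n_replicates),
      baseline_hazard = baseline_hazard, hazard_beta = hazard_beta,
      death_baseline_hazard = death_baseline_hazard,
      death_hazard_beta = death_hazard_beta,
      censor_rate = censor_rate, followup_months = followup_months
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> seed %d; %d patients in %d diagnosis/group cells; compartments: %s\n",
    x$seed, sum(x$group_sizes$n), nrow(x$group_sizes),
    paste(x$compartments, collapse = ", ")
  ))
  invisible(x)
}

sd_for <- function(config, mirna) {
  s <- config$sd_log2
  if (!is.null(names(s))) unname(s[mirna]) else rep(s[1], length(mirna))
}

#' Generate a synthetic diagnosis-time cohort
#'
#' Draws, per patient and compartment, latent oncomiR abundances from the
#' log-normal model (control mean x group/compartment fold-change, Gaussian
#' on the log2 scale), back-computes Ct records with replicate noise, emits
#' the reference (miR-let-7a) and spike-in (cel-miR-39) records every sample
#' must carry, and attaches per-patient survival outcomes generated from the
#' latent plasma index through the proportional-hazards link (see
#' [generate_survival()]).
#'
#' @param config A [synthetic_config()].
#' @return An object of class `oncomir_cohort`: a list of tibbles `ct`
#'   (long Ct records), `metadata` (one row per sample), `truth` (latent
#'   abundances per sample and miRNA), plus the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  gs <- config$group_sizes[config$group_sizes$n > 0, , drop = FALSE]
  if (nrow(gs) == 0) abort("`group_sizes` contains no patients.")

  patients <- purrr::map_dfr(seq_len(nrow(gs)), function(i) {
    tibble(diagnosis = gs$diagnosis[i], group = gs$group[i],
           idx = seq_len(gs$n[i]))
  })
  patients$patient_id <- sprintf("P%03d", seq_len(nrow(patients)))
  n_pat <- nrow(patients)

  is_scnsl <- patients$group == "SCNSL"
  patients$localization <- ifelse(
    is_scnsl,
    sample(c("parenchymal", "meningeal", "parenchymal+meningeal"),
           n_pat, replace = TRUE, prob = c(0.35, 0.4, 0.25)),
    NA_character_
  )
  # Lumbar-puncture cohorts are enriched for CNS-IPI high-risk patients.
  patients$cns_ipi <- ifelse(
    patients$group == "control", NA_character_,
    sample(c("low", "intermediate", "high"), n_pat, replace = TRUE,
           prob = c(0.2, 0.35, 0.45))
  )

  samples <- tidyr::expand_grid(patients[c("patient_id", "diagnosis", "group",
                                           "localization", "cns_ipi")],
                                compartment = config$compartments)
  samples$timepoint_months <- 0
  samples$sample_id <- paste0(samples$patient_id, "_",
                              samples$compartment, "_t00")

  truth <- tidyr::expand_grid(
    samples[c("sample_id", "patient_id", "group", "compartment",
              "timepoint_months")],
    mirna = config$mirnas
  )
  truth <- dplyr::left_join(
    truth, config$fold_changes,
    by = c("group", "compartment", "mirna")
  )
  if (any(is.na(truth$fold_change))) {
    missing <- unique(truth[is.na(truth$fold_change),
                            c("group", "compartment", "mirna")])
    abort(sprintf("`fold_changes` has no entry for: %s.",
                  paste(apply(missing, 1, paste, collapse = "/"),
                        collapse = ", ")))
  }
  truth$log2_abundance <- unname(config$base_log2_abundance[truth$mirna]) +
    log2(truth$fold_change) +
    rnorm(nrow(truth), 0, sd_for(config, truth$mirna))
  truth$abundance <- 2^truth$log2_abundance

  samples$ref_ct <- rnorm(nrow(samples), config$ct_reference_mean,
                          config$ct_reference_sd)
  samples$spike_ct <- rnorm(nrow(samples), config$spike_ct_mean,
                            config$spike_ct_sd)

  assays <- dplyr::bind_rows(
    dplyr::left_join(truth[c("sample_id", "mirna")],
                     samples[c("sample_id", "ref_ct")], by = "sample_id") |>
      dplyr::mutate(
        assay = .data$mirna,
        true_ct = .data$ref_ct - truth$log2_abundance
      ) |>
      dplyr::select("sample_id", "assay", "true_ct"),
    samples |>
      dplyr::transmute(sample_id = .data$sample_id, assay = REFERENCE_ASSAY,
                       true_ct = .data$ref_ct),
    samples |>
      dplyr::transmute(sample_id = .data$sample_id, assay = SPIKE_ASSAY,
                       true_ct = .data$spike_ct)
  )
  ct <- tidyr::expand_grid(assays, replicate = seq_len(config$n_replicates))
  ct$ct <- ct$true_ct + rnorm(nrow(ct), 0, config$ct_noise_sd)
  ct <- dplyr::left_join(
    ct, samples[c("sample_id", "patient_id", "compartment",
                  "timepoint_months")],
    by = "sample_id"
  ) |>
    dplyr::select("patient_id", "sample_id", "compartment",
                  "timepoint_months", "assay", "replicate", "ct")

  # Outcomes driven by the latent plasma (or first-compartment) index.
  score_comp <- if ("plasma" %in% config$compartments) "plasma" else
    config$compartments[1]
  latent_index <- truth |>
    dplyr::filter(.data$compartment == score_comp) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(latent_score = sum(.data$abundance), .groups = "drop")
  outcomes <- generate_survival(latent_index, latent_score, config)

  metadata <- samples |>
    dplyr::left_join(outcomes, by = "patient_id") |>
    dplyr::select("sample_id", "patient_id", "diagnosis", "group",
                  "compartment", "localization", "timepoint_months",
                  "cns_ipi", "relapse_time", "relapse_event", "death_time",
                  "death_event")

  structure(
    list(ct = ct, metadata = metadata,
         truth = truth[c("sample_id", "patient_id", "group", "compartment",
                         "timepoint_months", "mirna", "fold_change",
                         "log2_abundance", "abundance")],
         config = config),
    class = "oncomir_cohort"
  )
}

#' @export
print.oncomir_cohort <- function(x, ...) {
  cat(sprintf(
    "<oncomir_cohort> %d samples / %d patients; %d Ct records; seed %d\n",
    nrow(x$metadata), length(unique(x$metadata$patient_id)), nrow(x$ct),
    x$config$seed
  ))
  invisible(x)
}

#' Generate survival outcomes from index scores
#'
#' Draws CNS-relapse and death times from independent exponential models
#' whose hazards follow a proportional-hazards link on the log2 index score:
#' h(patient) = baseline_hazard x exp(hazard_beta x log2(score)). The true
#' hazard ratio between two patients is therefore
#' exp(hazard_beta x (log2(score1) - log2(score2))). Observation is
#' administratively censored at `followup_months`; an additional
#' `censor_rate` fraction of patients is censored uniformly earlier. Death
#' generation is skipped (all-censored at follow-up) when
#' `death_baseline_hazard` is 0.
#'
#' @param data One row per patient with a score column.
#' @param score Column (unquoted) of positive index scores.
#' @param config A [synthetic_config()] providing the hazard parameters.
#' @param seed Optional seed; by default the current RNG state is used (so
#'   [generate_cohort()] stays deterministic as a whole).
#' @return `data` with `relapse_time`, `relapse_event`, `death_time`,
#'   `death_event` added.
#' @export
generate_survival <- function(data, score, config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  assert_data_frame(data)
  s <- eval_tidy(enquo(score), data)
  if (any(!is.finite(s)) || any(s <= 0)) {
    abort("Scores must be finite and positive (the hazard acts on log2(score)).")
  }
  run <- function() {
    n <- length(s)
    draw <- function(h0, beta) {
      if (h0 == 0) {
        list(time = rep(config$followup_months, n), event = rep(0L, n))
      } else {
        h <- h0 * exp(beta * log2(s))
        true_time <- rexp(n, rate = h)
        cens <- rep(config$followup_months, n)
        early <- runif(n) < config$censor_rate
        cens[early] <- runif(sum(early), 0, config$followup_months)
        list(time = pmin(true_time, cens),
             event = as.integer(true_time <= cens))
      }
    }
    relapse <- draw(config$baseline_hazard, config$hazard_beta)
    death <- draw(config$death_baseline_hazard, config$death_hazard_beta)
    out <- as_tibble(data)
    out$relapse_time <- relapse$time
    out$relapse_event <- relapse$event
    out$death_time <- death$time
    out$death_event <- death$event
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate longitudinal oncomiR trajectories
#'
#' Serial samples of one compartment following one of three clinical
#' trajectory shapes observed under therapy monitoring:
#' \describe{
#'   \item{responder}{latent log2 abundance declines linearly from the
#'     CNS-involved level back to the control level;}
#'   \item{refractory}{latent abundance climbs steadily during treatment;}
#'   \item{pre_relapse}{abundance is flat at baseline, then rises from
#'     `onset_lead` months before the recorded relapse at `relapse_month` -
#'     emulating the 1-4-month (median 3) pre-relapse rise window.}
#' }
#' `noise_sd` adds Gaussian jitter on the latent log2 scale per timepoint
#' (0 = deterministic trajectory shapes); Ct synthesis then adds the usual
#' replicate noise from `config`.
#'
#' @param config A [synthetic_config()] (seed, Ct parameters, miRNA panel).
#' @param pattern `"responder"`, `"refractory"` or `"pre_relapse"`.
#' @param n_timepoints Number of serial samples per patient (>= 3).
#' @param n_patients Number of patients to simulate.
#' @param noise_sd Latent log2 jitter per timepoint (default 0.1).
#' @param onset_lead Months between rise onset and relapse (`pre_relapse`
#'   only). A scalar fixes the lead; a vector (e.g. `1:4`) samples one lead
#'   per patient.
#' @param relapse_month Recorded relapse time (`pre_relapse` only).
#' @param compartment Single compartment for the serial samples.
#' @return An `oncomir_cohort` (ct, metadata, truth, config); `truth` here
#'   carries the per-timepoint latent log2 abundance.
#' @export
generate_longitudinal <- function(config, pattern, n_timepoints,
                                  n_patients = 6, noise_sd = 0.1,
                                  onset_lead = 3, relapse_month = 12,
                                  compartment = "CSF") {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.character(pattern) || length(pattern) != 1 ||
      !pattern %in% c("responder", "refractory", "pre_relapse")) {
    abort("`pattern` must be one of 'responder', 'refractory', 'pre_relapse'.")
  }
  assert_number(n_timepoints, "n_timepoints", min = 3)
  assert_number(noise_sd, "noise_sd", min = 0)
  if (pattern == "pre_relapse") {
    if (any(onset_lead <= 0) || any(onset_lead >= relapse_month)) {
      abort("`onset_lead` must lie strictly between 0 and `relapse_month`.")
    }
  }
  with_seed(config$seed, {
    timepoints <- if (pattern == "pre_relapse") {
      seq(0, relapse_month, length.out = n_timepoints)
    } else {
      seq(0, n_timepoints - 1)
    }
    rows <- purrr::map_dfr(seq_len(n_patients), function(p) {
      lead <- if (length(onset_lead) > 1) sample(onset_lead, 1) else onset_lead
      base <- switch(pattern,
        responder = seq(3, 0, length.out = n_timepoints),
        refractory = seq(1, 4, length.out = n_timepoints),
        pre_relapse = {
          onset <- relapse_month - lead
          ifelse(timepoints <= onset, 1,
                 1 + 3 * (timepoints - onset) / lead)
        }
      )
      tidyr::expand_grid(
        tibble(patient_id = sprintf("L%03d", p), timepoint_months = timepoints,
               base_log2 = base, onset_lead = lead),
        mirna = config$mirnas
      )
    })
    rows$log2_abundance <- rows$base_log2 + rnorm(nrow(rows), 0, noise_sd)
    rows$abundance <- 2^rows$log2_abundance
    rows$sample_id <- sprintf("%s_%s_t%05.1f", rows$patient_id, compartment,
                              rows$timepoint_months)
    rows$compartment <- compartment

    samples <- dplyr::distinct(rows, .data$sample_id, .data$patient_id,
                               .data$compartment, .data$timepoint_months)
    samples$ref_ct <- rnorm(nrow(samples), config$ct_reference_mean,
                            config$ct_reference_sd)
    samples$spike_ct <- rnorm(nrow(samples), config$spike_ct_mean,
                              config$spike_ct_sd)

    assays <- dplyr::bind_rows(
      dplyr::left_join(rows[c("sample_id", "mirna", "log2_abundance")],
                       samples[c("sample_id", "ref_ct")], by = "sample_id") |>
        dplyr::transmute(sample_id = .data$sample_id, assay = .data$mirna,
                         true_ct = .data$ref_ct - .data$log2_abundance),
      samples |>
        dplyr::transmute(sample_id = .data$sample_id, assay = REFERENCE_ASSAY,
                         true_ct = .data$ref_ct),
      samples |>
        dplyr::transmute(sample_id = .data$sample_id, assay = SPIKE_ASSAY,
                         true_ct = .data$spike_ct)
    )
    ct <- tidyr::expand_grid(assays, replicate = seq_len(config$n_replicates))
    ct$ct <- ct$true_ct + rnorm(nrow(ct), 0, config$ct_noise_sd)
    ct <- dplyr::left_join(
      ct,
      samples[c("sample_id", "patient_id", "compartment", "timepoint_months")],
      by = "sample_id"
    ) |>
      dplyr::select("patient_id", "sample_id", "compartment",
                    "timepoint_months", "assay", "replicate", "ct")

    metadata <- samples |>
      dplyr::transmute(
        sample_id = .data$sample_id, patient_id = .data$patient_id,
        diagnosis = "DLBCL", group = pattern,
        compartment = .data$compartment, localization = NA_character_,
        timepoint_months = .data$timepoint_months, cns_ipi = NA_character_,
        relapse_time = if (pattern == "pre_relapse") relapse_month else NA_real_,
        relapse_event = if (pattern == "pre_relapse") 1L else NA_integer_,
        death_time = NA_real_, death_event = NA_integer_
      )

    structure(
      list(
        ct = ct, metadata = metadata,
        truth = rows[c("sample_id", "patient_id", "compartment",
                       "timepoint_months", "mirna", "onset_lead",
                       "log2_abundance", "abundance")],
        config = config
      ),
      class = "oncomir_cohort"
    )
  })
}
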