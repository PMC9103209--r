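test_that("configuration invariants are enforced", {
  expect_error(small_config(n_systemic = -1), ">= 0")
  expect_error(synthetic_config(group_sizes = default_group_sizes()[0, ]),
               "empty")
  bad_fc <- default_fold_changes()
  bad_fc$fold_change[3] <- 0
  expect_error(synthetic_config(fold_changes = bad_fc), "positive")
  expect_error(synthetic_config(sd_log2 = -1), ">= 0")
  expect_error(synthetic_config(censor_rate = 1.5), "censor_rate")
  expect_error(synthetic_config(baseline_hazard = 0), "positive")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 42, n_systemic = 8, n_scnsl = 8, n_control = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$ct, b$ct)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
})

test_that("cohort structure matches the requested design", {
  cfg <- small_config(seed = 2, n_systemic = 7, n_scnsl = 6, n_control = 4)
  co <- generate_cohort(cfg)

  counts <- co$metadata |>
    dplyr::distinct(patient_id, group) |>
    dplyr::count(group)
  expect_equal(counts$n[counts$group == "systemic"], 7)
  expect_equal(counts$n[counts$group == "SCNSL"], 6)
  expect_equal(counts$n[counts$group == "control"], 4)

  # every sample carries reference and spike-in records
  per_sample <- co$ct |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(has_ref = any(assay == "miR-let-7a"),
                     has_spike = any(assay == "cel-miR-39"))
  expect_true(all(per_sample$has_ref))
  expect_true(all(per_sample$has_spike))

  # paired compartments share patient and timepoint
  pairs <- co$metadata |>
    dplyr::count(patient_id, timepoint_months)
  expect_true(all(pairs$n == 2))

  # truth has one row per sample x miRNA
  expect_equal(nrow(co$truth), nrow(co$metadata) * 5)

  # duplicates emitted
  reps <- co$ct |> dplyr::count(sample_id, assay)
  expect_true(all(reps$n == 2))
})

test_that("fold-change errors name the offending configuration", {
  fc <- default_fold_changes()
  fc <- fc[fc$mirna != "miR-21", ]
  cfg <- synthetic_config(fold_changes = fc,
                          group_sizes = default_group_sizes()[1:3, ])
  expect_error(generate_cohort(cfg), "miR-21")
})

test_that("strong CSF signal yields a near-perfect fitted index", {
  gs <- tibble::tibble(diagnosis = c("control", "DLBCL", "DLBCL"),
                       group = c("control", "systemic", "SCNSL"),
                       n = c(10L, 50L, 50L))
  fc <- default_fold_changes(csf_systemic = 1, csf_scnsl = 8,
                             plasma_systemic = 1, plasma_scnsl = 1)
  aucs <- sapply(1:3, function(s) {
    cfg <- synthetic_config(seed = s, group_sizes = gs, fold_changes = fc,
                            sd_log2 = 1)
    co <- generate_cohort(cfg)
    w <- expression_wide(quantify_expression(co$ct, co$metadata)) |>
      dplyr::filter(compartment == "CSF", group != "control")
    f <- fit_index(w, group, panel = paste0("miR-", c("21", "19a", "20a", "92a", "155")),
                   positive = "SCNSL", seed = s)
    roc_auc(compute_index(w, f), index, group, positive = "SCNSL")
  })
  expect_true(all(aucs > 0.95))
})

test_that("survival generation follows the proportional-hazards link", {
  cfg <- synthetic_config(seed = 1, baseline_hazard = 0.01,
                          hazard_beta = log(4), death_baseline_hazard = 0,
                          censor_rate = 0)
  d <- tibble::tibble(patient_id = sprintf("P%03d", 1:2000),
                      score = rep(c(1, 2), each = 1000))
  out <- generate_survival(d, score, cfg, seed = 5)
  expect_true(all(out$relapse_time <= cfg$followup_months))
  # death switched off: all death records censored at follow-up
  expect_true(all(out$death_event == 0))
  expect_true(all(out$death_time == cfg$followup_months))
  # empirical event-rate ratio near the designed HR 4 (exponential rates)
  rate <- function(g) {
    sum(out$relapse_event[d$score == g]) / sum(out$relapse_time[d$score == g])
  }
  expect_equal(rate(2) / rate(1), 4, tolerance = 0.25)

  expect_error(generate_survival(tibble::tibble(score = c(1, -2)), score, cfg),
               "positive")
  expect_error(synthetic_config(baseline_hazard = -1), "positive")
})

test_that("null hazards leave strata exchangeable", {
  cfg <- synthetic_config(seed = 3, hazard_beta = 0, baseline_hazard = 0.01,
                          death_baseline_hazard = 0)
  d <- tibble::tibble(patient_id = sprintf("P%03d", 1:200),
                      score = rep(c(1, 16), each = 100))
  out <- generate_survival(d, score, cfg, seed = 9)
  out$stratum <- rep(c("low", "high"), each = 100)
  lr <- logrank_test(out, relapse_time, relapse_event, stratum)
  expect_gt(lr$p_value, 0.05)
})

test_that("longitudinal patterns have the designed latent shapes", {
  cfg <- small_config(seed = 21)
  resp <- generate_longitudinal(cfg, "responder", n_timepoints = 5,
                                n_patients = 2, noise_sd = 0)
  lat <- resp$truth |>
    dplyr::filter(patient_id == "L001", mirna == "miR-21") |>
    dplyr::arrange(timepoint_months)
  expect_true(all(diff(lat$log2_abundance) < 0))

  refr <- generate_longitudinal(cfg, "refractory", n_timepoints = 5,
                                n_patients = 1, noise_sd = 0)
  lat <- refr$truth |>
    dplyr::filter(mirna == "miR-21") |>
    dplyr::arrange(timepoint_months)
  expect_true(all(diff(lat$log2_abundance) > 0))

  pre <- generate_longitudinal(cfg, "pre_relapse", n_timepoints = 13,
                               n_patients = 1, noise_sd = 0,
                               onset_lead = 3, relapse_month = 12)
  lat <- pre$truth |>
    dplyr::filter(mirna == "miR-21") |>
    dplyr::arrange(timepoint_months)
  # flat at baseline through month 9 (= 12 - 3), rising strictly after
  expect_true(all(lat$log2_abundance[lat$timepoint_months <= 9] == 1))
  expect_true(all(diff(lat$log2_abundance[lat$timepoint_months >= 9]) > 0))
  expect_equal(unique(pre$metadata$relapse_time), 12)

  expect_error(generate_longitudinal(cfg, "mystery", 5), "pattern")
  expect_error(generate_longitudinal(cfg, "responder", 2), "n_timepoints")
  expect_error(
    generate_longitudinal(cfg, "pre_relapse", 5, onset_lead = 15,
                          relapse_month = 12),
    "onset_lead"
  )
})

test_that("the monitoring flag detects refractory trajectories reliably", {
  m <- oncomir_presets("DLBCL-CSF")
  fired <- sapply(1:100, function(s) {
    cfg <- small_config(seed = s)
    traj <- generate_longitudinal(cfg, "refractory", n_timepoints = 6,
                                  n_patients = 1, noise_sd = 0.1)
    series <- traj$truth |>
      dplyr::filter(mirna %in% m$panel) |>
      tidyr::pivot_wider(id_cols = timepoint_months, names_from = mirna,
                         values_from = abundance) |>
      dplyr::arrange(timepoint_months)
    scored <- compute_index(series, m)
    flag_rising_trajectory(scored, timepoint_months, index)$alert
  })
  expect_gte(mean(fired), 0.95)
})

test_that("null abundance model yields approximately uniform test p-values", {
  # Mann-Whitney on two groups drawn from one log-normal population
  set.seed(202)
  pvals <- replicate(500, {
    d <- tibble::tibble(v = 2^rnorm(40), g = rep(c("a", "b"), each = 20))
    mann_whitney_u(d, v, g)$p_value
  })
  ks <- max(abs(sort(pvals) - seq_along(pvals) / length(pvals)))
  expect_lt(ks, 0.1)
})
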