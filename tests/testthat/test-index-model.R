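PRESET_SUMS <- c(
  "DLBCL-CSF" = 4.92, "MCL-CSF" = 5.33, "BL-CSF" = 3.32,
  "B-NHL-NOS-CSF" = 2.74, "DLBCL-plasma" = 7.46, "MCL-plasma" = 3.82,
  "BL-plasma" = 2.30, "B-NHL-NOS-plasma" = 6.30
)

test_that("all eight presets load with consistent thresholds", {
  presets <- oncomir_presets()
  expect_length(presets, 8)
  for (m in presets) {
    expect_s3_class(m, "index_model")
    expect_true(all(m$coefficients > 0))
    expect_lt(abs(log2(m$threshold_raw) - m$threshold_log2), 0.005)
    expect_true(is.na(m$intercept)) # published forms carry no intercept X
  }
  perf <- oncomir_preset_performance()
  expect_equal(nrow(perf), 8)
  expect_equal(perf$youden, youden_index(perf$sensitivity, perf$specificity))
  expect_error(oncomir_presets("nope"), "Unknown preset")
})

test_that("compute_index is the weighted abundance sum", {
  unit <- tibble::tibble(`miR-21` = 1, `miR-19a` = 1, `miR-20a` = 1,
                         `miR-92a` = 1, `miR-155` = 1)
  for (nm in names(PRESET_SUMS)) {
    got <- compute_index(unit, oncomir_presets(nm))$index
    expect_equal(got, unname(PRESET_SUMS[nm]), tolerance = 1e-12)
  }

  zero <- tibble::tibble(`miR-21` = 0, `miR-20a` = 0, `miR-155` = 0)
  expect_equal(compute_index(zero, oncomir_presets("DLBCL-CSF"))$index, 0)

  bl <- tibble::tibble(`miR-21` = 2, `miR-155` = 1)
  expect_equal(compute_index(bl, oncomir_presets("BL-CSF"))$index, 4.89)

  # linear in each abundance
  m <- oncomir_presets("BL-CSF")
  d1 <- tibble::tibble(`miR-21` = 3, `miR-155` = 2)
  d2 <- tibble::tibble(`miR-21` = 4, `miR-155` = 2)
  expect_equal(compute_index(d2, m)$index - compute_index(d1, m)$index, 1.57)

  expect_error(compute_index(tibble::tibble(`miR-21` = 1), m), "miR-155")
  expect_error(
    compute_index(tibble::tibble(`miR-21` = 1, `miR-155` = NA), m),
    "does not impute"
  )
})

test_that("index_model validates coefficients and drops zero-weight miRNAs", {
  m <- index_model(c("miR-21" = 1.5, "miR-155" = 0))
  expect_equal(m$panel, "miR-21")
  expect_error(index_model(c("miR-21" = -1)), "non-negative")
  expect_error(index_model(c("miR-21" = 0)), "empty panel")
  expect_error(index_model(c("miR-21" = 1), threshold_raw = 8,
                           threshold_log2 = 3.2), "inconsistent")
  expect_equal(tidy(m)$coefficient, 1.5)
  expect_equal(glance(m)$n_mirnas, 1)
})

test_that("cns_probability is the logistic link with midpoint at X", {
  m <- index_model(c("miR-21" = 1), intercept = 2)
  expect_equal(cns_probability(tibble::tibble(`miR-21` = 2), m)$cns_probability,
               0.5)
  m0 <- index_model(c("miR-21" = 1), intercept = 0)
  expect_equal(
    cns_probability(tibble::tibble(`miR-21` = log(3)), m0)$cns_probability,
    0.75
  )
  # strictly increasing in the score, saturating toward 1
  d <- tibble::tibble(`miR-21` = c(0.1, 1, 5, 20, 100))
  p <- cns_probability(d, m0)$cns_probability
  expect_true(all(diff(p) > 0))
  expect_gt(p[5], 1 - 1e-8)
  # presets require an explicit intercept
  expect_error(
    cns_probability(tibble::tibble(`miR-21` = 1, `miR-155` = 1),
                    oncomir_presets("BL-CSF")),
    "intercept"
  )
  expect_equal(
    cns_probability(tibble::tibble(`miR-21` = 1, `miR-155` = 1),
                    oncomir_presets("BL-CSF"), intercept = 3.32)$cns_probability,
    0.5
  )
})

test_that("classification is >= threshold and agrees between raw and log2 scales", {
  m <- index_model(c("miR-21" = 1), threshold_raw = 2)
  calls <- classify_samples(tibble::tibble(`miR-21` = c(1.999, 2, 2.001)), m)
  expect_equal(calls$cns_positive, c(FALSE, TRUE, TRUE)) # boundary is positive

  dl <- oncomir_presets("DLBCL-CSF")
  d <- tibble::tibble(`miR-21` = c(10, 0.1), `miR-20a` = c(0, 0.1),
                      `miR-155` = c(0, 0.1))
  calls <- classify_samples(d, dl)
  expect_equal(calls$cns_positive, c(TRUE, FALSE))
  # raw and log2 decisions agree around the threshold
  scores <- c(8.40, 8.42, 8.45, 2, 40)
  raw_call <- scores >= dl$threshold_raw
  log2_call <- log2(scores) >= log2(dl$threshold_raw)
  expect_equal(raw_call, log2_call)

  expect_error(classify_samples(d, index_model(c("miR-21" = 1))),
               "threshold")
})

test_that("probability and score yield identical ROC curves", {
  set.seed(6)
  d <- tibble::tibble(
    `miR-21` = 2^rnorm(60, rep(c(0, 1.5), each = 30)),
    `miR-155` = 2^rnorm(60),
    y = rep(c(0, 1), each = 30)
  )
  m <- index_model(c("miR-21" = 1.6, "miR-155" = 1.8), intercept = 4)
  scored <- cns_probability(d, m)
  a_score <- roc_auc(scored, index, y)
  a_prob <- roc_auc(scored, cns_probability, y)
  expect_equal(a_score, a_prob, tolerance = 1e-12)
})

test_that("rising-trajectory monitoring implements the k-rise fold rule", {
  flat <- tibble::tibble(t = 0:3, s = c(4, 4, 4, 4))
  expect_false(flag_rising_trajectory(flat, t, s)$alert)

  rise <- tibble::tibble(t = 0:2, s = c(2, 3, 5))
  res <- flag_rising_trajectory(rise, t, s)
  expect_true(res$alert)
  expect_equal(res$onset_time, 0)
  expect_equal(res$max_fold, 2.5)

  sawtooth <- tibble::tibble(t = 0:3, s = c(2, 3, 2, 3))
  expect_false(flag_rising_trajectory(sawtooth, t, s)$alert)

  # two consecutive rises but insufficient total fold
  shallow <- tibble::tibble(t = 0:2, s = c(2, 2.2, 2.4))
  expect_false(flag_rising_trajectory(shallow, t, s)$alert)

  # brute-force check of onset: first qualifying run start
  late <- tibble::tibble(t = 0:4, s = c(5, 4, 2, 3.1, 5))
  res <- flag_rising_trajectory(late, t, s)
  expect_true(res$alert)
  expect_equal(res$onset_time, 2)

  expect_error(flag_rising_trajectory(tibble::tibble(t = c(1, 0, 2), s = 1:3),
                                      t, s), "increasing")
  expect_error(flag_rising_trajectory(rise[1:2, ], t, s), "timepoints")
})
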