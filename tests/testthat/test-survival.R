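test_that("Kaplan-Meier matches the hand product-limit computation", {
  toy <- tibble::tibble(t = c(1, 2, 3), e = c(1, 0, 1))
  km <- tidy(km_curve(toy, t, e))
  expect_equal(km$estimate[km$time == 1], 2 / 3)
  expect_equal(km$estimate[km$time == 3], 0)

  none <- tibble::tibble(t = c(5, 8, 12), e = 0)
  expect_true(all(tidy(km_curve(none, t, e))$estimate == 1))

  # no censoring: KM equals the empirical survivor function
  set.seed(4)
  d <- tibble::tibble(t = rexp(50), e = 1)
  km <- tidy(km_curve(d, t, e))
  ecdf_surv <- sapply(km$time, function(x) mean(d$t > x))
  expect_equal(km$estimate, ecdf_surv, tolerance = 1e-12)

  expect_error(km_curve(tibble::tibble(t = c(-1, 2), e = 1), t, e),
               "non-negative")
})

test_that("cumulative incidence uses the last step at or before the horizon", {
  toy <- tibble::tibble(t = c(1, 2, 3), e = c(1, 0, 1))
  res <- cumulative_incidence_at(toy, t, e, horizon = 2)
  expect_equal(res$incidence_pct, 100 / 3, tolerance = 1e-12)
  expect_false(res$extrapolated)

  none <- tibble::tibble(t = c(5, 8), e = 0)
  expect_equal(cumulative_incidence_at(none, t, e, horizon = 6)$incidence_pct, 0)

  res <- cumulative_incidence_at(toy, t, e, horizon = 10)
  expect_true(res$extrapolated)

  # closed-form recovery: exponential hazard, no censoring
  set.seed(10)
  lam <- 0.02
  d <- tibble::tibble(t = rexp(4000, lam), e = 1)
  res <- cumulative_incidence_at(d, t, e, horizon = 48)
  expect_equal(res$incidence_pct, 100 * (1 - exp(-lam * 48)), tolerance = 0.03)
})

test_that("Aalen-Johansen option accounts for competing deaths", {
  set.seed(12)
  n <- 3000
  d <- tibble::tibble(
    t_rel = rexp(n, 0.02), t_death = rexp(n, 0.02)
  ) |>
    dplyr::mutate(t = pmin(t_rel, t_death), rel = as.integer(t_rel <= t_death),
                  death = as.integer(t_death < t_rel))
  aj <- cumulative_incidence_at(d, t, rel, horizon = 48,
                                method = "aalen-johansen", competing = death)
  # true cause-specific cumulative incidence:
  # (lam1/(lam1+lam2)) * (1 - exp(-(lam1+lam2) t)) = 0.5 * (1 - e^-1.92)
  truth <- 100 * 0.5 * (1 - exp(-0.04 * 48))
  expect_equal(aj$incidence_pct, truth, tolerance = 0.05)
  # 1 - KM overestimates the incidence under competing deaths
  km <- cumulative_incidence_at(d, t, rel, horizon = 48)
  expect_gt(km$incidence_pct, aj$incidence_pct)
  expect_error(cumulative_incidence_at(d, t, rel, horizon = 48,
                                       method = "aalen-johansen"),
               "competing")
})

test_that("log-rank matches the hand observed-minus-expected table", {
  d <- tibble::tibble(t = c(1, 2, 3, 4), e = 1, g = c("A", "A", "B", "B"))
  res <- logrank_test(d, t, e, g)
  expect_equal(res$statistic, 49 / 17, tolerance = 1e-9) # hand O-E arithmetic
  expect_equal(res$df, 1)

  dup <- tibble::tibble(t = rep(c(1, 3, 7), 2), e = rep(c(1, 0, 1), 2),
                        g = rep(c("A", "B"), each = 3))
  res <- logrank_test(dup, t, e, g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  quiet <- tibble::tibble(t = c(1, 2, 3, 4), e = 0, g = c("A", "A", "B", "B"))
  res <- logrank_test(quiet, t, e, g)
  expect_true(res$no_events)
  expect_equal(res$p_value, 1)
})

test_that("log-rank chi-squared equals the Cox score test on tie-free data", {
  set.seed(9)
  d <- tibble::tibble(t = rexp(40) * rep(c(1, 0.4), each = 20), e = 1,
                      g = rep(c("A", "B"), each = 20))
  lr <- logrank_test(d, t, e, g)
  cf <- survival::coxph(survival::Surv(t, e) ~ g, data = d)
  expect_equal(lr$statistic, unname(summary(cf)$sctest[1]), tolerance = 1e-9)
})

test_that("Cox fit matches a hand-enumerated partial likelihood", {
  d <- tibble::tibble(t = c(1, 2, 3), e = c(1, 1, 0), x = c(1, 0, 1))
  fit <- cox_univariate(d, t, e, x)
  # risk sets: at t=1 {1,2,3}; at t=2 {2,3} ->
  # L(b) = e^b/(2 e^b + 1) * 1/(1 + e^b), maximised numerically
  oracle <- optimize(function(b) log(exp(b) / (2 * exp(b) + 1)) - log(1 + exp(b)),
                     c(-10, 10), maximum = TRUE)$maximum
  expect_equal(fit$estimate, oracle, tolerance = 1e-4)
  expect_equal(fit$hazard_ratio, exp(fit$estimate))
  expect_equal(fit$n_events, 2)

  expect_error(cox_univariate(tibble::tibble(t = 1:3, e = 1, x = 1), t, e, x),
               "no variation")
  expect_error(cox_univariate(tibble::tibble(t = 1:3, e = 0, x = c(1, 0, 1)),
                              t, e, x), "at least one event")
})

test_that("monotone likelihood is flagged with an unbounded interval", {
  d <- tibble::tibble(t = c(1, 2, 3, 4, 10, 10, 10, 10),
                      e = c(1, 1, 1, 1, 0, 0, 0, 0),
                      x = c(1, 1, 1, 1, 0, 0, 0, 0))
  fit <- cox_univariate(d, t, e, x)
  expect_true(fit$monotone_likelihood)
  expect_equal(fit$conf_high, Inf)
})

test_that("index stratification reproduces classify() and reports sizes", {
  d <- tibble::tibble(patient_id = 1:4, score = c(1, 2, 3, 4))
  res <- stratify_by_index(d, score, cutoff = 2.5)
  expect_equal(res$oncomir_level, c("low", "low", "high", "high"))
  sizes <- attr(res, "stratum_sizes")
  expect_equal(sizes$pct, c(50, 50))

  low <- stratify_by_index(d, score, cutoff = 10)
  expect_equal(attr(low, "stratum_sizes")$n, c(0L, 4L))

  expect_message(
    stratify_by_index(tibble::tibble(score = c(1, NA)), score, 0.5),
    "missing scores"
  )

  # boundary agreement with classify_samples on identical data
  m <- index_model(c("miR-21" = 1), threshold_raw = 2.5)
  dm <- tibble::tibble(`miR-21` = c(1, 2.5, 3))
  calls <- classify_samples(dm, m)
  strat <- stratify_by_index(dplyr::mutate(dm, score = `miR-21`), score, 2.5)
  expect_equal(strat$oncomir_level == "high", calls$cns_positive)
})

test_that("combined risk strata implement the two-factor rule and partition", {
  d <- tibble::tibble(
    om = c("high", "low", "high", "low", NA),
    ipi = c("high", "low", "low", "high", "high")
  )
  expect_message(res <- combined_risk_strata(d, om, ipi), "missing")
  expect_equal(as.character(res$combined_risk),
               c("both risks", "no risk", "one risk", "one risk"))
  expect_equal(nrow(res), 4)
  expect_equal(sum(table(res$combined_risk)), 4)
})

test_that("risk_table reports per-stratum incidence and HR vs reference", {
  set.seed(33)
  n <- 300
  d <- tibble::tibble(
    g = rep(c("low", "high"), each = n / 2),
    t = pmin(rexp(n, rate = rep(c(0.004, 0.016), each = n / 2)), 60),
    e = as.integer(rexp(n, rate = rep(c(0.004, 0.016), each = n / 2)) < 60)
  )
  # regenerate consistently: event time then administrative censoring
  tt <- rexp(n, rate = rep(c(0.004, 0.016), each = n / 2))
  d$t <- pmin(tt, 60)
  d$e <- as.integer(tt <= 60)
  rt <- risk_table(d, t, e, g, horizon = 48, reference = "low")
  expect_equal(rt$stratum, c("high", "low"))
  expect_equal(sum(rt$pct), 100)
  expect_gt(rt$incidence_pct[1], rt$incidence_pct[2])
  expect_gt(rt$hazard_ratio[1], 1.5)
  expect_true(is.na(rt$hazard_ratio[2]))
})
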