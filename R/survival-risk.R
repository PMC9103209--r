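#' Kaplan-Meier survival curves, optionally stratified
#'
#' Product-limit estimator of the survival function for right-censored
#' time-to-event data (time to CNS relapse, or overall survival), computed
#' with [survival::survfit()]. S(0) = 1 and the curve steps down at event
#' times only; censored subjects leave the risk set at their censoring time.
#'
#' @param data One row per patient.
#' @param time Column (unquoted) of non-negative follow-up times (months).
#' @param event Column (unquoted) of event indicators (1/TRUE = event,
#'   0/FALSE = censored).
#' @param strata Optional stratification column (unquoted).
#' @return An object of class `oncomir_km` wrapping the `survfit` fit, with
#'   `tidy()` (step-function points and risk table) and `autoplot()` methods.
#' @examples
#' d <- tibble::tibble(t = c(1, 2, 3), e = c(1, 0, 1))
#' tidy(km_curve(d, t, e))
#' @export
km_curve <- function(data, time, event, strata = NULL) {
  assert_data_frame(data)
  t <- eval_tidy(enquo(time), data)
  e <- as.integer(eval_tidy(enquo(event), data))
  check_surv_inputs(t, e)
  sq <- enquo(strata)
  if (rlang::quo_is_null(sq)) {
    df <- data.frame(t = t, e = e)
    fit <- survival::survfit(survival::Surv(t, e) ~ 1, data = df)
    strata_labels <- NULL
  } else {
    s <- as.character(eval_tidy(sq, data))
    df <- data.frame(t = t, e = e, s = s)
    fit <- survival::survfit(survival::Surv(t, e) ~ s, data = df)
    strata_labels <- sub("^s=", "", names(fit$strata))
  }
  structure(list(fit = fit, strata_labels = strata_labels, n = length(t)),
            class = "oncomir_km")
}

check_surv_inputs <- function(t, e) {
  if (any(is.na(t)) || any(t < 0)) {
    abort("Follow-up times must be non-negative and non-missing.")
  }
  if (!all(e %in% c(0L, 1L))) abort("`event` must be 0/1 (or FALSE/TRUE).")
}

#' @rdname km_curve
#' @param x,object An `oncomir_km` object.
#' @param ... Unused.
#' @export
tidy.oncomir_km <- function(x, ...) {
  f <- x$fit
  k <- length(f$time)
  stratum <- if (is.null(x$strata_labels)) {
    rep("all", k)
  } else {
    rep(x$strata_labels, f$strata)
  }
  tibble(
    stratum = stratum, time = f$time, n_risk = f$n.risk,
    n_event = f$n.event, n_censor = f$n.censor, estimate = f$surv
  )
}

#' @export
print.oncomir_km <- function(x, ...) {
  cat(sprintf("<oncomir_km> Kaplan-Meier fit, n = %d%s\n", x$n,
              if (is.null(x$strata_labels)) "" else
                sprintf(", strata: %s", paste(x$strata_labels, collapse = ", "))))
  invisible(x)
}

#' @rdname km_curve
#' @export
autoplot.oncomir_km <- function(object, ...) {
  d <- tidy(object)
  d0 <- d |>
    dplyr::distinct(.data$stratum) |>
    dplyr::mutate(time = 0, estimate = 1)
  d <- dplyr::bind_rows(d0, d[c("stratum", "time", "estimate")]) |>
    dplyr::arrange(.data$stratum, .data$time)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$estimate,
                                  colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL)
}

#' Cumulative incidence at a horizon
#'
#' 1 - S(horizon) in percent from the Kaplan-Meier estimator, using the last
#' step at or before the horizon (per stratum when stratified). By default
#' this matches the common clinical presentation of "4-year cumulative
#' relapse risk" (1 - KM), which treats death as censoring; set
#' `method = "aalen-johansen"` and supply a `competing` event column for the
#' competing-risk estimator as a sensitivity analysis.
#'
#' @inheritParams km_curve
#' @param horizon Months from start-point (e.g. 48 for 4 years).
#' @param method `"km"` (default, 1 - KM) or `"aalen-johansen"`.
#' @param competing Column (unquoted) with a competing-event indicator
#'   (e.g. death without CNS relapse); required for `"aalen-johansen"`.
#' @return A tibble per stratum: `stratum`, `horizon`, `incidence_pct`,
#'   `extrapolated` (TRUE when the horizon exceeds the last follow-up in the
#'   stratum, so the estimate carries the last step forward).
#' @export
cumulative_incidence_at <- function(data, time, event, horizon,
                                    strata = NULL, method = c("km", "aalen-johansen"),
                                    competing = NULL) {
  method <- match.arg(method)
  assert_number(horizon, "horizon", min = 0)
  t <- eval_tidy(enquo(time), data)
  e <- as.integer(eval_tidy(enquo(event), data))
  check_surv_inputs(t, e)
  sq <- enquo(strata)
  s <- if (rlang::quo_is_null(sq)) rep("all", length(t))
       else as.character(eval_tidy(sq, data))

  if (method == "km") {
    km <- km_curve(data, {{ time }}, {{ event }}, strata = {{ strata }})
    pts <- tidy(km)
    res <- purrr::map_dfr(split(pts, pts$stratum), function(d) {
      before <- d$estimate[d$time <= horizon]
      surv <- if (length(before) == 0) 1 else tail(before, 1)
      tibble(stratum = d$stratum[1], horizon = horizon,
             incidence_pct = 100 * (1 - surv),
             extrapolated = horizon > max(d$time))
    })
    return(res)
  }

  cq <- enquo(competing)
  if (rlang::quo_is_null(cq)) {
    abort("`competing` event column is required for the Aalen-Johansen estimator.")
  }
  cmp <- as.integer(eval_tidy(cq, data))
  if (any(cmp == 1 & e == 1)) {
    abort("A record cannot have both the event of interest and the competing event.")
  }
  state <- factor(dplyr::case_when(e == 1 ~ "event", cmp == 1 ~ "competing",
                                   TRUE ~ "censor"),
                  levels = c("censor", "event", "competing"))
  purrr::map_dfr(split(seq_along(t), s), function(i) {
    fit <- survival::survfit(survival::Surv(t[i], state[i]) ~ 1)
    j <- match("event", fit$states)
    ci <- fit$pstate[, j]
    before <- ci[fit$time <= horizon]
    val <- if (length(before) == 0) 0 else tail(before, 1)
    tibble(stratum = s[i][1], horizon = horizon,
           incidence_pct = 100 * val, extrapolated = horizon > max(fit$time))
  })
}

#' Log-rank (Mantel-Cox) test between strata
#'
#' Observed-minus-expected chi-squared statistic over the pooled event
#' times (via [survival::survdiff()]), with k - 1 degrees of freedom. When
#' no events occurred at all the comparison is vacuous: chi-squared 0,
#' p = 1, flagged.
#'
#' @inheritParams km_curve
#' @param strata Stratification column (unquoted), at least two levels.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `no_events`.
#' @export
logrank_test <- function(data, time, event, strata) {
  assert_data_frame(data)
  t <- eval_tidy(enquo(time), data)
  e <- as.integer(eval_tidy(enquo(event), data))
  s <- as.character(eval_tidy(enquo(strata), data))
  check_surv_inputs(t, e)
  if (length(unique(s)) < 2) abort("Need at least two strata.")
  if (sum(e) == 0) {
    return(tibble(statistic = 0, df = length(unique(s)) - 1,
                  p_value = 1, no_events = TRUE))
  }
  df0 <- data.frame(t = t, e = e, s = s)
  fit <- survival::survdiff(survival::Surv(t, e) ~ s, data = df0)
  df_ <- length(fit$n) - 1
  tibble(statistic = unname(fit$chisq), df = df_,
         p_value = pchisq(fit$chisq, df_, lower.tail = FALSE),
         no_events = FALSE)
}

#' Univariate Cox proportional-hazards model
#'
#' Partial-likelihood fit ([survival::coxph()], Efron tie handling) of a
#' single covariate (continuous score or stratum indicator). Returns the
#' hazard ratio exp(beta) with a 95\% Wald confidence interval from the
#' observed information, and a p-value from the log-likelihood ratio test
#' against the null model. Monotone likelihood (complete separation of the
#' event order) is flagged and the CI reported as unbounded.
#'
#' @inheritParams km_curve
#' @param covariate Column (unquoted): numeric, or a factor / character
#'   stratum indicator. Characters are factorized alphabetically, so the
#'   first label is the reference; pass a factor to control the reference
#'   level.
#' @return One-row tibble: `term`, `estimate` (log hazard ratio),
#'   `hazard_ratio`, `conf_low`, `conf_high`, `p_value` (LRT), `n`,
#'   `n_events`, `monotone_likelihood`.
#' @export
cox_univariate <- function(data, time, event, covariate) {
  assert_data_frame(data)
  t <- eval_tidy(enquo(time), data)
  e <- as.integer(eval_tidy(enquo(event), data))
  x <- eval_tidy(enquo(covariate), data)
  term <- rlang::as_label(enquo(covariate))
  check_surv_inputs(t, e)
  if (sum(e) < 1) abort("Need at least one event.")
  if (length(unique(x[!is.na(x)])) < 2) {
    abort(sprintf("Covariate `%s` has no variation.", term))
  }
  if (is.character(x)) x <- factor(x)
  df0 <- data.frame(t = t, e = e, x = x)
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(t, e) ~ x, data = df0, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(diag(fit$var))[1]
  lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
  ci <- beta + c(-1, 1) * qnorm(0.975) * se
  if (monotone) ci <- c(-Inf, Inf) * sign(beta)
  tibble(
    term = term, estimate = beta, hazard_ratio = exp(beta),
    conf_low = if (monotone) 0 else exp(ci[1]),
    conf_high = if (monotone) Inf else exp(ci[2]),
    p_value = pchisq(lrt, 1, lower.tail = FALSE),
    n = fit$n, n_events = fit$nevent, monotone_likelihood = monotone
  )
}

#' Stratify patients into oncomiR high/low by an index cut-off
#'
#' Adds an `oncomir_level` column (`"high"` when the score is at or above
#' the cut-off, else `"low"`). Patients with missing scores are dropped with
#' a message reporting the count. The default cut-off of record, when tied
#' to the same data, reproduces [classify_samples()] calls exactly.
#'
#' @param data One row per patient.
#' @param score Column (unquoted) of index scores at the stated timepoint.
#' @param cutoff Numeric threshold (e.g. the ROC closest-corner threshold).
#' @return `data` (rows with non-missing scores) with `oncomir_level` added;
#'   stratum sizes and fractions are attached as attribute
#'   `"stratum_sizes"`.
#' @export
stratify_by_index <- function(data, score, cutoff) {
  assert_data_frame(data)
  assert_number(cutoff, "cutoff")
  s <- eval_tidy(enquo(score), data)
  if (!is.numeric(s)) abort("`score` must be numeric.")
  dropped <- sum(is.na(s))
  if (dropped > 0) {
    rlang::inform(sprintf("Dropping %d patient(s) with missing scores.", dropped))
  }
  out <- as_tibble(data)[!is.na(s), , drop = FALSE]
  out$oncomir_level <- ifelse(s[!is.na(s)] >= cutoff, "high", "low")
  sizes <- table(factor(out$oncomir_level, levels = c("high", "low")))
  attr(out, "stratum_sizes") <- tibble(
    oncomir_level = names(sizes), n = as.integer(sizes),
    pct = 100 * as.integer(sizes) / nrow(out)
  )
  out
}

#' Combined oncomiR + CNS-IPI risk strata
#'
#' Collapses the two dichotomized risk factors into the three-level combined
#' model: `"both risks"` when both the oncomiR level and the CNS-IPI are
#' high, `"one risk"` when exactly one is, `"no risk"` when neither is.
#' Rows with a missing label are dropped with a message.
#'
#' @param data One row per patient.
#' @param oncomir_level Column (unquoted): `"high"`/`"low"`.
#' @param cnsipi_level Column (unquoted): `"high"` vs anything else
#'   (low/intermediate collapse to not-high).
#' @return `data` (labelled rows) with a `combined_risk` factor added
#'   (levels: no risk, one risk, both risks).
#' @export
combined_risk_strata <- function(data, oncomir_level, cnsipi_level) {
  assert_data_frame(data)
  om <- as.character(eval_tidy(enquo(oncomir_level), data))
  ip <- as.character(eval_tidy(enquo(cnsipi_level), data))
  keep <- !is.na(om) & !is.na(ip)
  if (any(!keep)) {
    rlang::inform(sprintf("Dropping %d patient(s) with missing risk labels.",
                          sum(!keep)))
  }
  out <- as_tibble(data)[keep, , drop = FALSE]
  n_high <- (om[keep] == "high") + (ip[keep] == "high")
  out$combined_risk <- factor(
    c("no risk", "one risk", "both risks")[n_high + 1],
    levels = c("no risk", "one risk", "both risks")
  )
  out
}

#' Per-stratum risk table for a stratification
#'
#' Summarises a stratified cohort the way risk-model figures tabulate it:
#' per-stratum n and percentage of the cohort, cumulative incidence at the
#' horizon, and the univariate Cox hazard ratio of each stratum against the
#' reference stratum.
#'
#' @inheritParams km_curve
#' @param strata Stratification column (unquoted).
#' @param horizon Months for the cumulative-incidence column (default 48,
#'   i.e. 4 years).
#' @param reference Reference stratum label for hazard ratios; defaults to
#'   the first level alphabetically.
#' @return A tibble with one row per stratum: `stratum`, `n`, `pct`,
#'   `incidence_pct`, `hazard_ratio`, `conf_low`, `conf_high`, `p_value`
#'   (HR columns are `NA` for the reference stratum, and for degenerate
#'   comparisons without events).
#' @export
risk_table <- function(data, time, event, strata, horizon = 48,
                       reference = NULL) {
  assert_data_frame(data)
  s <- as.character(eval_tidy(enquo(strata), data))
  levs <- sort(unique(s))
  reference <- reference %||% levs[1]
  if (!reference %in% levs) abort("`reference` is not a stratum label.")
  ci <- cumulative_incidence_at(data, {{ time }}, {{ event }},
                                horizon = horizon, strata = {{ strata }})
  t <- eval_tidy(enquo(time), data)
  e <- as.integer(eval_tidy(enquo(event), data))
  purrr::map_dfr(levs, function(lv) {
    row <- tibble(
      stratum = lv, n = sum(s == lv), pct = 100 * sum(s == lv) / length(s),
      incidence_pct = ci$incidence_pct[match(lv, ci$stratum)],
      hazard_ratio = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
      p_value = NA_real_
    )
    if (lv != reference) {
      sub <- tibble(t = t, e = e,
                    s = factor(s, levels = c(reference, lv))) |>
        dplyr::filter(!is.na(.data$s))
      fit <- tryCatch(
        cox_univariate(sub, t, e, s),
        error = function(err) NULL
      )
      if (!is.null(fit)) {
        row$hazard_ratio <- fit$hazard_ratio
        row$conf_low <- fit$conf_low
        row$conf_high <- fit$conf_high
        row$p_value <- fit$p_value
      }
    }
    row
  })
}
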