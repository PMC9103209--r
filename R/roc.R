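#' Youden index from sensitivity and specificity percentages
#'
#' The Youden index summarises a binary classifier at one operating point as
#' sensitivity\% + specificity\% - 100, ranging from -100 (always wrong) over
#' 0 (chance) to 100 (perfect).
#'
#' @param sensitivity,specificity Numeric vectors of percentages in
#'   \[0, 100\]. Recycled against each other.
#' @return Numeric vector of Youden indices in \[-100, 100\].
#' @examples
#' youden_index(91.3, 90.4)
#' youden_index(c(100, 50), c(100, 50))
#' @export
youden_index <- function(sensitivity, specificity) {
  if (!is.numeric(sensitivity) || !is.numeric(specificity)) {
    abort("`sensitivity` and `specificity` must be numeric.")
  }
  bad <- function(x) any(!is.na(x) & (x < 0 | x > 100))
  if (bad(sensitivity) || bad(specificity)) {
    abort("`sensitivity` and `specificity` must be percentages in [0, 100].")
  }
  sensitivity + specificity - 100
}

#' Build a ROC curve for a score against a binary class label
#'
#' Candidate cut-offs are the midpoints between consecutive distinct observed
#' scores, plus -Inf/+Inf sentinels, so every decision-distinct threshold is
#' represented exactly once. A sample is called positive when its score is
#' greater than or equal to the cut-off. The AUC is computed as the
#' Mann-Whitney concordance probability (ties credited 0.5), which for this
#' construction coincides with trapezoidal integration of the curve.
#'
#' A closest-to-corner operating point (see [select_threshold()]) is selected
#' automatically and stored on the returned object.
#'
#' @param data A data frame with one row per sample.
#' @param score Column (unquoted) holding the numeric score.
#' @param class Column (unquoted) holding the class label.
#' @param positive Value of `class` treated as the positive (diseased) class.
#'   Defaults to the larger of two unique labels, which errors unless the
#'   labels are unambiguous (`TRUE`/`FALSE` or 0/1).
#' @return An object of class `oncomir_roc`: a list with `points` (tibble of
#'   cut-offs with sensitivity/specificity in percent), `auc`, `n_pos`,
#'   `n_neg`, and the selected `threshold`, `sensitivity`, `specificity`,
#'   `youden`.
#' @seealso [select_threshold()], [roc_auc()]
#' @examples
#' d <- tibble::tibble(score = c(1, 2, 3, 4), cns = c(0, 0, 1, 1))
#' r <- roc_curve(d, score, cns, positive = 1)
#' r$auc
#' glance(r)
#' @export
roc_curve <- function(data, score, class, positive = NULL) {
  assert_data_frame(data)
  s <- eval_tidy(enquo(score), data)
  y <- eval_tidy(enquo(class), data)
  if (!is.numeric(s)) abort("`score` must be numeric.")
  keep <- !is.na(s) & !is.na(y)
  s <- s[keep]
  y <- y[keep]
  labels <- unique(y)
  if (is.null(positive)) {
    if (is.logical(y)) {
      positive <- TRUE
    } else if (setequal(labels, c(0, 1))) {
      positive <- 1
    } else {
      abort("`positive` must be supplied when class labels are not TRUE/FALSE or 0/1.")
    }
  }
  pos <- y == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC needs at least one positive and one negative sample.")
  }

  cuts <- roc_cutoffs(s)
  tp <- colSums(outer(s[pos], cuts, `>=`))
  fp <- colSums(outer(s[!pos], cuts, `>=`))
  pts <- tibble(
    cutoff = cuts, tp = tp, fp = fp, fn = n_pos - tp, tn = n_neg - fp,
    sensitivity = 100 * tp / n_pos, specificity = 100 * (n_neg - fp) / n_neg
  )
  pts$youden <- youden_index(pts$sensitivity, pts$specificity)

  auc <- auc_concordance(s[pos], s[!pos])

  out <- structure(
    list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg,
         positive = positive),
    class = "oncomir_roc"
  )
  sel <- select_threshold(out, method = "closest_corner")
  out$threshold <- sel$threshold
  out$sensitivity <- sel$sensitivity
  out$specificity <- sel$specificity
  out$youden <- sel$youden
  out
}

# Midpoints between consecutive distinct scores, with sentinels.
roc_cutoffs <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1) {
    c(-Inf, Inf)
  } else {
    c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  }
}

# AUC as P(pos > neg) + 0.5 P(pos == neg), via midranks (exact under ties).
auc_concordance <- function(pos_scores, neg_scores) {
  n_pos <- length(pos_scores)
  n_neg <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the ROC curve
#'
#' Computes the AUC directly from scores and labels as the Mann-Whitney
#' concordance probability, with ties counted 0.5.
#'
#' @inheritParams roc_curve
#' @return A single number in \[0, 1\].
#' @export
roc_auc <- function(data, score, class, positive = NULL) {
  roc_curve(data, {{ score }}, {{ class }}, positive = positive)$auc
}

#' Select an operating threshold on a ROC curve
#'
#' `"closest_corner"` minimises the squared distance of the operating point
#' to the ideal corner of the unit square, (1 - sensitivity)^2 +
#' (specificity - 1)^2 with sensitivity/specificity as fractions; this is in
#' most cases the same point as the highest Youden index, which is available
#' as `method = "youden"`. Ties are broken toward higher Youden index, then
#' higher specificity, then lower cut-off.
#'
#' @param roc An `oncomir_roc` object from [roc_curve()].
#' @param method `"closest_corner"` (default) or `"youden"`.
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`
#'   (percent), `youden`, and `distance2` (the squared corner distance).
#' @export
select_threshold <- function(roc, method = c("closest_corner", "youden")) {
  if (!inherits(roc, "oncomir_roc")) abort("`roc` must be an `oncomir_roc` object.")
  method <- match.arg(method)
  pts <- roc$points
  d2 <- (1 - pts$sensitivity / 100)^2 + (pts$specificity / 100 - 1)^2
  key <- if (method == "closest_corner") d2 else -pts$youden
  ord <- order(key, -pts$youden, -pts$specificity, pts$cutoff)
  i <- ord[1]
  tibble(
    threshold = pts$cutoff[i],
    sensitivity = pts$sensitivity[i],
    specificity = pts$specificity[i],
    youden = pts$youden[i],
    distance2 = d2[i]
  )
}

#' Sensitivity and specificity at an arbitrary cut-off
#'
#' Evaluates the `score >= cutoff` decision rule at a user-supplied cut-off
#' (for instance a published threshold) rather than a curve-derived one.
#'
#' @inheritParams roc_curve
#' @param cutoff Numeric cut-off on the score scale.
#' @return One-row tibble with `cutoff`, `sensitivity`, `specificity`,
#'   `youden` (percent scale).
#' @export
sens_spec_at <- function(data, score, class, cutoff, positive = NULL) {
  r <- roc_curve(data, {{ score }}, {{ class }}, positive = positive)
  s <- eval_tidy(enquo(score), data)
  y <- eval_tidy(enquo(class), data)
  keep <- !is.na(s) & !is.na(y)
  s <- s[keep]
  pos <- y[keep] == r$positive
  call_pos <- s >= cutoff
  sens <- 100 * sum(call_pos & pos) / sum(pos)
  spec <- 100 * sum(!call_pos & !pos) / sum(!pos)
  tibble(cutoff = cutoff, sensitivity = sens, specificity = spec,
         youden = youden_index(sens, spec))
}

#' @export
print.oncomir_roc <- function(x, ...) {
  cat(sprintf(
    "<oncomir_roc> %d positive / %d negative samples\n  AUC %.3f; threshold %.4g (sens %.1f%%, spec %.1f%%, Youden %.1f)\n",
    x$n_pos, x$n_neg, x$auc, x$threshold, x$sensitivity, x$specificity,
    x$youden
  ))
  invisible(x)
}

#' @rdname roc_curve
#' @param x An `oncomir_roc` object.
#' @param ... Unused.
#' @export
tidy.oncomir_roc <- function(x, ...) {
  x$points
}

#' @rdname roc_curve
#' @export
glance.oncomir_roc <- function(x, ...) {
  tibble(
    auc = x$auc, threshold = x$threshold,
    threshold_log2 = if (x$threshold > 0) log2(x$threshold) else NA_real_,
    sensitivity = x$sensitivity, specificity = x$specificity,
    youden = x$youden, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @rdname roc_curve
#' @param object An `oncomir_roc` object.
#' @export
autoplot.oncomir_roc <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = 100 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::annotate(
      "point",
      x = 100 - object$specificity, y = object$sensitivity,
      colour = "red", size = 2
    ) +
    ggplot2::labs(
      x = "100 - specificity (%)", y = "Sensitivity (%)",
      title = sprintf("ROC curve (AUC = %.2f)", object$auc)
    ) +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100))
}
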