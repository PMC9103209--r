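#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum U statistic with mid-ranks for ties. The two-sided p-value is
#' computed by exact enumeration of the permutation distribution of U when
#' both groups have at most `exact_max` observations (default 8), and by the
#' normal approximation with tie correction otherwise. If the pooled sample
#' is constant the test is degenerate: U = n_x n_y / 2, p = 1, flagged.
#'
#' The identity U / (n_x n_y) = AUC links this statistic to [roc_auc()] when
#' one group is scored against the other.
#'
#' @param data A data frame in long format.
#' @param value Column (unquoted) of numeric values.
#' @param group Column (unquoted) with exactly two group labels.
#' @param exact_max Largest per-group size for which the exact permutation
#'   p-value is used.
#' @return A one-row tibble: `group_x`, `group_y`, `n_x`, `n_y`,
#'   `statistic` (U for the first group), `p_value`, `method`, `degenerate`.
#' @examples
#' d <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' mann_whitney_u(d, v, g)
#' @export
mann_whitney_u <- function(data, value, group, exact_max = 8) {
  assert_data_frame(data)
  v <- eval_tidy(enquo(value), data)
  g <- eval_tidy(enquo(group), data)
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- as.character(g[keep])
  levels <- sort(unique(g))
  if (length(levels) != 2) {
    abort(sprintf("`group` must have exactly 2 levels, found %d.", length(levels)))
  }
  x <- v[g == levels[1]]
  y <- v[g == levels[2]]
  nx <- length(x)
  ny <- length(y)
  if (nx == 0 || ny == 0) abort("Both groups must be non-empty.")

  r <- rank(c(x, y), ties.method = "average")
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2

  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    return(tibble(group_x = levels[1], group_y = levels[2],
                  n_x = nx, n_y = ny, statistic = u, p_value = 1,
                  method = "degenerate", degenerate = TRUE))
  }

  if (nx <= exact_max && ny <= exact_max) {
    p <- mwu_exact_p(pooled, nx, u)
    method <- "exact"
  } else {
    n <- nx + ny
    ties <- table(pooled)
    correction <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - correction)
    z <- (u - nx * ny / 2) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  tibble(group_x = levels[1], group_y = levels[2], n_x = nx, n_y = ny,
         statistic = u, p_value = p, method = method, degenerate = FALSE)
}

# Exact two-sided p for U by full enumeration of group assignments
# (handles ties: the permutation distribution of U under mid-ranks).
mwu_exact_p <- function(pooled, nx, u_obs) {
  n <- length(pooled)
  r <- rank(pooled, ties.method = "average")
  idx <- combn(n, nx)
  us <- apply(idx, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
  centre <- nx * (n - nx) / 2
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

#' Kruskal-Wallis rank test across two or more groups
#'
#' Tie-corrected H statistic with a chi-squared reference distribution on
#' k - 1 degrees of freedom (via [stats::kruskal.test()]). An all-identical
#' sample returns H = 0, p = 1 with a degeneracy flag instead of `NaN`.
#'
#' @inheritParams mann_whitney_u
#' @return A one-row tibble: `n_groups`, `statistic` (H), `df`, `p_value`,
#'   `degenerate`.
#' @export
kruskal_wallis <- function(data, value, group) {
  assert_data_frame(data)
  v <- eval_tidy(enquo(value), data)
  g <- eval_tidy(enquo(group), data)
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- factor(as.character(g[keep]))
  if (nlevels(g) < 2) abort("Need at least 2 non-empty groups.")
  if (length(v) < 3) abort("Need a total of at least 3 observations.")
  if (length(unique(v)) == 1) {
    return(tibble(n_groups = nlevels(g), statistic = 0,
                  df = nlevels(g) - 1, p_value = 1, degenerate = TRUE))
  }
  kt <- stats::kruskal.test(v, g)
  tibble(n_groups = nlevels(g), statistic = unname(kt$statistic),
         df = unname(kt$parameter), p_value = kt$p.value, degenerate = FALSE)
}

#' Dunn's post hoc pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics from mean-rank differences on the pooled ranking,
#' with the tie-corrected pooled variance
#' (N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j). Two-sided p-values
#' are adjusted across all pairs by the chosen method (Bonferroni by
#' default, the usual companion of Dunn's test; also `"holm"` or `"none"`).
#'
#' @inheritParams mann_whitney_u
#' @param adjust Multiplicity adjustment: `"bonferroni"`, `"holm"`, `"none"`.
#' @return A tibble with one row per pair: `group_1`, `group_2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(data, value, group,
                         adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  assert_data_frame(data)
  v <- eval_tidy(enquo(value), data)
  g <- eval_tidy(enquo(group), data)
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- factor(as.character(g[keep]))
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  counts <- table(g)
  if (any(counts == 0)) abort("Every group must be non-empty.")
  n <- length(v)
  r <- rank(v, ties.method = "average")
  mean_ranks <- tapply(r, g, mean)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- combn(levels(g), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / counts[[a]] + 1 / counts[[b]]))
    z <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    tibble(group_1 = a, group_2 = b, z = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, method = adjust)
  res
}

#' Median with interquartile range per group
#'
#' Group summaries on the scale of the data: n, median, and Tukey-hinge
#' quartiles (the `fivenum` convention, matching common clinical-stats
#' software), so Q1 <= median <= Q3 always holds.
#'
#' @inheritParams mann_whitney_u
#' @param group Optional grouping column; omit for a single overall summary.
#' @return A tibble: (`group`,) `n`, `median`, `q1`, `q3`.
#' @examples
#' median_iqr(tibble::tibble(v = c(1, 2, 3, 4, 5)), v)
#' @export
median_iqr <- function(data, value, group = NULL) {
  assert_data_frame(data)
  v <- eval_tidy(enquo(value), data)
  gq <- enquo(group)
  summarise_one <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) abort("Need at least one non-missing value.")
    fn <- fivenum(x)
    tibble(n = length(x), median = fn[3], q1 = fn[2], q3 = fn[4])
  }
  if (rlang::quo_is_null(gq)) {
    return(summarise_one(v))
  }
  g <- eval_tidy(gq, data)
  purrr::map_dfr(split(v, g), summarise_one, .id = "group")
}

#' Significance stars for p-values
#'
#' Figure-caption convention: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
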