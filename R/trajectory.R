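#' Flag a rising oncomiR-index trajectory
#'
#' Longitudinal monitoring rule for serial index measurements of one patient:
#' an alert fires when `k` consecutive strictly increasing scores accumulate
#' a total fold-rise of at least `rel_increase` across the run (score at the
#' end of the run divided by score at its start). This operationalises the
#' observation that circulating oncomiR levels begin to climb one to four
#' months before clinical CNS relapse.
#'
#' @param data A data frame of one patient's serial measurements.
#' @param time Column (unquoted) of timestamps (months); must be strictly
#'   increasing.
#' @param score Column (unquoted) of index scores (positive).
#' @param k Number of consecutive strict rises required (default 2).
#' @param rel_increase Minimum total fold-rise over the run (default 1.5).
#' @return A one-row tibble: `alert` (logical), `onset_time` (time at the
#'   start of the first qualifying run, `NA` if no alert), `max_fold` (the
#'   largest fold-rise over any `k`-rise run, `NA` if none).
#' @examples
#' d <- tibble::tibble(t = 0:2, idx = c(2, 3, 5))
#' flag_rising_trajectory(d, t, idx)
#' @export
flag_rising_trajectory <- function(data, time, score, k = 2,
                                   rel_increase = 1.5) {
  assert_data_frame(data)
  t <- eval_tidy(enquo(time), data)
  s <- eval_tidy(enquo(score), data)
  if (any(is.na(t)) || any(is.na(s))) abort("Timestamps and scores must be non-missing.")
  if (is.unsorted(t, strictly = TRUE)) {
    abort("Timestamps must be strictly increasing; sort the series first.")
  }
  assert_number(k, "k", min = 1)
  assert_number(rel_increase, "rel_increase", min = 0)
  n <- length(s)
  if (n < k + 1) {
    abort(sprintf("Need at least k + 1 = %d timepoints.", k + 1))
  }
  rising <- diff(s) > 0
  onset <- NA_real_
  max_fold <- NA_real_
  for (i in seq_len(n - k)) {
    if (all(rising[i:(i + k - 1)])) {
      fold <- s[i + k] / s[i]
      if (is.na(max_fold) || fold > max_fold) max_fold <- fold
      if (fold >= rel_increase && is.na(onset)) onset <- t[i]
    }
  }
  tibble(alert = !is.na(onset), onset_time = onset, max_fold = max_fold)
}
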