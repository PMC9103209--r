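#' Average replicate Ct values per sample and assay
#'
#' qPCR measurements are run in duplicate; replicates are averaged on the Ct
#' (cycle) scale, where replicate noise is approximately Gaussian. Undetermined
#' Ct values (missing) are dropped from the mean and flagged, never imputed;
#' if every replicate is undetermined the averaged Ct is missing with a QC
#' flag rather than an error.
#'
#' @param data Long-format Ct records: columns `sample_id`, `assay`,
#'   `replicate`, `ct` (numeric cycles, `NA` = undetermined).
#' @param tolerance Maximum allowed replicate spread (max - min) in cycles
#'   before the pair is flagged discordant (default 1.0).
#' @return A tibble with one row per (sample, assay): `sample_id`, `assay`,
#'   `ct` (mean of non-missing replicates), `n_replicates`, `n_used`,
#'   `qc_discordant`, `qc_partial`, `qc_undetermined`.
#' @examples
#' d <- tibble::tibble(sample_id = "s1", assay = "miR-21",
#'                     replicate = 1:2, ct = c(24, 26))
#' average_duplicates(d)
#' @export
average_duplicates <- function(data, tolerance = 1.0) {
  assert_data_frame(data)
  assert_columns(data, c("sample_id", "assay", "replicate", "ct"))
  assert_number(tolerance, "tolerance", min = 0)
  if (any(data$replicate < 1, na.rm = TRUE)) {
    abort("`replicate` indices must be >= 1.")
  }
  data |>
    dplyr::group_by(.data$sample_id, .data$assay) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_used = sum(!is.na(.data$ct)),
      spread = if (sum(!is.na(.data$ct)) > 1) {
        max(.data$ct, na.rm = TRUE) - min(.data$ct, na.rm = TRUE)
      } else 0,
      ct = if (all(is.na(.data$ct))) NA_real_ else mean(.data$ct, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      qc_discordant = .data$n_used > 1 & .data$spread > tolerance,
      qc_partial = .data$n_used > 0 & .data$n_used < .data$n_replicates,
      qc_undetermined = .data$n_used == 0
    ) |>
    dplyr::select("sample_id", "assay", "ct", "n_replicates", "n_used",
                  "qc_discordant", "qc_partial", "qc_undetermined")
}

#' Relative expression by the 2^-dCt method
#'
#' Relative expression of a target miRNA against the endogenous reference
#' (miR-let-7a here): 2^-(Ct_target - Ct_reference). One cycle less than the
#' reference doubles the estimate; the result is strictly positive and
#' strictly decreasing in the target Ct. Missing inputs yield `NA`.
#'
#' @param ct_target,ct_reference Numeric Ct values in cycles (vectorised).
#' @return Numeric vector of relative expression values.
#' @examples
#' relative_expression(24, 25) # one cycle earlier = 2x the reference
#' @export
relative_expression <- function(ct_target, ct_reference) {
  ok <- function(x) is.numeric(x) || all(is.na(x))
  if (!ok(ct_target) || !ok(ct_reference)) {
    abort("Ct values must be numeric.")
  }
  2^(-(as.numeric(ct_target) - as.numeric(ct_reference)))
}

#' Spike-in recovery QC (cel-miR-39)
#'
#' The exogenous cel-miR-39 spike-in, added before RNA extraction, monitors
#' isolation and quantification efficiency. A sample fails when its spike-in
#' Ct deviates from the batch median by more than `max_deviation` cycles, or
#' when the spike-in is missing entirely. Failed samples are excluded from
#' equalization statistics downstream but retained with their flags.
#'
#' @param data One row per sample: columns `sample_id` and `spike_ct`
#'   (averaged cel-miR-39 Ct; `NA` = not detected).
#' @param max_deviation Allowed absolute deviation from the batch median in
#'   cycles (default 2.0).
#' @return A tibble: `sample_id`, `spike_ct`, `batch_median`, `deviation`,
#'   `spike_pass`, `spike_reason`.
#' @export
spike_in_qc <- function(data, max_deviation = 2.0) {
  assert_data_frame(data)
  assert_columns(data, c("sample_id", "spike_ct"))
  assert_number(max_deviation, "max_deviation", min = 0)
  if (nrow(data) < 3) {
    abort("Spike-in batch too small: need >= 3 samples for a meaningful batch median.")
  }
  med <- median(data$spike_ct, na.rm = TRUE)
  dev <- abs(data$spike_ct - med)
  tibble(
    sample_id = data$sample_id,
    spike_ct = data$spike_ct,
    batch_median = med,
    deviation = dev,
    spike_pass = !is.na(dev) & dev <= max_deviation,
    spike_reason = dplyr::case_when(
      is.na(data$spike_ct) ~ "no spike-in",
      dev > max_deviation ~ sprintf("deviation %.2f > %.2f cycles", dev, max_deviation),
      TRUE ~ NA_character_
    )
  )
}

#' Equalize relative expression to a reference group
#'
#' Divides each relative-expression value by the mean value of the reference
#' group for the same miRNA (and compartment, when a `compartment` column is
#' present), so the reference-group mean becomes exactly 1 per cell. This is
#' the "equalized to the average value of control samples" step; the
#' reference group can equally be set to the systemic-lymphoma group for
#' index-fitting use. Samples with `qc_pass == FALSE` (if that column is
#' present) are excluded from the denominator but still rescaled.
#'
#' @param data Long-format expression: columns `mirna`, `expression`, the
#'   grouping column, optionally `compartment` and `qc_pass`.
#' @param group Column (unquoted) with the group label.
#' @param reference_group Label of the reference group (default `"control"`).
#' @return `data` with `expression` rescaled (a tibble).
#' @export
equalize_to_reference <- function(data, group, reference_group = "control") {
  assert_data_frame(data)
  assert_columns(data, c("mirna", "expression"))
  g <- eval_tidy(enquo(group), data)
  if (any(!is.na(data$expression) & data$expression <= 0)) {
    abort("Relative expression must be positive (2^-dCt scale).")
  }
  out <- as_tibble(data)
  out$.group <- g
  by_comp <- "compartment" %in% names(out)
  usable <- if ("qc_pass" %in% names(out)) out$qc_pass else TRUE
  keys <- if (by_comp) c("mirna", "compartment") else "mirna"
  denom <- out |>
    dplyr::filter(.data$.group == reference_group, usable,
                  !is.na(.data$expression)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(.ref_mean = mean(.data$expression), .groups = "drop")
  cells <- dplyr::distinct(out, dplyr::across(dplyr::all_of(keys)))
  missing_cells <- dplyr::anti_join(cells, denom, by = keys)
  if (nrow(missing_cells) > 0) {
    abort(sprintf(
      "Reference group '%s' is empty for: %s.",
      reference_group,
      paste(apply(missing_cells, 1, paste, collapse = "/"), collapse = ", ")
    ))
  }
  out <- dplyr::left_join(out, denom, by = keys)
  out$expression <- out$expression / out$.ref_mean
  out$.ref_mean <- NULL
  out$.group <- NULL
  out
}

#' Full quantification pipeline: raw Ct records to an expression table
#'
#' Chains replicate averaging, spike-in QC, let-7a normalization (2^-dCt)
#' and reference-group equalization. Missing values propagate with QC flags;
#' nothing is imputed.
#'
#' @param ct_records Long-format Ct records (`sample_id`, `assay`,
#'   `replicate`, `ct`).
#' @param metadata Per-sample metadata with `sample_id`, a `group` column and
#'   optionally `compartment`; carried onto the output.
#' @param reference_assay Endogenous normalizer assay (default miR-let-7a).
#' @param spike_assay Spike-in assay name (default cel-miR-39).
#' @param reference_group Equalization reference group (default `"control"`).
#' @param replicate_tolerance Passed to [average_duplicates()].
#' @param spike_max_deviation Passed to [spike_in_qc()]; use `NULL` to skip
#'   spike-in QC (e.g. when no spike-in was run).
#' @param equalize Set `FALSE` to return let-7a-normalized values without
#'   reference-group equalization.
#' @return A long tibble: `sample_id`, metadata columns, `mirna`,
#'   `expression` (equalized relative expression), `qc_pass`, plus QC detail
#'   columns. The spike-in and reference assays are consumed, not reported as
#'   targets.
#' @seealso [expression_wide()] to pivot samples x miRNAs.
#' @export
quantify_expression <- function(ct_records, metadata,
                                reference_assay = REFERENCE_ASSAY,
                                spike_assay = SPIKE_ASSAY,
                                reference_group = "control",
                                replicate_tolerance = 1.0,
                                spike_max_deviation = 2.0,
                                equalize = TRUE) {
  assert_data_frame(ct_records, "ct_records")
  assert_data_frame(metadata, "metadata")
  assert_columns(metadata, c("sample_id", "group"), "metadata")

  avg <- average_duplicates(ct_records, tolerance = replicate_tolerance)

  ref <- avg |>
    dplyr::filter(.data$assay == reference_assay) |>
    dplyr::select("sample_id", ref_ct = "ct")
  if (nrow(ref) == 0) {
    abort(sprintf("No '%s' reference records found.", reference_assay))
  }

  if (!is.null(spike_max_deviation)) {
    spike <- avg |>
      dplyr::filter(.data$assay == spike_assay) |>
      dplyr::select("sample_id", spike_ct = "ct")
    spike_tbl <- spike_in_qc(
      dplyr::left_join(dplyr::distinct(avg, .data$sample_id), spike,
                       by = "sample_id"),
      max_deviation = spike_max_deviation
    )
  } else {
    spike_tbl <- tibble(sample_id = unique(avg$sample_id), spike_ct = NA_real_,
                        batch_median = NA_real_, deviation = NA_real_,
                        spike_pass = TRUE, spike_reason = NA_character_)
  }

  targets <- avg |>
    dplyr::filter(!.data$assay %in% c(reference_assay, spike_assay)) |>
    dplyr::left_join(ref, by = "sample_id") |>
    dplyr::left_join(spike_tbl[c("sample_id", "spike_pass", "spike_reason")],
                     by = "sample_id") |>
    dplyr::mutate(
      qc_no_reference = is.na(.data$ref_ct),
      expression = relative_expression(.data$ct, .data$ref_ct),
      qc_pass = !is.na(.data$expression) & .data$spike_pass &
        !.data$qc_discordant
    ) |>
    dplyr::rename(mirna = "assay") |>
    dplyr::left_join(metadata, by = "sample_id")

  if (equalize) {
    targets <- equalize_to_reference(targets, .data$group,
                                     reference_group = reference_group)
  }
  dplyr::relocate(targets, "sample_id", "mirna", "expression", "qc_pass")
}

#' Pivot long expression to a samples-by-miRNAs table
#'
#' @param data Long expression tibble from [quantify_expression()].
#' @param id_cols Columns identifying a sample (kept as-is); defaults to
#'   every non-(mirna/expression/QC) column present.
#' @return A wide tibble: one row per sample, one column per miRNA.
#' @export
expression_wide <- function(data, id_cols = NULL) {
  assert_data_frame(data)
  assert_columns(data, c("sample_id", "mirna", "expression"))
  qc_cols <- c("ct", "ref_ct", "n_replicates", "n_used", "spread",
               "qc_discordant", "qc_partial", "qc_undetermined",
               "qc_no_reference", "spike_pass", "spike_reason", "qc_pass")
  if (is.null(id_cols)) {
    id_cols <- setdiff(names(data), c("mirna", "expression", qc_cols))
  }
  tidyr::pivot_wider(
    data,
    id_cols = dplyr::all_of(id_cols),
    names_from = "mirna", values_from = "expression"
  )
}
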