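#' Construct an oncomiR index model
#'
#' An oncomiR index is a weighted linear combination of equalized miRNA
#' relative expressions: score = sum over the panel of
#' coefficient_i x abundance_i. Fed through a logistic link
#' p = 1 / (1 + exp(X - score)) it scores the probability of CNS lymphoma
#' involvement; compared against a threshold it yields a binary call.
#'
#' Coefficients must be non-negative; a miRNA whose coefficient is zero is
#' excluded from the panel. `threshold_log2` is derived from `threshold_raw`
#' when not supplied and the two must agree within 0.005 on the log2 scale.
#'
#' @param coefficients Named numeric vector of non-negative per-miRNA weights
#'   (names are miRNA assay names, e.g. `"miR-21"`).
#' @param intercept The logistic intercept X (dimensionless). `NA` for models
#'   whose published form reports only the linear index and threshold.
#' @param threshold_raw Decision cut-off on the raw index scale, or `NA`.
#' @param threshold_log2 Cut-off on the log2 index scale; derived from
#'   `threshold_raw` if omitted.
#' @param name Model label, e.g. `"DLBCL-CSF"`.
#' @param compartment `"CSF"`, `"plasma"`, or `NA`.
#' @param objective For fitted models, the achieved value of the fitting
#'   objective (difference of average class probabilities).
#' @return An object of class `index_model`.
#' @examples
#' m <- index_model(c("miR-21" = 1.57, "miR-155" = 1.75), threshold_raw = 6.83)
#' tidy(m)
#' @export
index_model <- function(coefficients, intercept = NA_real_,
                        threshold_raw = NA_real_, threshold_log2 = NULL,
                        name = NA_character_, compartment = NA_character_,
                        objective = NA_real_) {
  if (!is.numeric(coefficients) || is.null(names(coefficients)) ||
      any(names(coefficients) == "")) {
    abort("`coefficients` must be a named numeric vector of miRNA weights.")
  }
  if (any(coefficients < 0)) {
    abort("Index coefficients must be non-negative.")
  }
  # Zero-weight oncomiRs are excluded from the panel.
  coefficients <- coefficients[coefficients > 0]
  if (length(coefficients) == 0) {
    abort("All coefficients are zero; the index has an empty panel.")
  }
  if (!is.na(threshold_raw) && threshold_raw <= 0) {
    abort("`threshold_raw` must be positive (the index is non-negative).")
  }
  if (is.null(threshold_log2)) {
    threshold_log2 <- if (is.na(threshold_raw)) NA_real_ else log2(threshold_raw)
  }
  if (!is.na(threshold_raw) && !is.na(threshold_log2) &&
      abs(log2(threshold_raw) - threshold_log2) > 0.005) {
    abort("`threshold_log2` is inconsistent with log2(`threshold_raw`) (tolerance 0.005).")
  }
  structure(
    list(
      name = name, compartment = compartment,
      panel = names(coefficients), coefficients = coefficients,
      intercept = intercept,
      threshold_raw = threshold_raw, threshold_log2 = threshold_log2,
      objective = objective
    ),
    class = "index_model"
  )
}

#' Published oncomiR index presets
#'
#' The eight published index formulae (four B-NHL diagnoses x two
#' compartments) with their per-miRNA coefficients and ROC-derived decision
#' thresholds, loaded from the versioned JSON resource shipped with the
#' package. The published models report only the linear index and threshold;
#' their logistic intercept X is not public, so presets carry
#' `intercept = NA` and [cns_probability()] on a preset requires an explicit
#' intercept.
#'
#' @param name Optional preset name (e.g. `"DLBCL-CSF"`). When `NULL`, all
#'   presets are returned as a named list.
#' @return An `index_model`, or a named list of all eight.
#' @examples
#' oncomir_presets("BL-CSF")
#' names(oncomir_presets())
#' @export
oncomir_presets <- function(name = NULL) {
  path <- system.file("extdata", "oncomir_presets.json", package = "oncomir")
  reg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  models <- purrr::map(reg$models, function(m) {
    index_model(
      coefficients = unlist(m$coefficients),
      threshold_raw = m$threshold_raw, threshold_log2 = m$threshold_log2,
      name = m$name, compartment = m$compartment
    )
  })
  names(models) <- purrr::map_chr(reg$models, "name")
  if (is.null(name)) {
    return(models)
  }
  if (!name %in% names(models)) {
    abort(sprintf("Unknown preset '%s'. Available: %s.", name,
                  paste(names(models), collapse = ", ")))
  }
  models[[name]]
}

#' Published per-preset performance summary
#'
#' The published operating characteristics (AUC, sensitivity, specificity,
#' Youden index, raw and log2 threshold) of the eight index presets, as a
#' tibble. These are reference values shipped with the preset registry, not
#' quantities recomputed by this package.
#'
#' @return A tibble with one row per preset.
#' @export
oncomir_preset_performance <- function() {
  path <- system.file("extdata", "oncomir_presets.json", package = "oncomir")
  reg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  purrr::map_dfr(reg$models, function(m) {
    tibble(
      name = m$name, diagnosis = m$diagnosis, compartment = m$compartment,
      panel = paste(names(m$coefficients), collapse = "/"),
      auc = m$auc, sensitivity = m$sensitivity, specificity = m$specificity,
      youden = m$youden,
      threshold_raw = m$threshold_raw, threshold_log2 = m$threshold_log2
    )
  })
}

panel_matrix <- function(data, model, arg = "data") {
  assert_data_frame(data, arg)
  missing_cols <- setdiff(model$panel, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Panel miRNA%s missing from `%s`: %s.",
                  if (length(missing_cols) > 1) "s" else "", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(data[model$panel])
  if (!is.numeric(m)) abort("Panel columns must be numeric abundances.")
  na_rows <- which(!complete.cases(m))
  if (length(na_rows) > 0) {
    abort(sprintf(
      "Missing abundance for panel miRNA(s) in row(s) %s; the index does not impute.",
      paste(head(na_rows, 5), collapse = ", ")
    ))
  }
  m
}

#' Compute the oncomiR index score per sample
#'
#' Adds an `index` column: the weighted sum of the model's panel abundances,
#' sum(coefficient_i x abundance_i). All panel miRNAs must be present and
#' non-missing; nothing is imputed.
#'
#' @param data A data frame with one column per panel miRNA (relative
#'   expression, equalized scale) and one row per sample.
#' @param model An [index_model].
#' @return `data` as a tibble with an added `index` column.
#' @examples
#' d <- tibble::tibble(`miR-21` = c(1, 2), `miR-155` = c(1, 1))
#' compute_index(d, oncomir_presets("BL-CSF"))
#' @export
compute_index <- function(data, model) {
  stopifnot(inherits(model, "index_model"))
  m <- panel_matrix(data, model)
  out <- as_tibble(data)
  out$index <- as.numeric(m %*% model$coefficients[model$panel])
  out
}

#' Logistic probability of CNS involvement
#'
#' Adds a `cns_probability` column: p = 1 / (1 + exp(X - index)), a strictly
#' increasing transform of the index with p = 0.5 exactly at index = X.
#'
#' @inheritParams compute_index
#' @param intercept The logistic intercept X. Required when the model does
#'   not carry one (all published presets).
#' @return `data` as a tibble with added `index` and `cns_probability`
#'   columns.
#' @export
cns_probability <- function(data, model, intercept = NULL) {
  stopifnot(inherits(model, "index_model"))
  x <- intercept %||% model$intercept
  if (is.null(x) || is.na(x)) {
    abort(paste0(
      "Model carries no intercept X (published presets expose only the ",
      "linear index and threshold); supply `intercept` explicitly."
    ))
  }
  assert_number(x, "intercept")
  out <- compute_index(data, model)
  out$cns_probability <- 1 / (1 + exp(x - out$index))
  out
}

#' Classify samples by the model threshold
#'
#' Adds `index` and a logical `cns_positive` column: positive if and only if
#' the index is greater than or equal to the raw threshold (the boundary
#' counts as involved). The equivalent comparison on the log2 scale yields
#' the same calls.
#'
#' @inheritParams compute_index
#' @return `data` as a tibble with added `index` and `cns_positive` columns.
#' @export
classify_samples <- function(data, model) {
  stopifnot(inherits(model, "index_model"))
  if (is.na(model$threshold_raw)) {
    abort("Model has no decision threshold; set `threshold_raw` or fit one.")
  }
  out <- compute_index(data, model)
  out$cns_positive <- out$index >= model$threshold_raw
  out
}

#' @export
print.index_model <- function(x, ...) {
  cat(sprintf("<index_model> %s (%s)\n",
              x$name %||% "unnamed", x$compartment %||% "?"))
  cat("  index =", paste(sprintf("%.2f x %s", x$coefficients, x$panel),
                         collapse = " + "), "\n")
  if (!is.na(x$threshold_raw)) {
    cat(sprintf("  threshold %.4g (log2 %.4g)\n", x$threshold_raw,
                x$threshold_log2))
  }
  if (!is.na(x$intercept)) cat(sprintf("  intercept X = %.4g\n", x$intercept))
  if (!is.na(x$objective)) cat(sprintf("  fit objective = %.4g\n", x$objective))
  invisible(x)
}

#' @rdname index_model
#' @param x,object An `index_model`.
#' @param ... Unused.
#' @export
tidy.index_model <- function(x, ...) {
  tibble(mirna = x$panel, coefficient = unname(x$coefficients[x$panel]))
}

#' @rdname index_model
#' @export
glance.index_model <- function(x, ...) {
  tibble(
    name = x$name, compartment = x$compartment,
    n_mirnas = length(x$panel), intercept = x$intercept,
    threshold_raw = x$threshold_raw, threshold_log2 = x$threshold_log2,
    objective = x$objective
  )
}
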