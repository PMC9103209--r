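# Strict CSV table I/O. All files: UTF-8, comma-separated, header row,
# "." decimal separator. Missing-value tokens accepted on input:
# "", "NA", "Undetermined" (qPCR software exports undetermined Ct as text).

MISSING_TOKENS <- c("", "NA", "Undetermined")

CT_LONG_COLS <- c("patient_id", "sample_id", "compartment",
                  "timepoint_months", "assay", "replicate", "ct")
METADATA_COLS <- c("sample_id", "patient_id", "diagnosis", "group",
                   "compartment", "localization", "timepoint_months",
                   "cns_ipi", "relapse_time", "relapse_event", "death_time",
                   "death_event")

validate_schema <- function(data, required, path, allow_extra = TRUE) {
  missing <- setdiff(required, names(data))
  extra <- setdiff(names(data), required)
  problems <- character()
  if (length(missing) > 0) {
    problems <- c(problems, sprintf("missing column(s): %s",
                                    paste(missing, collapse = ", ")))
  }
  if (!allow_extra && length(extra) > 0) {
    problems <- c(problems, sprintf("unexpected column(s): %s",
                                    paste(extra, collapse = ", ")))
  }
  if (length(problems) > 0) {
    abort(sprintf("Schema violation in '%s': %s.", path,
                  paste(problems, collapse = "; ")))
  }
  invisible(data)
}

read_validated_csv <- function(path, col_types, required, allow_extra = TRUE) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  header <- tryCatch(
    suppressWarnings(names(readr::read_csv(path, n_max = 0,
                                           col_types = readr::cols(),
                                           progress = FALSE))),
    error = function(e) abort(sprintf("Failed to parse '%s': %s", path,
                                      conditionMessage(e)))
  )
  validate_schema(setNames(data.frame(matrix(ncol = length(header), nrow = 0)),
                           header),
                  required, path, allow_extra = allow_extra)
  out <- tryCatch(
    readr::read_csv(path, col_types = col_types, na = MISSING_TOKENS,
                    progress = FALSE),
    error = function(e) abort(sprintf("Failed to parse '%s': %s", path,
                                      conditionMessage(e)))
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("Parse error in '%s' at line %d: expected %s, got '%s'.",
                  path, probs$row[1] + 1, probs$expected[1], probs$actual[1]))
  }
  validate_schema(out, required, path, allow_extra = allow_extra)
}

#' Read a long-format Ct record table
#'
#' Strictly validated CSV reader for raw qPCR records: one row per
#' (sample, assay, replicate) with columns `patient_id`, `sample_id`,
#' `compartment`, `timepoint_months`, `assay`, `replicate`, `ct`.
#' `"Undetermined"`, `"NA"` and empty cells parse as missing Ct (carried as
#' `NA`, flagged downstream - never as a pseudo-Ct of 40).
#'
#' @param path CSV file path.
#' @return A tibble in Ct-long format.
#' @export
read_ct_long <- function(path) {
  read_validated_csv(
    path,
    readr::cols(
      patient_id = readr::col_character(),
      sample_id = readr::col_character(),
      compartment = readr::col_character(),
      timepoint_months = readr::col_double(),
      assay = readr::col_character(),
      replicate = readr::col_integer(),
      ct = readr::col_double()
    ),
    CT_LONG_COLS
  )
}

#' Read a per-sample metadata table
#'
#' Validated CSV reader for sample metadata (`sample_id`, `patient_id`,
#' `diagnosis`, `group`, `compartment`, `localization`, `timepoint_months`,
#' `cns_ipi`, `relapse_time`, `relapse_event`, `death_time`, `death_event`).
#'
#' @param path CSV file path.
#' @return A tibble with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  read_validated_csv(
    path,
    readr::cols(
      sample_id = readr::col_character(),
      patient_id = readr::col_character(),
      diagnosis = readr::col_character(),
      group = readr::col_character(),
      compartment = readr::col_character(),
      localization = readr::col_character(),
      timepoint_months = readr::col_double(),
      cns_ipi = readr::col_character(),
      relapse_time = readr::col_double(),
      relapse_event = readr::col_integer(),
      death_time = readr::col_double(),
      death_event = readr::col_integer()
    ),
    METADATA_COLS
  )
}

#' Write a table as standardized CSV
#'
#' UTF-8 CSV with a header, `"."` decimal separator and `NA` for missing
#' values, so a write-then-read round trip is the identity for the schemas
#' this package reads.
#'
#' @param data A data frame.
#' @param path Output path (directories are created as needed).
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(data, path) {
  assert_data_frame(data)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(data, path, na = "NA", progress = FALSE)
  invisible(path)
}
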