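# Internal helpers: argument checking and column validation.

assert_data_frame <- function(data, arg = "data") {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame, not %s.", arg, class(data)[1]))
  }
}

assert_columns <- function(data, cols, arg = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column%s: %s.",
      arg, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
}

assert_number <- function(x, arg, min = -Inf, max = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
      (finite && !is.finite(x)) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", arg,
                  format(min), format(max)))
  }
  invisible(x)
}

assert_flag <- function(x, arg) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", arg))
  }
  invisible(x)
}

# Deterministic seed scoping: run `expr` under `seed` and restore the RNG
# state afterwards so generators do not perturb the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
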