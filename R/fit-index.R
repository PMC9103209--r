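#' Fit oncomiR index coefficients by separating average class probabilities
#'
#' Fits the coefficients and intercept X of the logistic index model
#' p = 1 / (1 + exp(X - sum(coefficient_i x abundance_i))) by maximising the
#' difference of average probabilities between the CNS-positive and systemic
#' classes, mean(p | positive) - mean(p | negative).
#'
#' The objective is scale-degenerate: inflating all coefficients and X
#' together drives p toward a step function, so an unconstrained search is
#' ill-posed. Coefficients are therefore box-constrained (default \[0, 10\]
#' each) and X is bounded (default \[-20, 20\]); optimisation is a
#' multi-start bounded quasi-Newton search (`optim` L-BFGS-B) from a
#' deterministic grid of starts plus seeded random starts, so results are
#' reproducible given `seed`. Near-equal optima (objective within `tie_tol`)
#' are tie-broken toward the smallest L2 norm of the coefficient vector, and
#' the same preference is applied to the panel itself: after optimisation,
#' any coefficient whose removal (with re-optimisation of the rest) costs at
#' most `prune_tol` of the objective is set to zero, so near-equal optima
#' resolve to the sparser, smaller-norm model rather than carrying
#' pseudo-informative weights. Coefficients below `zero_tol` are then
#' treated as exactly zero and the miRNA is dropped from the panel.
#'
#' After fitting, a decision threshold is selected on the training scores by
#' the closest-to-corner ROC rule.
#'
#' @param data A data frame with one row per sample: one numeric column per
#'   candidate panel miRNA plus a class column.
#' @param class Column (unquoted) with the class label.
#' @param panel Character vector of candidate miRNA column names.
#' @param positive Value of `class` for the CNS-positive class (see
#'   [roc_curve()] for the default).
#' @param coef_bounds Length-2 numeric, finite box for every coefficient.
#' @param intercept_bounds Length-2 numeric, finite box for X.
#' @param n_random_starts Number of seeded random starts added to the
#'   deterministic grid.
#' @param seed Integer seed for the random starts.
#' @param zero_tol Coefficients below this are treated as exactly zero.
#' @param tie_tol Objective difference below which optima count as tied.
#' @param prune_tol Largest objective loss accepted when zeroing a
#'   coefficient during backward pruning (default 1e-3 on the \[0, 1\]
#'   objective scale).
#' @param name,compartment Labels stored on the returned model.
#' @return A fitted [index_model] with `intercept`, `threshold_raw` and
#'   `objective` set.
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   `miR-21` = 2^rnorm(60, mean = rep(c(0, 3), each = 30)),
#'   cns = rep(c(0, 1), each = 30)
#' )
#' fit <- fit_index(d, cns, panel = "miR-21", positive = 1)
#' glance(fit)
#' @export
fit_index <- function(data, class, panel, positive = NULL,
                      coef_bounds = c(0, 10), intercept_bounds = c(-20, 20),
                      n_random_starts = 16, seed = 1,
                      zero_tol = 1e-6, tie_tol = 1e-8, prune_tol = 1e-3,
                      name = "fitted", compartment = NA_character_) {
  assert_data_frame(data)
  assert_columns(data, panel)
  if (any(!is.finite(coef_bounds)) || any(!is.finite(intercept_bounds))) {
    abort(paste0(
      "Coefficient and intercept bounds must be finite: the objective is ",
      "scale-degenerate (scaling all coefficients and X together approaches ",
      "a step function), so an unbounded search is not identifiable."
    ))
  }
  if (coef_bounds[1] < 0) abort("Coefficients are constrained non-negative.")
  y <- eval_tidy(enquo(class), data)
  labels <- unique(y[!is.na(y)])
  if (is.null(positive)) {
    if (is.logical(y)) positive <- TRUE
    else if (setequal(labels, c(0, 1))) positive <- 1
    else abort("`positive` must be supplied for non-logical/non-0-1 labels.")
  }
  a <- as.matrix(data[panel])
  keep <- complete.cases(a) & !is.na(y)
  a <- a[keep, , drop = FALSE]
  pos <- y[keep] == positive
  if (sum(pos) < 2 || sum(!pos) < 2) {
    abort("Fitting needs at least 2 samples in each class.")
  }
  if (any(a < 0)) abort("Abundances must be non-negative.")

  p <- length(panel)
  # p_i = 1/(1 + exp(X - score_i)) = plogis(score_i - X); plogis avoids
  # exp() overflow at steep optima near the box boundary.
  objective <- function(theta) {
    score <- as.numeric(a %*% theta[seq_len(p)])
    prob <- stats::plogis(score - theta[p + 1])
    mean(prob[pos]) - mean(prob[!pos])
  }
  gradient <- function(theta) {
    score <- as.numeric(a %*% theta[seq_len(p)])
    prob <- stats::plogis(score - theta[p + 1])
    w <- prob * (1 - prob)
    w_signed <- ifelse(pos, w / sum(pos), -w / sum(!pos))
    c(as.numeric(crossprod(a, w_signed)), -sum(w_signed))
  }

  # Deterministic grid starts: uniform coefficient levels with X centred on
  # the resulting median score, plus seeded random starts inside the box.
  med <- apply(a, 2, median)
  grid_levels <- c(0.1, 0.5, 1, 2, 5)
  starts <- purrr::map(grid_levels, function(cv) {
    cc <- rep(cv, p)
    x0 <- min(max(sum(cc * med), intercept_bounds[1]), intercept_bounds[2])
    c(pmin(cc, coef_bounds[2]), x0)
  })
  rand <- with_seed(seed, purrr::map(seq_len(n_random_starts), function(i) {
    c(runif(p, coef_bounds[1], coef_bounds[2]),
      runif(1, intercept_bounds[1], intercept_bounds[2]))
  }))
  starts <- c(starts, rand)

  lower <- c(rep(coef_bounds[1], p), intercept_bounds[1])
  upper <- c(rep(coef_bounds[2], p), intercept_bounds[2])
  fits <- purrr::map(starts, function(th0) {
    fit <- tryCatch(
      optim(th0, objective, gradient, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(fnscale = -1, maxit = 500)),
      error = function(e) NULL
    )
    fit
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) abort("All optimisation starts failed.")

  values <- purrr::map_dbl(fits, "value")
  best_val <- max(values)
  tied <- which(values >= best_val - tie_tol)
  # Reproducible tie-break: smallest L2 norm of the coefficient vector.
  norms <- purrr::map_dbl(fits[tied],
                          function(f) sum(f$par[seq_len(p)]^2))
  best <- fits[tied][[order(norms)[1]]]

  # Backward pruning: drop any miRNA whose removal costs <= prune_tol of
  # the objective after re-optimising the remaining weights and X.
  theta <- best$par
  best_val <- best$value
  up_cur <- upper # pruned coefficients stay capped at 0 permanently
  repeat {
    active <- which(theta[seq_len(p)] > 0)
    if (length(active) <= 1) break
    pruned <- FALSE
    for (j in active[order(theta[active])]) {
      th0 <- theta
      th0[j] <- 0
      up_try <- up_cur
      up_try[j] <- 0
      ref <- tryCatch(
        optim(th0, objective, gradient, method = "L-BFGS-B",
              lower = lower, upper = up_try,
              control = list(fnscale = -1, maxit = 500)),
        error = function(e) NULL
      )
      if (!is.null(ref) && ref$value >= best_val - prune_tol) {
        theta <- ref$par
        theta[j] <- 0
        up_cur <- up_try
        best_val <- max(best_val, ref$value)
        pruned <- TRUE
        break
      }
    }
    if (!pruned) break
  }

  coefs <- theta[seq_len(p)]
  coefs[coefs < zero_tol] <- 0
  names(coefs) <- panel
  if (all(coefs == 0)) {
    abort("No informative coefficient found (all fitted weights are zero).")
  }
  model <- index_model(
    coefs, intercept = theta[p + 1],
    name = name, compartment = compartment,
    objective = objective(c(coefs, theta[p + 1]))
  )

  # Training-data threshold by the closest-to-corner ROC rule.
  scored <- compute_index(as_tibble(data[keep, , drop = FALSE]), model)
  roc <- roc_curve(tibble(score = scored$index, y = pos), score, y,
                   positive = TRUE)
  thr <- roc$threshold
  if (is.finite(thr) && thr > 0) {
    model$threshold_raw <- thr
    model$threshold_log2 <- log2(thr)
  }
  model
}
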