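# Shared fixture builders. Everything is generated in code; no files.

# Minimal duplicate Ct records for one sample/assay.
ct_rows <- function(sample_id, assay, cts) {
  tibble::tibble(sample_id = sample_id, assay = assay,
                 replicate = seq_along(cts), ct = cts)
}

# A small two-group, one-compartment cohort configuration for fast tests.
small_config <- function(seed = 1, n_systemic = 30, n_scnsl = 30,
                         n_control = 10, ...) {
  synthetic_config(
    seed = seed,
    group_sizes = tibble::tibble(
      diagnosis = c("control", "DLBCL", "DLBCL"),
      group = c("control", "systemic", "SCNSL"),
      n = c(n_control, n_systemic, n_scnsl)
    ),
    ...
  )
}

# Two-class lognormal expression table with one informative and one noise
# miRNA (log2 shift `shift` on the informative one in the positive class).
two_mirna_classes <- function(n_per_class, shift, sd_log2, seed) {
  withr::with_seed(seed, tibble::tibble(
    `miR-21` = 2^rnorm(2 * n_per_class,
                       mean = rep(c(0, shift), each = n_per_class),
                       sd = sd_log2),
    `miR-92a` = 2^rnorm(2 * n_per_class, mean = 0, sd = sd_log2),
    cns = rep(c(0, 1), each = n_per_class)
  ))
}

# O(n^2) pairwise-concordance AUC oracle (ties counted 0.5), independent of
# the rank-based implementation.
auc_bruteforce <- function(pos, neg) {
  grid <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(grid)
}
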