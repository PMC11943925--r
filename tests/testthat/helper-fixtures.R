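# fixtures built in code

random_bucket_table <- function(n = 6, K = 4, seed = 1, normalized = FALSE) {
  set.seed(seed)
  vals <- matrix(stats::rlnorm(n * K), n, K,
                 dimnames = list(sprintf("s%02d", seq_len(n)),
                                 sprintf("B%d", seq_len(K))))
  tab <- bucket_table(vals,
                      group = rep(c("control", "study"), length.out = n),
                      week = 1L, normalized = FALSE)
  if (normalized) normalize_total_intensity(tab) else tab
}

# a small, fast metabolite library: `n_lines` singlets, first `n_affected`
# of them affected, spaced 0.1 ppm apart from 1.0 ppm upward
small_library <- function(n_lines = 20, n_affected = 3,
                          log_mean = 0.5, log_sd = 0.12) {
  data.frame(metabolite = sprintf("met%02d", seq_len(n_lines)),
             ppm = 1.0 + 0.1 * (seq_len(n_lines) - 1),
             rel_intensity = 1,
             baseline_log_mean = log_mean, baseline_log_sd = log_sd,
             affected = seq_len(n_lines) <= n_affected)
}

small_design <- function(..., n_lines = 20, n_affected = 3,
                         weeks = 1L, effect_trajectory = c(`1` = 1),
                         n_control = 10, n_study = 10, seed = 1L) {
  synthetic_design(metabolites = small_library(n_lines, n_affected),
                   weeks = weeks, effect_trajectory = effect_trajectory,
                   n_control = n_control, n_study = n_study, seed = seed,
                   ...)
}

expect_tables_equal <- function(a, b) {
  expect_identical(a$sample_id, b$sample_id)
  expect_identical(a$group, b$group)
  expect_identical(a$week, b$week)
  expect_identical(a$bucket_ids, b$bucket_ids)
  expect_equal(unname(a$values), unname(b$values), tolerance = 0)
  expect_identical(a$normalized, b$normalized)
}
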