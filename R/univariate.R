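#' Two-group location test for one bucket
#'
#' Default is Welch's unequal-variance two-sided t-test; a Wilcoxon rank-sum
#' alternative is available behind `method`. When both groups have zero
#' variance the test degenerates: p = 1 for equal means, p = 0 otherwise.
#'
#' @param xs,ys Numeric vectors (each of length >= 2) of bucket intensities
#'   for the two groups.
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @return Two-sided p-value.
#' @export
two_group_test <- function(xs, ys, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  if (length(xs) < 2 || length(ys) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (anyNA(xs) || anyNA(ys) || any(!is.finite(c(xs, ys))))
    stop("values must be finite", call. = FALSE)
  if (method == "welch") {
    if (stats::var(xs) == 0 && stats::var(ys) == 0)
      return(if (mean(xs) == mean(ys)) 1 else 0)
    stats::t.test(xs, ys, var.equal = FALSE)$p.value
  } else {
    if (stats::var(xs) == 0 && stats::var(ys) == 0 && mean(xs) == mean(ys))
      return(1)
    suppressWarnings(stats::wilcox.test(xs, ys, exact = FALSE)$p.value)
  }
}

#' Bonferroni-corrected per-bucket alpha
#'
#' Family-wise control at level `alpha_total` over a family of
#' `n_buckets` simultaneous per-bucket tests: each bucket is tested at
#' `alpha_total / n_buckets`.
#'
#' @param n_buckets Number of buckets tested (>= 1).
#' @param alpha_total Family-wise error rate to maintain (default 0.05).
#' @return The per-bucket alpha.
#' @examples
#' bonferroni_alpha(114)   # 0.05/114
#' @export
bonferroni_alpha <- function(n_buckets, alpha_total = 0.05) {
  if (length(n_buckets) != 1 || is.na(n_buckets) || n_buckets < 1)
    stop("n_buckets must be >= 1", call. = FALSE)
  alpha_total / n_buckets
}

#' Mann-Whitney AUC for group membership
#'
#' The probability that a randomly chosen study-group value exceeds a
#' randomly chosen control-group value: over all (x, y) pairs, the fraction
#' with y > x, ties counted 0.5. Computed from ranks, which is exactly the
#' pair-counting definition.
#'
#' @param xs Control-group values (non-empty).
#' @param ys Study-group values (non-empty).
#' @return AUC in \[0, 1\].
#' @export
auc_group_membership <- function(xs, ys) {
  nx <- length(xs); ny <- length(ys)
  if (nx == 0 || ny == 0) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(ys, xs))
  (sum(r[seq_len(ny)]) - ny * (ny + 1) / 2) / (nx * ny)
}

#' Per-bucket two-group screening with Bonferroni control
#'
#' Runs the location test and the Mann-Whitney AUC for every bucket of a
#' normalized table, flags buckets with p below the Bonferroni-corrected
#' alpha and with AUC beyond the discrimination threshold (in either
#' direction), and reports the log2 fold change of group means
#' (study vs control).
#'
#' @param table A normalized `bucket_table` containing both groups.
#' @param alpha_total Family-wise alpha (default 0.05); the per-bucket alpha
#'   is `alpha_total / K`.
#' @param auc_threshold AUC flagged when `auc >= auc_threshold` or
#'   `auc <= 1 - auc_threshold` (default 0.75).
#' @param method Passed to [two_group_test()].
#' @return Object of class `comparison_result`: a list with `buckets` (data
#'   frame: `bucket_id`, `p_value`, `auc`, `log2_fold_change`,
#'   `significant_p`, `significant_auc`), `alpha_bonferroni`,
#'   `n_buckets_tested`, `n_significant`, `n1`, `n2`.
#' @export
compare_buckets <- function(table, alpha_total = 0.05, auc_threshold = 0.75,
                            method = c("welch", "wilcoxon")) {
  stopifnot(inherits(table, "bucket_table"))
  method <- match.arg(method)
  if (!table$normalized)
    stop("table must be normalized to total intensity before testing",
         call. = FALSE)
  ctrl <- table$group == "control"
  stdy <- table$group == "study"
  if (!any(ctrl) || !any(stdy))
    stop("both groups must be present", call. = FALSE)
  X <- table$values
  K <- ncol(X)
  alpha_b <- bonferroni_alpha(K, alpha_total)
  p <- numeric(K); auc <- numeric(K); lfc <- numeric(K)
  for (k in seq_len(K)) {
    xs <- X[ctrl, k]; ys <- X[stdy, k]
    p[k] <- two_group_test(xs, ys, method = method)
    auc[k] <- auc_group_membership(xs, ys)
    lfc[k] <- log2(mean(ys) / mean(xs))
  }
  sig_p <- p < alpha_b
  sig_auc <- auc >= auc_threshold | auc <= 1 - auc_threshold
  structure(
    list(buckets = data.frame(bucket_id = table$bucket_ids,
                              p_value = p, auc = auc,
                              log2_fold_change = lfc,
                              significant_p = sig_p,
                              significant_auc = sig_auc,
                              stringsAsFactors = FALSE),
         alpha_bonferroni = alpha_b,
         n_buckets_tested = K,
         n_significant = sum(sig_p),
         n1 = sum(ctrl), n2 = sum(stdy),
         alpha_total = alpha_total, auc_threshold = auc_threshold,
         method = method),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %d buckets tested (%s), alpha_bonferroni = %.3g\n",
    x$n_buckets_tested, x$method, x$alpha_bonferroni))
  cat(sprintf("  significant by p: %d; by AUC: %d (threshold %.2f)\n",
              x$n_significant, sum(x$buckets$significant_auc),
              x$auc_threshold))
  invisible(x)
}
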