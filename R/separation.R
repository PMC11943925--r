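#' Mahalanobis distance between two groups of scores
#'
#' Distance between the group centroids scaled by the pooled within-group
#' covariance: `D = sqrt((m1-m2)' S^-1 (m1-m2))` with
#' `S = ((n1-1)S1 + (n2-1)S2)/(n1+n2-2)`. This is the distance the
#' score-plot separation test converts to an F statistic.
#'
#' @param scores1,scores2 Numeric matrices (points x dimensions), one row per
#'   sample; each group needs at least `p + 1` points so the pooled
#'   covariance is estimable.
#' @return The Mahalanobis distance D (>= 0).
#' @export
mahalanobis_between_groups <- function(scores1, scores2) {
  scores1 <- as.matrix(scores1); scores2 <- as.matrix(scores2)
  if (ncol(scores1) != ncol(scores2))
    stop("score matrices must have the same number of dimensions",
         call. = FALSE)
  p <- ncol(scores1)
  n1 <- nrow(scores1); n2 <- nrow(scores2)
  if (n1 < p + 1 || n2 < p + 1)
    stop("each group needs at least p + 1 points", call. = FALSE)
  S <- ((n1 - 1) * stats::cov(scores1) + (n2 - 1) * stats::cov(scores2)) /
    (n1 + n2 - 2)
  d <- colMeans(scores1) - colMeans(scores2)
  Sinv_d <- tryCatch(solve(S, d), error = function(e)
    stop("pooled covariance is singular; reduce the number of score dimensions",
         call. = FALSE))
  if (rcond(S) < 1e-12)
    stop("pooled covariance is near-singular; reduce the number of score dimensions",
         call. = FALSE)
  sqrt(drop(crossprod(d, Sinv_d)))
}

#' Convert a Mahalanobis distance to Hotelling T2 and an F-value
#'
#' Two-sample Hotelling statistic: `T2 = (n1 n2/(n1+n2)) D^2`, converted to
#' `F = ((n1+n2-p-1)/(p (n1+n2-2))) T2`, which under the null of one common
#' centroid follows an F distribution with `(p, n1+n2-p-1)` degrees of
#' freedom.
#'
#' @param D Mahalanobis distance between group centroids (>= 0).
#' @param n1,n2 Group sizes.
#' @param p_dims Number of score dimensions (default 2, a two-dimensional
#'   score plot).
#' @return List with `t_squared` and `f_value`.
#' @examples
#' separation_f_value(6.735, 14, 14, 2)$f_value   # ~152.65
#' @export
separation_f_value <- function(D, n1, n2, p_dims = 2) {
  if (D < 0) stop("D must be non-negative", call. = FALSE)
  if (n1 + n2 <= p_dims + 1)
    stop("degenerate degrees of freedom: need n1 + n2 > p_dims + 1",
         call. = FALSE)
  t2 <- (n1 * n2 / (n1 + n2)) * D^2
  f <- (n1 + n2 - p_dims - 1) / (p_dims * (n1 + n2 - 2)) * t2
  list(t_squared = t2, f_value = f)
}

#' Upper-tail critical value of the F distribution
#'
#' The value q with `P(F_{df1, df2} > q) = alpha`.
#'
#' @param alpha Upper-tail probability in (0, 1).
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return The critical F value.
#' @examples
#' critical_f(0.05, 18, 18)   # 2.217
#' @export
critical_f <- function(alpha, df1, df2) {
  if (length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1",
                               call. = FALSE)
  stats::qf(alpha, df1, df2, lower.tail = FALSE)
}

#' Test the significance of PLS-DA score-plot cluster separation
#'
#' Computes the Mahalanobis distance between the control and study score
#' clouds, converts it to Hotelling T2 and an F-value, and compares against
#' the critical F. Two degrees-of-freedom conventions are offered:
#' `"paper"` uses `(n1 - 1, n2 - 1)` — the rule used with this test in the
#' metabolic-profiling literature it comes from — while `"hotelling"` uses
#' the textbook two-sample Hotelling degrees of freedom
#' `(p, n1 + n2 - p - 1)`, which is the calibrated choice (rejects at about
#' rate alpha under the null). The `"paper"` convention is anti-conservative
#' and kept for comparability.
#'
#' @param model A fitted `plsda_model` (its score matrix supplies the
#'   clouds), or a numeric score matrix if `labels` is given.
#' @param labels Optional group labels overriding the model's.
#' @param alpha Significance level (default 0.05).
#' @param convention `"paper"` (default) or `"hotelling"`.
#' @return Object of class `separation_test`: list with `mahalanobis_d`,
#'   `t_squared`, `f_value`, `n1`, `n2`, `p_dims`, `df1`, `df2`,
#'   `critical_f`, `alpha`, `convention`, `significant`.
#' @export
assess_separation <- function(model, labels = NULL, alpha = 0.05,
                              convention = c("paper", "hotelling")) {
  convention <- match.arg(convention)
  if (inherits(model, "plsda_model")) {
    scores <- model$scores
    if (is.null(labels)) labels <- model$groups
  } else {
    scores <- as.matrix(model)
    if (is.null(labels))
      stop("labels are required when scores are given directly",
           call. = FALSE)
  }
  grp <- ifelse(encode_groups(labels) > 0, "study", "control")
  s1 <- scores[grp == "control", , drop = FALSE]
  s2 <- scores[grp == "study", , drop = FALSE]
  n1 <- nrow(s1); n2 <- nrow(s2); p <- ncol(scores)
  D <- mahalanobis_between_groups(s1, s2)
  fv <- separation_f_value(D, n1, n2, p)
  df <- switch(convention,
               paper = c(n1 - 1, n2 - 1),
               hotelling = c(p, n1 + n2 - p - 1))
  fcrit <- critical_f(alpha, df[1], df[2])
  structure(
    list(mahalanobis_d = D, t_squared = fv$t_squared, f_value = fv$f_value,
         n1 = n1, n2 = n2, p_dims = p, df1 = df[1], df2 = df[2],
         critical_f = fcrit, alpha = alpha, convention = convention,
         significant = fv$f_value > fcrit),
    class = "separation_test")
}

#' @export
print.separation_test <- function(x, ...) {
  cat(sprintf("<separation_test> D = %.3f, T2 = %.2f, F = %.3f\n",
              x$mahalanobis_d, x$t_squared, x$f_value))
  cat(sprintf("  critical F(%.2g; %d, %d) = %.3f [%s convention] -> %s\n",
              x$alpha, x$df1, x$df2, x$critical_f, x$convention,
              if (x$significant) "separation significant"
              else "not significant"))
  invisible(x)
}
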