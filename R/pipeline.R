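#' Run the full analysis for one timepoint
#'
#' One week's control-vs-study comparison, end to end: total-intensity
#' normalization (if not already done), Bonferroni-controlled per-bucket
#' screening with AUC and fold changes, PLS-DA with cross-validated Q2, the
#' Mahalanobis/F cluster-separation test, and mapping of significant buckets
#' to metabolite names (a metabolite counts as significant if any of its
#' buckets is). Buckets missing from the annotation are reported by bucket
#' id with a warning.
#'
#' @param table A `bucket_table` containing exactly one week and both
#'   groups.
#' @param annotation Optional data frame (`bucket_id`, `metabolite`) as from
#'   [read_annotation()].
#' @param alpha_total Family-wise alpha for the screening (default 0.05).
#' @param auc_threshold AUC flag threshold (default 0.75).
#' @param ncomp PLS-DA components (default 2).
#' @param scaling PLS-DA scaling mode (default `"uv"`).
#' @param n_folds Cross-validation segments (default 7).
#' @param convention Degrees-of-freedom convention for the separation test.
#' @param method Per-bucket test, `"welch"` or `"wilcoxon"`.
#' @return Object of class `timepoint_result`: list with `week`,
#'   `comparison`, `plsda`, `separation`, `significant_metabolites`.
#' @export
run_timepoint <- function(table, annotation = NULL, alpha_total = 0.05,
                          auc_threshold = 0.75, ncomp = 2,
                          scaling = c("uv", "pareto", "none"), n_folds = 7,
                          convention = c("paper", "hotelling"),
                          method = c("welch", "wilcoxon")) {
  stopifnot(inherits(table, "bucket_table"))
  scaling <- match.arg(scaling); convention <- match.arg(convention)
  method <- match.arg(method)
  weeks <- unique(table$week)
  if (length(weeks) != 1)
    stop("table must contain exactly one week; got: ",
         paste(weeks, collapse = ", "), call. = FALSE)
  if (!all(c("control", "study") %in% table$group))
    stop("both groups must be present", call. = FALSE)
  if (!table$normalized) table <- normalize_total_intensity(table)
  cmp <- compare_buckets(table, alpha_total = alpha_total,
                         auc_threshold = auc_threshold, method = method)
  # degenerate tables (e.g. a single normalized bucket) carry no
  # multivariate signal: report the univariate screen only
  rk <- qr(sweep(table$values, 2, colMeans(table$values)))$rank
  if (rk < 1) {
    warning("no variation left after normalization; ",
            "multivariate steps skipped", call. = FALSE)
    model <- NULL; sep <- NULL
  } else {
    if (ncomp > rk) {
      warning("ncomp reduced to rank(X) = ", rk, call. = FALSE)
      ncomp <- rk
    }
    model <- fit_plsda(table, ncomp = ncomp, scaling = scaling)
    model$q2_cum <- cross_validate_q2(table, ncomp = ncomp,
                                      scaling = scaling, n_folds = n_folds)
    sep <- assess_separation(model, alpha = alpha_total,
                             convention = convention)
  }
  sig_buckets <- cmp$buckets$bucket_id[cmp$buckets$significant_p]
  sig_met <- character(0)
  if (!is.null(annotation)) {
    unannotated <- setdiff(sig_buckets, annotation$bucket_id)
    if (length(unannotated) > 0)
      warning("significant bucket(s) without annotation: ",
              paste(unannotated, collapse = ", "), call. = FALSE)
    sig_met <- unique(
      annotation$metabolite[annotation$bucket_id %in% sig_buckets])
  }
  structure(
    list(week = weeks, comparison = cmp, plsda = model, separation = sep,
         significant_metabolites = sig_met),
    class = "timepoint_result")
}

#' @export
print.timepoint_result <- function(x, ...) {
  cat(sprintf("<timepoint_result> week %d\n", x$week))
  cat(sprintf("  %d/%d buckets significant (alpha_bonferroni = %.3g)\n",
              x$comparison$n_significant, x$comparison$n_buckets_tested,
              x$comparison$alpha_bonferroni))
  if (!is.null(x$plsda))
    cat(sprintf("  R2Y(cum) = %.3f, Q2(cum) = %.3f; D = %.3f, F = %.2f vs %.3f -> %s\n",
                x$plsda$r2y_cum, x$plsda$q2_cum, x$separation$mahalanobis_d,
                x$separation$f_value, x$separation$critical_f,
                if (x$separation$significant) "significant" else "ns"))
  if (length(x$significant_metabolites) > 0)
    cat("  metabolites:",
        paste(utils::head(x$significant_metabolites, 8), collapse = ", "),
        if (length(x$significant_metabolites) > 8) "..." else "", "\n")
  invisible(x)
}

#' Longitudinal trend matrix behind the heat-map summary
#'
#' Builds a metabolites-by-weeks matrix of signed scores: the log2 fold
#' change (study vs control) of each metabolite's most-changed significant
#' bucket, masked to 0 in weeks where none of the metabolite's buckets
#' passes the Bonferroni screen. Rows are ordered by peak absolute score,
#' descending.
#'
#' @param results List of `timepoint_result` objects (one per week), all
#'   computed over the same bucket set.
#' @param annotation Data frame (`bucket_id`, `metabolite`) shared by all
#'   weeks.
#' @return Object of class `longitudinal_summary`: list with `matrix`
#'   (metabolites x weeks), `weeks`, `metabolites`.
#' @export
build_trend_matrix <- function(results, annotation) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "timepoint_result")))
  bucket_sets <- lapply(results, function(r) r$comparison$buckets$bucket_id)
  ref <- bucket_sets[[1]]
  for (i in seq_along(bucket_sets)) {
    if (!identical(sort(bucket_sets[[i]]), sort(ref)))
      stop("inconsistent bucket sets across weeks; mismatches: ",
           paste(union(setdiff(bucket_sets[[i]], ref),
                       setdiff(ref, bucket_sets[[i]])), collapse = ", "),
           call. = FALSE)
  }
  weeks <- vapply(results, `[[`, integer(1), "week")
  o <- order(weeks)
  results <- results[o]; weeks <- weeks[o]
  mets <- unique(annotation$metabolite[annotation$bucket_id %in% ref])
  M <- matrix(0, length(mets), length(weeks),
              dimnames = list(mets, paste0("week", weeks)))
  for (j in seq_along(results)) {
    b <- results[[j]]$comparison$buckets
    sig <- b[b$significant_p & b$bucket_id %in% annotation$bucket_id, ]
    if (nrow(sig) == 0) next
    sig$metabolite <- annotation$metabolite[
      match(sig$bucket_id, annotation$bucket_id)]
    for (m in unique(sig$metabolite)) {
      lfc <- sig$log2_fold_change[sig$metabolite == m]
      M[m, j] <- lfc[which.max(abs(lfc))]
    }
  }
  peak <- apply(abs(M), 1, max)
  M <- M[order(peak, decreasing = TRUE), , drop = FALSE]
  structure(list(matrix = M, weeks = weeks, metabolites = rownames(M)),
            class = "longitudinal_summary")
}

#' @export
print.longitudinal_summary <- function(x, ...) {
  nz <- sum(rowSums(x$matrix != 0) > 0)
  cat(sprintf(
    "<longitudinal_summary> %d metabolites x %d weeks (%d ever significant)\n",
    nrow(x$matrix), length(x$weeks), nz))
  invisible(x)
}

#' Plot the longitudinal trend matrix as a heat map
#'
#' Thin wrapper: uses pheatmap when available, otherwise base
#' [graphics::image()]. Rows are metabolites (only those ever significant),
#' columns weeks; color encodes the masked signed log2 fold change.
#'
#' @param summary A `longitudinal_summary`.
#' @param ... Passed to the underlying plotting function.
#' @return Invisibly, the plotted matrix.
#' @export
plot_trend_heatmap <- function(summary, ...) {
  stopifnot(inherits(summary, "longitudinal_summary"))
  M <- summary$matrix[rowSums(summary$matrix != 0) > 0, , drop = FALSE]
  if (nrow(M) == 0) stop("nothing ever significant; nothing to plot",
                         call. = FALSE)
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(M, cluster_cols = FALSE, ...)
  } else {
    graphics::image(t(M[nrow(M):1, , drop = FALSE]), axes = FALSE, ...)
  }
  invisible(M)
}

#' Run every timepoint of a cohort and summarize longitudinally
#'
#' Convenience driver: applies [run_timepoint()] to each week's table and
#' assembles the trend matrix.
#'
#' @param tables Named list of one-week `bucket_table`s (as produced by
#'   [generate_cohort()]), or a single multi-week table to be split.
#' @param annotation Bucket-to-metabolite annotation shared by all weeks.
#' @param ... Passed to [run_timepoint()].
#' @return List with `timepoints` (list of `timepoint_result`) and `trend`
#'   (a `longitudinal_summary`).
#' @export
run_longitudinal <- function(tables, annotation, ...) {
  if (inherits(tables, "bucket_table"))
    tables <- lapply(sort(unique(tables$week)), subset_week, table = tables)
  results <- lapply(tables, run_timepoint, annotation = annotation, ...)
  list(timepoints = results,
       trend = build_trend_matrix(results, annotation))
}

#' Serialize a timepoint result to JSON
#'
#' Writes the per-bucket screening table, the PLS-DA summary (R2Y, Q2, VIP,
#' scores), and the separation test of one timepoint as a JSON document.
#'
#' @param result A `timepoint_result`.
#' @param file Path to write.
#' @return Invisibly, `file`.
#' @export
write_timepoint_json <- function(result, file) {
  stopifnot(inherits(result, "timepoint_result"))
  out <- list(
    week = result$week,
    alpha_bonferroni = result$comparison$alpha_bonferroni,
    n_significant = result$comparison$n_significant,
    buckets = result$comparison$buckets,
    significant_metabolites = result$significant_metabolites)
  if (!is.null(result$plsda)) {
    out$plsda <- list(ncomp = result$plsda$ncomp,
                      r2y_cum = result$plsda$r2y_cum,
                      q2_cum = result$plsda$q2_cum,
                      vip = as.list(result$plsda$vip),
                      scores = unname(apply(result$plsda$scores, 1,
                                            as.list, simplify = FALSE)))
    out$separation <- unclass(result$separation)
  }
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
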