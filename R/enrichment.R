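#' Hypergeometric over-representation analysis of metabolite sets
#'
#' For each metabolite set, tests whether the significant metabolites hit it
#' more often than chance: with N metabolites in the universe, K of them in
#' the set, and n significant, the p-value is the upper tail
#' `P(X >= k)` for X hypergeometric — the probability of at least the
#' observed overlap under random draws. P-values are Holm-adjusted across
#' the tested sets. Sets are intersected with the universe first; sets with
#' no members in the universe are skipped with a warning.
#'
#' @param significant Character vector of significant metabolite names (must
#'   be a subset of `universe`).
#' @param universe Character vector of all metabolites considered.
#' @param library Named list of metabolite sets, as from
#'   [read_metabolite_sets()], or a single character vector.
#' @return Data frame (class `enrichment_result`), one row per tested set:
#'   `set_id`, `set_name`, `k` (hits), `K_set` (set size in universe),
#'   `n_sig`, `N`, `p_hyper`, `holm_adjusted_p`, sorted by `p_hyper`.
#' @export
hypergeometric_ora <- function(significant, universe, library) {
  universe <- unique(as.character(universe))
  significant <- unique(as.character(significant))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  extra <- setdiff(significant, universe)
  if (length(extra) > 0)
    stop("significant metabolites not in universe: ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (is.character(library)) library <- list(set1 = library)
  N <- length(universe)
  n_sig <- length(significant)
  rows <- lapply(names(library), function(id) {
    members <- intersect(unique(as.character(library[[id]])), universe)
    if (length(members) == 0) {
      warning("set '", id, "' has no members in the universe; skipped",
              call. = FALSE)
      return(NULL)
    }
    k <- length(intersect(members, significant))
    K_set <- length(members)
    p <- stats::phyper(k - 1, K_set, N - K_set, n_sig, lower.tail = FALSE)
    nm <- attr(library[[id]], "set_name")
    data.frame(set_id = id,
               set_name = if (is.null(nm)) id else nm,
               k = k, K_set = K_set, n_sig = n_sig, N = N,
               p_hyper = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no testable sets", call. = FALSE)
  out <- do.call(rbind, rows)
  out$holm_adjusted_p <- stats::p.adjust(out$p_hyper, method = "holm")
  out <- out[order(out$p_hyper), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
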