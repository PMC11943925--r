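#' Reference a spectrum to the TSP peak at 0.0 ppm
#'
#' Shifts the ppm axis so that the intensity maximum inside the search window
#' (where the TSP internal standard resonates) sits exactly at 0.000 ppm.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param search_window Length-2 numeric, ppm interval to search (default
#'   `c(0.3, -0.3)`); must contain at least one data point and is assumed to
#'   hold a single dominant peak.
#' @return The referenced `nmr_spectrum`; the applied shift (ppm added to the
#'   axis) is attached as attribute `"shift"`.
#' @export
reference_to_tsp <- function(spectrum, search_window = c(0.3, -0.3)) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  hi <- max(search_window); lo <- min(search_window)
  in_win <- spectrum$ppm <= hi & spectrum$ppm >= lo
  if (!any(in_win))
    stop("TSP search window contains no data points", call. = FALSE)
  peak_ppm <- spectrum$ppm[in_win][which.max(spectrum$intensity[in_win])]
  out <- spectrum
  out$ppm <- spectrum$ppm - peak_ppm
  attr(out, "shift") <- -peak_ppm
  out
}

#' Integrate a spectrum over a bucket scheme
#'
#' Each bucket value is the trapezoidal integral of intensity over the
#' bucket's ppm interval on the native grid, with intensities interpolated at
#' the two boundaries. Numerically negative integrals (baseline artifacts)
#' are clipped to 0 with a warning.
#'
#' @param spectrum An `nmr_spectrum` whose ppm range covers every bucket.
#' @param scheme A `bucket_scheme`.
#' @return Named numeric vector of bucket integrals, in scheme order.
#' @export
integrate_buckets <- function(spectrum, scheme) {
  stopifnot(inherits(spectrum, "nmr_spectrum"),
            inherits(scheme, "bucket_scheme"))
  # work on ascending axis for interpolation/integration
  ppm <- rev(spectrum$ppm)
  y <- rev(spectrum$intensity)
  lo <- min(ppm); hi <- max(ppm)
  b <- scheme$buckets
  out <- numeric(nrow(b))
  clipped <- character(0)
  for (i in seq_len(nrow(b))) {
    l <- b$right_ppm[i]; r <- b$left_ppm[i]   # ascending-axis endpoints
    if (l < lo || r > hi)
      stop("bucket outside spectral range: ", b$bucket_id[i], call. = FALSE)
    inner <- ppm[ppm > l & ppm < r]
    xs <- c(l, inner, r)
    ys <- stats::approx(ppm, y, xout = xs, rule = 1)$y
    v <- sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
    if (v < 0) { clipped <- c(clipped, b$bucket_id[i]); v <- 0 }
    out[i] <- v
  }
  if (length(clipped) > 0)
    warning("negative integral clipped to 0 for bucket(s): ",
            paste(clipped, collapse = ", "), call. = FALSE)
  names(out) <- b$bucket_id
  out
}

#' Bucket a collection of spectra into a bucket table
#'
#' @param spectra List of `nmr_spectrum` objects carrying group/week metadata.
#' @param scheme A `bucket_scheme`.
#' @param reference If `TRUE` (default), each spectrum is TSP-referenced
#'   before integration.
#' @return An unnormalized `bucket_table` (one row per spectrum).
#' @export
bucket_spectra <- function(spectra, scheme, reference = TRUE) {
  stopifnot(length(spectra) > 0)
  rows <- lapply(spectra, function(sp) {
    if (reference) sp <- reference_to_tsp(sp)
    integrate_buckets(sp, scheme)
  })
  values <- do.call(rbind, rows)
  bucket_table(values,
               group = vapply(spectra, `[[`, character(1), "group"),
               week = vapply(spectra, `[[`, integer(1), "week"),
               sample_id = vapply(spectra, `[[`, character(1), "sample_id"),
               normalized = FALSE)
}

#' Normalize each spectrum's buckets to total intensity
#'
#' Divides every row by its own sum so row totals equal 1 — the constant is
#' immaterial for the scale-invariant statistics downstream, and 1 gives the
#' cleanest invariant. Idempotent: normalizing a normalized table changes
#' nothing.
#'
#' @param table A `bucket_table` with strictly positive row sums.
#' @return The normalized `bucket_table` (`normalized = TRUE`).
#' @export
normalize_total_intensity <- function(table) {
  stopifnot(inherits(table, "bucket_table"))
  rs <- rowSums(table$values)
  zero <- which(rs <= 0)
  if (length(zero) > 0)
    stop("all-zero row for sample: ",
         paste(table$sample_id[zero], collapse = ", "), call. = FALSE)
  bucket_table(table$values / rs, group = table$group, week = table$week,
               sample_id = table$sample_id, normalized = TRUE)
}
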