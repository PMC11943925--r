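#' Default urine metabolite library for the cohort generator
#'
#' A long-format table, one row per resonance line: `metabolite`, `ppm`
#' (line center), `rel_intensity` (proton-count-like weight),
#' `baseline_log_mean` and `baseline_log_sd` (log-normal concentration
#' model), `affected` (whether the study-group effect trajectory applies).
#' The shipped default has 114 lines — 32 named urine metabolites with
#' literature-style shift positions plus unassigned singlets, spaced so that
#' one 0.04-ppm bucket per line never overlaps. The shift values are
#' illustrative configuration for simulation, not measured data; the file is
#' editable and any table with these columns can be supplied instead.
#'
#' @param file Path to a library TSV; default is the file shipped with the
#'   package.
#' @return Data frame with the columns above.
#' @export
read_metabolite_library <- function(file = system.file(
  "extdata", "metabolite_library.tsv", package = "uromet")) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("metabolite", "ppm", "rel_intensity", "baseline_log_mean",
            "baseline_log_sd", "affected")
  if (!all(need %in% names(df)))
    stop("library needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$rel_intensity <= 0))
    stop("relative intensities must be positive", call. = FALSE)
  if (any(df$ppm < 0.5 | df$ppm > 9.5))
    stop("line positions must lie within 0.5-9.5 ppm", call. = FALSE)
  df$affected <- as.logical(df$affected)
  df
}

#' Default exclusion regions for urine spectra
#'
#' Water (5.00-4.50 ppm), urea (6.20-5.40 ppm) and the TSP reference region
#' (0.20 to -0.20 ppm) — standard regions removed from urine NMR analyses.
#'
#' @return Data frame with columns `left_ppm`, `right_ppm`.
#' @export
default_exclusions <- function() {
  data.frame(left_ppm = c(5.00, 6.20, 0.20),
             right_ppm = c(4.50, 5.40, -0.20))
}

#' Bucket scheme derived from a metabolite library
#'
#' One bucket of the given width centered on every resonance line, with
#' bucket ids `B<ppm>`; the library's spacing guarantees no overlap.
#'
#' @param library A metabolite library data frame
#'   (see [read_metabolite_library()]).
#' @param width Bucket width in ppm (default 0.04).
#' @param exclusions Exclusion regions (default [default_exclusions()]).
#' @return A `bucket_scheme` with one bucket per library line, in ascending
#'   line order matching the library rows.
#' @export
scheme_from_library <- function(library, width = 0.04,
                                exclusions = default_exclusions()) {
  b <- data.frame(bucket_id = sprintf("B%.3f", library$ppm),
                  left_ppm = library$ppm + width / 2,
                  right_ppm = library$ppm - width / 2)
  bucket_scheme(b, exclusions)
}

#' Bucket-to-metabolite annotation derived from a metabolite library
#'
#' @inheritParams scheme_from_library
#' @return Data frame with columns `bucket_id`, `metabolite`, matching the
#'   scheme produced by [scheme_from_library()].
#' @export
annotation_from_library <- function(library) {
  data.frame(bucket_id = sprintf("B%.3f", library$ppm),
             metabolite = library$metabolite, stringsAsFactors = FALSE)
}

#' Describe a synthetic two-group longitudinal urine-NMR cohort
#'
#' Bundles everything the generator needs: the metabolite library, the
#' collection weeks, the multiplicative effect trajectory applied to affected
#' metabolites in the study group, group sizes, noise and line-shape
#' parameters, and the master seed. The defaults encode the study design the
#' pipeline targets: two groups at weeks 1/3/5/7 with an effect that rises
#' to a peak at weeks 3-5 and attenuates at week 7.
#'
#' @param metabolites Metabolite library data frame (default: shipped
#'   library).
#' @param weeks Integer vector of collection weeks.
#' @param effect_trajectory Named numeric vector, week -> multiplicative fold
#'   applied to affected metabolites' study-group concentrations.
#' @param n_control,n_study Group sizes (>= 3); scalars or one value per
#'   week.
#' @param noise_sd Additive noise, as a fraction of the median resonance
#'   scale (default 0.01 = 1%).
#' @param shift_jitter_sd Per-sample, per-line chemical-shift jitter SD in
#'   ppm (default 0.002).
#' @param linewidth Lorentzian full width at half maximum in ppm (default
#'   0.0017, about 1 Hz at 600 MHz).
#' @param seed Master seed; together with the design it determines every
#'   generated spectrum, table and truth record.
#' @return Object of class `synthetic_design`.
#' @export
synthetic_design <- function(metabolites = read_metabolite_library(),
                             weeks = c(1L, 3L, 5L, 7L),
                             effect_trajectory = c(`1` = 1.2, `3` = 1.6,
                                                   `5` = 1.5, `7` = 1.1),
                             n_control = 15, n_study = 15,
                             noise_sd = 0.01, shift_jitter_sd = 0.002,
                             linewidth = 0.0017, seed = 1L) {
  weeks <- as.integer(weeks)
  if (!all(as.character(weeks) %in% names(effect_trajectory)))
    stop("effect_trajectory must name every week", call. = FALSE)
  if (any(!is.finite(effect_trajectory)) || any(effect_trajectory <= 0))
    stop("effect folds must be positive and finite", call. = FALSE)
  if (length(n_control) == 1) n_control <- rep(n_control, length(weeks))
  if (length(n_study) == 1) n_study <- rep(n_study, length(weeks))
  if (any(n_control < 3) || any(n_study < 3))
    stop("group sizes must be >= 3", call. = FALSE)
  stopifnot(is.finite(noise_sd), noise_sd >= 0,
            is.finite(shift_jitter_sd), shift_jitter_sd >= 0,
            is.finite(linewidth), linewidth > 0)
  structure(
    list(metabolites = metabolites, weeks = weeks,
         effect_trajectory = effect_trajectory,
         n_control = as.integer(n_control), n_study = as.integer(n_study),
         noise_sd = noise_sd, shift_jitter_sd = shift_jitter_sd,
         linewidth = linewidth, seed = as.integer(seed)),
    class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(
    "<synthetic_design> %d metabolites (%d lines, %d affected), weeks %s\n",
    length(unique(x$metabolites$metabolite)), nrow(x$metabolites),
    length(unique(x$metabolites$metabolite[x$metabolites$affected])),
    paste(x$weeks, collapse = ",")))
  cat(sprintf("  folds: %s; n = %s/%s; noise %.3g, jitter %.3g ppm, seed %d\n",
              paste(x$effect_trajectory[as.character(x$weeks)],
                    collapse = ","),
              paste(x$n_control, collapse = ","),
              paste(x$n_study, collapse = ","), x$noise_sd,
              x$shift_jitter_sd, x$seed))
  invisible(x)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Render one synthetic spectrum from metabolite concentrations
#'
#' Sum of unit-area Lorentzian lines (one per library line, height scaled by
#' concentration times relative intensity) on a uniform ppm grid, with
#' optional per-line chemical-shift jitter and additive Gaussian noise scaled
#' to the median peak height. Draws (jitter, noise) come from the current
#' R random-number state, so seeding before the call makes the spectrum
#' fully reproducible.
#'
#' @param concentrations Named numeric vector, one concentration per
#'   metabolite in the design's library.
#' @param design A `synthetic_design` (supplies library, linewidth, jitter
#'   and noise levels).
#' @param n_points Grid size over 0.5-9.5 ppm (default 2^15); must give at
#'   least 4 points per linewidth.
#' @inheritParams nmr_spectrum
#' @return An `nmr_spectrum`.
#' @export
generate_spectrum <- function(concentrations, design, n_points = 2^15,
                              sample_id = "synthetic",
                              group = "control", week = 1L) {
  stopifnot(inherits(design, "synthetic_design"))
  lib <- design$metabolites
  conc <- concentrations[lib$metabolite]
  if (anyNA(conc))
    stop("concentrations must name every library metabolite", call. = FALSE)
  grid <- seq(0.5, 9.5, length.out = n_points)
  dg <- grid[2] - grid[1]
  if (dg > design$linewidth / 4)
    stop("grid too coarse: need at least 4 points per linewidth",
         call. = FALSE)
  hw <- design$linewidth / 2
  jitter <- stats::rnorm(nrow(lib), 0, design$shift_jitter_sd)
  y <- numeric(n_points)
  amp <- conc * lib$rel_intensity
  for (j in which(amp > 0)) {
    x0 <- lib$ppm[j] + jitter[j]
    y <- y + amp[j] * (hw / pi) / ((grid - x0)^2 + hw^2)
  }
  heights <- amp / (pi * hw)
  med_h <- stats::median(heights[heights > 0])
  if (length(med_h) == 1 && is.finite(med_h) && design$noise_sd > 0)
    y <- y + stats::rnorm(n_points, 0, design$noise_sd * med_h)
  nmr_spectrum(grid, y, sample_id = sample_id, group = group, week = week)
}

# Lorentzian mass of each library line inside each nearby bucket, for one
# sample's jittered line positions. `pairs` is the precomputed line/bucket
# neighbour list.
lorentzian_bucket_mass <- function(x0, pairs, hw) {
  (atan((pairs$left - x0[pairs$line]) / hw) -
   atan((pairs$right - x0[pairs$line]) / hw)) / pi
}

line_bucket_pairs <- function(lib, scheme, window = 0.2) {
  b <- scheme$buckets
  out <- lapply(seq_len(nrow(lib)), function(j) {
    near <- which(abs((b$left_ppm + b$right_ppm) / 2 - lib$ppm[j]) <= window)
    data.frame(line = j, bucket = near,
               left = b$left_ppm[near], right = b$right_ppm[near])
  })
  do.call(rbind, out)
}

# one week's unnormalized bucket table + per-sample true concentrations
generate_week <- function(design, week, seed, scheme = NULL, pairs = NULL) {
  lib <- design$metabolites
  if (is.null(scheme)) scheme <- scheme_from_library(lib)
  if (is.null(pairs)) pairs <- line_bucket_pairs(lib, scheme)
  wi <- match(week, design$weeks)
  n1 <- design$n_control[wi]; n2 <- design$n_study[wi]
  n <- n1 + n2
  group <- rep(c("control", "study"), c(n1, n2))
  mets <- unique(lib$metabolite)
  mrow <- match(mets, lib$metabolite)   # first library row per metabolite
  fold <- design$effect_trajectory[[as.character(week)]]
  hw <- design$linewidth / 2
  K <- nrow(scheme$buckets)
  # deterministic noise scale: median per-line expected mass at baseline
  base_amp <- exp(lib$baseline_log_mean) * lib$rel_intensity
  noise_scale <- design$noise_sd * stats::median(base_amp)
  with_seed(seed, {
    conc <- matrix(stats::rlnorm(n * length(mets),
                                 rep(lib$baseline_log_mean[mrow], each = n),
                                 rep(lib$baseline_log_sd[mrow], each = n)),
                   n, length(mets), dimnames = list(NULL, mets))
    aff <- mets[lib$affected[mrow]]
    conc[group == "study", aff] <- conc[group == "study", aff] * fold
    amp <- conc[, lib$metabolite, drop = FALSE] *
      rep(lib$rel_intensity, each = n)        # n x lines
    jit <- matrix(stats::rnorm(n * nrow(lib), 0, design$shift_jitter_sd),
                  n, nrow(lib))
    vals <- matrix(0, n, K)
    for (i in seq_len(n)) {
      mass <- lorentzian_bucket_mass(lib$ppm + jit[i, ], pairs, hw)
      vals[i, ] <- unname(
        rowsum(mass * amp[i, pairs$line], pairs$bucket)[, 1])
    }
    if (noise_scale > 0)
      vals <- vals + matrix(stats::rnorm(n * K, 0, noise_scale), n, K)
    vals[vals < 0] <- 0
    tab <- bucket_table(vals, group = group, week = week,
                        sample_id = sprintf("w%d_%s%02d", week,
                                            ifelse(group == "control",
                                                   "c", "s"),
                                            c(seq_len(n1), seq_len(n2))),
                        normalized = FALSE)
    colnames(tab$values) <- scheme$buckets$bucket_id
    tab$bucket_ids <- scheme$buckets$bucket_id
    list(table = tab, concentrations = conc)
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Control-group concentrations are drawn log-normal per metabolite; study
#' samples of affected metabolites are multiplied by the week's effect fold.
#' Bucket values are the analytic Lorentzian line masses inside each bucket
#' (jittered line positions, contributions of all lines within 0.2 ppm of a
#' bucket), plus additive Gaussian noise, clipped at zero. Everything is
#' determined by the design's master seed.
#'
#' @param design A `synthetic_design`.
#' @param output `"table"` (default, fast analytic bucket tables) or
#'   `"spectra"` (full rendered spectra via [generate_spectrum()], which the
#'   bucketing stage can then integrate).
#' @return List with elements `tables` (named list of unnormalized
#'   `bucket_table`s, one per week; or `spectra`, a list of spectrum lists),
#'   `truth` (list: `concentrations` per week, `affected_metabolites`,
#'   `affected_buckets`), `scheme`, `annotation`.
#' @export
generate_cohort <- function(design, output = c("table", "spectra")) {
  stopifnot(inherits(design, "synthetic_design"))
  output <- match.arg(output)
  lib <- design$metabolites
  scheme <- scheme_from_library(lib)
  ann <- annotation_from_library(lib)
  aff_met <- unique(lib$metabolite[lib$affected])
  aff_buckets <- ann$bucket_id[ann$metabolite %in% aff_met]
  truth <- list(concentrations = list(), affected_metabolites = aff_met,
                affected_buckets = aff_buckets)
  out <- list()
  if (output == "table") {
    pairs <- line_bucket_pairs(lib, scheme)
    for (w in design$weeks) {
      g <- generate_week(design, w, seed = design$seed + 1000L * w,
                         scheme = scheme, pairs = pairs)
      out[[as.character(w)]] <- g$table
      truth$concentrations[[as.character(w)]] <- g$concentrations
    }
    list(tables = out, truth = truth, scheme = scheme, annotation = ann)
  } else {
    for (w in design$weeks) {
      g <- generate_week(design, w, seed = design$seed + 1000L * w,
                         scheme = scheme)
      conc <- g$concentrations
      sp <- with_seed(design$seed + 1000L * w + 1L, {
        lapply(seq_len(nrow(conc)), function(i)
          generate_spectrum(conc[i, ], design,
                            sample_id = g$table$sample_id[i],
                            group = g$table$group[i], week = w))
      })
      out[[as.character(w)]] <- sp
      truth$concentrations[[as.character(w)]] <- conc
    }
    list(spectra = out, truth = truth, scheme = scheme, annotation = ann)
  }
}

#' Family-wise false-positive rate of the screening under a null design
#'
#' Repeatedly generates null cohorts (all effect folds 1), runs the
#' Bonferroni-controlled per-bucket screening on one week, and reports the
#' fraction of replicates with at least one significant bucket — the
#' family-wise error the correction is meant to cap at `alpha_total`.
#'
#' @param design A null `synthetic_design` (every effect fold exactly 1).
#' @param n_reps Number of replicates (>= 1; use >= 200 for a stable rate).
#' @param alpha_total Family-wise alpha passed to [compare_buckets()].
#' @param week Which design week to simulate (default the first).
#' @return List with `rate`, `se` (binomial standard error), `n_reps`.
#' @export
estimate_type1_error <- function(design, n_reps, alpha_total = 0.05,
                                 week = design$weeks[1]) {
  stopifnot(inherits(design, "synthetic_design"))
  if (any(design$effect_trajectory != 1))
    stop("type-I error estimation requires a null design (all folds 1)",
         call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  scheme <- scheme_from_library(design$metabolites)
  pairs <- line_bucket_pairs(design$metabolites, scheme)
  hits <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    g <- generate_week(design, week, seed = design$seed + r,
                       scheme = scheme, pairs = pairs)
    cmp <- compare_buckets(normalize_total_intensity(g$table),
                           alpha_total = alpha_total)
    hits[r] <- cmp$n_significant > 0
  }
  rate <- mean(hits)
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_reps), n_reps = n_reps)
}

#' Per-metabolite detection power of the screening
#'
#' Repeatedly generates cohorts from an effect design and reports, for each
#' affected metabolite, the fraction of replicates in which any of its
#' buckets is flagged significant by the Bonferroni-controlled screen.
#'
#' @param design A `synthetic_design` with at least one affected metabolite.
#' @param n_reps Number of replicates.
#' @param alpha_total Family-wise alpha.
#' @param week Which design week to simulate (default: the week with the
#'   largest effect fold).
#' @return Named numeric vector of detection rates per affected metabolite,
#'   with attributes `n_reps` and `se` (binomial SEs).
#' @export
estimate_power <- function(design, n_reps, alpha_total = 0.05,
                           week = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  lib <- design$metabolites
  aff <- unique(lib$metabolite[lib$affected])
  if (length(aff) == 0)
    stop("design has no affected metabolites", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (is.null(week)) {
    tr <- design$effect_trajectory[as.character(design$weeks)]
    week <- design$weeks[which.max(abs(log(tr)))]
  }
  scheme <- scheme_from_library(lib)
  pairs <- line_bucket_pairs(lib, scheme)
  ann <- annotation_from_library(lib)
  det <- matrix(FALSE, n_reps, length(aff),
                dimnames = list(NULL, aff))
  for (r in seq_len(n_reps)) {
    g <- generate_week(design, week, seed = design$seed + r,
                       scheme = scheme, pairs = pairs)
    cmp <- compare_buckets(normalize_total_intensity(g$table),
                           alpha_total = alpha_total)
    sig_buckets <- cmp$buckets$bucket_id[cmp$buckets$significant_p]
    sig_met <- unique(ann$metabolite[ann$bucket_id %in% sig_buckets])
    det[r, ] <- aff %in% sig_met
  }
  rates <- colMeans(det)
  structure(rates, n_reps = n_reps,
            se = sqrt(rates * (1 - rates) / n_reps))
}
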