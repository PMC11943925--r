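#' Construct a 1D NMR spectrum object
#'
#' A spectrum is a ppm axis (stored in descending order, the NMR display
#' convention, with TSP at 0.0 ppm) and one intensity per point, plus the
#' sample metadata the downstream statistics need (group and collection week).
#'
#' @param ppm Numeric vector of chemical shifts (ppm). Any strictly monotonic
#'   order is accepted; the constructor re-sorts to descending ppm and carries
#'   the intensities along.
#' @param intensity Numeric vector of intensities, same length as `ppm`.
#' @param sample_id Character scalar identifying the sample.
#' @param group `"control"` or `"study"`.
#' @param week Integer collection week (the study design uses 1, 3, 5, 7, but
#'   any integer is accepted).
#' @return An object of class `nmr_spectrum`: a list with elements
#'   `sample_id`, `group`, `week`, `ppm`, `intensity`.
#' @examples
#' sp <- nmr_spectrum(c(10, 5, 0), c(0, 2, 0), "s1", "control", 1)
#' sp$ppm
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id = "sample",
                         group = c("control", "study"), week = 1L) {
  group <- match.arg(group)
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have equal length", call. = FALSE)
  if (length(ppm) < 2)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(ppm) || anyNA(intensity) || any(!is.finite(intensity)))
    stop("ppm and intensity must be finite", call. = FALSE)
  d <- diff(ppm)
  if (any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotonic", call. = FALSE)
  if (d[1] > 0) {               # ascending input: flip to descending
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  }
  structure(
    list(sample_id = as.character(sample_id), group = group,
         week = as.integer(week), ppm = ppm, intensity = intensity),
    class = "nmr_spectrum"
  )
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s (%s, week %d): %d points, %.3f to %.3f ppm\n",
              x$sample_id, x$group, x$week, length(x$ppm),
              max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' Read a spectrum from two-column text
#'
#' Parses plain two-column text (ppm, intensity), whitespace- or
#' comma-delimited, with `#` comment lines. The ppm axis is re-sorted to
#' descending order if needed.
#'
#' @param file Path or connection to the text file.
#' @inheritParams nmr_spectrum
#' @return An `nmr_spectrum`.
#' @export
read_spectrum <- function(file, sample_id = "sample",
                          group = c("control", "study"), week = 1L) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) < 2)
    stop("spectrum file has fewer than 2 data points", call. = FALSE)
  ppm <- numeric(length(idx)); intensity <- numeric(length(idx))
  for (i in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[i]]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) != 2 || anyNA(vals))
      stop(sprintf("cannot parse spectrum line %d: '%s'",
                   idx[i], lines[idx[i]]), call. = FALSE)
    ppm[i] <- vals[1]; intensity[i] <- vals[2]
  }
  nmr_spectrum(ppm, intensity, sample_id = sample_id,
               group = group, week = week)
}

#' Write a spectrum as two-column text
#'
#' @param spectrum An `nmr_spectrum`.
#' @param file Path or connection.
#' @return Invisibly, `file`.
#' @export
write_spectrum <- function(spectrum, file) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  writeLines(sprintf("%.17g %.17g", spectrum$ppm, spectrum$intensity), file)
  invisible(file)
}

#' Construct a bucket table
#'
#' The central exchange object of the pipeline: a samples-by-buckets matrix of
#' non-negative integrated intensities with group/week metadata and a flag
#' recording whether rows have been normalized to unit total intensity.
#'
#' @param values Numeric matrix, samples in rows, buckets in columns. Column
#'   names are the bucket ids; row names (or `sample_id`) the sample ids.
#' @param group Character vector, `"control"`/`"study"` per sample.
#' @param week Integer vector (or scalar) of collection weeks per sample.
#' @param sample_id Character vector of unique sample ids.
#' @param normalized Logical flag; if `TRUE` every row must sum to 1 within
#'   `1e-9`.
#' @return Object of class `bucket_table`: list with `values`, `sample_id`,
#'   `group`, `week`, `bucket_ids`, `normalized`.
#' @export
bucket_table <- function(values, group, week, sample_id = rownames(values),
                         normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(sample_id)) sample_id <- sprintf("sample%d", seq_len(n))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  if (length(group) == 1) group <- rep(group, n)
  if (length(week) == 1) week <- rep(week, n)
  if (length(group) != n || length(week) != n || length(sample_id) != n)
    stop("metadata length does not match number of rows", call. = FALSE)
  if (!all(group %in% c("control", "study")))
    stop("group must be 'control' or 'study'", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("bucket values must be finite", call. = FALSE)
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative bucket value at sample '%s', bucket '%s'",
                 sample_id[neg[1, 1]], colnames(values)[neg[1, 2]]),
         call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("bucket%d", seq_len(ncol(values)))
  rownames(values) <- sample_id
  if (isTRUE(normalized) && n > 0 &&
      any(abs(rowSums(values) - 1) > 1e-9))
    stop("normalized flag set but row sums differ from 1", call. = FALSE)
  structure(
    list(values = values, sample_id = sample_id,
         group = as.character(group), week = as.integer(week),
         bucket_ids = colnames(values), normalized = isTRUE(normalized)),
    class = "bucket_table"
  )
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf(
    "<bucket_table> %d samples x %d buckets (%s), weeks: %s, groups: %s\n",
    nrow(x$values), ncol(x$values),
    if (x$normalized) "normalized" else "unnormalized",
    paste(sort(unique(x$week)), collapse = ","),
    paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
          collapse = ", ")))
  invisible(x)
}

#' @export
dim.bucket_table <- function(x) dim(x$values)

#' Read a bucket table from CSV/TSV
#'
#' Expects a header row with metadata columns `sample_id`, `group`, `week`
#' followed by one numeric column per bucket. Deposited tables that use other
#' metadata column names (e.g. a public archive's layout) are ingested by
#' remapping via `col_map`.
#'
#' @param file Path or connection.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @param col_map Named character vector remapping metadata columns, e.g.
#'   `c(sample_id = "Sample", group = "Class", week = "Timepoint")`.
#' @param group_map Optional named character vector translating group labels
#'   found in the file to `"control"`/`"study"`, e.g.
#'   `c(sham = "control", orthotopic = "study")`.
#' @return A `bucket_table` with `normalized = FALSE`.
#' @export
read_bucket_table <- function(file, sep = ",",
                              col_map = c(sample_id = "sample_id",
                                          group = "group", week = "week"),
                              group_map = NULL) {
  need <- c("sample_id", "group", "week")
  if (!all(need %in% names(col_map)))
    stop("col_map must name sample_id, group and week columns", call. = FALSE)
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(col_map[need]), names(df))
  if (length(missing_cols) > 0)
    stop("metadata column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  meta <- df[, unname(col_map[need]), drop = FALSE]
  names(meta) <- need
  if (!is.null(group_map)) {
    mapped <- group_map[as.character(meta$group)]
    if (anyNA(mapped))
      stop("group_map does not cover label(s): ",
           paste(unique(meta$group[is.na(mapped)]), collapse = ", "),
           call. = FALSE)
    meta$group <- unname(mapped)
  }
  vcols <- setdiff(names(df), unname(col_map[need]))
  if (nrow(df) == 0) {
    vm <- matrix(numeric(0), 0, length(vcols),
                 dimnames = list(NULL, vcols))
    return(bucket_table(vm, group = character(0), week = integer(0),
                        sample_id = character(0), normalized = FALSE))
  }
  vals <- df[, vcols, drop = FALSE]
  nonnum <- vcols[!vapply(vals, is.numeric, logical(1))]
  if (length(nonnum) > 0)
    stop("non-numeric bucket column(s): ", paste(nonnum, collapse = ", "),
         call. = FALSE)
  bucket_table(as.matrix(vals), group = meta$group, week = meta$week,
               sample_id = meta$sample_id, normalized = FALSE)
}

#' Write a bucket table to CSV
#'
#' Values are written with 17 significant digits so that a write/read
#' roundtrip is bit-stable.
#'
#' @param table A `bucket_table`.
#' @param file Path or connection.
#' @param sep Field separator.
#' @return Invisibly, `file`.
#' @export
write_bucket_table <- function(table, file, sep = ",") {
  stopifnot(inherits(table, "bucket_table"))
  header <- paste(c("sample_id", "group", "week", table$bucket_ids),
                  collapse = sep)
  if (nrow(table$values) == 0) {
    writeLines(header, file)
    return(invisible(file))
  }
  body <- vapply(seq_len(nrow(table$values)), function(i) {
    paste(c(table$sample_id[i], table$group[i], table$week[i],
            sprintf("%.17g", table$values[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Construct a bucket scheme
#'
#' Bucket boundaries follow the NMR display convention: descending ppm, so
#' each bucket has `left_ppm > right_ppm` and covers the closed-left /
#' open-right interval `[left_ppm, right_ppm)` on the descending axis (the
#' left edge belongs to the bucket, the right edge to its neighbour).
#'
#' @param buckets Data frame with columns `bucket_id`, `left_ppm`,
#'   `right_ppm`.
#' @param exclusions Optional data frame with columns `left_ppm`, `right_ppm`
#'   of regions (water, urea, TSP) no bucket may intersect.
#' @return Object of class `bucket_scheme`.
#' @export
bucket_scheme <- function(buckets, exclusions = NULL) {
  buckets <- as.data.frame(buckets)
  stopifnot(all(c("bucket_id", "left_ppm", "right_ppm") %in% names(buckets)))
  buckets$bucket_id <- as.character(buckets$bucket_id)
  if (anyDuplicated(buckets$bucket_id))
    stop("duplicate bucket_id in scheme", call. = FALSE)
  bad <- buckets$bucket_id[buckets$left_ppm <= buckets$right_ppm]
  if (length(bad) > 0)
    stop("inverted interval (left_ppm must exceed right_ppm) for bucket: ",
         paste(bad, collapse = ", "), call. = FALSE)
  # pairwise overlap: sort by left edge descending, check neighbours
  o <- order(buckets$left_ppm, decreasing = TRUE)
  b <- buckets[o, ]
  if (nrow(b) > 1) {
    ov <- which(b$right_ppm[-nrow(b)] < b$left_ppm[-1])
    if (length(ov) > 0)
      stop("overlapping buckets: ",
           paste(b$bucket_id[ov[1]], b$bucket_id[ov[1] + 1], sep = " / "),
           call. = FALSE)
  }
  if (!is.null(exclusions) && nrow(as.data.frame(exclusions)) > 0) {
    exclusions <- as.data.frame(exclusions)
    stopifnot(all(c("left_ppm", "right_ppm") %in% names(exclusions)))
    if (any(exclusions$left_ppm <= exclusions$right_ppm))
      stop("inverted exclusion interval", call. = FALSE)
    for (i in seq_len(nrow(exclusions))) {
      hit <- buckets$bucket_id[buckets$left_ppm > exclusions$right_ppm[i] &
                               buckets$right_ppm < exclusions$left_ppm[i]]
      if (length(hit) > 0)
        stop("bucket intersects exclusion region: ",
             paste(hit, collapse = ", "), call. = FALSE)
    }
  } else {
    exclusions <- data.frame(left_ppm = numeric(0), right_ppm = numeric(0))
  }
  structure(list(buckets = buckets,
                 exclusions = exclusions[, c("left_ppm", "right_ppm")]),
            class = "bucket_scheme")
}

#' @export
print.bucket_scheme <- function(x, ...) {
  cat(sprintf("<bucket_scheme> %d buckets, %d exclusion region(s)\n",
              nrow(x$buckets), nrow(x$exclusions)))
  invisible(x)
}

#' Load a bucket scheme from YAML
#'
#' The file lists buckets (`id`, `left`, `right` in ppm, descending-ppm
#' convention) and optional `exclusions` as `[left, right]` pairs:
#' ```yaml
#' buckets:
#'   - {id: B1.33, left: 1.35, right: 1.31}
#' exclusions:
#'   - [5.00, 4.50]
#' ```
#'
#' @param file Path to the YAML file.
#' @return A validated `bucket_scheme`.
#' @export
load_bucket_scheme <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$buckets) || length(cfg$buckets) == 0)
    stop("scheme file lists no buckets", call. = FALSE)
  buckets <- do.call(rbind, lapply(cfg$buckets, function(b) {
    if (is.null(b$id) || is.null(b$left) || is.null(b$right))
      stop("each bucket needs id, left and right", call. = FALSE)
    data.frame(bucket_id = as.character(b$id),
               left_ppm = as.numeric(b$left),
               right_ppm = as.numeric(b$right))
  }))
  exclusions <- NULL
  if (!is.null(cfg$exclusions) && length(cfg$exclusions) > 0) {
    exclusions <- do.call(rbind, lapply(cfg$exclusions, function(e)
      data.frame(left_ppm = as.numeric(e[[1]]),
                 right_ppm = as.numeric(e[[2]]))))
  }
  bucket_scheme(buckets, exclusions)
}

#' Read a bucket-to-metabolite annotation table
#'
#' Two-column (plus optional free-text confidence note) TSV mapping
#' `bucket_id` to a metabolite name; many buckets may map to one metabolite.
#'
#' @param file Path to the TSV.
#' @param scheme Optional `bucket_scheme`; if given, every annotated
#'   bucket_id must exist in the scheme.
#' @return Data frame with columns `bucket_id`, `metabolite` and, when
#'   present in the file, `note`.
#' @export
read_annotation <- function(file, scheme = NULL) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (!all(c("bucket_id", "metabolite") %in% names(df)))
    stop("annotation needs columns bucket_id and metabolite", call. = FALSE)
  df$bucket_id <- as.character(df$bucket_id)
  df$metabolite <- as.character(df$metabolite)
  if (anyDuplicated(df$bucket_id))
    stop("duplicate bucket_id in annotation", call. = FALSE)
  if (!is.null(scheme)) {
    unknown <- setdiff(df$bucket_id, scheme$buckets$bucket_id)
    if (length(unknown) > 0)
      stop("annotated bucket_id not in scheme: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a metabolite-set library
#'
#' TSV with columns `set_id`, `set_name`, `members` (comma-separated
#' metabolite names), one pathway/set per row.
#'
#' @param file Path to the TSV.
#' @return Named list of sets; each element carries a `set_name` attribute
#'   and is a character vector of unique member metabolite names.
#' @export
read_metabolite_sets <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (!all(c("set_id", "set_name", "members") %in% names(df)))
    stop("set library needs columns set_id, set_name, members",
         call. = FALSE)
  sets <- lapply(seq_len(nrow(df)), function(i) {
    members <- trimws(strsplit(df$members[i], ",")[[1]])
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop("empty metabolite set: ", df$set_id[i], call. = FALSE)
    if (anyDuplicated(members))
      stop("duplicate members in set: ", df$set_id[i], call. = FALSE)
    structure(members, set_name = df$set_name[i])
  })
  names(sets) <- df$set_id
  sets
}

#' Subset a bucket table to one collection week
#'
#' @param table A `bucket_table`.
#' @param week Integer week to keep.
#' @return A `bucket_table` containing only that week's samples.
#' @export
subset_week <- function(table, week) {
  stopifnot(inherits(table, "bucket_table"))
  keep <- table$week == week
  if (!any(keep)) stop("no samples for week ", week, call. = FALSE)
  bucket_table(table$values[keep, , drop = FALSE],
               group = table$group[keep], week = table$week[keep],
               sample_id = table$sample_id[keep],
               normalized = table$normalized)
}
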