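#!/usr/bin/env Rscript
# Slot for re-analyzing a deposited binned-urine-NMR CSV (one row per sample,
# metadata columns then bucket columns). Not run by the test suite: it needs
# the external download. Point --table at the deposited file and remap the
# metadata column names / group labels to match its layout.
#
# Usage:
#   Rscript scripts/soft_validation.R --table binned.csv \
#     --sample-col Sample --group-col Class --week-col Week \
#     --control-label sham --study-label orthotopic --out report/

suppressPackageStartupMessages({
  library(optparse)
  library(uromet)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--table", type = "character"),
  make_option("--sample-col", type = "character", default = "sample_id"),
  make_option("--group-col", type = "character", default = "group"),
  make_option("--week-col", type = "character", default = "week"),
  make_option("--control-label", type = "character", default = "control"),
  make_option("--study-label", type = "character", default = "study"),
  make_option("--annotation", type = "character", default = NULL),
  make_option("--out", type = "character", default = "report")
)))
if (is.null(opts$table)) stop("--table is required")

gm <- c("control", "study")
names(gm) <- c(opts$`control-label`, opts$`study-label`)
tab <- read_bucket_table(opts$table,
                         col_map = c(sample_id = opts$`sample-col`,
                                     group = opts$`group-col`,
                                     week = opts$`week-col`),
                         group_map = gm)
ann <- if (!is.null(opts$annotation)) read_annotation(opts$annotation)
dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)

for (w in sort(unique(tab$week))) {
  tp <- run_timepoint(subset_week(tab, w), annotation = ann)
  print(tp)
  write_timepoint_json(tp, file.path(opts$out, sprintf("week%d.json", w)))
}
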