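test_that("spectra parse from two-column text and re-sort to descending ppm", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "10.0 0", "5.0 2", "0.0 0"), f)
  sp <- read_spectrum(f, "s1", "control", 1)
  expect_s3_class(sp, "nmr_spectrum")
  expect_equal(sp$ppm, c(10, 5, 0))
  expect_equal(sp$intensity, c(0, 2, 0))

  # ascending input yields the identical spectrum after re-sorting
  writeLines(c("0.0 0", "5.0 2", "10.0 0"), f)
  expect_equal(read_spectrum(f, "s1", "control", 1)$intensity, c(0, 2, 0))

  # comma-delimited also accepted
  writeLines(c("10.0,0", "5.0,2"), f)
  expect_equal(read_spectrum(f)$ppm, c(10, 5))
})

test_that("spectrum parse errors cite the offending line", {
  f <- withr::local_tempfile()
  writeLines(c("5.0 abc", "1.0 2"), f)
  expect_error(read_spectrum(f), "line 1")
  writeLines(c("1.0 2 3", "0.5 1"), f)
  expect_error(read_spectrum(f), "line 1")
  writeLines("1.0 2", f)
  expect_error(read_spectrum(f), "fewer than 2")
})

test_that("spectrum write/read roundtrip is the identity", {
  f <- withr::local_tempfile()
  set.seed(42)
  for (i in 1:5) {
    sp <- nmr_spectrum(sort(runif(50, 0, 10), decreasing = TRUE),
                       rnorm(50), sprintf("s%d", i), "study", 3)
    write_spectrum(sp, f)
    back <- read_spectrum(f, sprintf("s%d", i), "study", 3)
    expect_equal(back$ppm, sp$ppm, tolerance = 0)
    expect_equal(back$intensity, sp$intensity, tolerance = 0)
  }
})

test_that("bucket tables validate negatives, duplicates and the normalized flag", {
  vals <- matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("a", "b"), c("B1", "B2")))
  tab <- bucket_table(vals, c("control", "study"), 1)
  expect_equal(dim(tab), c(2L, 2L))
  vals[2, 1] <- -1
  expect_error(bucket_table(vals, c("control", "study"), 1),
               "sample 'b', bucket 'B1'")
  vals[2, 1] <- 1
  rownames(vals) <- c("a", "a")
  expect_error(bucket_table(vals, c("control", "study"), 1), "duplicate")
  rownames(vals) <- c("a", "b")
  expect_error(bucket_table(vals, c("control", "study"), 1,
                            normalized = TRUE), "row sums")
})

test_that("bucket-table CSV roundtrip preserves values bit-for-bit", {
  f <- withr::local_tempfile()
  for (seed in 1:10) {
    tab <- random_bucket_table(n = 5, K = 7, seed = seed)
    write_bucket_table(tab, f)
    expect_tables_equal(read_bucket_table(f), tab)
  }
  # normalized rows survive with row sums intact
  tab <- random_bucket_table(n = 8, K = 10, seed = 99, normalized = TRUE)
  write_bucket_table(tab, f)
  back <- read_bucket_table(f)
  expect_true(all(abs(rowSums(back$values) - 1) < 1e-12))
})

test_that("degenerate and malformed bucket tables are handled", {
  f <- withr::local_tempfile()
  empty <- bucket_table(matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("B1", "B2"))),
                        character(0), integer(0), character(0))
  write_bucket_table(empty, f)
  expect_equal(nrow(read_bucket_table(f)$values), 0)
  expect_equal(read_bucket_table(f)$bucket_ids, c("B1", "B2"))

  writeLines(c("sample_id,group,week,B1", "s1,control,1,-1.0"), f)
  expect_error(read_bucket_table(f), "negative")
  writeLines(c("sample_id,group,week,B1", "s1,control,1,x"), f)
  expect_error(read_bucket_table(f), "non-numeric")
})

test_that("deposited-style layouts are ingested via column and group remapping", {
  f <- withr::local_tempfile()
  writeLines(c("Sample,Class,Timepoint,B1.330,B2.410",
               "m1,sham,1,0.5,0.5",
               "m2,orthotopic,1,0.25,0.75"), f)
  tab <- read_bucket_table(
    f, col_map = c(sample_id = "Sample", group = "Class",
                   week = "Timepoint"),
    group_map = c(sham = "control", orthotopic = "study"))
  expect_equal(tab$group, c("control", "study"))
  expect_equal(tab$bucket_ids, c("B1.330", "B2.410"))
  expect_false(tab$normalized)
  expect_error(read_bucket_table(f), "not found")
})

test_that("bucket schemes validate intervals, overlaps and exclusions", {
  ok <- bucket_scheme(data.frame(bucket_id = c("a", "b"),
                                 left_ppm = c(1.35, 1.50),
                                 right_ppm = c(1.31, 1.46)))
  expect_equal(nrow(ok$buckets), 2)
  expect_error(bucket_scheme(data.frame(bucket_id = c("a", "b"),
                                        left_ppm = c(2.0, 1.5),
                                        right_ppm = c(1.0, 0.5))),
               "overlap")
  expect_error(bucket_scheme(data.frame(bucket_id = "a", left_ppm = 1.0,
                                        right_ppm = 2.0)), "inverted.*a")
  expect_error(bucket_scheme(data.frame(bucket_id = "w", left_ppm = 4.8,
                                        right_ppm = 4.7),
                             data.frame(left_ppm = 5.0, right_ppm = 4.5)),
               "exclusion.*w")
  # adjacent buckets sharing an edge are fine (closed-left/open-right)
  adj <- bucket_scheme(data.frame(bucket_id = c("a", "b"),
                                  left_ppm = c(1.35, 1.31),
                                  right_ppm = c(1.31, 1.27)))
  expect_equal(nrow(adj$buckets), 2)
})

test_that("bucket schemes load from YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("buckets:",
               "  - {id: B1.33, left: 1.35, right: 1.31}",
               "  - {id: B1.48, left: 1.50, right: 1.46}",
               "exclusions:",
               "  - [5.00, 4.50]"), f)
  sch <- load_bucket_scheme(f)
  expect_equal(sch$buckets$bucket_id, c("B1.33", "B1.48"))
  expect_equal(nrow(sch$exclusions), 1)
  writeLines(c("buckets:",
               "  - {id: W, left: 4.8, right: 4.7}",
               "exclusions:",
               "  - [5.00, 4.50]"), f)
  expect_error(load_bucket_scheme(f), "W")
})

test_that("annotation and metabolite-set libraries read and validate", {
  f <- withr::local_tempfile()
  writeLines(c("bucket_id\tmetabolite", "B1.330\tlactate",
               "B4.120\tlactate", "B2.410\tsuccinate"), f)
  ann <- read_annotation(f)
  expect_equal(sum(ann$metabolite == "lactate"), 2)
  sch <- bucket_scheme(data.frame(bucket_id = "B1.330", left_ppm = 1.35,
                                  right_ppm = 1.31))
  expect_error(read_annotation(f, scheme = sch), "B4.120")

  g <- withr::local_tempfile()
  writeLines(c("set_id\tset_name\tmembers",
               "tca\tTCA cycle\tcitrate, succinate, cis-aconitate",
               "gly\tGlycolysis\tlactate"), g)
  sets <- read_metabolite_sets(g)
  expect_equal(length(sets), 2)
  expect_equal(sort(sets$tca), sort(c("citrate", "succinate",
                                      "cis-aconitate")))
  writeLines(c("set_id\tset_name\tmembers", "bad\tBad\tx, x"), g)
  expect_error(read_metabolite_sets(g), "duplicate")
})

test_that("the shipped example scheme and pathway library load and validate", {
  sch <- load_bucket_scheme(system.file("extdata", "example_scheme.yaml",
                                        package = "uromet"))
  expect_equal(nrow(sch$buckets), 10)
  expect_equal(nrow(sch$exclusions), 3)
  sets <- read_metabolite_sets(system.file("extdata",
                                           "example_pathways.tsv",
                                           package = "uromet"))
  lib <- read_metabolite_library()
  expect_true(all(unlist(sets) %in% lib$metabolite))

  # end to end: enrichment of the affected metabolites against the library
  res <- hypergeometric_ora(
    c("lactate", "alanine", "acetate", "citrate", "succinate"),
    unique(lib$metabolite), sets)
  expect_lt(res$p_hyper[res$set_id == "glycolysis"], 0.01)
})
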