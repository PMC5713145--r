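test_that("XDS-ASCII reader echoes header and records", {
  f <- withr::local_tempfile(fileext = ".HKL")
  writeLines(toy_xds_text(), f)
  ds <- read_xds_ascii(f)
  expect_s3_class(ds, "partial_dataset")
  expect_equal(ds$spacegroup$number, 96)
  expect_equal(ds$cell$a, 57.80)
  expect_equal(ds$cell$c, 150.00)
  expect_equal(ds$wavelength, 0.979)
  expect_equal(nrow(ds$observations), 2)
  # file order preserved, extra columns ignored
  expect_equal(ds$observations$h, c(1L, -1L))
  expect_equal(ds$observations$intensity, c(123.4, 80))
  expect_equal(ds$observations$sigma, c(5.6, 4))
})

test_that("observations with sigma <= 0 are dropped and counted", {
  f <- withr::local_tempfile()
  recs <- sprintf("%d 1 0 %g %g", 1:10, 100 + 1:10, c(rep(2, 5), -1, rep(2, 4)))
  writeLines(c("# cell 20 20 20 90 90 90", "# spacegroup 1", recs), f)
  ds <- read_reflection_table(f)
  expect_equal(nrow(ds$observations), 9)
  expect_equal(ds$n_dropped, 1)
  expect_false(6L %in% ds$observations$h)
})

test_that("missing header fields raise format errors naming the field", {
  f <- withr::local_tempfile()
  writeLines(c("!FORMAT=XDS_ASCII", "!UNIT_CELL_CONSTANTS= 10 10 10 90 90 90",
               "1 2 3 5 1"), f)
  expect_error(read_xds_ascii(f), "SPACE_GROUP_NUMBER",
               class = "mx_format_error")
  f2 <- withr::local_tempfile()
  writeLines(c("# spacegroup 1", "1 2 3 5 1"), f2)
  expect_error(read_reflection_table(f2), "cell", class = "mx_format_error")
  f3 <- withr::local_tempfile()
  writeLines(c("# cell 10 10 10 90 90 90", "# spacegroup 1", "1 2 3 5 -1"), f3)
  expect_error(read_reflection_table(f3), "no usable observations",
               class = "mx_format_error")
})

test_that("write/read round trip reproduces a synthetic wedge", {
  sim <- generate_partial_datasets(small_config(datasets_per_class = 1,
                                                n_classes = 1))
  ds <- sim$datasets[[1]]
  f <- withr::local_tempfile(fileext = ".hkl")
  write_reflection_table(ds, f)
  back <- read_reflections(f)
  expect_equal(back$id, ds$id)
  expect_equal(unlist(back$cell), unlist(ds$cell), tolerance = 1e-9)
  expect_equal(back$observations$h, ds$observations$h)
  expect_equal(back$observations$intensity, ds$observations$intensity,
               tolerance = 1e-9)
  expect_equal(back$observations$sigma, ds$observations$sigma,
               tolerance = 1e-9)
})

test_that("manifest reading keeps order and validates entries", {
  dir <- withr::local_tempdir()
  for (nm in c("a.hkl", "b.hkl", "c.hkl"))
    writeLines(c("# cell 10 10 10 90 90 90", "# spacegroup 1", "1 1 1 5 1"),
               file.path(dir, nm))
  mf <- file.path(dir, "manifest.txt")
  writeLines(c("ds2 b.hkl", "ds1 a.hkl", "ds3 c.hkl"), mf)
  m <- read_manifest(mf)
  expect_equal(m$id, c("ds2", "ds1", "ds3"))
  # id defaults to the file stem
  writeLines(c("a.hkl", "b.hkl"), mf)
  expect_equal(read_manifest(mf)$id, c("a", "b"))
  # duplicate ids name both offending lines
  writeLines(c("x a.hkl", "y b.hkl", "", "# comment", "x c.hkl"), mf)
  expect_error(read_manifest(mf), "lines 1 and 5",
               class = "mx_validation_error")
  # unreadable path names the line
  writeLines(c("x a.hkl", "y missing.hkl"), mf)
  expect_error(read_manifest(mf), "line 2", class = "mx_io_error")
})

test_that("merged reflections round trip through the text format", {
  sim <- simulate_experiment(small_config(n_classes = 1,
                                          datasets_per_class = 4,
                                          anomalous_signal = 0.2))
  pool <- pool_observations(names(sim$datasets), sim$datasets,
                            anomalous = TRUE)
  merged <- merge_intensities(pool)
  f <- withr::local_tempfile(fileext = ".hkl")
  write_merged(merged, f)
  back <- read_merged(f)
  expect_true(attr(back, "anomalous"))
  expect_equal(nrow(back), nrow(merged))
  for (col in c("h", "k", "l", "i_mean", "sigma", "multiplicity",
                "i_plus", "n_minus"))
    expect_equal(back[[col]], merged[[col]], tolerance = 1e-9)
  # anomalous off: no Friedel columns written
  merged0 <- merge_intensities(pool_observations(names(sim$datasets),
                                                 sim$datasets))
  write_merged(merged0, f)
  expect_null(read_merged(f)$i_plus)
})

test_that("run outputs contain the documented file set, deterministically", {
  sim <- simulate_experiment(small_config())
  run <- run_pipeline(sim$datasets, threshold = "growth", mode = "all",
                      anomalous = TRUE, quiet = TRUE)
  expect_gte(length(run$results), 2) # both classes merged under mode=all
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressWarnings(write_outputs(run, d1))
  expect_true(file.exists(file.path(d1, "distance_matrix.txt")))
  expect_true(file.exists(file.path(d1, "linkage.txt")))
  for (i in seq_along(run$results)) {
    cdir <- file.path(d1, sprintf("cluster_%02d", i))
    expect_true(all(file.exists(file.path(cdir, c("merged.hkl",
                                                  "statistics.json",
                                                  "members.txt",
                                                  "threshold.txt")))))
    hdr <- readLines(file.path(cdir, "merged.hkl"), n = 4)
    expect_true(any(grepl("anomalous true", hdr)))
    expect_true(any(grepl("i_plus", hdr))) # Friedel columns present
  }
  # rerun from scratch: byte-identical run-level tables
  sim2 <- simulate_experiment(small_config())
  run2 <- run_pipeline(sim2$datasets, threshold = "growth", mode = "all",
                       anomalous = TRUE, quiet = TRUE)
  suppressWarnings(write_outputs(run2, d2))
  expect_identical(readLines(file.path(d1, "linkage.txt")),
                   readLines(file.path(d2, "linkage.txt")))
  expect_identical(readLines(file.path(d1, "distance_matrix.txt")),
                   readLines(file.path(d2, "distance_matrix.txt")))
})
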