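test_that("ppm canonicalization rounds half away from zero at 0.01 precision", {
  expect_equal(canonicalize_ppm(1.004), 1.00)
  expect_equal(canonicalize_ppm(1.0), 1.00)
  expect_equal(canonicalize_ppm(1.005), 1.01)
  expect_equal(canonicalize_ppm(-1.005), -1.01)
  expect_equal(canonicalize_ppm(2.675), 2.68)  # value whose double sits below the half
  expect_error(canonicalize_ppm(NaN), class = "specmatch_invalid_value")
  expect_error(canonicalize_ppm(Inf), class = "specmatch_invalid_value")

  # idempotent and 0.01-quantized on random inputs
  set.seed(101)
  x <- runif(500, -12, 12)
  cx <- canonicalize_ppm(x)
  expect_equal(canonicalize_ppm(cx), cx)
  expect_true(all(abs(cx * 100 - round(cx * 100)) < 1e-9))
})

test_that("peak tables collapse canonical duplicates keeping the larger height", {
  expect_warning(
    tb <- peak_tbl(c(0.999, 1.001), c(2, 5), warn_duplicates = TRUE),
    "collapsed"
  )
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$ppm, 1.00)
  expect_equal(tb$height, 5)
  expect_error(peak_tbl(1.0, -1), class = "specmatch_invalid_value")
})

test_that("record and library invariants are enforced", {
  expect_error(metabolite_record("X", peaks = data.frame(ppm = numeric(),
                                                         height = numeric())),
               class = "specmatch_validation_error")
  expect_error(metabolite_record("X", peaks = 1, solvent = "benzene"),
               class = "specmatch_validation_error")
  expect_error(metabolite_record("X", peaks = 1, ph = 2.5),
               class = "specmatch_validation_error")
  expect_error(metabolite_record("X", peaks = 1, mtype = "mineral"),
               class = "specmatch_validation_error")
  expect_error(ref_library(list()), class = "specmatch_validation_error")
  expect_error(
    ref_library(list(metabolite_record("A", peaks = 1),
                     metabolite_record("A", peaks = 2))),
    class = "specmatch_validation_error"
  )
})

test_that("the peak index is exactly the inverse of the record peak sets", {
  set.seed(7)
  for (rep in 1:20) {
    lib <- random_case(k = 8)$lib
    idx <- peak_index(lib)
    # every record peak appears under its coordinate
    for (i in seq_len(nrow(lib))) {
      for (p in lib$peaks[[i]]$ppm) {
        expect_true(lib$id[i] %in% idx[[sprintf("%.2f", p)]])
      }
    }
    # and nothing else does
    for (key in names(idx)) {
      for (id in idx[[key]]) {
        pk <- lib$peaks[[match(id, lib$id)]]
        expect_true(as.numeric(key) %in% pk$ppm)
      }
    }
  }
})

test_that("feature filters select exactly the matching records", {
  lib <- ref_library(list(
    metabolite_record("A", peaks = 1, solvent = "water", ph = 3.0),
    metabolite_record("B", peaks = 2, solvent = "CDCl3", ph = 7.0),
    metabolite_record("C", peaks = 3, solvent = "water", ph = 10.0)
  ))
  expect_equal(filter_records(lib, list(solvent = "water"))$id, c("A", "C"))
  expect_identical(filter_records(lib, list()), lib)
  expect_equal(filter_records(lib, list(ph = c(6.5, 7.5)))$id, "B")
  expect_equal(nrow(filter_records(lib, list(solvent = "water",
                                             ph = c(6.5, 7.5)))), 0L)
  expect_error(filter_records(lib, list(color = "blue")),
               class = "specmatch_config_error")
})

test_that("native library files round-trip exactly and byte-stably", {
  lib <- ref_library(list(
    metabolite_record("HMDB01", "cafféine analogue", peaks = peak_tbl(
      c(1.23, 4.56, 7.89), c(0.123456789, 2, 3)),
      source = "HMDB-like", mtype = "drug", ph = 6.80, solvent = "CD3OD",
      frequency = 600),
    metabolite_record("USR02", "α-synthetic", peaks = c(2.00, 2.01))
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib, path)
  lib2 <- read_library(path)
  expect_equal(as.data.frame(lib2), as.data.frame(lib))
  # re-saving is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib2, path2)
  expect_identical(readLines(path), readLines(path2))
  # empty library refused
  empty <- filter_records(lib, list(solvent = "5% DMSO"))
  expect_error(write_library(empty, path), class = "specmatch_validation_error")
})

test_that("library parsing reports malformed input precisely", {
  p <- withr::local_tempfile()
  writeLines(c("# comment", ">A\tA\tuser\tmammalian\t7.00\twater\t500",
               "1.00\t2.0", "oops"), p)
  expect_error(read_library(p), regexp = "line 4",
               class = "specmatch_parse_error")
  writeLines(c(">A\tA\tuser\tmammalian\t7.00\twater\t500"), p)
  expect_error(read_library(p), class = "specmatch_validation_error")
  # canonicalization collapse on load warns and keeps one peak
  writeLines(c(">A\tA\tuser\tmammalian\t7.00\twater\t500",
               "0.999\t1.0", "1.001\t3.0"), p)
  expect_warning(lib <- read_library(p), "collapsed")
  expect_equal(lib$peaks[[1]]$ppm, 1.00)
  expect_equal(lib$peaks[[1]]$height, 3.0)
})

test_that("the hmdb-peaklist dialect reads sidecar plus per-metabolite files", {
  dir <- withr::local_tempdir()
  writeLines(c("1.00 2.5", "", "# tail comment", "3.00,4.0"),
             file.path(dir, "m1.txt"))
  writeLines(c("2.50\t1.0"), file.path(dir, "m2.txt"))
  sidecar <- file.path(dir, "meta.tsv")
  writeLines(c(
    "id\tname\tsource\tmtype\tph\tsolvent\tfrequency\tfile",
    "M1\tmet one\tHMDB-like\tmammalian\t7.00\twater\t500\tm1.txt",
    "M2\tmet two\tHMDB-like\tplant\t5.00\twater\t400\tm2.txt"
  ), sidecar)
  lib <- read_library(sidecar, dialect = "hmdb-peaklist")
  expect_equal(library_size(lib), 2L)
  expect_equal(lib$peaks[[match("M1", lib$id)]]$ppm, c(1.00, 3.00))
  expect_equal(lib$frequency[match("M2", lib$id)], 400)
})
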