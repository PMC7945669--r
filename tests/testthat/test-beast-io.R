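toy_alignment <- function(n = 3, len = 30) {
  anc <- random_seq(len)
  rows <- setNames(c(anc, vapply(seq_len(n - 1), function(i)
    mutate_seq(anc, 1, positions = i), "")), sprintf("tx%02d", seq_len(n)))
  mtcurate:::new_alignment(rows)
}

test_that("run configurations validate their fields", {
  expect_error(beast_run_config(mutation_rate = 0), "mutation_rate")
  expect_error(beast_run_config(1e-8, chain_length = -1), "chain_length")
  expect_error(beast_run_config(1e-8, skyline_groups = 0), "skyline_groups")
  cfg <- beast_run_config(1.2e-8, output_stem = "toy")
  expect_equal(cfg$skyline_groups, 5L)
  expect_equal(cfg$substitution_model, "HKY")
})

test_that("emitted XML parses and round-trips sequences, rate and chain", {
  set.seed(51)
  aln <- toy_alignment(3, 24)
  cfg <- beast_run_config(1.2e-8, chain_length = 1e7, output_stem = "toy")
  doc <- setup_basic_xml(aln, cfg)
  info <- beast_xml_info(doc)
  expect_equal(info$sequences[aln$seq_ids], aln$matrix)
  expect_setequal(info$taxa, aln$seq_ids)
  expect_equal(info$clock_rate, 1.2e-8)
  expect_equal(info$chain_length, 1e7)
  expect_true(any(grepl("^toy\\.log$", info$log_files)))
  # survives serialisation to disk
  f <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(doc, f)
  expect_equal(beast_xml_info(f)$sequences[aln$seq_ids], aln$matrix)
})

test_that("two configs differing only in rate differ only in rate fields", {
  set.seed(52)
  aln <- toy_alignment(4, 30)
  a <- beast_xml_info(setup_basic_xml(aln, beast_run_config(1e-8, output_stem = "x")))
  b <- beast_xml_info(setup_basic_xml(aln, beast_run_config(5e-8, output_stem = "x")))
  expect_equal(a$sequences, b$sequences)
  expect_equal(a$chain_length, b$chain_length)
  expect_equal(a$log_files, b$log_files)
  expect_false(a$clock_rate == b$clock_rate)
})

test_that("gapped or ambiguous alignments are refused for XML export", {
  aln <- mtcurate:::new_alignment(c(a = "AC-T", b = "ACGT"))
  expect_error(setup_basic_xml(aln, beast_run_config(1e-8)), "clean")
  aln2 <- mtcurate:::new_alignment(c(a = "ACNT", b = "ACGT"))
  expect_error(setup_basic_xml(aln2, beast_run_config(1e-8)), "clean")
})

test_that("ESS of i.i.d. draws approaches the sample size", {
  tr <- generate_trace(10000, rho = 0, seed = 5)
  ess <- effective_sample_size(tr)
  expect_gte(as.numeric(ess), 8000)
  expect_lte(as.numeric(ess), 12000)
  expect_false(attr(ess, "low_ess"))
})

test_that("a constant trace has ESS 1 with the low-ESS flag raised", {
  ess <- effective_sample_size(rep(3.14, 100))
  expect_equal(as.numeric(ess), 1)
  expect_true(attr(ess, "low_ess"))
})

test_that("AR(1) ESS matches the closed-form autocorrelation limit", {
  tr <- generate_trace(50000, rho = 0.9, seed = 6)
  ess <- as.numeric(effective_sample_size(tr))
  expected <- 50000 * (1 - 0.9) / (1 + 0.9)
  expect_gte(ess, expected * 0.8)
  expect_lte(ess, expected * 1.2)
})

test_that("ESS never exceeds the number of retained samples", {
  set.seed(53)
  for (rep in 1:10) {
    v <- rnorm(500) + if (rep %% 2) 0 else rep(c(-1, 1), length.out = 500)
    ess <- effective_sample_size(v)
    expect_lte(as.numeric(ess), attr(ess, "n"))
  }
  expect_error(effective_sample_size(rnorm(5)), "at least 10")
})

test_that("trace series enforce burn-in bounds and minimum retention", {
  expect_error(trace_series(rnorm(100), burn_in = 1), "burn_in")
  expect_error(trace_series(rnorm(10), burn_in = 0.5), "fewer than 10")
  tr <- trace_series(1:100, burn_in = 0.1)
  expect_length(tr$values, 90)
})

test_that("trace logs with comment headers are readable", {
  f <- withr::local_tempfile(fileext = ".log")
  writeLines(c("# BEAST run", "Sample\tposterior", "0\t-12.3", "1000\t-11.9"), f)
  log <- read_trace_log(f)
  expect_equal(names(log), c("Sample", "posterior"))
  expect_equal(log$posterior, c(-12.3, -11.9))
})

test_that("skyline summaries parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Time\tMedian\tUpper\tLower",
               "0\t1000\t1500\t800",
               "100\t1100\t1600\t900",
               "250\t1300\t2100\t950",
               "900\t1250\t2000\t940"), f)
  prof <- parse_skyline_summary(f)
  expect_s3_class(prof, "skyline_profile")
  expect_equal(nrow(prof), 4L)
  expect_equal(prof$median, c(1000, 1100, 1300, 1250))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_skyline_summary(prof, out)
  expect_equal(parse_skyline_summary(out), prof)

  hdr <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Time\tMedian\tUpper\tLower", hdr)
  expect_warning(empty <- parse_skyline_summary(hdr), "no rows")
  expect_equal(nrow(empty), 0L)

  miss <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Time\tMedian\tUpper", "0\t1\t2"), miss)
  expect_error(parse_skyline_summary(miss), "lower")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Time\tMedian\tUpper\tLower", "0\t1000\t1500\t800",
               "10\t900\t800\t700"), bad)
  expect_error(parse_skyline_summary(bad), "row 2")
})

test_that("a known piecewise-constant profile survives write and parse", {
  times <- c(0, 50, 100, 500, 1000, 5000)
  med <- c(1000, 1000, 4000, 4000, 2000, 2000)
  prof <- structure(data.frame(time = times, median = med,
                               lower = med * 0.5, upper = med * 2),
                    class = c("skyline_profile", "data.frame"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_skyline_summary(prof, f)
  back <- parse_skyline_summary(f)
  expect_equal(back$median, med)
  expect_equal(back$time, times)
})
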