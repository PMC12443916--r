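test_that("runAnalysis produces the full result bundle from DICOM", {
  in_dir <- withr::local_tempdir()
  out_dir <- withr::local_tempdir()
  cfg <- simConfig(template = fix_template(), noiseSigma = 0,
                   includeAdcMap = TRUE, seed = 12)
  simulateDicomStudy(cfg, in_dir)
  tpl_path <- system.file("extdata", "synthetic_phantom_template.yaml",
                          package = "phantomADC")
  bundle <- runAnalysis(list(input_dir = in_dir, phantom_config = tpl_path,
                             roi_policy = "optimal", detection = "shape",
                             output_dir = out_dir))
  expect_true(all(file.exists(file.path(out_dir,
    c("per_vial.csv", "series_table.csv", "qa_report.pdf",
      "detection_overlay.png")))))

  res <- read.csv(file.path(out_dir, "per_vial.csv"))
  fit <- res[res$source == "fit", ]
  expect_identical(nrow(fit), 13L)
  ref <- fix_ref_adc()
  bias <- fit$adc_um2s - ref[fit$vial_label]
  # noiseless pipeline through DICOM: bias limited only by 16-bit
  # quantisation of the written pixel data
  expect_lt(max(abs(bias)), 1)

  # inline map rows present alongside fitted rows
  expect_identical(sort(unique(res$source)), c("fit", "inline"))
  inline <- res[res$source == "inline", ]
  expect_identical(nrow(inline), 13L)
  expect_lt(max(abs(inline$adc_um2s - ref[inline$vial_label])), 5)
})

test_that("analysis results are deterministic across reruns", {
  in_dir <- withr::local_tempdir()
  cfg <- simConfig(template = fix_template(), noiseSigma = 10, seed = 14)
  simulateDicomStudy(cfg, in_dir)
  tpl_path <- system.file("extdata", "synthetic_phantom_template.yaml",
                          package = "phantomADC")
  run_once <- function() {
    out <- withr::local_tempdir()
    runAnalysis(list(input_dir = in_dir, phantom_config = tpl_path,
                     output_dir = out))
    readBin(file.path(out, "per_vial.csv"), raw(),
            file.size(file.path(out, "per_vial.csv")))
  }
  expect_identical(run_once(), run_once())
})

test_that("an empty input directory reports 'no series found'", {
  tpl_path <- system.file("extdata", "synthetic_phantom_template.yaml",
                          package = "phantomADC")
  expect_error(runAnalysis(list(input_dir = withr::local_tempdir(),
                                phantom_config = tpl_path,
                                output_dir = withr::local_tempdir())),
               "no series found")
})

test_that("runMetrics computes QIBA and RC/RDC tables from CSVs", {
  # synthetic per-vial CSV: 3 sessions x 2 repeats, one vial
  df <- expand.grid(session = c("s1", "s2", "s3"), repeat_index = 1:2)
  set.seed(15)
  df$vial_label <- "PVP0_centre"
  df$adc_um2s <- 1100 + rnorm(nrow(df), 0, 3)
  df$source <- "fit"
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, csv, row.names = FALSE)

  out <- runMetrics(csv, "qiba", refAdc = c(PVP0_centre = 1100))
  expect_identical(nrow(out), 1L)
  expect_false(is.na(out$rc_lt_um2ms))
  expect_true(all(c("pct_bias", "rc_st_um2ms", "cv_st_pct") %in% names(out)))

  # single session: long-term metrics empty with a warning
  one <- df[df$session == "s1", ]
  csv1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(one, csv1, row.names = FALSE)
  expect_warning(out1 <- runMetrics(csv1, "qiba",
                                    refAdc = c(PVP0_centre = 1100)),
                 "single session")
  expect_true(is.na(out1$rc_lt_um2ms))

  # rc_rdc mode: institute with one repeat excluded from %RC
  df2 <- rbind(df, data.frame(session = "sJ", repeat_index = 1,
                              vial_label = "PVP0_centre",
                              adc_um2s = 1090, source = "fit"))
  csv2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, csv2, row.names = FALSE)
  expect_message(out2 <- runMetrics(csv2, "rc_rdc"), "excluded.*sJ")
  rc_rows <- out2[out2$metric == "pct_rc", ]
  expect_true(is.na(rc_rows$value[rc_rows$institute == "sJ"]))
  expect_true("pct_rdc" %in% out2$metric)

  # malformed CSV: schema error names the missing column
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, setdiff(names(df), "adc_um2s")], bad, row.names = FALSE)
  expect_error(runMetrics(bad, "qiba", refAdc = c(PVP0_centre = 1100)),
               "adc_um2s")
})

test_that("compareToReference reproduces known equivalence structure", {
  labs <- vials(fix_template())$label
  base <- expand.grid(session = sprintf("s%02d", 1:8), repeat_index = 1:6,
                      vial_label = labs, stringsAsFactors = FALSE)
  set.seed(16)
  ref <- base
  ref$adc_um2s <- 1000 + rnorm(nrow(ref), 0, 2)
  res <- ref
  res$adc_um2s <- res$adc_um2s + 1.5   # constant 1.5 um2/s offset
  res$source <- "fit"
  f_res <- withr::local_tempfile(fileext = ".csv")
  f_ref <- withr::local_tempfile(fileext = ".csv")
  write.csv(res, f_res, row.names = FALSE)
  write.csv(ref, f_ref, row.names = FALSE)
  plot_file <- withr::local_tempfile(fileext = ".pdf")
  cmp <- compareToReference(f_res, f_ref, plotPath = plot_file)
  expect_true(cmp$achieved)
  # offset 1.5 with n = 48 pairs: equivalent at 2 um2/s but not below
  expect_equal(cmp$delta, 2)
  expect_identical(nrow(cmp$table), 13L)
  expect_true(all(cmp$table$equivalent))
  expect_true(file.exists(plot_file))
})
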