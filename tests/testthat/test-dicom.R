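test_that("a simulated study round-trips through classic DICOM", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(template = fix_template(), bValues = c(0, 500, 1000, 2000),
                   noiseSigma = 0, matrixSize = 60, spacing = c(2.5, 2.5, 2),
                   nSlices = 8, seed = 7)
  sim <- simulateDicomStudy(cfg, dir, dialect = "standard")
  back <- scanDicomDirectory(dir, quiet = TRUE)

  expect_length(back, 4L)
  expect_true(all(vapply(back, function(s) seriesMeta(s)$category,
                         character(1)) == "trace_dwi"))
  expect_setequal(vapply(back, bValue, numeric(1)), c(0, 500, 1000, 2000))

  # voxels equal up to the 16-bit quantisation step of the writer
  uid <- vapply(sim$series, function(s) seriesMeta(s)$series_uid, character(1))
  for (s in back) {
    orig <- sim$series[[match(seriesMeta(s)$series_uid, uid)]]
    q <- max(voxels(orig)) / 60000
    expect_lt(max(abs(voxels(s) - voxels(orig))), 0.6 * q)
    expect_equal(seriesOrigin(s), seriesOrigin(orig))
    expect_equal(voxelSpacing(s), voxelSpacing(orig))
    expect_equal(seriesOrientation(s), seriesOrientation(orig))
  }

  # voxel -> world mapping agrees with the generator's ground truth
  s <- back[[1]]
  idx <- rbind(c(0, 0, 0), c(10, 20, 3))
  w <- voxelToWorld(s, idx)
  expected <- sweep(idx %*% diag(sim$truth$spacing), 2, sim$truth$origin, "+")
  expect_lt(max(abs(w - expected)), 1e-6)
})

test_that("series assembly is invariant to file order on disk", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(template = fix_template(), bValues = c(0, 800),
                   noiseSigma = 5, matrixSize = 40, spacing = c(4, 4, 4),
                   nSlices = 6, seed = 19)
  simulateDicomStudy(cfg, dir)
  ref <- scanDicomDirectory(dir, quiet = TRUE)
  # shuffle by renaming files within each series directory
  set.seed(1)
  for (d in list.dirs(dir, recursive = FALSE)) {
    files <- list.files(d, full.names = TRUE)
    newnames <- file.path(d, sprintf("zz_%02d.dcm", sample(seq_along(files))))
    file.rename(files, newnames)
  }
  shuffled <- scanDicomDirectory(dir, quiet = TRUE)
  expect_identical(lapply(ref, voxels), lapply(shuffled, voxels))
  expect_identical(lapply(ref, seriesOrigin), lapply(shuffled, seriesOrigin))
})

test_that("inline ADC map series are classified as adc_map", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(template = fix_template(), bValues = c(0, 1000),
                   noiseSigma = 0, matrixSize = 40, spacing = c(4, 4, 4),
                   nSlices = 6, includeAdcMap = TRUE, seed = 5)
  simulateDicomStudy(cfg, dir)
  back <- scanDicomDirectory(dir, quiet = TRUE)
  cats <- vapply(back, function(s) seriesMeta(s)$category, character(1))
  expect_identical(sort(unique(cats)), c("adc_map", "trace_dwi"))
  expect_identical(sum(cats == "adc_map"), 1L)
  amap <- back[[which(cats == "adc_map")]]
  expect_equal(seriesMeta(amap)$adc_unit_scale, 1)
})

test_that("b-value extraction prefers the standard tag over private tags", {
  # standard tag passthrough
  expect_identical(extractBValue(list(`00189087` = 1000)), 1000)
  # private fallback per vendor
  expect_identical(extractBValue(list(`0019100C` = 200), "siemens"), 200)
  expect_identical(extractBValue(list(`20011003` = 750), "philips"), 750)
  expect_identical(extractBValue(list(`00431039` = 1000000900), "ge"), 900)
  # precedence: standard wins when both present
  expect_identical(
    extractBValue(list(`00189087` = 1000, `0019100C` = 5), "siemens"), 1000)
  # nothing found -> metadata error
  expect_error(extractBValue(list(`0020000E` = "1.2.3"), "siemens"),
               "no diffusion b-value")
})

test_that("vendor dialects round-trip the b-value through private tags", {
  for (dialect in c("siemens", "philips", "ge")) {
    dir <- withr::local_tempdir()
    cfg <- simConfig(template = fix_template(), bValues = c(0, 600),
                     noiseSigma = 0, matrixSize = 30, spacing = c(5, 5, 5),
                     nSlices = 4, seed = 3)
    simulateDicomStudy(cfg, dir, dialect = dialect)
    back <- scanDicomDirectory(dir, quiet = TRUE)
    expect_setequal(vapply(back, bValue, numeric(1)), c(0, 600))
    expect_true(all(vapply(back, function(s) seriesMeta(s)$vendor,
                           character(1)) == dialect))
  }
})

test_that("intensity scaling follows slope, intercept and private scale", {
  expect_identical(applyIntensityScaling(500), 500)
  expect_identical(applyIntensityScaling(100, slope = 2, intercept = 10), 210)
  # private-scale divide after the standard rescale
  expect_identical(
    applyIntensityScaling(100, slope = 2, intercept = 0, privateScale = 0.5),
    (100 * 2 + 0) / 0.5)
  expect_error(applyIntensityScaling(1, privateScale = 0), "zero")
})

test_that("enhanced multi-frame DICOM raises an explicit unsupported error", {
  enc <- phantomADC:::.enc_elem
  meta_els <- c(
    enc(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.4.1"),
    enc(0x0002, 0x0003, "UI", "1.2.3.4"),
    enc(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  body <- c(enc(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.4.1"),
            enc(0x0028, 0x0008, "IS", "30"))
  bytes <- c(raw(128), charToRaw("DICM"),
             enc(0x0002, 0x0000, "UL", length(meta_els)), meta_els, body)
  dir <- withr::local_tempdir()
  writeBin(bytes, file.path(dir, "enhanced.dcm"))
  expect_error(scanDicomDirectory(dir, quiet = TRUE), "not supported",
               class = "dicom_unsupported")
})

test_that("empty directories and non-DICOM files are handled", {
  dir <- withr::local_tempdir()
  expect_length(scanDicomDirectory(dir, quiet = TRUE), 0L)
  writeLines("not dicom at all", file.path(dir, "junk.txt"))
  expect_length(scanDicomDirectory(dir, quiet = TRUE), 0L)
})

test_that("sessions group by study date and repeats by acquisition time", {
  cfg <- simConfig(template = fix_template(), bValues = c(0, 1000),
                   noiseSigma = 0, matrixSize = 20, spacing = c(8, 8, 8),
                   nSlices = 4, nSessions = 3, nRepeats = 2, seed = 8)
  sim <- simulatePhantom(cfg)
  grp <- groupSessions(sim$series)
  tab <- grp$table
  expect_identical(length(unique(tab$session)), 3L)
  for (s in unique(tab$session)) {
    sub <- tab[tab$session == s, ]
    expect_identical(sort(unique(sub$repeat_index)), 1:2)
    # series at the same acquisition time (the b-sweep) share a repeat
    expect_identical(nrow(sub), 4L)
  }
  # single series: one session, one repeat
  one <- groupSessions(sim$series[1])
  expect_identical(one$table$repeat_index, 1L)
})

test_that("generated DICOM agrees with an independent reader (pydicom)", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(template = fix_template(), bValues = c(0, 1000),
                   noiseSigma = 0, matrixSize = 24, spacing = c(6, 6, 5),
                   nSlices = 3, seed = 13)
  sim <- simulateDicomStudy(cfg, dir, dialect = "standard")
  f <- list.files(file.path(dir, "series_001"), full.names = TRUE)[1]
  script <- sprintf("
import pydicom, json
ds = pydicom.dcmread(r'%s')
print(json.dumps({
  'rows': int(ds.Rows), 'cols': int(ds.Columns),
  'b': float(ds[0x0018, 0x9087].value),
  'ipp': [float(x) for x in ds.ImagePositionPatient],
  'spacing': [float(x) for x in ds.PixelSpacing],
  'pixel_sum': int(ds.pixel_array.sum())}))", f)
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  info <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_identical(info$rows, 24L)
  expect_identical(info$cols, 24L)
  expect_identical(info$b, 0)
  expect_equal(info$spacing, c(6, 6))
  ours <- readDicomFile(f)
  expect_identical(sum(ours$pixels), info$pixel_sum)
  expect_equal(ours$tags[["00200032"]], info$ipp)
})
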