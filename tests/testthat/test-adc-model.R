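test_that("log-linear fit matches closed forms exactly", {
  # two points: ADC = ln(s1/s2) / (b2 - b1)
  f <- fitAdcLoglinear(c(0, 1000), c(1000, 1000 * exp(-1)))
  expect_equal(f$adc_um2s, 1000)
  expect_equal(f$s0, 1000)

  # noiseless three-point series: exact recovery, r2 = 1
  b <- c(0, 500, 1000)
  s <- 800 * exp(-b * 1.1e-3)
  f <- fitAdcLoglinear(b, s)
  expect_equal(f$adc_um2s, 1100)
  expect_equal(f$s0, 800)
  expect_equal(f$r_squared, 1)

  # errors
  expect_error(fitAdcLoglinear(c(0, 0), c(1, 1)), "distinct")
  expect_error(fitAdcLoglinear(c(0, 500, 1000), c(10, 0, 5)),
               "non-positive signal at b = 500")
})

test_that("OLS slope and intercept match a normal-equations oracle", {
  set.seed(101)
  for (i in 1:100) {
    nb <- sample(3:8, 1)
    b <- sort(sample(0:2000, nb))
    s <- exp(rnorm(nb, log(1000) - b * 1e-3, 0.05))
    f <- fitAdcLoglinear(b, s)
    # independent oracle: solve X'X beta = X'y directly
    X <- cbind(1, b)
    beta <- solve(t(X) %*% X, t(X) %*% log(s))
    expect_equal(f$adc_um2s, adcMm2sToUm2s(-beta[2]), tolerance = 1e-10)
    expect_equal(log(f$s0), beta[1], tolerance = 1e-10)
  }
})

test_that("fit is invariant to uniform signal rescaling", {
  b <- c(0, 200, 600, 1000)
  s <- 1200 * exp(-b * 9e-4) * exp(rnorm(4, 0, 0.01))
  f1 <- fitAdcLoglinear(b, s)
  f2 <- fitAdcLoglinear(b, 7.3 * s)
  expect_equal(f2$adc_um2s, f1$adc_um2s)
  expect_equal(f2$s0, 7.3 * f1$s0)
})

test_that("noisy parameter recovery: median ADC within 1% at SNR >= 50", {
  set.seed(202)
  b <- c(0, 200, 400, 800, 1000)
  truth <- 1100
  fits <- replicate(1000, {
    s <- 1000 * exp(-b * adcUm2sToMm2s(truth))
    noisy <- sqrt((s + rnorm(5, 0, 10))^2 + rnorm(5, 0, 10)^2)
    fitAdcLoglinear(b, noisy)$adc_um2s
  })
  expect_lt(abs(median(fits) - truth) / truth, 0.01)
})

test_that("ROI-mean fit equals the voxel fit on a uniform vial", {
  sim <- simulatePhantom(simConfig(template = fix_template(),
                                   noiseSigma = 0, matrixSize = 40,
                                   spacing = c(4, 4, 4), nSlices = 6,
                                   seed = 3))
  roi <- carveCylinder(c(0, 0, 0), 5, sim$series[[1]], height = 10,
                       vialLabel = "PVP0_centre")
  roi_fit <- fitRoiMean(sim$series, roi)
  vm <- fitVoxelwise(sim$series, roi)
  expect_equal(unique(round(vm$adc_um2s, 9)), round(roi_fit$adc_um2s, 9))

  # b-subset restricts the number of fitted points
  sub_fit <- fitRoiMean(sim$series, roi, bSubset = c(200, 1000))
  expect_identical(sub_fit$n_points, 2L)
  expect_equal(sub_fit$adc_um2s, roi_fit$adc_um2s)
  expect_error(fitRoiMean(sim$series, roi, bSubset = c(200, 999)),
               "not available")
})

test_that("voxelwise fits recover a quadratic height bias field", {
  cfg <- simConfig(template = fix_template(), noiseSigma = 0,
                   biasField = biasField(quadraticCoeff = 0.5),
                   matrixSize = 40, spacing = c(4, 4, 2), nSlices = 16,
                   seed = 6)
  sim <- simulatePhantom(cfg)
  roi <- carveCylinder(c(0, 0, 0), 5, sim$series[[1]], height = 24,
                       vialLabel = "PVP0_centre")
  vm <- fitVoxelwise(sim$series, roi)
  expect_equal(vm$adc_um2s, 1100 + 0.5 * vm$h^2, tolerance = 1e-9)
})

test_that("voxels with non-positive signal are dropped and counted", {
  sim <- simulatePhantom(simConfig(template = fix_template(),
                                   bValues = c(0, 1000), noiseSigma = 0,
                                   matrixSize = 30, spacing = c(5, 5, 5),
                                   nSlices = 4, seed = 2))
  s0 <- sim$series[[1]]
  v <- voxels(s0)
  roi <- carveCylinder(c(0, 0, 0), 5, s0, height = 10, vialLabel = "v")
  ids <- roi@voxelIds[1, , drop = FALSE] + 1L
  v[ids[1, 1], ids[1, 2], ids[1, 3]] <- 0
  s0z <- new("ImageSeries", voxels = v, spacing = s0@spacing,
             origin = s0@origin, orientation = s0@orientation,
             meta = s0@meta)
  vm <- fitVoxelwise(list(s0z, sim$series[[2]]), roi)
  expect_identical(attr(vm, "n_dropped"), 1L)
  expect_identical(nrow(vm), nrow(roi@voxelIds) - 1L)
})

test_that("inline ADC extraction applies the unit scale once", {
  sim <- simulatePhantom(simConfig(template = fix_template(),
                                   bValues = c(0, 1000), noiseSigma = 0,
                                   matrixSize = 30, spacing = c(5, 5, 5),
                                   nSlices = 4, seed = 2))
  s <- sim$series[[1]]
  roi <- carveCylinder(c(0, 0, 0), 5, s, height = 10, vialLabel = "v")
  mk_map <- function(vals) {
    m <- s@meta
    m$category <- "adc_map"; m$adc_unit_scale <- 1; m$b_value <- NULL
    new("ImageSeries", voxels = vals, spacing = s@spacing,
        origin = s@origin, orientation = s@orientation, meta = m)
  }
  # constant map
  const <- mk_map(array(1100, dim(voxels(s))))
  got <- extractInlineAdc(const, roi)
  expect_equal(got$adc_um2s, 1100)
  expect_equal(got$adc_sd_um2s, 0)
  # map stored in um2/ms, scale 1000 to um2/s
  ms <- mk_map(array(1.1, dim(voxels(s))))
  expect_equal(extractInlineAdc(ms, roi, unitScale = 1000)$adc_um2s, 1100)
  # known per-voxel values match a brute-force mean/SD
  set.seed(17)
  vals <- array(runif(prod(dim(voxels(s))), 900, 1300), dim(voxels(s)))
  rnd <- mk_map(vals)
  ids <- roi@voxelIds + 1L
  ref_vals <- vals[cbind(ids[, 1], ids[, 2], ids[, 3])]
  got <- extractInlineAdc(rnd, roi)
  expect_equal(got$adc_um2s, mean(ref_vals))
  expect_equal(got$adc_sd_um2s, sd(ref_vals))
  # non-map input rejected
  expect_error(extractInlineAdc(s, roi), "not an ADC map")
})
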