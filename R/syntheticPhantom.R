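# Synthetic DW-MRI generator for a 13-vial diffusion phantom.
#
# The forward model is the same mono-exponential signal model the analysis
# fits: s(b) = s0 * exp(-b * ADC), with ADC spatially modulated by optional
# bias fields (quadratic along the vial axis, exponential in radius) that
# emulate gradient-non-linearity-like spatial bias. Magnitude images carry
# Rician noise: |(s + g1) + i g2| with g1, g2 ~ N(0, sigma).

#' Simulation configuration for the synthetic phantom
#'
#' @param template a [PhantomTemplate-class]; defaults to
#'   [syntheticPhantomTemplate()].
#' @param bValues b-values in s/mm2 (at least two distinct, >= 0).
#' @param s0 proton-density signal per vial (scalar or length-13, arbitrary
#'   units).
#' @param noiseSigma Gaussian channel SD of the Rician noise (same units as
#'   `s0`).
#' @param biasField see [biasField()].
#' @param rigidOffset numeric c(dx, dy, rot_deg): in-plane phantom shift in
#'   mm and rotation in degrees applied before rasterisation.
#' @param nRepeats,nSessions repeats per session / number of sessions.
#' @param matrixSize in-plane matrix (n x n voxels).
#' @param spacing voxel spacing c(x, y, z) mm.
#' @param nSlices number of axial slices.
#' @param includeAdcMap also emit a scanner-style inline ADC map per
#'   session/repeat (voxelwise log-linear fit of the noisy signals, um2/s).
#' @param seed integer RNG seed; a fixed seed gives byte-identical voxels.
#' @return a validated config list of class `simConfig`.
#' @export
simConfig <- function(template = syntheticPhantomTemplate(),
                      bValues = c(0, 200, 400, 800, 1000),
                      s0 = 1000, noiseSigma = 10,
                      biasField = list(),
                      rigidOffset = c(0, 0, 0),
                      nRepeats = 1L, nSessions = 1L,
                      matrixSize = 128L, spacing = c(1.25, 1.25, 2),
                      nSlices = 20L, includeAdcMap = FALSE, seed = 1L) {
  stopifnot(is(template, "PhantomTemplate"))
  if (length(unique(bValues)) < 2L || any(bValues < 0))
    stop("bValues must contain at least 2 distinct non-negative values")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (length(s0) == 1L) s0 <- rep(s0, nrow(vials(template)))
  if (length(s0) != nrow(vials(template)))
    stop("s0 must be scalar or one value per vial")
  if (length(rigidOffset) != 3L) stop("rigidOffset must be c(dx, dy, rot_deg)")
  structure(list(template = template, bValues = sort(unique(bValues)),
                 s0 = s0, noiseSigma = noiseSigma, biasField = biasField,
                 rigidOffset = rigidOffset,
                 nRepeats = as.integer(nRepeats),
                 nSessions = as.integer(nSessions),
                 matrixSize = as.integer(matrixSize), spacing = spacing,
                 nSlices = as.integer(nSlices),
                 includeAdcMap = isTRUE(includeAdcMap),
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' Spatial ADC bias field specification
#'
#' Optional spatial modulation of the true ADC inside each vial, expressed
#' in the vial's cylindrical frame: a quadratic term \code{coeff * (h -
#' hOffset)^2} along the vial axis and/or an exponential radial term
#' \code{amplitude * (exp(r / scale) - 1)}, both in um2/s.
#'
#' @param quadraticCoeff quadratic coefficient, um2/s per mm2 (0 = off).
#' @param hOffset axial position of the quadratic minimum, mm.
#' @param radialAmplitude amplitude of the radial term, um2/s (0 = off).
#' @param radialScale radial length scale, mm.
#' @return list usable as `biasField` in [simConfig()].
#' @export
biasField <- function(quadraticCoeff = 0, hOffset = 0,
                      radialAmplitude = 0, radialScale = 5) {
  list(quadraticCoeff = quadraticCoeff, hOffset = hOffset,
       radialAmplitude = radialAmplitude, radialScale = radialScale)
}

.vial_centres_world <- function(template, rigidOffset) {
  v <- vials(template)
  th <- rigidOffset[3] * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  xy <- cbind(v$dx_mm, v$dy_mm) %*% t(rot)
  cbind(x = xy[, 1] + rigidOffset[1], y = xy[, 2] + rigidOffset[2], z = 0)
}

#' Evaluate the true ADC field at world points
#'
#' Returns, for each point, the vial it falls in (by cylinder membership)
#' and the local true ADC: the vial's reference ADC plus the bias-field
#' terms evaluated in the vial's cylindrical frame. Points outside every
#' vial get NA (no-signal background).
#'
#' @param template a [PhantomTemplate-class].
#' @param bias a [biasField()] list (empty list = no bias).
#' @param points n x 3 matrix of world coordinates (mm).
#' @param rigidOffset c(dx, dy, rot_deg) applied to the vial layout.
#' @return list with `adc_um2s` (numeric, NA outside vials) and `vial`
#'   (integer row index into `vials(template)`, NA outside).
#' @examples
#' tpl <- syntheticPhantomTemplate()
#' adcField(tpl, biasField(), matrix(c(0, 0, 0), 1))$adc_um2s  # centre vial ref
#' @export
adcField <- function(template, bias = list(), points,
                     rigidOffset = c(0, 0, 0)) {
  points <- matrix(as.numeric(points), ncol = 3L)
  ctr <- .vial_centres_world(template, rigidOffset)
  v <- vials(template)
  n <- nrow(points)
  adc <- rep(NA_real_, n)
  vial <- rep(NA_integer_, n)
  qc <- bias$quadraticCoeff %||% 0
  h0 <- bias$hOffset %||% 0
  ra <- bias$radialAmplitude %||% 0
  rs <- bias$radialScale %||% 5
  for (i in seq_len(nrow(v))) {
    dx <- points[, 1] - ctr[i, 1]
    dy <- points[, 2] - ctr[i, 2]
    r <- sqrt(dx * dx + dy * dy)
    h <- points[, 3] - ctr[i, 3]
    inside <- r <= vialRadius(template) & abs(h) <= vialHeight(template) / 2
    if (!any(inside)) next
    a <- v$ref_adc_um2s[i]
    aa <- rep(a, sum(inside))
    if (qc != 0) aa <- aa + qc * (h[inside] - h0)^2
    if (ra != 0) aa <- aa + ra * (exp(r[inside] / rs) - 1)
    adc[inside] <- aa
    vial[inside] <- i
  }
  list(adc_um2s = adc, vial = vial)
}

.sim_grid <- function(config) {
  n <- config$matrixSize
  nz <- config$nSlices
  sp <- config$spacing
  origin <- c(-(n - 1) / 2 * sp[1], -(n - 1) / 2 * sp[2], -(nz - 1) / 2 * sp[3])
  idx <- as.matrix(expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(nz - 1)))
  world <- sweep(idx %*% diag(sp), 2L, origin, "+")
  list(origin = origin, idx = idx, world = world, dim = c(n, n, nz))
}

#' Simulate a synthetic phantom study in memory
#'
#' Generates one trace-weighted [ImageSeries-class] per (session, repeat,
#' b-value), with mono-exponential decay inside vials, optional spatial ADC
#' bias, Rician magnitude noise, and optional inline ADC maps. All series of
#' a session share a study date; repeats are distinguished by acquisition
#' time.
#'
#' @param config a [simConfig()].
#' @return list with `series` (list of ImageSeries), `truth` (ground-truth
#'   list: per-vial base ADC, world centres, s0, seed, config echoes), and
#'   `config`.
#' @export
simulatePhantom <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  g <- .sim_grid(config)
  fld <- adcField(config$template, config$biasField, g$world,
                  config$rigidOffset)
  inside <- !is.na(fld$adc_um2s)
  s0_vox <- numeric(nrow(g$world))
  s0_vox[inside] <- config$s0[fld$vial[inside]]
  adc_mm2s <- ifelse(inside, adcUm2sToMm2s(fld$adc_um2s), 0)

  ctr <- .vial_centres_world(config$template, config$rigidOffset)
  v <- vials(config$template)
  truth <- list(seed = config$seed,
                vials = data.frame(label = v$label,
                                   pvp_percent = v$pvp_percent,
                                   ref_adc_um2s = v$ref_adc_um2s,
                                   centre_x_mm = ctr[, 1],
                                   centre_y_mm = ctr[, 2],
                                   centre_z_mm = ctr[, 3],
                                   s0 = config$s0),
                spacing = config$spacing, origin = g$origin,
                rigid_offset = config$rigidOffset,
                bias_field = config$biasField,
                b_values = config$bValues)

  series <- list()
  base_date <- as.Date("2024-01-01")
  for (sess in seq_len(config$nSessions)) {
    study_date <- format(base_date + 30 * (sess - 1), "%Y%m%d")
    study_uid <- sprintf("1.2.826.0.1.3680043.10.1415.%d.%d",
                         config$seed, sess)
    for (rep_i in seq_len(config$nRepeats)) {
      acq_time <- sprintf("%02d%02d00", 8L + rep_i, 0L)
      sig_by_b <- list()
      for (bi in seq_along(config$bValues)) {
        b <- config$bValues[bi]
        s <- s0_vox * exp(-b * adc_mm2s)
        if (config$noiseSigma > 0) {
          nvox <- length(s)
          s <- sqrt((s + stats::rnorm(nvox, 0, config$noiseSigma))^2 +
                    stats::rnorm(nvox, 0, config$noiseSigma)^2)
        }
        vol <- array(s, dim = g$dim)
        sig_by_b[[bi]] <- vol
        meta <- list(category = "trace_dwi", b_value = b, vendor = "unknown",
                     series_uid = sprintf("%s.%d.%d", study_uid, rep_i, bi),
                     study_uid = study_uid, study_date = study_date,
                     acq_time = acq_time, session_id = study_date,
                     repeat_index = rep_i, intensity_scale_applied = FALSE)
        series[[length(series) + 1L]] <-
          new("ImageSeries", voxels = vol, spacing = config$spacing,
              origin = g$origin, orientation = diag(3), meta = meta)
      }
      if (config$includeAdcMap) {
        amap <- .inline_adc_volume(sig_by_b, config$bValues)
        meta <- list(category = "adc_map", vendor = "unknown",
                     series_uid = sprintf("%s.%d.adc", study_uid, rep_i),
                     study_uid = study_uid, study_date = study_date,
                     acq_time = acq_time, session_id = study_date,
                     repeat_index = rep_i, adc_unit_scale = 1,
                     series_description = "inline ADC",
                     intensity_scale_applied = FALSE)
        series[[length(series) + 1L]] <-
          new("ImageSeries", voxels = amap, spacing = config$spacing,
              origin = g$origin, orientation = diag(3), meta = meta)
      }
    }
  }
  list(series = series, truth = truth, config = config)
}

# Scanner-style inline map: voxelwise log-linear fit over all b-values,
# zero where any signal is non-positive.
.inline_adc_volume <- function(sig_by_b, b_values) {
  dims <- dim(sig_by_b[[1]])
  S <- vapply(sig_by_b, as.vector, numeric(prod(dims)))
  ok <- rowSums(S <= 0) == 0L
  adc <- numeric(nrow(S))
  if (any(ok)) {
    y <- log(S[ok, , drop = FALSE])
    bb <- b_values - mean(b_values)
    slope <- as.vector(y %*% bb) / sum(bb * bb)
    adc[ok] <- pmax(adcMm2sToUm2s(-slope), 0)
  }
  array(adc, dim = dims)
}

#' Simulate a phantom study and write it as DICOM
#'
#' Runs [simulatePhantom()] and writes every series as a classic DICOM
#' series (one sub-directory per series) in the chosen vendor dialect, plus
#' a `ground_truth.json` sidecar recording the true per-vial ADC, world
#' vial centres and the seed.
#'
#' @param config a [simConfig()].
#' @param outDir output directory.
#' @param dialect b-value/intensity encoding; see [writeDicomSeries()].
#' @return list as [simulatePhantom()], plus `out_dir`; invisibly.
#' @export
simulateDicomStudy <- function(config, outDir, dialect = "standard") {
  sim <- simulatePhantom(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(sim$series)) {
    writeDicomSeries(sim$series[[i]],
                     file.path(outDir, sprintf("series_%03d", i)),
                     dialect = dialect, seriesNumber = i)
  }
  sidecar <- sim$truth
  sidecar$vials <- as.list(sidecar$vials)
  jsonlite::write_json(sidecar, file.path(outDir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  sim$out_dir <- outDir
  invisible(sim)
}
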