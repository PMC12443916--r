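# ADC estimation from trace-weighted series.
#
# The signal model is mono-exponential, s(b) = s0 * exp(-b * ADC), fitted
# through its linearised form log(s(b)) = -b * ADC + log(s0) by ordinary
# (unweighted) least squares; no Rician-bias correction is applied.

#' Log-linear mono-exponential ADC fit
#'
#' Ordinary least squares of \code{log(signal)} on the b-value. The slope
#' equals \code{-ADC} in mm2/s (reported in um2/s), the intercept
#' \code{log(s0)}. With exactly two points this reduces to the closed form
#' \code{ADC = log(s1/s2) / (b2 - b1)}.
#'
#' @param bValues b-values, s/mm2 (>= 2 distinct).
#' @param signals positive signal intensities, same length.
#' @return list: `adc_um2s`, `s0`, `r_squared` (log-domain), `n_points`.
#' @examples
#' fitAdcLoglinear(c(0, 1000), c(1000, 1000 * exp(-1)))$adc_um2s  # 1000
#' @export
fitAdcLoglinear <- function(bValues, signals) {
  if (length(bValues) != length(signals))
    stop("bValues and signals must have the same length")
  if (length(unique(bValues)) < 2L)
    stop("ADC fit needs at least 2 distinct b-values")
  bad <- which(!is.finite(signals) | signals <= 0)
  if (length(bad))
    stop("non-positive signal at b = ",
         paste(bValues[bad], collapse = ", "), " s/mm2")
  y <- log(signals)
  if (length(bValues) == 2L) {
    # closed form: ADC = log(s1/s2) / (b2 - b1)
    o <- order(bValues)
    slope <- -log(signals[o[1]] / signals[o[2]]) /
      (bValues[o[2]] - bValues[o[1]])
    intercept <- y[o[1]] - slope * bValues[o[1]]
  } else {
    bc <- bValues - mean(bValues)
    slope <- sum(bc * y) / sum(bc * bc)
    intercept <- mean(y) - slope * mean(bValues)
  }
  fitted <- intercept + slope * bValues
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(adc_um2s = adcMm2sToUm2s(-slope), s0 = exp(intercept),
       r_squared = r2, n_points = length(bValues))
}

.signal_matrix <- function(seriesByB, roi) {
  ids <- roi@voxelIds + 1L  # 1-based
  b <- vapply(seriesByB, bValue, numeric(1))
  S <- vapply(seriesByB, function(s) {
    v <- voxels(s)
    v[cbind(ids[, 1], ids[, 2], ids[, 3])]
  }, numeric(nrow(ids)))
  if (nrow(ids) == 1L) S <- matrix(S, nrow = 1L)
  list(b = b, S = S)
}

.filter_b <- function(seriesByB, bSubset) {
  b <- vapply(seriesByB, bValue, numeric(1))
  if (is.null(bSubset)) return(seriesByB)
  missing_b <- setdiff(bSubset, b)
  if (length(missing_b))
    stop("requested b-values not available: ",
         paste(missing_b, collapse = ", "),
         " (available: ", paste(sort(b), collapse = ", "), ")")
  seriesByB[b %in% bSubset]
}

#' Fit ADC to the ROI-mean signal
#'
#' Computes the mean signal over the ROI's member voxels at each b-value,
#' then fits the log-linear model to the means. An optional `bSubset`
#' restricts the fit to specific b-values (e.g. c(200, 1000)).
#'
#' @param seriesByB list of trace [ImageSeries-class], one per b-value.
#' @param roi a [CylindricalROI-class].
#' @param bSubset optional numeric vector of b-values to use.
#' @return list: `vial_label`, `adc_um2s`, `s0`, `r_squared`, `n_points`,
#'   `n_vox`, `source = "fit"`.
#' @export
fitRoiMean <- function(seriesByB, roi, bSubset = NULL) {
  seriesByB <- .filter_b(seriesByB, bSubset)
  sm <- .signal_matrix(seriesByB, roi)
  means <- colMeans(sm$S)
  fit <- fitAdcLoglinear(sm$b, means)
  c(list(vial_label = roi@vialLabel), fit,
    list(n_vox = nrow(roi@voxelIds), source = "fit"))
}

#' Voxelwise ADC fit over an ROI
#'
#' Fits the log-linear model independently per voxel; voxels with any
#' non-positive signal are dropped and counted (a warning is raised when
#' more than half drop out).
#'
#' @inheritParams fitRoiMean
#' @return data.frame with columns i, j, k (0-based voxel indices), r, h
#'   (cylindrical coordinates, mm), adc_um2s, s0, r_squared; attribute
#'   `n_dropped` holds the dropped-voxel count.
#' @export
fitVoxelwise <- function(seriesByB, roi, bSubset = NULL) {
  seriesByB <- .filter_b(seriesByB, bSubset)
  sm <- .signal_matrix(seriesByB, roi)
  ok <- rowSums(!is.finite(sm$S) | sm$S <= 0) == 0L
  n_drop <- sum(!ok)
  if (n_drop > 0.5 * length(ok))
    warning(sprintf("%d of %d voxels dropped (non-positive signal) in vial %s",
                    n_drop, length(ok), roi@vialLabel))
  y <- log(sm$S[ok, , drop = FALSE])
  bc <- sm$b - mean(sm$b)
  denom <- sum(bc * bc)
  slope <- as.vector(y %*% bc) / denom
  ybar <- rowMeans(y)
  intercept <- ybar - slope * mean(sm$b)
  fitted_dev <- outer(slope, bc)                 # fitted - rowmean
  ss_res <- rowSums((y - ybar - fitted_dev)^2)
  ss_tot <- rowSums((y - ybar)^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 1)
  out <- data.frame(i = roi@voxelIds[ok, 1], j = roi@voxelIds[ok, 2],
                    k = roi@voxelIds[ok, 3], r = roi@r[ok], h = roi@h[ok],
                    adc_um2s = adcMm2sToUm2s(-slope), s0 = exp(intercept),
                    r_squared = r2)
  attr(out, "n_dropped") <- n_drop
  out
}

#' Statistics of a scanner-generated (inline) ADC map over an ROI
#'
#' @param adcMap an [ImageSeries-class] with category `adc_map`.
#' @param roi a [CylindricalROI-class].
#' @param unitScale factor converting stored map values to um2/s; defaults
#'   to the series' recorded `adc_unit_scale`.
#' @return list: `vial_label`, `adc_um2s` (ROI mean), `adc_sd_um2s`,
#'   `n_vox`, `source = "inline"`.
#' @export
extractInlineAdc <- function(adcMap, roi, unitScale = NULL) {
  if (!identical(seriesMeta(adcMap)$category, "adc_map"))
    stop("series is not an ADC map")
  if (is.null(unitScale))
    unitScale <- seriesMeta(adcMap)$adc_unit_scale %||% 1
  ids <- roi@voxelIds + 1L
  if (!nrow(ids)) stop("empty ROI")
  vals <- voxels(adcMap)[cbind(ids[, 1], ids[, 2], ids[, 3])] * unitScale
  list(vial_label = roi@vialLabel, adc_um2s = mean(vals),
       adc_sd_um2s = stats::sd(vals), n_vox = length(vals),
       source = "inline")
}
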