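# Spatial ADC bias analysis in cylindrical vial coordinates.
#
# bias = mean estimated ADC - reference ADC (um2/s); the relative bias at a
# cylindrical position subtracts the bias of the small central core
# (r <= 1 mm, |h| <= 1 mm), so profiles show spatial structure independent
# of each vial's overall offset.

#' ADC bias against the reference value
#'
#' @param meanEstimate mean estimated ADC over (possibly repeated)
#'   measurements, um2/s.
#' @param truth reference ADC, um2/s (> 0).
#' @return bias in um2/s.
#' @examples
#' adcBias(1091, 1100)  # -9
#' @export
adcBias <- function(meanEstimate, truth) {
  if (any(truth <= 0)) stop("reference ADC must be positive")
  meanEstimate - truth
}

#' Build spatial bias profiles from voxelwise fits
#'
#' Pools voxelwise ADC estimates from any number of scans in the shared
#' cylindrical frame of each vial, bins them by radial distance and by
#' height, and expresses each bin as relative bias: bin-mean bias minus the
#' central-core bias (r <= `coreR`, |h| <= `coreH`). Confidence intervals
#' are normal-approximation 95% (1.96 * SD / sqrt(n)).
#'
#' @param voxelMaps list of data.frames from [fitVoxelwise()], each with a
#'   `vial_label` column added (one element per scan, or pre-bound rows).
#' @param truthPerVial named numeric: reference ADC (um2/s) per vial label.
#' @param rBinWidth,hBinWidth bin widths in mm (defaults 0.5 and 1).
#' @param coreR,coreH central-core half-extents in mm (defaults 1 and 1).
#' @return named list (per vial) of `SpatialProfile` lists: `vial_label`,
#'   `centre_bias`, `radial` and `height` data.frames (bin centre,
#'   mean relative bias, ci half-width, n).
#' @export
buildSpatialProfiles <- function(voxelMaps, truthPerVial,
                                 rBinWidth = 0.5, hBinWidth = 1,
                                 coreR = 1, coreH = 1) {
  df <- do.call(rbind, voxelMaps)
  if (is.null(df$vial_label))
    stop("voxel maps must carry a vial_label column")
  out <- list()
  for (lab in unique(df$vial_label)) {
    sub <- df[df$vial_label == lab, ]
    truth <- truthPerVial[[lab]]
    if (is.null(truth) || !is.finite(truth))
      stop("no reference ADC for vial ", lab)
    bias_vox <- sub$adc_um2s - truth
    core <- sub$r <= coreR & abs(sub$h) <= coreH
    if (!any(core))
      stop("empty central core (r <= ", coreR, ", |h| <= ", coreH,
           ") for vial ", lab)
    centre_bias <- mean(bias_vox[core])
    rel <- bias_vox - centre_bias

    bin_stats <- function(x, width) {
      idx <- floor(x / width)
      agg <- tapply(rel, idx, function(v)
        c(mean = mean(v), ci = 1.96 * stats::sd(v) / sqrt(length(v)),
          n = length(v)))
      keys <- as.numeric(names(agg))
      m <- do.call(rbind, agg)
      res <- data.frame(centre = (keys + 0.5) * width,
                        mean_bias_relative = m[, "mean"],
                        ci_halfwidth = ifelse(is.na(m[, "ci"]), 0, m[, "ci"]),
                        n = as.integer(m[, "n"]), row.names = NULL)
      res[order(res$centre), , drop = FALSE]
    }
    out[[lab]] <- list(vial_label = lab, centre_bias = centre_bias,
                       radial = bin_stats(sub$r, rBinWidth),
                       height = bin_stats(sub$h, hBinWidth))
  }
  out
}

#' Optimal central ROI size from spatial bias profiles
#'
#' Finds the largest cylindrical (radius, height) on the search grids such
#' that, in every vial, every radial bin with centre <= radius and every
#' height bin with |centre| <= height/2 has |mean relative bias| below the
#' threshold. The radial and height conditions are independent, so the
#' unique maximal pair is (max feasible radius, max feasible height). If no
#' grid value is feasible in one direction, the smallest grid value is
#' returned for it with a warning.
#'
#' @param profiles output of [buildSpatialProfiles()].
#' @param threshold relative-bias threshold, um2/s (default 5).
#' @param radiusGrid candidate radii, mm (default 1--12 by 0.5).
#' @param heightGrid candidate full heights, mm (default 2--32 by 2).
#' @return list: `radius_mm`, `height_mm`, `feasible` (logical: both
#'   directions satisfied).
#' @export
findOptimalRoi <- function(profiles, threshold = 5,
                           radiusGrid = seq(1, 12, by = 0.5),
                           heightGrid = seq(2, 32, by = 2)) {
  if (threshold <= 0) stop("threshold must be positive")
  rad_all <- do.call(rbind, lapply(profiles, `[[`, "radial"))
  hei_all <- do.call(rbind, lapply(profiles, `[[`, "height"))
  feas_r <- vapply(radiusGrid, function(rr) {
    sel <- rad_all$centre <= rr
    all(abs(rad_all$mean_bias_relative[sel]) < threshold)
  }, logical(1))
  feas_h <- vapply(heightGrid, function(hh) {
    sel <- abs(hei_all$centre) <= hh / 2
    all(abs(hei_all$mean_bias_relative[sel]) < threshold)
  }, logical(1))
  ok <- TRUE
  if (any(feas_r)) radius <- max(radiusGrid[feas_r]) else {
    radius <- min(radiusGrid); ok <- FALSE
    warning("no radius on the grid satisfies the bias threshold; ",
            "returning the smallest grid radius")
  }
  if (any(feas_h)) height <- max(heightGrid[feas_h]) else {
    height <- min(heightGrid); ok <- FALSE
    warning("no height on the grid satisfies the bias threshold; ",
            "returning the smallest grid height")
  }
  list(radius_mm = radius, height_mm = height, feasible = ok)
}

#' Plot spatial bias profiles
#'
#' Radial and height panels of mean relative bias with 95% CI ribbons, one
#' line per vial, split into centre/inner-ring and outer-ring panels when
#' ring information is available from the template.
#'
#' @param profiles output of [buildSpatialProfiles()].
#' @param template optional [PhantomTemplate-class] for ring annotation.
#' @return a ggplot object.
#' @export
plotSpatialProfiles <- function(profiles, template = NULL) {
  rows <- list()
  for (p in profiles) {
    rows[[length(rows) + 1L]] <-
      cbind(p$radial, vial = p$vial_label, axis = "radial distance (mm)")
    rows[[length(rows) + 1L]] <-
      cbind(p$height, vial = p$vial_label, axis = "height distance (mm)")
  }
  df <- do.call(rbind, rows)
  if (!is.null(template)) {
    v <- vials(template)
    ring <- ifelse(sqrt(v$dx_mm^2 + v$dy_mm^2) > stats::median(sqrt(v$dx_mm^2 + v$dy_mm^2)),
                   "outer ring", "centre / inner ring")
    df$ring <- ring[match(df$vial, v$label)]
  } else df$ring <- "all vials"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$centre,
                                   y = .data$mean_bias_relative,
                                   colour = .data$vial, fill = .data$vial)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_bias_relative - .data$ci_halfwidth,
      ymax = .data$mean_bias_relative + .data$ci_halfwidth),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(ring ~ axis, scales = "free_x") +
    ggplot2::labs(y = "relative ADC bias (um2/s)", x = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "bottom")
}
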