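# Vial ROI placement.
#
# Two detection routes: shape-based (threshold -> connected components ->
# circularity filter -> constellation match against the template layout by
# exhaustive 1-degree rotation search), robust to EPI distortion; and rigid
# intensity-based registration to a template image carrying pre-drawn ROIs,
# suited to longitudinal data with stable geometry.

#' Carve a cylindrical ROI from an image grid
#'
#' Membership is decided at the voxel centre; the cylinder axis runs along
#' the slice normal through `centre`. Per-voxel cylindrical coordinates are
#' r (in-plane distance to the axis) and h (signed distance along the
#' normal), both in mm.
#'
#' With `nSlices` instead of `height`, the ROI spans that many whole slices
#' nearest the centre and the ROI centre is snapped axially to the middle
#' of the chosen slice run.
#'
#' @param centre world coordinates (mm), length 3.
#' @param radius cylinder radius, mm.
#' @param series an [ImageSeries-class] providing the grid.
#' @param height full cylinder height, mm (exclusive with `nSlices`).
#' @param nSlices integer slice count (exclusive with `height`).
#' @param vialLabel label stored on the ROI.
#' @return a [CylindricalROI-class].
#' @export
carveCylinder <- function(centre, radius, series, height = NULL,
                          nSlices = NULL, vialLabel = "") {
  if (is.null(height) == is.null(nSlices))
    stop("give exactly one of height or nSlices")
  d <- dim(voxels(series))
  sp <- series@spacing
  R <- series@orientation
  nrm <- R[, 3]
  centre <- as.numeric(centre)

  slice_z <- sapply(0:(d[3] - 1), function(k)
    sum((series@origin + R[, 3] * sp[3] * k - centre) * nrm))
  if (!is.null(nSlices)) {
    k0 <- order(abs(slice_z))[seq_len(min(nSlices, d[3]))]
    k_set <- sort(k0)
    # snap the ROI centre onto the middle of the slice run
    centre <- centre + nrm * mean(slice_z[k_set])
    slice_z <- slice_z - mean(slice_z[k_set])
    height <- nSlices * sp[3]
    k_keep <- k_set
  } else {
    k_keep <- which(abs(slice_z) <= height / 2 + 1e-9)
  }
  if (!length(k_keep)) stop("cylinder does not intersect the image grid")

  # in-plane candidate box
  rel <- as.vector(crossprod(R, centre - series@origin)) / sp  # voxel coords
  ri <- ceiling(radius / sp[1]) + 1L
  rj <- ceiling(radius / sp[2]) + 1L
  i_lo <- max(0L, floor(rel[1]) - ri); i_hi <- min(d[1] - 1L, ceiling(rel[1]) + ri)
  j_lo <- max(0L, floor(rel[2]) - rj); j_hi <- min(d[2] - 1L, ceiling(rel[2]) + rj)
  if (i_lo > i_hi || j_lo > j_hi)
    stop("cylinder does not intersect the image grid")
  i_rng <- i_lo:i_hi
  j_rng <- j_lo:j_hi

  grid <- expand.grid(i = i_rng, j = j_rng, k = k_keep - 1L)
  w <- voxelToWorld(series, as.matrix(grid))
  dvec <- sweep(w, 2L, centre)
  h <- as.vector(dvec %*% nrm)
  radial <- dvec - outer(h, nrm)
  r <- sqrt(rowSums(radial^2))
  keep <- r <= radius + 1e-9 & abs(h) <= height / 2 + 1e-9
  if (!any(keep)) stop("cylinder contains no voxel centres")
  new("CylindricalROI", vialLabel = vialLabel, centre = centre,
      radius = radius, height = height,
      voxelIds = as.matrix(grid[keep, , drop = FALSE]),
      r = r[keep], h = h[keep])
}

.carve_policy <- function(centre, policy, series, vialLabel) {
  hm <- policy$height_mode
  if (!is.null(hm$slices))
    carveCylinder(centre, policy$radius_mm, series, nSlices = hm$slices,
                  vialLabel = vialLabel)
  else
    carveCylinder(centre, policy$radius_mm, series, height = hm$height_mm,
                  vialLabel = vialLabel)
}

.detection_failure <- function(msg) {
  stop(structure(class = c("detection_failure", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# global Otsu threshold via EBImage, on the volume rescaled to [0, 1]
.otsu_threshold <- function(vol) {
  vmax <- max(vol)
  if (vmax <= 0) return(Inf)
  vn <- vol / vmax
  th <- EBImage::otsu(EBImage::Image(vn), range = c(0, 1))
  stats::median(th[is.finite(th)]) * vmax
}

#' Shape-based detection of the 13 vial ROIs
#'
#' Thresholds the lowest-b trace image, keeps connected in-plane components
#' of vial-like area and circularity, and matches the 13-point template
#' constellation to the component centroids by exhaustive rotation search
#' (default 1 degree steps) with centroid-aligned translation, minimising
#' the summed nearest-neighbour distance. ROI centres take the matched
#' centroid in-plane (falling back to the transformed template point) and
#' the centre of the contiguous axial range where the vial's mean signal
#' stays at or above half its peak. Fewer than 10 matched vials is a
#' detection failure; a mean residual above 3 mm raises a warning.
#'
#' @param b0 lowest-b trace [ImageSeries-class].
#' @param template a [PhantomTemplate-class].
#' @param policy an ROI policy from [roiPolicy()].
#' @param options list of tuning parameters: `areaBand` (c(0.5, 2), factor
#'   of the expected vial cross-section), `circularity` (0.6),
#'   `rotStepDeg` (1), `axialCut` (0.5), `maxMatchDist` (vial radius, mm),
#'   `overlayPath` (optional PNG path for a diagnostic overlay, written on
#'   failure or on request).
#' @return a [DetectionResult-class].
#' @export
detectShape <- function(b0, template, policy = roiPolicy("optimal"),
                        options = list()) {
  opt <- utils::modifyList(list(areaBand = c(0.5, 2), circularity = 0.6,
                                rotStepDeg = 1, axialCut = 0.5,
                                maxMatchDist = vialRadius(template),
                                overlayPath = NULL), options)
  vol <- voxels(b0)
  d <- dim(vol)
  sp <- b0@spacing
  thr <- .otsu_threshold(vol)
  fg_count <- apply(vol > thr, 3L, sum)
  cand_slices <- which(fg_count >= 0.5 * max(fg_count) & fg_count > 0)
  if (!length(cand_slices))
    .detection_failure("no foreground found: image does not contain a phantom")

  expected_px <- pi * vialRadius(template)^2 / (sp[1] * sp[2])
  cents <- list()
  for (k in cand_slices) {
    bw <- EBImage::Image((vol[, , k] > thr) * 1)
    lab <- EBImage::bwlabel(bw)
    if (max(lab) == 0) next
    shp <- EBImage::computeFeatures.shape(lab)
    mom <- EBImage::computeFeatures.moment(lab)
    if (is.null(shp) || !nrow(shp)) next
    area <- shp[, "s.area"]
    per <- pmax(shp[, "s.perimeter"], 1e-6)
    circ <- 4 * pi * area / per^2
    ok <- area >= opt$areaBand[1] * expected_px &
          area <= opt$areaBand[2] * expected_px &
          circ >= opt$circularity
    if (!any(ok)) next
    idx0 <- cbind(mom[ok, "m.cx"] - 1, mom[ok, "m.cy"] - 1, k - 1)
    w <- voxelToWorld(b0, idx0)
    cents[[length(cents) + 1L]] <- w[, 1:2, drop = FALSE]
  }
  pts <- do.call(rbind, cents)
  if (is.null(pts) || nrow(pts) == 0L) {
    .overlay_dump(b0, NULL, opt$overlayPath)
    .detection_failure("no vial-like components found")
  }

  # cluster slice-wise centroids into per-vial candidates
  clusters <- list()
  for (i in seq_len(nrow(pts))) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      if (sqrt(sum((colMeans(clusters[[ci]]) - pts[i, ])^2)) <
          vialRadius(template)) {
        clusters[[ci]] <- rbind(clusters[[ci]], pts[i, ])
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- pts[i, , drop = FALSE]
  }
  counts <- vapply(clusters, nrow, integer(1))
  keep <- counts >= max(1L, floor(0.5 * max(counts)))
  cand <- t(vapply(clusters[keep], colMeans, numeric(2)))

  # exhaustive rotation search, centroid-aligned translation
  tpl <- as.matrix(vials(template)[, c("dx_mm", "dy_mm")])
  cand_ctr <- colMeans(cand)
  thetas <- seq(0, 360 - opt$rotStepDeg, by = opt$rotStepDeg)
  best <- NULL
  for (th in thetas) {
    a <- th * pi / 180
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
    tp <- tpl %*% t(rot)
    tp <- sweep(tp, 2L, cand_ctr - colMeans(tp), "+")
    dmat <- outer(rowSums(tp^2), rowSums(cand^2), "+") - 2 * tp %*% t(cand)
    res <- sum(sqrt(pmax(apply(dmat, 1L, min), 0)))
    th_norm <- ((th + 180) %% 360) - 180
    if (is.null(best) || res < best$res - 1e-9 ||
        (abs(res - best$res) <= 1e-9 && abs(th_norm) < abs(best$th_norm))) {
      best <- list(res = res, th = th, th_norm = th_norm, tp = tp,
                   translation = cand_ctr - colMeans(tpl %*% t(rot)))
    }
  }

  # unique greedy assignment template point -> candidate
  tp <- best$tp
  dmat <- sqrt(pmax(outer(rowSums(tp^2), rowSums(cand^2), "+") -
                    2 * tp %*% t(cand), 0))
  match_idx <- rep(NA_integer_, nrow(tp))
  dm <- dmat
  repeat {
    m <- which(dm == min(dm), arr.ind = TRUE)[1, , drop = FALSE]
    if (dm[m] > opt$maxMatchDist || !is.finite(dm[m])) break
    match_idx[m[1]] <- m[2]
    dm[m[1], ] <- Inf
    dm[, m[2]] <- Inf
    if (all(!is.finite(dm))) break
  }
  n_matched <- sum(!is.na(match_idx))
  if (n_matched < 10L) {
    .overlay_dump(b0, cand, opt$overlayPath)
    .detection_failure(sprintf(
      "only %d of 13 vials matched; phantom not detected", n_matched))
  }
  resid <- dmat[cbind(which(!is.na(match_idx)), match_idx[!is.na(match_idx)])]
  quality <- mean(resid)
  if (quality > 3)
    warning(sprintf("detection quality poor: mean residual %.2f mm", quality))

  labels <- vials(template)$label
  inplane <- tp
  inplane[!is.na(match_idx), ] <- cand[match_idx[!is.na(match_idx)], ]

  # axial centre: contiguous slice range with mean vial signal >= cut * peak
  slice_z <- b0@origin[3] + b0@orientation[3, 3] * sp[3] * (0:(d[3] - 1))
  ii <- (0:(d[1] - 1)) * sp[1] + b0@origin[1]
  jj <- (0:(d[2] - 1)) * sp[2] + b0@origin[2]
  rois <- vector("list", 13L)
  for (vI in seq_len(13L)) {
    dx2 <- (ii - inplane[vI, 1])^2
    dy2 <- (jj - inplane[vI, 2])^2
    disc <- outer(dx2, dy2, "+") <= (0.9 * vialRadius(template))^2
    prof <- vapply(seq_len(d[3]), function(k) mean(vol[, , k][disc]),
                   numeric(1))
    pk <- which.max(prof)
    lo <- pk; hi <- pk
    while (lo > 1 && prof[lo - 1] >= opt$axialCut * prof[pk]) lo <- lo - 1
    while (hi < d[3] && prof[hi + 1] >= opt$axialCut * prof[pk]) hi <- hi + 1
    zc <- (slice_z[lo] + slice_z[hi]) / 2
    rois[[vI]] <- .carve_policy(c(inplane[vI, ], zc), policy, b0, labels[vI])
  }
  names(rois) <- labels
  if (!is.null(opt$overlayPath)) .overlay_dump(b0, inplane, opt$overlayPath)
  new("DetectionResult", rois = rois,
      transform = list(rotation_deg = best$th_norm,
                       translation_mm = best$translation),
      quality = quality)
}

.overlay_dump <- function(b0, centres, path) {
  if (is.null(path)) return(invisible(NULL))
  vol <- voxels(b0)
  k <- which.max(apply(vol, 3L, sum))
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  sp <- b0@spacing
  xs <- b0@origin[1] + (0:(dim(vol)[1] - 1)) * sp[1]
  ys <- b0@origin[2] + (0:(dim(vol)[2] - 1)) * sp[2]
  graphics::image(xs, ys, vol[, , k], col = grDevices::gray.colors(64),
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("detection overlay (slice %d)", k))
  if (!is.null(centres))
    graphics::points(centres[, 1], centres[, 2], col = "red", pch = 3, cex = 2)
  invisible(path)
}

.trilinear <- function(series, w) {
  # sample series at world points (n x 3); outside the grid -> 0
  sp <- series@spacing
  v <- voxels(series)
  d <- dim(v)
  rel <- sweep(w, 2L, series@origin) %*% series@orientation
  rel <- sweep(rel, 2L, sp, "/")
  out <- numeric(nrow(rel))
  i0 <- floor(rel)
  fr <- rel - i0
  ok <- i0[, 1] >= 0 & i0[, 1] <= d[1] - 2 &
        i0[, 2] >= 0 & i0[, 2] <= d[2] - 2 &
        i0[, 3] >= 0 & i0[, 3] <= d[3] - 2
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE] + 1L
  f <- fr[ok, , drop = FALSE]
  g <- function(di, dj, dk)
    v[cbind(i0[, 1] + di, i0[, 2] + dj, i0[, 3] + dk)]
  out[ok] <-
    g(0L, 0L, 0L) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    g(1L, 0L, 0L) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    g(0L, 1L, 0L) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    g(1L, 1L, 0L) * f[, 1] * f[, 2] * (1 - f[, 3]) +
    g(0L, 0L, 1L) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    g(1L, 0L, 1L) * f[, 1] * (1 - f[, 2]) * f[, 3] +
    g(0L, 1L, 1L) * (1 - f[, 1]) * f[, 2] * f[, 3] +
    g(1L, 1L, 1L) * f[, 1] * f[, 2] * f[, 3]
  out
}

.intensity_centroid <- function(series) {
  v <- voxels(series)
  if (sum(v) <= 0)
    .detection_failure("image has no signal: intensity centroid undefined")
  d <- dim(v)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  w <- voxelToWorld(series, idx)
  wt <- as.vector(v) / sum(v)
  colSums(w * wt)
}

#' Rigid registration-based ROI detection
#'
#' Registers the target to a template image (in-plane translation and
#' rotation plus axial translation; phantom acquisitions are axial by
#' scope) by maximising normalised cross-correlation with Nelder-Mead,
#' initialised from the intensity centroids. Template ROI centres are
#' mapped through the fitted transform; radius and height are unchanged.
#'
#' @param target target [ImageSeries-class].
#' @param templateImage template [ImageSeries-class].
#' @param templateRois list of [CylindricalROI-class] defined on the
#'   template image.
#' @param minCorrelation registration acceptance threshold on the final
#'   correlation (default 0.5); below it, detection fails.
#' @return a [DetectionResult-class] (quality = 1 - final correlation).
#' @export
detectRegistration <- function(target, templateImage, templateRois,
                               minCorrelation = 0.5) {
  c0 <- .intensity_centroid(templateImage)
  c1 <- .intensity_centroid(target)
  init <- c(c1 - c0, 0)  # dx, dy, dz, theta(deg)

  v <- voxels(templateImage)
  d <- dim(v)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  # sample foreground plus surrounding background so the correlation metric
  # sees the phantom outline even on images with uniform vial intensity
  tvals <- as.vector(v)
  if (stats::sd(tvals) == 0)
    .detection_failure("template image has no usable contrast")
  if (nrow(idx) > 30000L) {
    pick <- round(seq(1L, nrow(idx), length.out = 30000L))
    idx <- idx[pick, , drop = FALSE]
    tvals <- tvals[pick]
  }
  w_tpl <- voxelToWorld(templateImage, idx)

  apply_tf <- function(p, w) {
    a <- p[4] * pi / 180
    rot <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L)
    sweep(sweep(w, 2L, c0) %*% t(rot), 2L, c0 + p[1:3], "+")
  }
  objective <- function(p) {
    sv <- .trilinear(target, apply_tf(p, w_tpl))
    if (stats::sd(sv) == 0) return(1)
    val <- -stats::cor(tvals, sv)
    if (!is.finite(val)) 1 else val
  }
  fit <- stats::optim(c(init[1:3], 0), objective, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
  final_cor <- -fit$value
  if (!is.finite(final_cor) || final_cor < minCorrelation)
    .detection_failure(sprintf(
      "registration failed: correlation %.3f below %.2f",
      final_cor, minCorrelation))
  p <- fit$par
  rois <- lapply(templateRois, function(roi) {
    ctr <- apply_tf(p, matrix(roiCentre(roi), 1L))
    carveCylinder(as.vector(ctr), roi@radius, target, height = roi@height,
                  vialLabel = roi@vialLabel)
  })
  names(rois) <- vapply(rois, function(x) x@vialLabel, character(1))
  new("DetectionResult", rois = rois,
      transform = list(rotation_deg = p[4], translation_mm = p[1:2],
                       translation_z_mm = p[3]),
      quality = 1 - final_cor)
}
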