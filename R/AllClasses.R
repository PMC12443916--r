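#' @import methods
NULL

#' PhantomTemplate: geometry and reference values of a 13-vial diffusion phantom
#'
#' Describes the NIST/NCI/RSNA-style diffusion phantom: thirteen vials of
#' aqueous polyvinylpyrrolidone (PVP) at concentrations 0--50\%, arranged in
#' an axial plane as one central vial plus two rings. Vial centre offsets are
#' expressed in the phantom frame (mm, central vial at the origin); each vial
#' carries its certified reference ADC at 0 degC in um2/s.
#'
#' @slot vials data.frame with one row per vial and columns \code{label},
#'   \code{pvp_percent}, \code{dx_mm}, \code{dy_mm}, \code{ref_adc_um2s}.
#' @slot vialRadius numeric, inner vial radius in mm.
#' @slot vialHeight numeric, fluid height in mm.
#' @slot ringRadii numeric, nominal ring radii in mm (informational).
#' @export
setClass("PhantomTemplate",
  representation(vials = "data.frame", vialRadius = "numeric",
                 vialHeight = "numeric", ringRadii = "numeric"))

.validPhantomTemplate <- function(object) {
  msgs <- character()
  v <- object@vials
  need <- c("label", "pvp_percent", "dx_mm", "dy_mm", "ref_adc_um2s")
  if (!all(need %in% names(v)))
    return(paste("vials must have columns:", paste(need, collapse = ", ")))
  if (nrow(v) != 13L)
    msgs <- c(msgs, sprintf("phantom template must contain exactly 13 vials, got %d", nrow(v)))
  if (anyDuplicated(v$label))
    msgs <- c(msgs, "duplicate vial labels")
  if (any(!v$pvp_percent %in% c(0, 10, 20, 30, 40, 50)))
    msgs <- c(msgs, "pvp_percent must be one of 0, 10, 20, 30, 40, 50")
  if (any(!is.finite(v$ref_adc_um2s)) || any(v$ref_adc_um2s <= 0))
    msgs <- c(msgs, "ref_adc_um2s must be positive and finite")
  if (length(object@vialRadius) != 1L || object@vialRadius <= 0)
    msgs <- c(msgs, "vialRadius must be a single positive number")
  if (length(object@vialHeight) != 1L || object@vialHeight <= 0)
    msgs <- c(msgs, "vialHeight must be a single positive number")
  if (length(msgs)) msgs else TRUE
}
setValidity("PhantomTemplate", .validPhantomTemplate)

setMethod("show", "PhantomTemplate", function(object) {
  cat("PhantomTemplate with", nrow(object@vials), "vials\n")
  cat("  vial radius:", object@vialRadius, "mm, height:", object@vialHeight, "mm\n")
  cat("  PVP %:", paste(sort(unique(object@vials$pvp_percent)), collapse = ", "), "\n")
  cat("  ref ADC range:", min(object@vials$ref_adc_um2s), "-",
      max(object@vials$ref_adc_um2s), "um2/s\n")
})

#' @describeIn PhantomTemplate data.frame of vial specifications.
#' @param object a \code{PhantomTemplate}.
#' @export
setGeneric("vials", function(object) standardGeneric("vials"))

#' @rdname PhantomTemplate
#' @export
setMethod("vials", "PhantomTemplate", function(object) object@vials)

#' @describeIn PhantomTemplate vial radius in mm.
#' @export
setGeneric("vialRadius", function(object) standardGeneric("vialRadius"))

#' @rdname PhantomTemplate
#' @export
setMethod("vialRadius", "PhantomTemplate", function(object) object@vialRadius)

#' @describeIn PhantomTemplate vial height in mm.
#' @export
setGeneric("vialHeight", function(object) standardGeneric("vialHeight"))

#' @rdname PhantomTemplate
#' @export
setMethod("vialHeight", "PhantomTemplate", function(object) object@vialHeight)

#' ImageSeries: one 3-D magnitude volume with geometry and normalised metadata
#'
#' A single DICOM series resampled to nothing: the voxel array as stored,
#' plus the geometric mapping to the DICOM patient (LPS) frame and the
#' vendor-normalised acquisition metadata. Voxel indices are 0-based in the
#' world mapping; the value is taken at the voxel centre, so
#' \code{world = origin + orientation \%*\% (spacing * index)}.
#'
#' @slot voxels 3-D numeric array, dimensions (columns, rows, slices);
#'   intensities after rescale/vendor scaling.
#' @slot spacing numeric length 3, mm along the three array dimensions.
#' @slot origin numeric length 3, world position (mm) of voxel (0,0,0).
#' @slot orientation 3x3 matrix, columns = direction cosines of the three
#'   array axes (orthonormal).
#' @slot meta list of normalised metadata: \code{category} (one of
#'   \code{trace_dwi}, \code{adc_map}, \code{other}), \code{b_value} (s/mm2,
#'   trace series), \code{vendor}, \code{series_uid}, \code{study_uid},
#'   \code{session_id}, \code{repeat_index}, \code{acq_time},
#'   \code{study_date}, \code{intensity_scale_applied},
#'   \code{adc_unit_scale}.
#' @export
setClass("ImageSeries",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 orientation = "matrix", meta = "list"))

.validImageSeries <- function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 3L)
    msgs <- c(msgs, "voxels must be a 3-D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive numbers (mm)")
  if (length(object@origin) != 3L)
    msgs <- c(msgs, "origin must be length 3")
  R <- object@orientation
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-6)
    msgs <- c(msgs, "orientation must be a 3x3 orthonormal matrix (tol 1e-6)")
  cat_ <- object@meta$category
  if (is.null(cat_) || !cat_ %in% c("trace_dwi", "adc_map", "other"))
    msgs <- c(msgs, "meta$category must be trace_dwi, adc_map or other")
  if (identical(cat_, "trace_dwi")) {
    b <- object@meta$b_value
    if (is.null(b) || !is.finite(b) || b < 0)
      msgs <- c(msgs, "trace_dwi series must carry a b_value >= 0")
  }
  if (identical(cat_, "adc_map") && is.null(object@meta$adc_unit_scale))
    msgs <- c(msgs, "adc_map series must record adc_unit_scale")
  if (length(msgs)) msgs else TRUE
}
setValidity("ImageSeries", .validImageSeries)

setMethod("show", "ImageSeries", function(object) {
  d <- dim(object@voxels)
  m <- object@meta
  cat(sprintf("ImageSeries %dx%dx%d, spacing %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3]))
  cat("  category:", m$category,
      if (identical(m$category, "trace_dwi")) sprintf("(b = %g s/mm2)", m$b_value) else "",
      "\n")
  cat("  vendor:", m$vendor %||% "unknown",
      " session:", m$session_id %||% "?",
      " repeat:", m$repeat_index %||% 1L, "\n")
})

#' @describeIn ImageSeries the voxel array.
#' @param object an \code{ImageSeries}.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname ImageSeries
#' @export
setMethod("voxels", "ImageSeries", function(object) object@voxels)

#' @describeIn ImageSeries voxel spacing (mm).
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname ImageSeries
#' @export
setMethod("voxelSpacing", "ImageSeries", function(object) object@spacing)

#' @describeIn ImageSeries world origin (mm).
#' @export
setGeneric("seriesOrigin", function(object) standardGeneric("seriesOrigin"))

#' @rdname ImageSeries
#' @export
setMethod("seriesOrigin", "ImageSeries", function(object) object@origin)

#' @describeIn ImageSeries 3x3 direction matrix.
#' @export
setGeneric("seriesOrientation", function(object) standardGeneric("seriesOrientation"))

#' @rdname ImageSeries
#' @export
setMethod("seriesOrientation", "ImageSeries", function(object) object@orientation)

#' @describeIn ImageSeries normalised metadata list.
#' @export
setGeneric("seriesMeta", function(object) standardGeneric("seriesMeta"))

#' @rdname ImageSeries
#' @export
setMethod("seriesMeta", "ImageSeries", function(object) object@meta)

#' @describeIn ImageSeries b-value in s/mm2 (NA for non-trace series).
#' @export
setGeneric("bValue", function(object) standardGeneric("bValue"))

#' @rdname ImageSeries
#' @export
setMethod("bValue", "ImageSeries", function(object) {
  b <- object@meta$b_value
  if (is.null(b)) NA_real_ else b
})

#' World coordinates of voxel indices
#'
#' Maps 0-based voxel indices to the DICOM patient (LPS) frame, taking the
#' value position at the voxel centre.
#'
#' @param series an \code{ImageSeries}.
#' @param idx integer matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxelToWorld <- function(series, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(idx %*% diag(series@spacing) %*% t(series@orientation), 2L,
        series@origin, "+")
}

#' CylindricalROI: a cylindrical vial region with per-voxel coordinates
#'
#' Member voxels of a cylinder (axis along the slice normal), each carrying
#' its cylindrical coordinates: radial distance r from the axis and signed
#' height h along the axis, both in mm from the ROI centre.
#'
#' @slot vialLabel character, the vial this ROI samples.
#' @slot centre numeric length 3, world position (mm) of the ROI centre.
#' @slot radius numeric, mm.
#' @slot height numeric, mm (full height; members satisfy |h| <= height/2).
#' @slot voxelIds integer matrix (n x 3) of 0-based voxel indices.
#' @slot r numeric, per-voxel radial distance (mm).
#' @slot h numeric, per-voxel signed height distance (mm).
#' @export
setClass("CylindricalROI",
  representation(vialLabel = "character", centre = "numeric",
                 radius = "numeric", height = "numeric",
                 voxelIds = "matrix", r = "numeric", h = "numeric"))

.validCylindricalROI <- function(object) {
  msgs <- character()
  n <- nrow(object@voxelIds)
  if (n == 0L) msgs <- c(msgs, "ROI has no member voxels")
  if (length(object@r) != n || length(object@h) != n)
    msgs <- c(msgs, "r/h must have one entry per member voxel")
  if (any(!is.finite(object@r)) || any(!is.finite(object@h)))
    msgs <- c(msgs, "cylindrical coordinates must be finite")
  tol <- 1e-9
  if (n > 0L && any(object@r > object@radius + tol))
    msgs <- c(msgs, "member voxel with r > radius")
  if (n > 0L && any(abs(object@h) > object@height / 2 + tol))
    msgs <- c(msgs, "member voxel with |h| > height/2")
  if (length(msgs)) msgs else TRUE
}
setValidity("CylindricalROI", .validCylindricalROI)

setMethod("show", "CylindricalROI", function(object) {
  cat(sprintf("CylindricalROI '%s': r = %g mm, h = %g mm, %d voxels\n",
              object@vialLabel, object@radius, object@height,
              nrow(object@voxelIds)))
  cat(sprintf("  centre (mm): %.2f, %.2f, %.2f\n",
              object@centre[1], object@centre[2], object@centre[3]))
})

#' @describeIn CylindricalROI ROI centre in world mm.
#' @param object a \code{CylindricalROI}.
#' @export
setGeneric("roiCentre", function(object) standardGeneric("roiCentre"))

#' @rdname CylindricalROI
#' @export
setMethod("roiCentre", "CylindricalROI", function(object) object@centre)

#' @describeIn CylindricalROI data.frame of member voxels with (r, h).
#' @export
setGeneric("roiVoxels", function(object) standardGeneric("roiVoxels"))

#' @rdname CylindricalROI
#' @export
setMethod("roiVoxels", "CylindricalROI", function(object) {
  data.frame(i = object@voxelIds[, 1], j = object@voxelIds[, 2],
             k = object@voxelIds[, 3], r = object@r, h = object@h)
})

#' DetectionResult: 13 detected vial ROIs plus the fitted phantom transform
#'
#' @slot rois named list of 13 \code{CylindricalROI}, names = vial labels.
#' @slot transform list with \code{rotation_deg} and \code{translation_mm}
#'   (phantom frame to world, in-plane).
#' @slot quality numeric, mean residual (mm) between detected vial centres
#'   and the transformed template constellation.
#' @export
setClass("DetectionResult",
  representation(rois = "list", transform = "list", quality = "numeric"))

.validDetectionResult <- function(object) {
  msgs <- character()
  if (length(object@rois) != 13L)
    msgs <- c(msgs, "detection must produce exactly 13 ROIs")
  if (!all(vapply(object@rois, is, logical(1), "CylindricalROI")))
    msgs <- c(msgs, "rois must all be CylindricalROI")
  labs <- vapply(object@rois, function(x) x@vialLabel, character(1))
  if (anyDuplicated(labs))
    msgs <- c(msgs, "ROI labels must be unique (bijective with vials)")
  if (length(msgs)) msgs else TRUE
}
setValidity("DetectionResult", .validDetectionResult)

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf("DetectionResult: %d ROIs, rotation %.2f deg, translation (%.2f, %.2f) mm\n",
              length(object@rois),
              object@transform$rotation_deg %||% NA_real_,
              object@transform$translation_mm[1] %||% NA_real_,
              object@transform$translation_mm[2] %||% NA_real_))
  cat(sprintf("  match quality (mean residual): %.3f mm\n", object@quality))
})

#' @describeIn DetectionResult named list of detected ROIs.
#' @param object a \code{DetectionResult}.
#' @export
setGeneric("detectedRois", function(object) standardGeneric("detectedRois"))

#' @rdname DetectionResult
#' @export
setMethod("detectedRois", "DetectionResult", function(object) object@rois)

#' @describeIn DetectionResult fitted phantom-to-world transform.
#' @export
setGeneric("detectionTransform", function(object) standardGeneric("detectionTransform"))

#' @rdname DetectionResult
#' @export
setMethod("detectionTransform", "DetectionResult", function(object) object@transform)

`%||%` <- function(a, b) if (is.null(a)) b else a
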