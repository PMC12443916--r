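#' Load a phantom template from a YAML configuration
#'
#' Reference ADC values are certified per phantom serial number, so they are
#' configuration, not code. The YAML layout is:
#' \preformatted{
#' geometry:
#'   vial_radius_mm: 13
#'   vial_height_mm: 40
#'   ring_radii_mm: [28, 58]
#' vials:
#'   - {label: PVP0_centre, pvp_percent: 0,
#'      centre_offset_mm: [0, 0], ref_adc_um2_per_s: 1100}
#'   # ... 13 entries in total
#' }
#'
#' @param path path to the YAML config.
#' @return a validated [PhantomTemplate-class].
#' @seealso [writePhantomTemplate()], [syntheticPhantomTemplate()]
#' @export
loadPhantomTemplate <- function(path) {
  if (!file.exists(path))
    stop("phantom config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$vials) || is.null(cfg$geometry))
    stop("phantom config must contain 'vials' and 'geometry' sections")
  rows <- lapply(cfg$vials, function(v) {
    off <- as.numeric(v$centre_offset_mm)
    if (length(off) != 2L || any(!is.finite(off)))
      stop("vial '", v$label, "': centre_offset_mm must be two finite numbers")
    data.frame(label = as.character(v$label),
               pvp_percent = as.numeric(v$pvp_percent),
               dx_mm = off[1], dy_mm = off[2],
               ref_adc_um2s = as.numeric(v$ref_adc_um2_per_s))
  })
  vdf <- do.call(rbind, rows)
  g <- cfg$geometry
  new("PhantomTemplate", vials = vdf,
      vialRadius = as.numeric(g$vial_radius_mm),
      vialHeight = as.numeric(g$vial_height_mm),
      ringRadii = as.numeric(g$ring_radii_mm %||% numeric()))
}

#' Write a phantom template back to YAML
#'
#' Inverse of [loadPhantomTemplate()]; re-loading the written file yields an
#' identical template.
#'
#' @param template a [PhantomTemplate-class].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writePhantomTemplate <- function(template, path) {
  stopifnot(is(template, "PhantomTemplate"))
  v <- template@vials
  vial_list <- lapply(seq_len(nrow(v)), function(i) {
    list(label = v$label[i], pvp_percent = v$pvp_percent[i],
         centre_offset_mm = c(v$dx_mm[i], v$dy_mm[i]),
         ref_adc_um2_per_s = v$ref_adc_um2s[i])
  })
  yaml::write_yaml(list(
    geometry = list(vial_radius_mm = template@vialRadius,
                    vial_height_mm = template@vialHeight,
                    ring_radii_mm = template@ringRadii),
    vials = vial_list), path)
  invisible(path)
}

#' Synthetic 13-vial phantom template
#'
#' A phantom layout with synthetic (round-number) reference ADC values for
#' simulation and testing: one central vial, an inner ring of six vials at
#' 28 mm, and an outer ring of six vials at 58 mm. The outer-ring angles are
#' deliberately staggered so the 13-point constellation has no non-trivial
#' rotational symmetry, which keeps geometric vial labelling unambiguous;
#' the values are NOT certified reference data for any physical phantom.
#'
#' @return a [PhantomTemplate-class].
#' @export
syntheticPhantomTemplate <- function() {
  inner_ang <- seq(0, 300, by = 60)
  outer_ang <- c(20, 80, 140, 190, 260, 320)
  ref <- c(`0` = 1100, `10` = 900, `20` = 700, `30` = 500,
           `40` = 300, `50` = 200)
  pvp_inner <- c(0, 10, 20, 30, 40, 50)
  pvp_outer <- c(10, 20, 30, 40, 50, 0)
  deg2rad <- pi / 180
  vdf <- rbind(
    data.frame(label = "PVP0_centre", pvp_percent = 0, dx_mm = 0, dy_mm = 0,
               ref_adc_um2s = ref[["0"]]),
    data.frame(label = sprintf("PVP%d_inner%d", pvp_inner, seq_along(inner_ang)),
               pvp_percent = pvp_inner,
               dx_mm = 28 * cos(inner_ang * deg2rad),
               dy_mm = 28 * sin(inner_ang * deg2rad),
               ref_adc_um2s = unname(ref[as.character(pvp_inner)])),
    data.frame(label = sprintf("PVP%d_outer%d", pvp_outer, seq_along(outer_ang)),
               pvp_percent = pvp_outer,
               dx_mm = 58 * cos(outer_ang * deg2rad),
               dy_mm = 58 * sin(outer_ang * deg2rad),
               ref_adc_um2s = unname(ref[as.character(pvp_outer)])))
  new("PhantomTemplate", vials = vdf, vialRadius = 13, vialHeight = 40,
      ringRadii = c(28, 58))
}

.roi_policies <- list(
  manual_single_site = list(name = "manual_single_site", radius_mm = 5,
                            height_mode = list(slices = 3L),
                            placement = "fixed_template"),
  manual_multi_centre = list(name = "manual_multi_centre", radius_mm = 8,
                             height_mode = list(slices = 1L),
                             placement = "detected"),
  optimal = list(name = "optimal", radius_mm = 5,
                 height_mode = list(height_mm = 10),
                 placement = "detected"),
  whole_vial = list(name = "whole_vial", radius_mm = 12,
                    height_mode = list(height_mm = 32),
                    placement = "detected"))

#' Named ROI placement policies
#'
#' The four cylindrical ROI geometries used for per-vial ADC assessment:
#' \describe{
#'   \item{manual_single_site}{3 central slices, radius 5 mm (matches the
#'     single-centre longitudinal protocol).}
#'   \item{manual_multi_centre}{single slice, radius 8 mm (matches the
#'     multi-centre protocol).}
#'   \item{optimal}{radius 5 mm, height 10 mm: the central low-variation
#'     region derived from the spatial bias analysis.}
#'   \item{whole_vial}{radius 12 mm, height 32 mm, covering most of a vial.}
#' }
#'
#' @param name one of the four policy names.
#' @return list with `name`, `radius_mm`, `height_mode` (either
#'   `list(slices = n)` or `list(height_mm = h)`), and `placement`.
#' @examples
#' roiPolicy("optimal")$radius_mm       # 5
#' roiPolicy("whole_vial")$height_mode  # height_mm = 32
#' @export
roiPolicy <- function(name) {
  p <- .roi_policies[[name]]
  if (is.null(p))
    stop("unknown ROI policy '", name, "'; available: ",
         paste(names(.roi_policies), collapse = ", "))
  p
}

#' @rdname roiPolicy
#' @export
roiPolicyNames <- function() names(.roi_policies)
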