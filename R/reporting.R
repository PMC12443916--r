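# Pipeline orchestration and reporting. CSV is the canonical output; the
# PDF report is a rendering of the same numbers.

#' Analyse a set of image series against a phantom template
#'
#' The core pipeline: groups series into sessions and repeats, detects the
#' 13 vial ROIs per scan (shape-based or registration-based) on the
#' lowest-b trace image, fits the ROI-mean ADC per vial, extracts inline
#' ADC-map statistics where maps are present, and optionally returns
#' voxelwise fits for spatial analysis.
#'
#' @param seriesList list of [ImageSeries-class] (e.g. from
#'   [scanDicomDirectory()] or [simulatePhantom()]).
#' @param template a [PhantomTemplate-class].
#' @param policy ROI policy name or object from [roiPolicy()].
#' @param detection "shape" or "registration".
#' @param bSubset optional b-values to fit (e.g. c(200, 1000)).
#' @param templateImage,templateRois required for registration detection.
#' @param voxelwise also compute voxelwise fits (whole-vial ROIs).
#' @param detectOptions options passed to [detectShape()].
#' @param dataset label recorded in the results.
#' @param sessionRule session grouping rule, see [groupSessions()].
#' @return list: `results` (per-vial data.frame), `detections` (per scan),
#'   `voxel_maps` (list of voxelwise data.frames, when requested),
#'   `series_table` (sorting table).
#' @export
analyzeSeries <- function(seriesList, template, policy = "optimal",
                          detection = c("shape", "registration"),
                          bSubset = NULL, templateImage = NULL,
                          templateRois = NULL, voxelwise = FALSE,
                          detectOptions = list(), dataset = "dataset",
                          sessionRule = "study_date") {
  detection <- match.arg(detection)
  if (is.character(policy)) policy <- roiPolicy(policy)
  if (!length(seriesList)) stop("no series found")
  grp <- groupSessions(seriesList, sessionRule)
  series <- grp$series
  meta <- lapply(series, seriesMeta)
  sess <- vapply(meta, function(m) m$session_id, character(1))
  reps <- vapply(meta, function(m) m$repeat_index, integer(1))
  cats <- vapply(meta, function(m) m$category, character(1))

  v <- vials(template)
  rows <- list()
  detections <- list()
  voxel_maps <- list()
  for (s in unique(sess)) {
    for (rp in sort(unique(reps[sess == s]))) {
      in_scan <- sess == s & reps == rp
      trace <- series[in_scan & cats == "trace_dwi"]
      maps <- series[in_scan & cats == "adc_map"]
      if (!length(trace)) next
      b <- vapply(trace, bValue, numeric(1))
      trace <- trace[order(b)]
      b <- sort(b)
      det <- if (detection == "shape")
        detectShape(trace[[1]], template, policy, detectOptions)
      else
        detectRegistration(trace[[1]], templateImage, templateRois)
      detections[[paste(s, rp, sep = "/")]] <- det
      for (lab in names(detectedRois(det))) {
        roi <- detectedRois(det)[[lab]]
        fit <- fitRoiMean(trace, roi, bSubset)
        vi <- match(lab, v$label)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = dataset, session = s, repeat_index = rp,
          vial_label = lab,
          pvp_percent = if (is.na(vi)) NA_real_ else v$pvp_percent[vi],
          roi_policy = policy$name, adc_um2s = fit$adc_um2s, s0 = fit$s0,
          r2 = fit$r_squared, n_b = fit$n_points, n_vox = fit$n_vox,
          source = "fit", stringsAsFactors = FALSE)
        for (am in maps) {
          ia <- extractInlineAdc(am, roi)
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = dataset, session = s, repeat_index = rp,
            vial_label = lab,
            pvp_percent = if (is.na(vi)) NA_real_ else v$pvp_percent[vi],
            roi_policy = policy$name, adc_um2s = ia$adc_um2s,
            s0 = NA_real_, r2 = NA_real_, n_b = NA_integer_,
            n_vox = ia$n_vox, source = "inline", stringsAsFactors = FALSE)
        }
        if (voxelwise) {
          wroi <- carveCylinder(roiCentre(roi), roiPolicy("whole_vial")$radius_mm,
                                trace[[1]],
                                height = roiPolicy("whole_vial")$height_mode$height_mm,
                                vialLabel = lab)
          vm <- fitVoxelwise(trace, wroi, bSubset)
          vm$vial_label <- lab
          vm$session <- s
          vm$repeat_index <- rp
          voxel_maps[[length(voxel_maps) + 1L]] <- vm
        }
      }
    }
  }
  if (!length(rows)) stop("no trace DW-MRI series found")
  list(results = do.call(rbind, rows), detections = detections,
       voxel_maps = if (voxelwise) voxel_maps else NULL,
       series_table = grp$table)
}

#' Run the full analysis from a configuration
#'
#' Reads DICOM from `input_dir`, runs [analyzeSeries()], and writes the
#' result bundle to `output_dir`: `per_vial.csv` (canonical per-vial
#' results), `series_table.csv`, a detection overlay PNG, optionally
#' `voxelwise.csv`, and a PDF QA report with (a) the detected ROIs, (b) the
#' bias-vs-reference table and (c) per-vial signal decay curves.
#'
#' @param config list or YAML file path with fields: `input_dir`,
#'   `phantom_config` (YAML path, see [loadPhantomTemplate()]),
#'   `roi_policy`, `detection`, optional `b_subset`, `inline_adc_scale`,
#'   `session_rule`, `voxelwise`, `output_dir`, `dataset`.
#' @return the [analyzeSeries()] bundle plus `output_dir`, invisibly.
#' @export
runAnalysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("input_dir", "phantom_config", "output_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config missing fields: ", paste(miss, collapse = ", "))
  template <- loadPhantomTemplate(config$phantom_config)
  series <- scanDicomDirectory(config$input_dir,
                               adcUnitScale = config$inline_adc_scale %||% 1)
  if (!length(series)) stop("no series found in ", config$input_dir)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- analyzeSeries(
    series, template,
    policy = config$roi_policy %||% "optimal",
    detection = config$detection %||% "shape",
    bSubset = config$b_subset,
    voxelwise = isTRUE(config$voxelwise),
    detectOptions = list(overlayPath = file.path(out_dir, "detection_overlay.png")),
    dataset = config$dataset %||% basename(config$input_dir),
    sessionRule = config$session_rule %||% "study_date")
  utils::write.csv(bundle$results, file.path(out_dir, "per_vial.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$series_table, file.path(out_dir, "series_table.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$voxel_maps))
    utils::write.csv(do.call(rbind, bundle$voxel_maps),
                     file.path(out_dir, "voxelwise.csv"), row.names = FALSE)
  writePdfReport(bundle, template, series,
                 file.path(out_dir, "qa_report.pdf"))
  bundle$output_dir <- out_dir
  invisible(bundle)
}

#' Render the QA report PDF
#'
#' Three components: the detected ROIs drawn on the lowest-b image, a
#' per-vial accuracy table (mean ADC, reference, bias), and per-vial
#' signal-decay panels with the fitted mono-exponential curve.
#'
#' @param bundle output of [analyzeSeries()].
#' @param template a [PhantomTemplate-class].
#' @param seriesList the analysed series.
#' @param path output PDF path.
#' @return `path`, invisibly.
#' @export
writePdfReport <- function(bundle, template, seriesList, path) {
  res <- bundle$results
  fit_res <- res[res$source == "fit", ]
  v <- vials(template)
  grDevices::pdf(path, width = 8, height = 10)
  on.exit(grDevices::dev.off())

  # (a) ROI overlay on the lowest-b series of the first scan
  cats <- vapply(seriesList, function(s) seriesMeta(s)$category, character(1))
  trace <- seriesList[cats == "trace_dwi"]
  b <- vapply(trace, bValue, numeric(1))
  b0 <- trace[[which.min(b)]]
  det <- bundle$detections[[1]]
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 3, 1))
  vol <- voxels(b0)
  k <- which.max(apply(vol, 3L, sum))
  sp <- b0@spacing
  xs <- b0@origin[1] + (0:(dim(vol)[1] - 1)) * sp[1]
  ys <- b0@origin[2] + (0:(dim(vol)[2] - 1)) * sp[2]
  graphics::image(xs, ys, vol[, , k], col = grDevices::gray.colors(64),
                  xlab = "x (mm)", ylab = "y (mm)", asp = 1,
                  main = "(a) detected ROIs")
  th <- seq(0, 2 * pi, length.out = 64)
  for (roi in detectedRois(det)) {
    ctr <- roiCentre(roi)
    graphics::lines(ctr[1] + roi@radius * cos(th),
                    ctr[2] + roi@radius * sin(th), col = "red")
    graphics::text(ctr[1], ctr[2], roi@vialLabel, col = "yellow", cex = 0.4)
  }

  # (b) accuracy table
  agg <- stats::aggregate(adc_um2s ~ vial_label, fit_res, mean)
  agg$ref <- v$ref_adc_um2s[match(agg$vial_label, v$label)]
  agg$bias <- adcBias(agg$adc_um2s, agg$ref)
  graphics::plot.new()
  graphics::title("(b) ADC accuracy vs reference (um2/s)")
  txt <- c(sprintf("%-18s %10s %10s %10s", "vial", "mean ADC", "reference",
                   "bias"),
           sprintf("%-18s %10.1f %10.1f %10.2f", agg$vial_label,
                   agg$adc_um2s, agg$ref, agg$bias))
  graphics::text(0, seq(0.95, by = -0.055, length.out = length(txt)), txt,
                 adj = 0, family = "mono", cex = 0.7)

  # (c) signal decay per vial (first scan)
  first_scan <- fit_res[fit_res$session == fit_res$session[1] &
                        fit_res$repeat_index == fit_res$repeat_index[1], ]
  roi_list <- detectedRois(det)
  graphics::par(mfrow = c(4, 4), mar = c(3, 3, 2, 1))
  bb <- sort(b)
  for (lab in first_scan$vial_label) {
    roi <- roi_list[[lab]]
    means <- vapply(trace[order(b)], function(s) {
      ids <- roi@voxelIds + 1L
      mean(voxels(s)[cbind(ids[, 1], ids[, 2], ids[, 3])])
    }, numeric(1))
    row <- first_scan[first_scan$vial_label == lab, ]
    graphics::plot(bb, means, pch = 16, cex = 0.8, xlab = "", ylab = "",
                   main = sprintf("%s\nADC %.0f", lab, row$adc_um2s[1]),
                   cex.main = 0.7)
    bfine <- seq(min(bb), max(bb), length.out = 50)
    graphics::lines(bfine,
                    row$s0[1] * exp(-bfine * adcUm2sToMm2s(row$adc_um2s[1])),
                    col = "blue")
  }
  invisible(path)
}

#' Compute summary metrics from a per-vial results CSV
#'
#' In `qiba` mode computes the QIBA diffusion-profile metrics per vial
#' (sessions from the `session` column, repeats within sessions); with a
#' single session the long-term metrics are empty and a warning is given.
#' In `rc_rdc` mode treats `session` as the institute: %RC per institute
#' and vial (institutes without repeats excluded) and %RDC across
#' institutes from the first repeat.
#'
#' @param resultsCsv path to a per-vial CSV from [runAnalysis()] (columns
#'   session, repeat_index, vial_label, adc_um2s; `source == "fit"` rows
#'   are used when a source column is present).
#' @param mode "qiba" or "rc_rdc".
#' @param refAdc named numeric, reference ADC (um2/s) per vial label
#'   (required for qiba mode).
#' @param outCsv optional output CSV path.
#' @return data.frame of metrics (one row per vial for qiba; %RC rows plus
#'   %RDC rows for rc_rdc).
#' @export
runMetrics <- function(resultsCsv, mode = c("qiba", "rc_rdc"),
                       refAdc = NULL, outCsv = NULL) {
  mode <- match.arg(mode)
  df <- utils::read.csv(resultsCsv, stringsAsFactors = FALSE)
  need <- c("session", "repeat_index", "vial_label", "adc_um2s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("results CSV lacks column(s): ", paste(miss, collapse = ", "))
  if ("source" %in% names(df)) df <- df[df$source == "fit", ]
  if (mode == "qiba") {
    if (is.null(refAdc)) stop("qiba mode needs refAdc")
    if (length(unique(df$session)) < 2L)
      warning("single session: long-term QIBA metrics unavailable")
    rows <- lapply(split(df, df$vial_label), function(g) {
      truth <- refAdc[[g$vial_label[1]]]
      if (is.null(truth)) return(NULL)
      m <- qibaSummary(g$adc_um2s, g$session, truth)
      data.frame(vial_label = g$vial_label[1], pct_bias = m$pct_bias,
                 rc_st_um2ms = m$rc_st, cv_st_pct = m$cv_st,
                 rc_lt_um2ms = m$rc_lt, cv_lt_pct = m$cv_lt,
                 conformant = all(m$conformant, na.rm = TRUE))
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    rc <- pctRC(df$adc_um2s, df$session, df$vial_label)
    if (length(rc$excluded))
      message("institutes excluded from %RC (no repeats): ",
              paste(rc$excluded, collapse = ", "))
    first <- df[df$repeat_index == 1L, ]
    rdc <- pctRDC(first$adc_um2s, first$session, first$vial_label)
    out <- rbind(
      data.frame(metric = "pct_rc", vial_label = rc$per_vial$vial,
                 institute = rc$per_vial$institute,
                 value = rc$per_vial$pct_rc),
      data.frame(metric = "pct_rdc", vial_label = rdc$per_vial$vial,
                 institute = NA_character_, value = rdc$per_vial$pct_rdc),
      data.frame(metric = c("pct_rc_median", "pct_rdc_median"),
                 vial_label = NA_character_, institute = NA_character_,
                 value = c(rc$median, rdc$median)))
  }
  if (!is.null(outCsv)) utils::write.csv(out, outCsv, row.names = FALSE)
  out
}

#' Equivalence comparison against a reference per-vial CSV
#'
#' Aligns this pipeline's per-vial results with an independent reference
#' (e.g. a previously published central analysis) on (session,
#' repeat_index, vial_label), forms paired ADC differences per vial, runs
#' the minimal-tolerance TOST search, and reports the per-vial equivalence
#' at the found tolerance.
#'
#' @param resultsCsv path to this pipeline's per-vial CSV.
#' @param referenceCsv path to the reference CSV (columns session,
#'   repeat_index, vial_label, adc_um2s).
#' @param grid tolerance grid, see [minimalEquivalenceTolerance()].
#' @param plotPath optional path for a bias boxplot (PDF/PNG by extension).
#' @param refAdc optional named reference ADC for the bias plot.
#' @return list: `delta` (minimal tolerance, um2/s), `achieved`,
#'   `table` (per-vial n, median diff, p_tost, stars), `diffs` per vial.
#' @export
compareToReference <- function(resultsCsv, referenceCsv,
                               grid = equivalenceToleranceGrid(),
                               plotPath = NULL, refAdc = NULL) {
  res <- utils::read.csv(resultsCsv, stringsAsFactors = FALSE)
  ref <- utils::read.csv(referenceCsv, stringsAsFactors = FALSE)
  if ("source" %in% names(res)) res <- res[res$source == "fit", ]
  keys <- c("session", "repeat_index", "vial_label")
  miss <- setdiff(keys, intersect(names(res), names(ref)))
  if (length(miss))
    stop("both CSVs need columns: ", paste(keys, collapse = ", "))
  m <- merge(res[, c(keys, "adc_um2s")], ref[, c(keys, "adc_um2s")],
             by = keys, suffixes = c("_res", "_ref"))
  if (!nrow(m)) stop("no overlapping (session, repeat, vial) pairs")
  m$diff <- m$adc_um2s_res - m$adc_um2s_ref
  diffs <- split(m$diff, m$vial_label)
  search <- minimalEquivalenceTolerance(diffs, grid)
  delta_eval <- if (search$achieved) search$delta else max(grid)
  tab <- do.call(rbind, lapply(names(diffs), function(lab) {
    t <- suppressWarnings(tostWilcoxon(diffs[[lab]], delta_eval))
    data.frame(vial_label = lab, n = t$n,
               median_diff = stats::median(diffs[[lab]]),
               p_tost = t$p_tost, equivalent = t$equivalent,
               stars = t$stars, stringsAsFactors = FALSE)
  }))
  if (!is.null(plotPath)) {
    long <- rbind(data.frame(vial = m$vial_label, adc = m$adc_um2s_res,
                             analysis = "this pipeline"),
                  data.frame(vial = m$vial_label, adc = m$adc_um2s_ref,
                             analysis = "reference"))
    if (!is.null(refAdc))
      long$adc <- long$adc - unname(refAdc[long$vial])
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$vial, y = .data$adc,
                                            fill = .data$analysis)) +
      ggplot2::geom_boxplot(outlier.size = 0.5) +
      ggplot2::labs(y = if (is.null(refAdc)) "ADC (um2/s)"
                        else "ADC bias (um2/s)", x = NULL) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    ggplot2::ggsave(plotPath, p, width = 8, height = 5)
  }
  list(delta = search$delta, achieved = search$achieved, table = tab,
       diffs = diffs)
}
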