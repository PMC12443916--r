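# Minimal classic DICOM part-10 I/O (explicit VR little endian).
#
# Scope: single-frame magnitude MR images with the geometry, rescale and
# diffusion tags this pipeline needs. Enhanced (multi-frame) DICOM and
# compressed transfer syntaxes are rejected with an explicit error; they are
# outside the supported input set, matching the exclusion applied to the
# source studies.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_MR <- "1.2.840.10008.5.1.4.1.1.4"
.SOP_ENHANCED_MR <- "1.2.840.10008.5.1.4.1.1.4.1"

.str_vrs <- c("UI", "SH", "CS", "DA", "TM", "LO", "PN", "DS", "IS", "AE", "LT", "ST")
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.tagkey <- function(group, elem) sprintf("%04X%04X", group, elem)

.uint16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(rbind(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L))))
}

.uint32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
                 (x %/% 16777216) %% 256)))
}

.enc_elem <- function(group, elem, vr, value) {
  if (vr %in% .str_vrs) {
    s <- paste(as.character(value), collapse = "\\")
    payload <- charToRaw(s)
    if (length(payload) %% 2L == 1L)
      payload <- c(payload, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  } else if (vr == "US") {
    payload <- .uint16le(value)
  } else if (vr == "UL") {
    payload <- .uint32le(value)
  } else if (vr == "FD") {
    payload <- writeBin(as.double(value), raw(), size = 8L, endian = "little")
  } else if (vr == "FL") {
    payload <- writeBin(as.double(value), raw(), size = 4L, endian = "little")
  } else if (vr == "OW") {
    payload <- value  # already raw
  } else {
    stop("internal: unsupported VR encoder ", vr)
  }
  hdr <- c(.uint16le(group), .uint16le(elem), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(hdr, as.raw(c(0L, 0L)), .uint32le(length(payload)), payload)
  } else {
    if (length(payload) > 65534L) stop("internal: value too long for short VR")
    c(hdr, .uint16le(length(payload)), payload)
  }
}

.fmt_ds <- function(x) vapply(x, function(v) sprintf("%.8g", v), character(1))

.new_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste0("1.2.826.0.1.3680043.10.1415.",
           sample.int(1e8L, 1L), ".", counter)
  }
})

#' Write one ImageSeries as a classic DICOM series
#'
#' One file per slice, explicit VR little endian. The diffusion b-value is
#' encoded per `dialect`: \code{standard} uses the standard diffusion tag
#' (0018,9087); \code{siemens}, \code{philips} and \code{ge} instead use the
#' respective vendor-private locations, and \code{philips} additionally
#' stores intensities under the floating-point private scale convention.
#'
#' @param series an [ImageSeries-class].
#' @param dir output directory (created; one series per directory).
#' @param dialect one of "standard", "siemens", "philips", "ge".
#' @param seriesNumber integer series number.
#' @return the directory, invisibly.
#' @export
writeDicomSeries <- function(series, dir, dialect = "standard",
                             seriesNumber = 1L) {
  dialect <- match.arg(dialect, c("standard", "siemens", "philips", "ge"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- series@voxels
  d <- dim(v)
  m <- series@meta
  manuf <- switch(dialect, siemens = "SIEMENS", philips = "Philips Medical Systems",
                  ge = "GE MEDICAL SYSTEMS", standard = "SYNTHETIC")
  series_uid <- m$series_uid %||% .new_uid()
  study_uid <- m$study_uid %||% .new_uid()
  is_adc <- identical(m$category, "adc_map")

  # intensity encoding: value = (raw*slope + intercept) [/ private scale]
  vmax <- max(v, 0)
  slope <- if (vmax > 0) vmax / 60000 else 1
  intercept <- 0
  priv_scale <- if (dialect == "philips") 0.5 else NA_real_
  enc <- function(x) {
    raw_vals <- if (is.na(priv_scale)) (x - intercept) / slope
                else (x * priv_scale - intercept) / slope
    pmin(pmax(round(raw_vals), 0), 65535)
  }

  spc <- series@spacing
  R <- series@orientation
  for (k in seq_len(d[3])) {
    ipp <- series@origin + R[, 3] * spc[3] * (k - 1)
    els <- list()
    add <- function(g, e, vr, val) els[[length(els) + 1L]] <<- .enc_elem(g, e, vr, val)
    img_type <- if (is_adc) "DERIVED\\PRIMARY\\ADC" else "ORIGINAL\\PRIMARY\\M\\ND"
    add(0x0008, 0x0008, "CS", img_type)
    add(0x0008, 0x0016, "UI", .SOP_MR)
    sop_uid <- .new_uid()
    add(0x0008, 0x0018, "UI", sop_uid)
    add(0x0008, 0x0020, "DA", m$study_date %||% "20240101")
    add(0x0008, 0x0031, "TM", m$acq_time %||% "120000")
    add(0x0008, 0x0032, "TM", m$acq_time %||% "120000")
    add(0x0008, 0x0060, "CS", "MR")
    add(0x0008, 0x0070, "LO", manuf)
    add(0x0008, 0x103E, "LO", m$series_description %||%
          (if (is_adc) "dADC map" else sprintf("trace DWI b=%g", m$b_value %||% 0)))
    add(0x0010, 0x0010, "PN", "PHANTOM^QA")
    add(0x0010, 0x0020, "LO", "PHANTOM001")
    add(0x0018, 0x0050, "DS", .fmt_ds(spc[3]))
    if (!is_adc) {
      b <- m$b_value %||% 0
      if (dialect == "standard") {
        add(0x0018, 0x9087, "FD", b)
      } else if (dialect == "siemens") {
        add(0x0019, 0x0010, "LO", "SIEMENS MR HEADER")
        add(0x0019, 0x100C, "IS", sprintf("%d", as.integer(round(b))))
      } else if (dialect == "philips") {
        add(0x2001, 0x0010, "LO", "Philips Imaging DD 001")
        add(0x2001, 0x1003, "FL", b)
      } else if (dialect == "ge") {
        add(0x0043, 0x0010, "LO", "GEMS_PARM_01")
        add(0x0043, 0x1039, "IS", sprintf("%d", as.integer(round(b)) + 1000000000L))
      }
    }
    add(0x0020, 0x000D, "UI", study_uid)
    add(0x0020, 0x000E, "UI", series_uid)
    add(0x0020, 0x0011, "IS", sprintf("%d", seriesNumber))
    add(0x0020, 0x0013, "IS", sprintf("%d", k))
    add(0x0020, 0x0032, "DS", .fmt_ds(ipp))
    add(0x0020, 0x0037, "DS", .fmt_ds(c(R[, 1], R[, 2])))
    if (dialect == "philips") {
      add(0x2005, 0x0010, "LO", "Philips MR Imaging DD 001")
      add(0x2005, 0x100E, "FL", priv_scale)
    }
    add(0x0028, 0x0002, "US", 1L)
    add(0x0028, 0x0004, "CS", "MONOCHROME2")
    add(0x0028, 0x0010, "US", d[2])  # Rows
    add(0x0028, 0x0011, "US", d[1])  # Columns
    add(0x0028, 0x0030, "DS", .fmt_ds(c(spc[2], spc[1])))  # row, col spacing
    add(0x0028, 0x0100, "US", 16L)
    add(0x0028, 0x0101, "US", 16L)
    add(0x0028, 0x0102, "US", 15L)
    add(0x0028, 0x0103, "US", 0L)
    add(0x0028, 0x1052, "DS", .fmt_ds(intercept))
    add(0x0028, 0x1053, "DS", .fmt_ds(slope))
    # pixel data: row-major (row 1 first), uint16 little endian
    add(0x7FE0, 0x0010, "OW", .uint16le(enc(as.vector(v[, , k]))))

    meta_els <- c(
      .enc_elem(0x0002, 0x0002, "UI", .SOP_MR),
      .enc_elem(0x0002, 0x0003, "UI", sop_uid),
      .enc_elem(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
      .enc_elem(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.10.1415.1"))
    meta <- c(.enc_elem(0x0002, 0x0000, "UL", length(meta_els)), meta_els)
    out <- c(raw(128L), charToRaw("DICM"), meta, unlist(els))
    writeBin(out, file.path(dir, sprintf("slice_%03d.dcm", k)))
  }
  invisible(dir)
}

.read_uint16 <- function(bytes, off) {
  as.integer(bytes[off]) + 256L * as.integer(bytes[off + 1L])
}

.read_uint32 <- function(bytes, off) {
  as.numeric(bytes[off]) + 256 * as.numeric(bytes[off + 1L]) +
    65536 * as.numeric(bytes[off + 2L]) + 16777216 * as.numeric(bytes[off + 3L])
}

.dcm_error <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.decode_value <- function(vr, payload) {
  if (vr %in% .str_vrs) {
    s <- rawToChar(payload[payload != as.raw(0)])
    s <- sub("\\s+$", "", s)
    parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
    if (vr %in% c("DS", "IS")) as.numeric(parts) else parts
  } else if (vr == "US") {
    readBin(payload, "integer", n = length(payload) / 2L, size = 2L,
            signed = FALSE, endian = "little")
  } else if (vr == "UL") {
    readBin(payload, "integer", n = length(payload) / 4L, size = 4L,
            endian = "little")
  } else if (vr == "FD") {
    readBin(payload, "double", n = length(payload) / 8L, size = 8L,
            endian = "little")
  } else if (vr %in% c("FL", "OF")) {
    readBin(payload, "double", n = length(payload) / 4L, size = 4L,
            endian = "little")
  } else {
    payload  # raw (OW/OB/UN)
  }
}

#' Read one classic DICOM file
#'
#' Parses an explicit-VR little-endian part-10 file and returns the decoded
#' data elements plus the pixel matrix. Enhanced multi-frame DICOM,
#' sequences with undefined length, and non-explicit-LE transfer syntaxes
#' raise an error of class \code{dicom_unsupported}.
#'
#' @param path file path.
#' @return list with \code{tags} (named by "GGGGEEEE" hex key), \code{pixels}
#'   (integer matrix, dim = c(Columns, Rows)), and \code{path}.
#' @export
readDicomFile <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 140)
    .dcm_error(paste0("not a DICOM file (too short): ", path), "dicom_unreadable")
  bytes <- readBin(path, raw(), n = n)
  if (rawToChar(bytes[129:132]) != "DICM")
    .dcm_error(paste0("not a DICOM part-10 file: ", path), "dicom_unreadable")
  tags <- list()
  off <- 133L  # 1-based offset after preamble+magic
  while (off + 7L <= n + 1L && off <= n) {
    group <- .read_uint16(bytes, off)
    elem <- .read_uint16(bytes, off + 2L)
    vr <- rawToChar(bytes[(off + 4L):(off + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      .dcm_error(sprintf("non explicit-VR element at offset %d in %s", off, path),
                 "dicom_unsupported")
    if (vr %in% .long_vrs) {
      len <- .read_uint32(bytes, off + 8L)
      hdr_len <- 12L
    } else {
      len <- .read_uint16(bytes, off + 6L)
      hdr_len <- 8L
    }
    if (len == 4294967295)  # undefined length (sequences): unsupported
      .dcm_error(paste0("undefined-length sequence (enhanced DICOM?) in ", path),
                 "dicom_unsupported")
    data_off <- off + hdr_len
    if (data_off + len - 1L > n)
      .dcm_error(paste0("truncated DICOM element in ", path), "dicom_unreadable")
    payload <- if (len > 0) bytes[data_off:(data_off + len - 1L)] else raw(0)
    key <- .tagkey(group, elem)
    if (vr != "SQ") tags[[key]] <- .decode_value(vr, payload)
    off <- data_off + len
  }
  ts <- tags[["00020010"]]
  if (!is.null(ts) && !identical(ts, .TS_EXPLICIT_LE))
    .dcm_error(paste0("unsupported transfer syntax ", ts, " in ", path),
               "dicom_unsupported")
  if (identical(tags[["00080016"]], .SOP_ENHANCED_MR))
    .dcm_error(paste0("enhanced multi-frame DICOM is not supported: ", path),
               "dicom_unsupported")
  nf <- tags[["00280008"]]
  if (!is.null(nf) && as.numeric(nf)[1] > 1)
    .dcm_error(paste0("enhanced multi-frame DICOM is not supported: ", path),
               "dicom_unsupported")
  rows <- tags[["00280010"]]
  cols <- tags[["00280011"]]
  pix <- tags[["7FE00010"]]
  pixels <- NULL
  if (!is.null(pix) && !is.null(rows) && !is.null(cols)) {
    vals <- readBin(pix, "integer", n = rows * cols, size = 2L,
                    signed = FALSE, endian = "little")
    pixels <- matrix(vals, nrow = cols)  # [column, row]
  }
  list(tags = tags, pixels = pixels, path = path)
}

#' Apply DICOM intensity rescaling and vendor private scaling
#'
#' Stored values are mapped to physical intensities as
#' \code{value = raw * slope + intercept}, then divided by the
#' vendor-private floating-point scale factor when one is present
#' (Philips-style convention).
#'
#' @param raw numeric array of stored values.
#' @param slope,intercept standard rescale slope/intercept.
#' @param privateScale vendor-private scale factor, or NA when absent.
#' @return scaled numeric array.
#' @examples
#' applyIntensityScaling(100, slope = 2, intercept = 10)       # 210
#' applyIntensityScaling(100, slope = 2, privateScale = 0.5)   # 400
#' @export
applyIntensityScaling <- function(raw, slope = 1, intercept = 0,
                                  privateScale = NA_real_) {
  v <- raw * slope + intercept
  if (!is.na(privateScale)) {
    if (privateScale == 0)
      stop("zero vendor-private intensity scale factor")
    v <- v / privateScale
  }
  v
}

#' Extract the diffusion b-value from a DICOM header
#'
#' The standard diffusion tag (0018,9087) takes precedence; when absent the
#' vendor-private location for the given vendor is consulted (Siemens
#' (0019,100C), Philips (2001,1003), GE (0043,1039); the GE value is
#' de-offset by 1e9 when encoded that way). With vendor "unknown" all
#' private locations are tried.
#'
#' @param tags named tag list from [readDicomFile()].
#' @param vendor one of "siemens", "philips", "ge", "unknown".
#' @return b-value in s/mm2.
#' @export
extractBValue <- function(tags, vendor = "unknown") {
  std <- tags[["00189087"]]
  if (!is.null(std) && is.finite(std[1])) return(as.numeric(std[1]))
  priv_keys <- switch(vendor,
                      siemens = "0019100C",
                      philips = "20011003",
                      ge = "00431039",
                      c("0019100C", "20011003", "00431039"))
  for (key in priv_keys) {
    val <- tags[[key]]
    if (!is.null(val) && is.finite(val[1])) {
      b <- as.numeric(val[1])
      if (b >= 1e9) b <- b - 1e9
      return(b)
    }
  }
  uid <- tags[["0020000E"]]
  stop("no diffusion b-value found in standard or vendor-private tags",
       if (!is.null(uid)) paste0(" (series ", uid, ")") else "")
}

.vendor_from_manufacturer <- function(manuf) {
  if (is.null(manuf) || !length(manuf)) return("unknown")
  m <- tolower(manuf[1])
  if (grepl("siemens", m)) "siemens"
  else if (grepl("philips", m)) "philips"
  else if (grepl("^ge|ge medical", m)) "ge"
  else "unknown"
}

#' Scan a directory tree for classic DICOM series
#'
#' Reads every file below `path`, groups single-frame DICOM files by series
#' UID, sorts slices along the slice normal, applies intensity scaling, and
#' classifies each series as trace DW-MRI, inline ADC map, or other.
#' Unreadable files are reported and skipped; enhanced multi-frame DICOM
#' raises an error.
#'
#' @param path directory.
#' @param adcUnitScale factor converting stored inline-ADC values to um2/s
#'   (default 1).
#' @param quiet suppress skip messages.
#' @return list of [ImageSeries-class], ordered by series UID.
#' @export
scanDicomDirectory <- function(path, adcUnitScale = 1, quiet = FALSE) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  files <- sort(list.files(path, recursive = TRUE, full.names = TRUE))
  slices <- list()
  for (f in files) {
    res <- tryCatch(readDicomFile(f), error = function(e) {
      if (inherits(e, "dicom_unsupported")) stop(e)  # hard error, no skip
      if (!quiet)
        message("skipping file: ", f, " (", conditionMessage(e), ")")
      NULL
    })
    if (!is.null(res)) slices[[length(slices) + 1L]] <- res
  }
  if (!length(slices)) return(list())
  uids <- vapply(slices, function(s) s$tags[["0020000E"]][1] %||% "unknown",
                 character(1))
  out <- list()
  for (uid in sort(unique(uids))) {
    grp <- slices[uids == uid]
    out[[length(out) + 1L]] <- .assemble_series(grp, adcUnitScale)
  }
  out
}

.assemble_series <- function(grp, adcUnitScale) {
  t1 <- grp[[1]]$tags
  iop <- t1[["00200037"]]
  if (is.null(iop) || length(iop) != 6)
    stop("series missing ImageOrientationPatient")
  rdir <- iop[1:3]; cdir <- iop[4:6]
  ndir <- c(rdir[2] * cdir[3] - rdir[3] * cdir[2],
            rdir[3] * cdir[1] - rdir[1] * cdir[3],
            rdir[1] * cdir[2] - rdir[2] * cdir[1])
  pos <- vapply(grp, function(s) sum(s$tags[["00200032"]] * ndir), numeric(1))
  ord <- order(pos)
  grp <- grp[ord]; pos <- pos[ord]
  nz <- length(grp)
  ps <- t1[["00280030"]]  # row spacing, col spacing
  slice_sp <- if (nz > 1) stats::median(diff(pos)) else
    (t1[["00180050"]][1] %||% 1)
  d1 <- dim(grp[[1]]$pixels)
  vox <- array(0, dim = c(d1[1], d1[2], nz))
  slope <- t1[["00281053"]][1] %||% 1
  intercept <- t1[["00281052"]][1] %||% 0
  priv <- t1[["2005100E"]]
  priv <- if (is.null(priv)) NA_real_ else priv[1]
  for (k in seq_len(nz))
    vox[, , k] <- applyIntensityScaling(grp[[k]]$pixels, slope, intercept, priv)

  vendor <- .vendor_from_manufacturer(t1[["00080070"]])
  img_type <- t1[["00080008"]] %||% character()
  descr <- t1[["0008103E"]][1] %||% ""
  is_adc <- any(img_type == "ADC") || grepl("ADC", descr, ignore.case = FALSE)
  b <- tryCatch(extractBValue(t1, vendor), error = function(e) NA_real_)
  category <- if (is_adc) "adc_map" else if (is.finite(b)) "trace_dwi" else "other"

  meta <- list(category = category, vendor = vendor,
               series_uid = t1[["0020000E"]][1],
               study_uid = t1[["0020000D"]][1],
               study_date = t1[["00080020"]][1] %||% NA_character_,
               acq_time = t1[["00080032"]][1] %||% NA_character_,
               series_description = descr,
               intensity_scale_applied = !is.na(priv) || slope != 1 || intercept != 0,
               repeat_index = 1L, session_id = NA_character_)
  if (category == "trace_dwi") meta$b_value <- b
  if (category == "adc_map") meta$adc_unit_scale <- adcUnitScale

  new("ImageSeries", voxels = vox,
      spacing = c(ps[2], ps[1], abs(slice_sp)),
      origin = grp[[1]]$tags[["00200032"]],
      orientation = cbind(rdir, cdir, ndir, deparse.level = 0),
      meta = meta)
}

#' Group series into sessions and repeats
#'
#' Sessions default to the study date (one imaging session per calendar
#' day); within a session, series acquired at the same time form one repeat
#' (e.g. the b-value sweep of a single acquisition), and repeats are ordered
#' by acquisition time. Series lacking date metadata land in session
#' "unassigned" with a warning.
#'
#' @param seriesList list of [ImageSeries-class].
#' @param rule "study_date" (default) or "study_uid".
#' @return list with \code{series} (metadata-updated list) and \code{table}
#'   (data.frame: series_uid, category, b_value, session, repeat_index).
#' @export
groupSessions <- function(seriesList, rule = c("study_date", "study_uid")) {
  rule <- match.arg(rule)
  key <- vapply(seriesList, function(s)
    as.character(seriesMeta(s)[[rule]] %||% NA_character_), character(1))
  if (anyNA(key)) {
    warning(sum(is.na(key)), " series without ", rule,
            " assigned to session 'unassigned'")
    key[is.na(key)] <- "unassigned"
  }
  times <- vapply(seriesList, function(s)
    seriesMeta(s)$acq_time %||% "000000", character(1))
  out <- seriesList
  tab <- data.frame(series_uid = character(), category = character(),
                    b_value = numeric(), session = character(),
                    repeat_index = integer(), stringsAsFactors = FALSE)
  for (sess in sort(unique(key))) {
    sel <- which(key == sess)
    tsel <- times[sel]
    rep_levels <- sort(unique(tsel))
    for (ii in seq_along(sel)) {
      i <- sel[ii]
      ridx <- match(tsel[ii], rep_levels)
      m <- out[[i]]@meta
      m$session_id <- sess
      m$repeat_index <- ridx
      out[[i]]@meta <- m
      tab <- rbind(tab, data.frame(
        series_uid = m$series_uid %||% NA_character_,
        category = m$category, b_value = m$b_value %||% NA_real_,
        session = sess, repeat_index = ridx, stringsAsFactors = FALSE))
    }
  }
  list(series = out, table = tab)
}
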