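#' EPID image constructor
#'
#' A portal image: a matrix of detector readings in arbitrary linear units,
#' its pixel spacing, and whether it records the MLC strip delivery or the
#' open field.
#'
#' @param pixels numeric matrix (rows x columns) of detector readings.
#' @param pixel_spacing numeric length-2, mm per pixel (row, column).
#' @param kind `"STRIP"` or `"OPEN"`.
#' @param machine_id,date acquisition metadata for reporting (optional).
#' @return object of class `epid_image`.
#' @export
epid_image <- function(pixels, pixel_spacing, kind = c("STRIP", "OPEN"),
                       machine_id = NA_character_, date = NA_character_) {
  kind <- match.arg(kind)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("image must have >= 1 pixel")
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be > 0")
  structure(list(pixels = pixels, pixel_spacing = as.numeric(pixel_spacing),
                 kind = kind, machine_id = as.character(machine_id),
                 date = as.character(date)),
            class = "epid_image")
}

#' @export
print.epid_image <- function(x, ...) {
  cat(sprintf("<epid_image> %s %dx%d px, %.3f x %.3f mm/px\n", x$kind,
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing[1],
              x$pixel_spacing[2]))
  invisible(x)
}

#' Read an EPID DICOM RT Image
#'
#' Reads rows/columns, 16-bit pixel data, image-plane pixel spacing, and the
#' rescale slope/intercept (applied on read). The image kind is taken from
#' the RT image label (a label containing "OPEN" marks the open field).
#'
#' @param path RT Image DICOM file.
#' @param kind override the kind detected from the label, or `NULL` to
#'   auto-detect.
#' @return an [epid_image()].
#' @export
read_rtimage <- function(path, kind = NULL) {
  dcm <- dcm_read(path)
  ds <- dcm$data
  need <- function(g, e, what) {
    el <- dcm_find(ds, g, e)
    if (is.null(el)) stop("RT Image missing ", what, ": ", path)
    el
  }
  rows <- dcm_decode_us(need(0x0028, 0x0010, "Rows"))
  cols <- dcm_decode_us(need(0x0028, 0x0011, "Columns"))
  sp_el <- dcm_find(ds, 0x3002, 0x0011)
  if (is.null(sp_el)) sp_el <- dcm_find(ds, 0x0028, 0x0030)
  spacing <- if (is.null(sp_el)) c(1, 1) else dcm_decode_numeric(sp_el)
  slope_el <- dcm_find(ds, 0x0028, 0x1053)
  inter_el <- dcm_find(ds, 0x0028, 0x1052)
  slope <- if (is.null(slope_el)) 1 else dcm_decode_numeric(slope_el)
  inter <- if (is.null(inter_el)) 0 else dcm_decode_numeric(inter_el)
  px_el <- need(0x7FE0, 0x0010, "PixelData")
  vals <- dcm_decode_us(px_el)
  if (length(vals) != rows * cols)
    stop("pixel data size does not match Rows x Columns: ", path)
  m <- matrix(vals * slope + inter, nrow = rows, ncol = cols, byrow = TRUE)
  if (is.null(kind)) {
    lab_el <- dcm_find(ds, 0x3002, 0x0002)
    lab <- if (is.null(lab_el)) "" else dcm_decode_string1(lab_el)
    kind <- if (grepl("OPEN", toupper(lab))) "OPEN" else "STRIP"
  }
  st_el <- dcm_find(ds, 0x0008, 0x1010)
  dt_el <- dcm_find(ds, 0x0008, 0x0023)
  epid_image(m, spacing, kind,
             machine_id = if (is.null(st_el)) NA else dcm_decode_string1(st_el),
             date = if (is.null(dt_el)) NA else dcm_decode_string1(dt_el))
}

#' Write an EPID image as a DICOM RT Image
#'
#' Stores pixels as unsigned 16-bit with a rescale slope chosen so the full
#' dynamic range is preserved (slope 1 when readings are already integers in
#' range, so integer fixtures round-trip exactly).
#'
#' @param image an [epid_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rtimage <- function(image, path) {
  px <- image$pixels
  if (min(px) < 0) stop("RT Image writer requires non-negative readings")
  integral <- all(abs(px - round(px)) < 1e-9) && max(px) <= 65535
  if (integral) {
    slope <- 1
    stored <- round(px)
  } else {
    slope <- max(px) / 65535
    stored <- round(px / slope)
  }
  uid <- dcm_new_uid()
  ds <- list(
    dcm_element(0x0008, 0x0016, "UI", dcm_ui_value(DCM_SOP_RTIMAGE)),
    dcm_element(0x0008, 0x0018, "UI", dcm_ui_value(uid)),
    dcm_element(0x0008, 0x0023, "DA",
                dcm_string_value(if (is.na(image$date)) "" else image$date)),
    dcm_element(0x0008, 0x0060, "CS", dcm_string_value("RTIMAGE")),
    dcm_element(0x0008, 0x1010, "SH",
                dcm_string_value(if (is.na(image$machine_id)) "" else image$machine_id)),
    dcm_element(0x0028, 0x0010, "US", dcm_us_value(nrow(px))),
    dcm_element(0x0028, 0x0011, "US", dcm_us_value(ncol(px))),
    dcm_element(0x0028, 0x0100, "US", dcm_us_value(16)),
    dcm_element(0x0028, 0x0101, "US", dcm_us_value(16)),
    dcm_element(0x0028, 0x0102, "US", dcm_us_value(15)),
    dcm_element(0x0028, 0x0103, "US", dcm_us_value(0)),
    dcm_element(0x0028, 0x1052, "DS", dcm_ds_value(0)),
    dcm_element(0x0028, 0x1053, "DS", dcm_ds_value(slope)),
    dcm_element(0x3002, 0x0002, "SH", dcm_string_value(image$kind)),
    dcm_element(0x3002, 0x0011, "DS", dcm_ds_value(image$pixel_spacing)),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(as.integer(t(stored)), raw(), size = 2,
                         endian = "little"))
  )
  dcm_write(ds, path, DCM_SOP_RTIMAGE, uid)
}

#' Open-field corrected image
#'
#' Divides the MLC-strip image pixelwise by the open-field image, removing
#' the beam profile so that strip readings become comparable across the
#' field. Pixels where the open-field reading falls below a floor (a fraction
#' of the open image's median) are masked `NA` and excluded from every
#' average downstream.
#'
#' @param strip an [epid_image()] of kind `"STRIP"`.
#' @param open_field an [epid_image()] of kind `"OPEN"`, same dimensions and
#'   spacing.
#' @param floor_fraction open-field floor as a fraction of the open image's
#'   median reading (default 0.05).
#' @return numeric matrix of dimensionless corrected readings, `NA` where
#'   masked.
#' @export
corrected_image <- function(strip, open_field, floor_fraction = 0.05) {
  stopifnot(inherits(strip, "epid_image"), inherits(open_field, "epid_image"))
  if (!all(dim(strip$pixels) == dim(open_field$pixels)))
    stop("strip and open-field images have different dimensions")
  if (!isTRUE(all.equal(strip$pixel_spacing, open_field$pixel_spacing)))
    stop("strip and open-field images have different pixel spacing")
  op <- open_field$pixels
  floor_val <- floor_fraction * stats::median(op)
  out <- strip$pixels / op
  out[op < floor_val | op <= 0] <- NA_real_
  if (all(is.na(out))) stop("corrected image is fully masked")
  out
}

#' Strip layout constructor
#'
#' Geometry of the MLC-defined strips on the imager: per-strip column bounds
#' and a common row band, all 0-based half-open pixel intervals.
#'
#' @param col_start,col_end integer vectors (one per strip, half-open).
#' @param row_start,row_end scalar row band shared by all strips.
#' @return object of class `strip_layout`.
#' @export
strip_layout <- function(col_start, col_end, row_start, row_end) {
  if (length(col_start) != length(col_end))
    stop("col_start and col_end lengths differ")
  if (any(col_end <= col_start)) stop("strips must have positive width")
  o <- order(col_start)
  structure(list(strips = data.frame(col_start = as.integer(col_start[o]),
                                     col_end = as.integer(col_end[o])),
                 row_start = as.integer(row_start),
                 row_end = as.integer(row_end)),
            class = "strip_layout")
}

#' Read / write a strip layout as JSON
#' @param path JSON path.
#' @return a [strip_layout()] (read) or `path` invisibly (write).
#' @export
read_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  strip_layout(j$strips$col_start, j$strips$col_end, j$row_start, j$row_end)
}

#' @rdname read_layout
#' @param layout a [strip_layout()].
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(list(strips = layout$strips,
                            row_start = layout$row_start,
                            row_end = layout$row_end),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Derive a strip layout from a DRGS plan's MLC apertures
#'
#' Projects each arc segment's open MLC slit (union of open leaf pairs, mm at
#' isocenter) onto the imager through a magnification factor and the image's
#' column pixel spacing. The row band defaults to the central half of the
#' image.
#'
#' @param plan a [treatment_plan()] whose arc beam carries MLC positions.
#' @param image the [epid_image()] the layout is for.
#' @param magnification source-to-imager over source-to-axis distance
#'   (default 1, i.e. isocenter-plane geometry).
#' @param min_gap_mm leaf gap below which a pair counts as closed (default 1).
#' @return a [strip_layout()] with one strip per arc segment.
#' @export
layout_from_plan <- function(plan, image, magnification = 1, min_gap_mm = 1) {
  arc <- NULL
  for (b in plan$beams) if (b$is_arc && !is.null(b$mlc)) { arc <- b; break }
  if (is.null(arc)) stop("plan has no arc beam with MLC positions")
  n_seg <- nrow(arc$control_points) - 1
  sp <- image$pixel_spacing[2]
  ctr <- ncol(image$pixels) / 2
  cs <- integer(n_seg); ce <- integer(n_seg)
  for (i in seq_len(n_seg)) {
    lp <- arc$mlc[[i]]
    npair <- length(lp) / 2
    a <- lp[seq_len(npair)]; b2 <- lp[npair + seq_len(npair)]
    open <- which(b2 - a > min_gap_mm)
    if (length(open) == 0) stop("segment ", i, " has no open leaf pair")
    x1 <- min(a[open]); x2 <- max(b2[open])
    cs[i] <- as.integer(round(ctr + x1 * magnification / sp))
    ce[i] <- as.integer(round(ctr + x2 * magnification / sp))
  }
  nr <- nrow(image$pixels)
  strip_layout(cs, ce, round(nr / 4), round(3 * nr / 4))
}

#' Locate sampling ROIs for the strips
#'
#' Erodes each strip's aperture on every side by `margin_fraction` of the
#' strip width to keep the sampling rectangle inside the flat strip core,
#' away from the penumbra. ROIs are ordered left to right (ROI 1 leftmost)
#' and must be pairwise disjoint and inside the image.
#'
#' @param layout a [strip_layout()], or a [treatment_plan()] (forwarded to
#'   [layout_from_plan()]).
#' @param image the [epid_image()] being analyzed.
#' @param margin_fraction erosion as a fraction of strip width (default 0.25;
#'   0.5 or more leaves nothing and is an error).
#' @return data frame with columns `roi_index`, `row_start`, `row_end`,
#'   `col_start`, `col_end` (0-based half-open).
#' @export
locate_rois <- function(layout, image, margin_fraction = 0.25) {
  if (inherits(layout, "treatment_plan"))
    layout <- layout_from_plan(layout, image)
  stopifnot(inherits(layout, "strip_layout"))
  s <- layout$strips
  width <- s$col_end - s$col_start
  e <- round(margin_fraction * width)
  cs <- s$col_start + e
  ce <- s$col_end - e
  rs <- layout$row_start + e
  re <- layout$row_end - e
  if (any(ce <= cs) || any(re <= rs))
    stop("margin_fraction ", margin_fraction, " leaves degenerate ROIs")
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (any(cs < 0) || any(ce > nc) || any(rs < 0) || any(re > nr))
    stop("ROI outside image bounds")
  if (any(utils::head(ce, -1) > utils::tail(cs, -1)))
    stop("eroded ROIs overlap")
  data.frame(roi_index = seq_along(cs), row_start = rs, row_end = re,
             col_start = cs, col_end = ce)
}

#' Per-segment deviations of a corrected image
#'
#' For each ROI, the mean corrected reading over unmasked pixels; the
#' deviation of segment i is its mean relative to the grand mean of all
#' segment means, as a percent:
#' `(mean_i / mean(means) - 1) * 100`. The grand mean is the unweighted mean
#' over segments, so the deviations always average to zero.
#'
#' @param corrected matrix from [corrected_image()].
#' @param rois data frame from [locate_rois()].
#' @return data frame with columns `roi_index`, `mean_corrected`,
#'   `deviation_pct`.
#' @export
segment_deviations <- function(corrected, rois) {
  if (nrow(rois) < 2) stop("need at least 2 ROIs")
  means <- vapply(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    block <- corrected[(r$row_start + 1):r$row_end,
                       (r$col_start + 1):r$col_end]
    if (all(is.na(block))) stop("ROI ", r$roi_index, " is fully masked")
    mean(block, na.rm = TRUE)
  }, 0)
  grand <- mean(means)
  data.frame(roi_index = rois$roi_index, mean_corrected = means,
             deviation_pct = (means / grand - 1) * 100)
}

#' Baseline record constructor
#'
#' Per-ROI reference mean corrected readings for a machine, against which new
#' measurements are differenced.
#'
#' @param machine_id machine label.
#' @param baseline_means numeric vector, one positive value per ROI.
#' @param date_range character, e.g. `"2020-01..2022-03"` (provenance).
#' @param n_sessions number of historical sessions aggregated.
#' @return object of class `baseline_record`.
#' @export
baseline_record <- function(machine_id, baseline_means,
                            date_range = NA_character_, n_sessions = NA_integer_) {
  if (any(!is.finite(baseline_means)) || any(baseline_means <= 0))
    stop("baseline means must be positive")
  structure(list(machine_id = as.character(machine_id),
                 rois = data.frame(roi_index = seq_along(baseline_means),
                                   baseline_mean = as.numeric(baseline_means)),
                 date_range = as.character(date_range),
                 n_sessions = as.integer(n_sessions)),
            class = "baseline_record")
}

#' Read / write a baseline record as JSON
#' @param path JSON path.
#' @export
read_baseline <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  opt <- function(x) if (is.null(x) || identical(x, "NA")) NA else x
  baseline_record(j$machine_id, j$rois$baseline_mean[order(j$rois$index)],
                  date_range = opt(j$date_range),
                  n_sessions = opt(j$n_sessions))
}

#' @rdname read_baseline
#' @param baseline a [baseline_record()].
#' @export
write_baseline <- function(baseline, path) {
  payload <- list(
    machine_id = baseline$machine_id,
    rois = data.frame(index = baseline$rois$roi_index,
                      baseline_mean = baseline$rois$baseline_mean))
  if (!is.na(baseline$date_range)) payload$date_range <- baseline$date_range
  if (!is.na(baseline$n_sessions)) payload$n_sessions <- baseline$n_sessions
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compare measured per-ROI means to a baseline
#'
#' Differences each ROI's measured mean corrected reading from its stored
#' baseline as a ratio percent, `(measured / baseline - 1) * 100`, and flags
#' each ROI against a tolerance (default 3%, the conventional per-ROI limit
#' for this test).
#'
#' @param measured numeric vector of per-ROI measured means, or the data
#'   frame returned by [segment_deviations()] (its `mean_corrected` column is
#'   used).
#' @param baseline a [baseline_record()] with matching ROI count.
#' @param tolerance_pct pass/fail tolerance in percent (default 3).
#' @return object of class `qa_report`: list with `rois` (data frame
#'   `roi_index`, `measured_mean`, `baseline_mean`, `difference_pct`,
#'   `pass`), `max_abs_difference_pct`, `tolerance_pct`, `pass`. Differences
#'   are kept at full precision; the print method rounds to 1 decimal.
#' @export
compare_to_baseline <- function(measured, baseline, tolerance_pct = 3) {
  stopifnot(inherits(baseline, "baseline_record"))
  if (is.data.frame(measured)) measured <- measured$mean_corrected
  if (tolerance_pct <= 0) stop("tolerance_pct must be > 0")
  base <- baseline$rois$baseline_mean
  if (length(measured) != length(base))
    stop("ROI count mismatch: ", length(measured), " measured vs ",
         length(base), " baseline")
  if (any(base <= 0)) stop("baseline means must be positive")
  diff_pct <- (measured / base - 1) * 100
  rois <- data.frame(roi_index = baseline$rois$roi_index,
                     measured_mean = measured, baseline_mean = base,
                     difference_pct = diff_pct,
                     pass = abs(diff_pct) <= tolerance_pct)
  structure(list(rois = rois,
                 max_abs_difference_pct = max(abs(diff_pct)),
                 tolerance_pct = tolerance_pct,
                 pass = all(rois$pass)),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report> tolerance ", x$tolerance_pct, "%\n", sep = "")
  r <- x$rois
  for (i in seq_len(nrow(r)))
    cat(sprintf("  ROI %d  measured %.4g  baseline %.4g  difference %+.1f%%  %s\n",
                r$roi_index[i], r$measured_mean[i], r$baseline_mean[i],
                r$difference_pct[i], if (r$pass[i]) "PASS" else "FAIL"))
  cat(sprintf("  max |difference| %.1f%%  => %s\n", x$max_abs_difference_pct,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Aggregate historical sessions into a baseline
#'
#' @param history list of numeric vectors (one per session, per-ROI means) or
#'   a matrix with one row per session.
#' @param machine_id machine label for the record.
#' @param date_range provenance string.
#' @param method aggregation method; only `"mean"` (arithmetic per-ROI mean).
#' @return a [baseline_record()].
#' @export
update_baseline <- function(history, machine_id = NA_character_,
                            date_range = NA_character_, method = "mean") {
  method <- match.arg(method, "mean")
  if (is.list(history)) {
    lens <- lengths(history)
    if (length(unique(lens)) != 1)
      stop("sessions have ragged ROI counts: ", paste(unique(lens), collapse = ", "))
    history <- do.call(rbind, history)
  }
  history <- as.matrix(history)
  if (nrow(history) < 1) stop("need at least one session")
  baseline_record(machine_id, colMeans(history), date_range = date_range,
                  n_sessions = nrow(history))
}
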