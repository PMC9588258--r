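#' Arc beam constructor
#'
#' An arc beam is the unit the kinematics operate on: an ordered control-point
#' sequence (gantry angle, cumulative meterset weight, optionally MLC leaf
#' positions per control point) together with the beam meterset in monitor
#' units and the final cumulative weight that normalizes the weights.
#'
#' @param beam_id character label for the beam.
#' @param beam_meterset total monitor units delivered by the beam (MU, > 0).
#' @param final_cumulative_weight value that the last control point's
#'   cumulative weight reaches; weights are divided by it, so it need not be 1.
#' @param rotation_direction `"CW"`, `"CC"`, or `"NONE"` (static beam).
#' @param control_points data frame with columns `index` (0-based, as stored
#'   in RT Plan files), `gantry_angle` (degrees, IEC 61217, in `[0, 360)`) and
#'   `cumulative_weight` (monotone non-decreasing).
#' @param mlc optional list, one numeric vector of leaf/jaw positions (mm at
#'   isocenter; bank A then bank B) per control point, or `NULL`.
#' @param beam_number integer DICOM beam number (used to link the fraction
#'   group's referenced meterset).
#' @return object of class `arc_beam`.
#' @export
arc_beam <- function(beam_id, beam_meterset, final_cumulative_weight,
                     rotation_direction = c("CW", "CC", "NONE"),
                     control_points, mlc = NULL, beam_number = 1L) {
  rotation_direction <- match.arg(rotation_direction)
  stopifnot(is.data.frame(control_points),
            all(c("index", "gantry_angle", "cumulative_weight") %in%
                  names(control_points)))
  if (!is.null(mlc) && length(mlc) != nrow(control_points))
    stop("mlc must have one entry per control point")
  structure(list(
    beam_id = as.character(beam_id),
    beam_number = as.integer(beam_number),
    beam_meterset = as.numeric(beam_meterset),
    final_cumulative_weight = as.numeric(final_cumulative_weight),
    rotation_direction = rotation_direction,
    control_points = control_points,
    mlc = mlc,
    is_arc = rotation_direction != "NONE" && nrow(control_points) >= 2
  ), class = "arc_beam")
}

#' Treatment plan constructor
#'
#' @param plan_label character label.
#' @param beams list of [arc_beam()] objects (at least one).
#' @param source_path provenance string (file of origin), or `NA`.
#' @return object of class `treatment_plan`.
#' @export
treatment_plan <- function(plan_label, beams, source_path = NA_character_) {
  if (length(beams) < 1) stop("a treatment plan needs at least one beam")
  structure(list(plan_label = as.character(plan_label), beams = beams,
                 source_path = as.character(source_path)),
            class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat("<treatment_plan> ", x$plan_label, "\n", sep = "")
  for (b in x$beams) {
    cat(sprintf("  beam %-12s %7.2f MU  %4s  %d CPs%s\n", b$beam_id,
                b$beam_meterset, b$rotation_direction,
                nrow(b$control_points), if (b$is_arc) "" else "  [non-arc]"))
  }
  invisible(x)
}

#' Total monitor units of a plan
#' @param plan a [treatment_plan()].
#' @return total MU summed over beams.
#' @export
plan_total_mu <- function(plan) sum(vapply(plan$beams, `[[`, 0, "beam_meterset"))

.normalize_angle <- function(a) {
  a <- a %% 360
  a[abs(a - 360) < 1e-12] <- 0
  a
}

# ---- reading --------------------------------------------------------------

#' Read a DICOM RT Plan
#'
#' Parses the beam sequence, control-point sequences (gantry angle, rotation
#' direction, cumulative meterset weight, MLC leaf positions) and the fraction
#' group's referenced beam metersets. Attributes that RT Plan files state only
#' on change (gantry angle, rotation direction, MLC positions) are carried
#' forward from the previous control point. Gantry angles of exactly 360 are
#' normalized to 0 (IEC 61217 `[0, 360)`); stored values are otherwise
#' preserved at full precision. Beams with fewer than two control points or no
#' rotation are retained but flagged non-arc.
#'
#' @param path path to an RT Plan DICOM file.
#' @return a [treatment_plan()].
#' @export
read_rtplan <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dcm <- dcm_read(path)
  ds <- dcm$data
  label_el <- dcm_find(ds, 0x300A, 0x0002)
  label <- if (is.null(label_el)) basename(path) else dcm_decode_string1(label_el)

  beam_sq <- dcm_find(ds, 0x300A, 0x00B0)
  if (is.null(beam_sq) || length(beam_sq$items) == 0)
    stop("RT Plan has no beam sequence: ", path)

  # fraction group: map beam number -> meterset
  metersets <- list()
  fg_sq <- dcm_find(ds, 0x300A, 0x0070)
  if (!is.null(fg_sq)) {
    for (fg in fg_sq$items) {
      rb_sq <- dcm_find(fg, 0x300C, 0x0004)
      if (is.null(rb_sq)) next
      for (rb in rb_sq$items) {
        num <- dcm_find(rb, 0x300C, 0x0006)
        mu <- dcm_find(rb, 0x300A, 0x0086)
        if (!is.null(num) && !is.null(mu))
          metersets[[as.character(dcm_decode_numeric(num))]] <- dcm_decode_numeric(mu)
      }
    }
  }

  beams <- lapply(beam_sq$items, function(bm) {
    num_el <- dcm_find(bm, 0x300A, 0x00C0)
    beam_number <- if (is.null(num_el)) NA_integer_ else as.integer(dcm_decode_numeric(num_el))
    name_el <- dcm_find(bm, 0x300A, 0x00C2)
    beam_id <- if (is.null(name_el)) paste0("Beam", beam_number)
               else dcm_decode_string1(name_el)
    cp_sq <- dcm_find(bm, 0x300A, 0x0111)
    if (is.null(cp_sq) || length(cp_sq$items) == 0)
      stop("beam '", beam_id, "' has no control point sequence")
    fw_el <- dcm_find(bm, 0x300A, 0x010E)
    final_w <- if (is.null(fw_el)) NA_real_ else dcm_decode_numeric(fw_el)

    n <- length(cp_sq$items)
    idx <- integer(n); ang <- numeric(n); wt <- numeric(n)
    mlc <- vector("list", n)
    dir <- "NONE"; last_ang <- NA_real_; last_mlc <- NULL
    for (i in seq_len(n)) {
      cp <- cp_sq$items[[i]]
      ix <- dcm_find(cp, 0x300A, 0x0112)
      idx[i] <- if (is.null(ix)) i - 1L else as.integer(dcm_decode_numeric(ix))
      ga <- dcm_find(cp, 0x300A, 0x011E)
      last_ang <- if (is.null(ga)) last_ang else dcm_decode_numeric(ga)
      ang[i] <- last_ang
      rd <- dcm_find(cp, 0x300A, 0x011F)
      if (!is.null(rd)) {
        d <- dcm_decode_string1(rd)
        if (!is.na(d) && d %in% c("CW", "CC")) dir <- d
      }
      wv <- dcm_find(cp, 0x300A, 0x0134)
      if (is.null(wv)) stop("beam '", beam_id, "': CP ", i - 1L,
                            " missing cumulative meterset weight")
      wt[i] <- dcm_decode_numeric(wv)
      bld <- dcm_find(cp, 0x300A, 0x011A)
      if (!is.null(bld)) {
        for (dev in bld$items) {
          type_el <- dcm_find(dev, 0x300A, 0x00B8)
          pos_el <- dcm_find(dev, 0x300A, 0x011C)
          if (!is.null(type_el) && !is.null(pos_el) &&
              isTRUE(startsWith(dcm_decode_string1(type_el), "MLC")))
            last_mlc <- dcm_decode_numeric(pos_el)
        }
      }
      mlc[[i]] <- last_mlc
    }
    if (any(is.na(ang))) stop("beam '", beam_id, "' has control points with no gantry angle")
    bad <- which(diff(wt) < -1e-12)
    if (length(bad))
      stop("beam '", beam_id, "': cumulative meterset weight decreases at CP index ",
           idx[bad[1] + 1])
    mu <- metersets[[as.character(beam_number)]]
    if (is.null(mu))
      stop("beam '", beam_id, "' (number ", beam_number,
           ") has no referenced beam meterset in the fraction group")
    if (is.na(final_w)) final_w <- wt[n]
    has_mlc <- !all(vapply(mlc, is.null, TRUE))
    arc_beam(beam_id, mu, final_w, dir,
             data.frame(index = idx, gantry_angle = .normalize_angle(ang),
                        cumulative_weight = wt),
             mlc = if (has_mlc) mlc else NULL,
             beam_number = beam_number)
  })
  treatment_plan(label, beams, source_path = path)
}

# ---- writing --------------------------------------------------------------

# dataset builders used by both the fixture writer and write_rtplan

.cp_item <- function(index, angle, weight, direction = NULL, mlc = NULL) {
  els <- list(dcm_element(0x300A, 0x0112, "IS", dcm_is_value(index)),
              dcm_element(0x300A, 0x011E, "DS", dcm_ds_value(angle)))
  if (!is.null(direction))
    els <- c(els, list(dcm_element(0x300A, 0x011F, "CS", dcm_string_value(direction))))
  if (!is.null(mlc)) {
    dev <- list(list(dcm_element(0x300A, 0x00B8, "CS", dcm_string_value("MLCX")),
                     dcm_element(0x300A, 0x011C, "DS", dcm_ds_value(mlc))))
    els <- c(els, list(dcm_sequence(0x300A, 0x011A, dev)))
  }
  c(els, list(dcm_element(0x300A, 0x0134, "DS", dcm_ds_value(weight))))
}

.beam_item <- function(beam) {
  n <- nrow(beam$control_points)
  cps <- lapply(seq_len(n), function(i) {
    .cp_item(beam$control_points$index[i],
             beam$control_points$gantry_angle[i],
             beam$control_points$cumulative_weight[i],
             direction = if (i == 1) beam$rotation_direction else NULL,
             mlc = if (is.null(beam$mlc)) NULL else beam$mlc[[i]])
  })
  list(dcm_element(0x300A, 0x00C0, "IS", dcm_is_value(beam$beam_number)),
       dcm_element(0x300A, 0x00C2, "LO", dcm_string_value(beam$beam_id)),
       dcm_element(0x300A, 0x00C4, "CS",
                   dcm_string_value(if (beam$is_arc) "DYNAMIC" else "STATIC")),
       dcm_element(0x300A, 0x010E, "DS", dcm_ds_value(beam$final_cumulative_weight)),
       dcm_element(0x300A, 0x0110, "IS", dcm_is_value(n)),
       dcm_sequence(0x300A, 0x0111, cps))
}

#' Write a treatment plan as a standalone DICOM RT Plan file
#'
#' Serializes the modeled fields (plan label, beams with control points and
#' MLC positions, fraction-group referenced beam metersets) into a fresh
#' RT Plan file. Used by the fixture generators; to modify an existing vendor
#' file while preserving its unmodeled elements use [write_rtplan()].
#'
#' @param plan a [treatment_plan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan_dicom <- function(plan, path) {
  uid <- dcm_new_uid()
  rb_items <- lapply(plan$beams, function(b) {
    list(dcm_element(0x300A, 0x0086, "DS", dcm_ds_value(b$beam_meterset)),
         dcm_element(0x300C, 0x0006, "IS", dcm_is_value(b$beam_number)))
  })
  fg <- list(list(dcm_element(0x300A, 0x0078, "IS", dcm_is_value(1L)),
                  dcm_sequence(0x300C, 0x0004, rb_items)))
  ds <- list(
    dcm_element(0x0008, 0x0016, "UI", dcm_ui_value(DCM_SOP_RTPLAN)),
    dcm_element(0x0008, 0x0018, "UI", dcm_ui_value(uid)),
    dcm_element(0x0008, 0x0060, "CS", dcm_string_value("RTPLAN")),
    dcm_element(0x300A, 0x0002, "SH", dcm_string_value(plan$plan_label)),
    dcm_sequence(0x300A, 0x0070, fg),
    dcm_sequence(0x300A, 0x00B0, lapply(plan$beams, .beam_item))
  )
  dcm_write(ds, path, DCM_SOP_RTPLAN, uid)
}

#' Write a modified plan over an RT Plan template
#'
#' Re-serializes the template with only the referenced beam metersets replaced
#' by the plan's values and a fresh SOP instance UID assigned; every other
#' element's bytes are preserved. The plan's beams must correspond one-to-one
#' (by position) with the template's beams.
#'
#' @param plan a [treatment_plan()] whose metersets are to be written.
#' @param template_path existing RT Plan file providing all other content.
#' @param out_path output path.
#' @return `out_path`, invisibly.
#' @export
write_rtplan <- function(plan, template_path, out_path) {
  dcm <- dcm_read(template_path)
  ds <- dcm$data
  beam_sq <- dcm_find(ds, 0x300A, 0x00B0)
  if (is.null(beam_sq)) stop("template has no beam sequence")
  n_template <- length(beam_sq$items)
  if (n_template != length(plan$beams))
    stop("beam count mismatch: template has ", n_template,
         " beams, plan has ", length(plan$beams))

  # template beam order gives the number -> position mapping
  tmpl_numbers <- vapply(beam_sq$items, function(bm) {
    el <- dcm_find(bm, 0x300A, 0x00C0)
    if (is.null(el)) NA_real_ else dcm_decode_numeric(el)
  }, 0)
  mu_by_number <- stats::setNames(
    vapply(plan$beams, `[[`, 0, "beam_meterset"),
    as.character(tmpl_numbers))

  for (i in seq_along(ds)) {
    if (ds[[i]]$group == 0x300A && ds[[i]]$element == 0x0070) {
      fg_items <- ds[[i]]$items
      for (j in seq_along(fg_items)) {
        for (k in seq_along(fg_items[[j]])) {
          el <- fg_items[[j]][[k]]
          if (el$group == 0x300C && el$element == 0x0004) {
            for (m in seq_along(el$items)) {
              num <- dcm_find(el$items[[m]], 0x300C, 0x0006)
              if (is.null(num)) stop("referenced beam without beam number in template")
              key <- as.character(dcm_decode_numeric(num))
              if (!key %in% names(mu_by_number))
                stop("template references beam number ", key, " absent from plan")
              el$items[[m]] <- dcm_set(el$items[[m]], 0x300A, 0x0086, "DS",
                                       dcm_ds_value(mu_by_number[[key]]))
            }
            fg_items[[j]][[k]] <- el
          }
        }
      }
      ds[[i]]$items <- fg_items
    }
  }
  uid <- dcm_new_uid()
  ds <- dcm_set(ds, 0x0008, 0x0018, "UI", dcm_ui_value(uid))
  dcm_write(ds, out_path, DCM_SOP_RTPLAN, uid)
  invisible(out_path)
}

# ---- validation -----------------------------------------------------------

#' Validate a treatment plan's invariants
#'
#' Checks the modeled invariants (angles in `[0, 360)`, monotone cumulative
#' weights, positive metersets and final weights, last weight reaching the
#' final weight) and returns findings rather than raising errors.
#'
#' @param plan a [treatment_plan()].
#' @return data frame with columns `beam_id`, `cp_index` (`NA` for beam-level
#'   findings) and `message`; zero rows iff the plan is valid.
#' @export
validate_plan <- function(plan) {
  out <- list()
  flag <- function(beam_id, cp_index, message)
    out[[length(out) + 1]] <<- data.frame(beam_id = beam_id,
                                          cp_index = cp_index,
                                          message = message)
  for (b in plan$beams) {
    cp <- b$control_points
    if (!is.finite(b$beam_meterset) || b$beam_meterset <= 0)
      flag(b$beam_id, NA_integer_, "beam_meterset must be > 0")
    if (!is.finite(b$final_cumulative_weight) || b$final_cumulative_weight <= 0)
      flag(b$beam_id, NA_integer_, "final_cumulative_weight must be > 0")
    bad_ang <- which(cp$gantry_angle < 0 | cp$gantry_angle >= 360)
    for (i in bad_ang)
      flag(b$beam_id, cp$index[i], sprintf("gantry angle %g outside [0, 360)",
                                           cp$gantry_angle[i]))
    if (nrow(cp) >= 2) {
      bad_w <- which(diff(cp$cumulative_weight) < 0)
      for (i in bad_w)
        flag(b$beam_id, cp$index[i + 1], "cumulative weight decreases")
    }
    if (nrow(cp) >= 1 && b$final_cumulative_weight > 0) {
      rel <- abs(cp$cumulative_weight[nrow(cp)] - b$final_cumulative_weight) /
        b$final_cumulative_weight
      if (!is.na(rel) && rel > 1e-6)
        flag(b$beam_id, cp$index[nrow(cp)],
             "last cumulative weight does not reach final_cumulative_weight")
    }
  }
  if (length(out) == 0)
    return(data.frame(beam_id = character(), cp_index = integer(),
                      message = character()))
  do.call(rbind, out)
}
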