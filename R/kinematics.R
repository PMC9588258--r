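#' Machine limits
#'
#' Deliverability envelope of a linac: maximum nominal dose rate, maximum
#' gantry speed, and the maximum MU per degree the machine can deliver at all
#' (the point at which even the slowest gantry rotation cannot accommodate the
#' requested meterset).
#'
#' @param max_dose_rate maximum dose rate in MU/min (e.g. 600 for a TrueBeam
#'   flattened beam).
#' @param max_gantry_speed maximum gantry speed in deg/s (e.g. 6).
#' @param max_mu_per_deg deliverability ceiling in MU/deg (e.g. 60); `Inf`
#'   disables the ceiling.
#' @return object of class `machine_limits`.
#' @export
machine_limits <- function(max_dose_rate, max_gantry_speed, max_mu_per_deg = Inf) {
  if (!is.finite(max_dose_rate) || max_dose_rate <= 0)
    stop("max_dose_rate must be > 0")
  if (!is.finite(max_gantry_speed) || max_gantry_speed <= 0)
    stop("max_gantry_speed must be > 0")
  if (is.na(max_mu_per_deg) || max_mu_per_deg <= 0)
    stop("max_mu_per_deg must be > 0")
  structure(list(max_dose_rate = max_dose_rate,
                 max_gantry_speed = max_gantry_speed,
                 max_mu_per_deg = max_mu_per_deg),
            class = "machine_limits")
}

#' Read machine limits from a config file
#'
#' Accepts a YAML or JSON key-value file with keys `max_dose_rate_mu_min`,
#' `max_gantry_speed_deg_s`, and optionally `max_mu_per_deg`.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return a [machine_limits()].
#' @export
read_machine_limits <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  machine_limits(cfg$max_dose_rate_mu_min, cfg$max_gantry_speed_deg_s,
                 if (is.null(cfg$max_mu_per_deg)) Inf else cfg$max_mu_per_deg)
}

#' Critical MU per degree
#'
#' The MU/deg at which a linac saturates its dose rate and starts slowing the
#' gantry instead: maximum dose rate (MU/min) divided by 60 times the maximum
#' gantry speed (deg/s). Below this value the machine can modulate dose rate
#' at full gantry speed; above it, gantry speed drops as MU/deg rises.
#'
#' @param limits a [machine_limits()].
#' @return critical MU/deg (numeric scalar).
#' @examples
#' critical_mu_per_deg(machine_limits(600, 6))  # 1.67 MU/deg for a TrueBeam
#' @export
critical_mu_per_deg <- function(limits) {
  stopifnot(inherits(limits, "machine_limits"))
  limits$max_dose_rate / (60 * limits$max_gantry_speed)
}

.check_arc <- function(beam) {
  if (nrow(beam$control_points) < 2)
    stop("beam '", beam$beam_id, "' has fewer than 2 control points")
}

#' MU delivered per control-point segment
#'
#' Monitor units delivered between consecutive control points:
#' `beam_meterset * diff(w) / final_cumulative_weight`. The elements sum to
#' the MU delivered between the first and last control point.
#'
#' @param beam an [arc_beam()] with at least 2 control points.
#' @return numeric vector of length `nCP - 1`, in MU.
#' @export
mu_per_cp <- function(beam) {
  .check_arc(beam)
  w <- beam$control_points$cumulative_weight
  if (any(diff(w) < 0)) stop("beam '", beam$beam_id, "' has non-monotone weights")
  beam$beam_meterset * diff(w) / beam$final_cumulative_weight
}

#' Degrees of gantry rotation per control-point segment
#'
#' Arc length traversed from each control point to the next along the beam's
#' stated rotation direction, with the 0/360 boundary unwrapped directionally
#' (CW segments accumulate increasing IEC angle, CC decreasing). Static beams
#' have no arc length and raise an error.
#'
#' @param beam an [arc_beam()] with rotation `"CW"` or `"CC"`.
#' @return numeric vector of length `nCP - 1`, degrees in `[0, 360)`.
#' @export
deg_per_cp <- function(beam) {
  .check_arc(beam)
  if (!beam$rotation_direction %in% c("CW", "CC"))
    stop("beam '", beam$beam_id, "' is static (rotation NONE): no deg/CP")
  a <- beam$control_points$gantry_angle
  d <- diff(a)
  if (beam$rotation_direction == "CW") d %% 360 else (-d) %% 360
}

#' Per-segment MU per degree
#'
#' The MU/deg kinematic profile of an arc beam: per inter-control-point
#' segment, MU/CP divided by deg/CP. Segments with zero arc length (the
#' gantry holds still while the machine delivers) have no defined MU/deg;
#' they are flagged `undefined` and carry `NA`, never dropped.
#'
#' @param beam an [arc_beam()] with rotation `"CW"` or `"CC"`.
#' @return data frame with columns `beam_id`, `segment_index` (1-based,
#'   segment i spans control point rows i to i+1), `mu_per_cp`, `deg_per_cp`,
#'   `mu_per_deg` (`NA` when undefined), `undefined`.
#' @export
mu_per_deg <- function(beam) {
  mu <- mu_per_cp(beam)
  deg <- deg_per_cp(beam)
  undefined <- deg == 0
  ratio <- ifelse(undefined, NA_real_, mu / deg)
  data.frame(beam_id = beam$beam_id,
             segment_index = seq_along(mu),
             mu_per_cp = mu, deg_per_cp = deg,
             mu_per_deg = ratio, undefined = undefined)
}

#' Kinematics table for whole plans
#'
#' Pools [mu_per_deg()] over every arc beam of one or more plans (static
#' beams are excluded; a DRGS file's open-field beam contributes no
#' segments).
#'
#' @param plans a [treatment_plan()] or list of them.
#' @return data frame with a leading `plan` column plus the [mu_per_deg()]
#'   columns.
#' @export
plan_kinematics <- function(plans) {
  if (inherits(plans, "treatment_plan")) plans <- list(plans)
  rows <- list()
  for (p in plans) {
    for (b in p$beams) {
      if (!b$is_arc) next
      k <- mu_per_deg(b)
      rows[[length(rows) + 1]] <- cbind(plan = p$plan_label, k)
    }
  }
  if (length(rows) == 0)
    return(data.frame(plan = character(), beam_id = character(),
                      segment_index = integer(), mu_per_cp = numeric(),
                      deg_per_cp = numeric(), mu_per_deg = numeric(),
                      undefined = logical()))
  do.call(rbind, rows)
}

#' Maximum defined MU/deg of a plan
#' @param plan a [treatment_plan()].
#' @return maximum MU/deg over all defined arc segments.
#' @export
plan_max_mu_per_deg <- function(plan) {
  k <- plan_kinematics(plan)
  v <- k$mu_per_deg[!k$undefined]
  if (length(v) == 0) stop("plan '", plan$plan_label, "' has no defined arc segments")
  max(v)
}

#' Cohort MU/deg distribution summary
#'
#' Pools the per-segment MU/deg values of a set of plans and summarizes their
#' distribution: a histogram, exceedance fractions above given thresholds
#' (e.g. the critical MU/deg, or the maximum of a reference test plan), the
#' pooled maximum, and both a segment count and a control-point count
#' (MU/deg is defined on control-point pairs, so the two differ by one per
#' beam).
#'
#' @param plans list of [treatment_plan()] objects (or a single plan).
#' @param thresholds numeric vector of MU/deg thresholds for exceedance
#'   fractions (may be empty).
#' @param bin_width histogram bin width in MU/deg (default 0.5, bins from 0).
#' @return object of class `cohort_summary`: list with `n_segments`,
#'   `n_control_points`, `n_undefined`, `histogram` (data frame `lower`,
#'   `upper`, `count`), `fraction_above` (named numeric), `max_mu_per_deg`.
#' @export
cohort_summary <- function(plans, thresholds = numeric(), bin_width = 0.5) {
  if (inherits(plans, "treatment_plan")) plans <- list(plans)
  k <- plan_kinematics(plans)
  if (nrow(k) == 0) stop("no arc segments in cohort")
  v <- k$mu_per_deg[!k$undefined]
  if (length(v) == 0) stop("no defined MU/deg segments in cohort")
  n_cp <- sum(vapply(plans, function(p)
    sum(vapply(p$beams, function(b) if (b$is_arc) nrow(b$control_points) else 0L, 0L)),
    0L))
  breaks <- seq(0, ceiling(max(v) / bin_width + 1e-12) * bin_width, by = bin_width)
  if (length(breaks) < 2) breaks <- c(0, bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE, right = FALSE)
  frac <- vapply(thresholds, function(t) mean(v > t), 0)
  names(frac) <- format(thresholds, trim = TRUE)
  structure(list(
    n_segments = length(v),
    n_control_points = n_cp,
    n_undefined = sum(k$undefined),
    histogram = data.frame(lower = utils::head(h$breaks, -1),
                           upper = utils::tail(h$breaks, -1),
                           count = h$counts),
    fraction_above = frac,
    max_mu_per_deg = max(v)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  segments: %d defined, %d undefined (%d control points)\n",
              x$n_segments, x$n_undefined, x$n_control_points))
  cat(sprintf("  max MU/deg: %.2f\n", x$max_mu_per_deg))
  for (nm in names(x$fraction_above))
    cat(sprintf("  fraction > %s MU/deg: %.1f%%\n", nm,
                100 * x$fraction_above[[nm]]))
  invisible(x)
}

#' Histogram of a cohort's MU/deg distribution
#'
#' Draws the pooled MU/deg histogram with optional vertical markers: the
#' critical MU/deg (dashed yellow), a reference test plan's maximum (dashed
#' red), and a modified test plan's maximum (dashed green) — the three lines
#' used when judging whether a QA plan covers the clinical MU/deg range.
#'
#' @param summary a [cohort_summary()].
#' @param critical optional critical MU/deg marker.
#' @param reference_max optional reference-plan maximum marker.
#' @param modified_max optional modified-plan maximum marker.
#' @return a ggplot object.
#' @export
plot_mu_per_deg_histogram <- function(summary, critical = NULL,
                                      reference_max = NULL, modified_max = NULL) {
  h <- summary$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(x = (lower + upper) / 2, y = count)) +
    ggplot2::geom_col(width = h$upper[1] - h$lower[1], fill = "grey35") +
    ggplot2::labs(x = "MU per degree (MU/deg)", y = "Segments",
                  title = "MU/deg distribution") +
    ggplot2::theme_minimal()
  add_line <- function(p, x, col) {
    if (is.null(x)) return(p)
    p + ggplot2::geom_vline(xintercept = x, linetype = "dashed",
                            colour = col, linewidth = 0.8)
  }
  p <- add_line(p, critical, "goldenrod2")
  p <- add_line(p, reference_max, "red3")
  add_line(p, modified_max, "green4")
}

#' Write a segment kinematics CSV
#'
#' @param plans plans passed to [plan_kinematics()].
#' @param path output CSV path (columns `plan`, `beam`, `segment`,
#'   `mu_per_cp`, `deg_per_cp`, `mu_per_deg`).
#' @return `path`, invisibly.
#' @export
write_kinematics_csv <- function(plans, path) {
  k <- plan_kinematics(plans)
  out <- data.frame(plan = k$plan, beam = k$beam_id, segment = k$segment_index,
                    mu_per_cp = k$mu_per_cp, deg_per_cp = k$deg_per_cp,
                    mu_per_deg = k$mu_per_deg)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
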