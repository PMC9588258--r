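# Deterministic synthetic fixtures: DRGS-style test plans, SBRT-like arc
# cohorts, and paired strip/open EPID images with known ground truth. These
# stand in for the vendor test file and for clinical plans, which cannot be
# redistributed; the vendor-replica layout reproduces the published
# constraints of the real file (7 strips, 250 MU total, maximum segment
# 2.272 MU/deg), not its confidential control-point table.

.strip_centers_mm <- function(n_strips = 7, pitch_mm = 30) {
  (seq_len(n_strips) - (n_strips + 1) / 2) * pitch_mm
}

#' Synthetic vendor-replica DRGS plan
#'
#' A dose-rate/gantry-speed strip-test plan: one arc beam delivering seven
#' MLC-defined strips, each strip a single inter-control-point segment with
#' its own MU/deg (a different dose-rate/gantry-speed combination per strip),
#' plus one static open-field beam. Defaults give 250 MU total (200 MU arc +
#' 50 MU open field) with a monotone MU/deg schedule whose maximum segment is
#' exactly 2.272 MU/deg, so a 10x MU rescale reaches 22.72 MU/deg.
#'
#' @param total_mu total plan MU (arc + open field).
#' @param open_field_mu MU of the static open-field beam.
#' @param mu_per_deg_schedule per-strip MU/deg values (length = number of
#'   strips); their sum times `strip_span_deg` must equal
#'   `total_mu - open_field_mu`.
#' @param strip_span_deg arc length of each strip segment in degrees.
#' @param start_angle gantry angle of the first control point (IEC degrees).
#' @param direction `"CW"` or `"CC"`.
#' @param strip_width_mm,strip_pitch_mm MLC slit width and center-to-center
#'   pitch at isocenter (also used by [make_epid_pair()], keeping plan and
#'   image geometry consistent).
#' @param n_leaf_pairs MLC leaf pairs in the synthetic carriage.
#' @param plan_label plan label.
#' @return a [treatment_plan()] with two beams (arc + open field).
#' @export
make_vendor_replica_plan <- function(total_mu = 250, open_field_mu = 50,
                                     mu_per_deg_schedule = c(0.4, 0.6, 0.8, 1.0,
                                                             1.2, 1.728, 2.272),
                                     strip_span_deg = 25, start_angle = 181,
                                     direction = "CW",
                                     strip_width_mm = 20, strip_pitch_mm = 30,
                                     n_leaf_pairs = 10,
                                     plan_label = "DRGS vendor replica (synthetic)") {
  n <- length(mu_per_deg_schedule)
  arc_mu <- total_mu - open_field_mu
  shares <- mu_per_deg_schedule * strip_span_deg
  if (abs(sum(shares) - arc_mu) > 1e-9 * max(1, arc_mu))
    stop("MU/deg schedule x span sums to ", sum(shares),
         " MU but arc MU is ", arc_mu)
  if (arc_mu <= 0 || open_field_mu < 0) stop("invalid MU split")

  sgn <- if (direction == "CW") 1 else -1
  angles <- .normalize_angle(start_angle + sgn * strip_span_deg * 0:n)
  weights <- c(0, cumsum(shares)) / arc_mu
  centers <- .strip_centers_mm(n, strip_pitch_mm)
  slit <- function(center) {
    a <- rep(center - strip_width_mm / 2, n_leaf_pairs)
    b <- rep(center + strip_width_mm / 2, n_leaf_pairs)
    c(a, b)
  }
  mlc <- c(lapply(centers, slit), list(slit(centers[n])))  # carry last strip
  arc <- arc_beam("DRGS arc", arc_mu, 1.0, direction,
                  data.frame(index = 0:n, gantry_angle = angles,
                             cumulative_weight = weights),
                  mlc = mlc, beam_number = 1L)
  open_mlc <- rep(list(c(rep(-(n * strip_pitch_mm) / 2 - strip_width_mm, n_leaf_pairs),
                         rep((n * strip_pitch_mm) / 2 + strip_width_mm, n_leaf_pairs))), 2)
  open <- arc_beam("Open field", open_field_mu, 1.0, "NONE",
                   data.frame(index = 0:1, gantry_angle = c(0, 0),
                              cumulative_weight = c(0, 1)),
                   mlc = open_mlc, beam_number = 2L)
  treatment_plan(plan_label, list(arc, open))
}

.beam_from_mu_per_deg <- function(values, deg_span, start_angle, direction,
                                  beam_id, beam_number = 1L) {
  n <- length(values)
  sgn <- if (direction == "CW") 1 else -1
  angles <- .normalize_angle(start_angle + sgn * deg_span * 0:n)
  shares <- values * deg_span
  meterset <- sum(shares)
  arc_beam(beam_id, meterset, 1.0, direction,
           data.frame(index = 0:n, gantry_angle = angles,
                      cumulative_weight = c(0, cumsum(shares)) / meterset),
           beam_number = beam_number)
}

#' Synthetic SBRT-like arc plan
#'
#' One arc beam whose per-segment MU/deg values are drawn from a clipped
#' log-normal distribution spanning roughly 0.1-22 MU/deg, the range covered
#' by stereotactic body radiotherapy arcs.
#'
#' @param n_cps number of control points (segments = `n_cps - 1`).
#' @param meanlog,sdlog log-normal parameters of the MU/deg draw.
#' @param range MU/deg values are clipped to this interval.
#' @param deg_span degrees per segment.
#' @param seed optional integer seed for reproducibility.
#' @param plan_label plan label.
#' @return a [treatment_plan()] with a single arc beam.
#' @export
make_sbrt_like_plan <- function(n_cps = 178, meanlog = log(3), sdlog = 0.8,
                                range = c(0.1, 22), deg_span = 2, seed = NULL,
                                plan_label = "SBRT-like arc (synthetic)") {
  if (!is.null(seed)) set.seed(seed)
  if (n_cps < 2) stop("an arc needs at least 2 control points")
  v <- pmin(pmax(stats::rlnorm(n_cps - 1, meanlog, sdlog), range[1]), range[2])
  treatment_plan(plan_label,
                 list(.beam_from_mu_per_deg(v, deg_span, 179, "CC", "Arc 1")))
}

#' Synthetic SBRT-like cohort with planted distribution features
#'
#' Generates a cohort of arc plans whose pooled per-segment MU/deg
#' distribution has an exactly known maximum and an exactly known count of
#' segments above a threshold, so distribution summaries can be verified
#' against planted ground truth. Defaults emulate a 21-plan stereotactic
#' cohort with 3822 pooled segments, a 21.29 MU/deg maximum, and 83% of
#' segments above 2.272 MU/deg (the vendor-replica plan's maximum).
#'
#' @param n_plans number of plans.
#' @param segments_per_plan arc segments per plan.
#' @param planted_max exact pooled maximum MU/deg.
#' @param threshold exceedance threshold (MU/deg).
#' @param exceedance_fraction fraction of pooled segments strictly above
#'   `threshold` (planted count = `round(fraction * n_segments)`).
#' @param meanlog,sdlog log-normal shape of the below-threshold mass.
#' @param min_mu_per_deg lower clip for below-threshold values.
#' @param deg_span degrees per segment.
#' @param seed optional integer seed.
#' @return list of [treatment_plan()] objects.
#' @export
make_sbrt_like_cohort <- function(n_plans = 21, segments_per_plan = 182,
                                  planted_max = 21.29, threshold = 2.272,
                                  exceedance_fraction = 0.83,
                                  meanlog = log(1), sdlog = 0.7,
                                  min_mu_per_deg = 0.1, deg_span = 1.9,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_total <- n_plans * segments_per_plan
  k <- round(exceedance_fraction * n_total)
  if (k < 1 || k > n_total)
    stop("planted exceedance count ", k, " infeasible for ", n_total, " segments")
  if (planted_max <= threshold) stop("planted_max must exceed threshold")
  if (threshold <= min_mu_per_deg) stop("threshold must exceed min_mu_per_deg")
  # above-threshold mass: strictly inside (threshold, planted_max], max planted
  above <- threshold + (planted_max - threshold) *
    pmax(stats::rbeta(k, 1.2, 3), 1e-9) * 0.999
  above[1] <- planted_max
  # below-threshold mass: truncated log-normal via inverse CDF
  p_hi <- stats::plnorm(threshold, meanlog, sdlog)
  p_lo <- stats::plnorm(min_mu_per_deg, meanlog, sdlog)
  below <- stats::qlnorm(p_lo + (p_hi - p_lo) * stats::runif(n_total - k),
                         meanlog, sdlog)
  below <- pmin(below, threshold)  # numerical safety at the boundary
  v <- c(above, below)
  v <- v[sample.int(length(v))]
  lapply(seq_len(n_plans), function(j) {
    vals <- v[((j - 1) * segments_per_plan + 1):(j * segments_per_plan)]
    dir <- if (j %% 2 == 1) "CW" else "CC"
    start <- .normalize_angle(180 + 7 * j)
    treatment_plan(sprintf("SBRT-like plan %02d (synthetic)", j),
                   list(.beam_from_mu_per_deg(vals, deg_span, start, dir, "Arc 1")))
  })
}

#' Synthetic paired strip/open EPID images
#'
#' Emulates the image pair a DRGS delivery produces: the open-field image is
#' a smooth radially symmetric beam profile; the strip image is the open
#' image masked to seven vertical MLC strips, each multiplied by a
#' configurable per-ROI perturbation factor, with optional seeded additive
#' Gaussian noise. The planted factors are returned as ground truth, and the
#' matching strip layout (in imager pixels) is derived from the same
#' millimeter geometry as [make_vendor_replica_plan()].
#'
#' @param factors per-strip multiplicative perturbations (length = number of
#'   strips; 1 = unperturbed).
#' @param noise_sd additive Gaussian noise standard deviation in detector
#'   units (0 disables noise).
#' @param n_rows,n_cols image dimensions in pixels.
#' @param pixel_spacing mm per pixel (row, col).
#' @param strip_width_mm,strip_pitch_mm strip geometry at the imager plane.
#' @param peak open-field reading at the beam axis (detector units).
#' @param profile_drop relative fall-off of the open profile at the image
#'   corner.
#' @param machine_id metadata stamped on both images.
#' @param seed optional integer seed (only the noise consumes randomness).
#' @return list with `strip` and `open` ([epid_image()]), `factors` (ground
#'   truth), and `layout` (a [strip_layout()]).
#' @export
make_epid_pair <- function(factors = rep(1, 7), noise_sd = 0,
                           n_rows = 768, n_cols = 1024,
                           pixel_spacing = c(0.336, 0.336),
                           strip_width_mm = 20, strip_pitch_mm = 30,
                           peak = 1000, profile_drop = 0.15,
                           machine_id = "TB-SIM", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- length(factors)
  ry <- (seq_len(n_rows) - (n_rows + 1) / 2) * pixel_spacing[1]
  rx <- (seq_len(n_cols) - (n_cols + 1) / 2) * pixel_spacing[2]
  r2 <- outer(ry^2, rx^2, `+`)
  open <- peak * (1 - profile_drop * r2 / max(r2))

  centers <- .strip_centers_mm(n, strip_pitch_mm)
  ctr <- n_cols / 2
  cs <- as.integer(round(ctr + (centers - strip_width_mm / 2) / pixel_spacing[2]))
  ce <- as.integer(round(ctr + (centers + strip_width_mm / 2) / pixel_spacing[2]))
  if (any(cs < 0) || any(ce > n_cols)) stop("strips fall outside the image")

  strip <- matrix(0, n_rows, n_cols)
  for (i in seq_len(n))
    strip[, (cs[i] + 1):ce[i]] <- open[, (cs[i] + 1):ce[i]] * factors[i]
  if (noise_sd > 0)
    strip <- strip + matrix(stats::rnorm(n_rows * n_cols, 0, noise_sd),
                            n_rows, n_cols)
  layout <- strip_layout(cs, ce, round(n_rows / 4), round(3 * n_rows / 4))
  list(strip = epid_image(strip, pixel_spacing, "STRIP", machine_id = machine_id),
       open = epid_image(open, pixel_spacing, "OPEN", machine_id = machine_id),
       factors = factors, layout = layout)
}
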