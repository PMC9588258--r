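#' Scale a plan's total MU
#'
#' Multiplies every beam meterset by a uniform factor while leaving the
#' control-point geometry (gantry angles, cumulative weights, MLC positions)
#' untouched. Because arc length is unchanged, every defined segment's MU/deg
#' scales by exactly the same factor — this is how a stock DRGS strip-test
#' plan is pushed to the slow gantry speeds (high MU/deg) that stereotactic
#' plans reach. The open-field beam scales along with the strips, preserving
#' the strip/open normalization of the image analysis.
#'
#' @param plan a [treatment_plan()].
#' @param factor positive multiplier (e.g. 10 to take a 250 MU test file to
#'   2500 MU).
#' @param limits optional [machine_limits()]; when given, the result's
#'   `deliverable` flag reports whether the scaled maximum MU/deg stays at or
#'   below `limits$max_mu_per_deg`. Exceeding the ceiling flags the result,
#'   it does not raise.
#' @return list with `plan` (the scaled [treatment_plan()]) and `result`
#'   (class `scaling_result`: `factor`, `original_total_mu`,
#'   `scaled_total_mu`, `original_max_mu_per_deg`, `scaled_max_mu_per_deg`,
#'   `deliverable`).
#' @export
scale_plan_mu <- function(plan, factor, limits = NULL) {
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0)
    stop("factor must be a positive number")
  orig_max <- plan_max_mu_per_deg(plan)
  scaled <- plan
  scaled$beams <- lapply(plan$beams, function(b) {
    b$beam_meterset <- b$beam_meterset * factor
    b
  })
  scaled_max <- plan_max_mu_per_deg(scaled)
  deliverable <- if (is.null(limits)) NA
                 else scaled_max <= limits$max_mu_per_deg
  result <- structure(list(
    factor = factor,
    original_total_mu = plan_total_mu(plan),
    scaled_total_mu = plan_total_mu(scaled),
    original_max_mu_per_deg = orig_max,
    scaled_max_mu_per_deg = scaled_max,
    deliverable = deliverable
  ), class = "scaling_result")
  list(plan = scaled, result = result)
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("<scaling_result> x%g: %.4g -> %.4g MU, max %.2f -> %.2f MU/deg",
              x$factor, x$original_total_mu, x$scaled_total_mu,
              x$original_max_mu_per_deg, x$scaled_max_mu_per_deg))
  if (!is.na(x$deliverable))
    cat(if (x$deliverable) "  [deliverable]" else "  [NOT deliverable]")
  cat("\n")
  invisible(x)
}

#' Smallest scale factor that surpasses a target MU/deg
#'
#' Finds the smallest factor (smallest integer when `integer_only`) such that
#' the plan's maximum MU/deg, multiplied by the factor, strictly exceeds the
#' target — e.g. the maximum MU/deg observed across a clinical cohort, so
#' that the scaled test plan probes beyond everything the clinic delivers.
#'
#' @param plan a [treatment_plan()] with at least one defined MU/deg segment.
#' @param target_mu_per_deg target to surpass (MU/deg, > 0).
#' @param integer_only return the smallest integer factor (default `TRUE`,
#'   matching how test plans are conventionally rescaled).
#' @return positive scale factor.
#' @export
required_scale_factor <- function(plan, target_mu_per_deg, integer_only = TRUE) {
  if (!is.finite(target_mu_per_deg) || target_mu_per_deg <= 0)
    stop("target_mu_per_deg must be > 0")
  m <- plan_max_mu_per_deg(plan)
  q <- target_mu_per_deg / m
  if (integer_only) {
    f <- floor(q) + 1
    # guard against floating error putting floor one too high/low
    while ((f - 1) >= 1 && (f - 1) * m > target_mu_per_deg) f <- f - 1
    while (f * m <= target_mu_per_deg) f <- f + 1
    f
  } else {
    f <- q * (1 + 1e-9)
    if (f * m <= target_mu_per_deg) f <- q * (1 + 1e-6)
    f
  }
}

#' Check a plan against a machine's MU/deg ceiling
#'
#' @param plan a [treatment_plan()].
#' @param limits a [machine_limits()].
#' @return data frame of findings (one row per arc segment whose MU/deg
#'   exceeds `limits$max_mu_per_deg`, with columns `plan`, `beam_id`,
#'   `segment_index`, `mu_per_deg`, `ceiling`); zero rows means deliverable.
#' @export
deliverability_check <- function(plan, limits) {
  stopifnot(inherits(limits, "machine_limits"))
  k <- plan_kinematics(plan)
  bad <- k[!k$undefined & k$mu_per_deg > limits$max_mu_per_deg, , drop = FALSE]
  data.frame(plan = bad$plan, beam_id = bad$beam_id,
             segment_index = bad$segment_index, mu_per_deg = bad$mu_per_deg,
             ceiling = rep(limits$max_mu_per_deg, nrow(bad)))
}
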