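# shared helpers: quick beam builders and independent oracles

# build an arc beam from explicit angles/weights
mk_beam <- function(angles, weights, meterset = 100, direction = "CW",
                    final = NULL, id = "B1") {
  if (is.null(final)) final <- weights[length(weights)]
  arc_beam(id, meterset, final, direction,
           data.frame(index = seq_along(angles) - 1L, gantry_angle = angles,
                      cumulative_weight = weights))
}

# exhaustive angle-unwrapping oracle: try every 360-degree offset and keep
# the candidate arc length in [0, 360) along the stated direction
oracle_deg <- function(angles, direction) {
  n <- length(angles)
  vapply(seq_len(n - 1), function(i) {
    raw <- if (direction == "CW") angles[i + 1] - angles[i]
           else angles[i] - angles[i + 1]
    cand <- raw + 360 * (-2:2)
    cand <- cand[cand >= 0 & cand < 360]
    if (length(cand) != 1) stop("oracle ambiguity")
    cand
  }, 0)
}

# spreadsheet-style cumulative-difference oracle for MU per segment
oracle_mu <- function(meterset, weights, final) {
  n <- length(weights)
  out <- numeric(n - 1)
  for (i in seq_len(n - 1))
    out[i] <- meterset * weights[i + 1] / final - meterset * weights[i] / final
  out
}

# closed-form deviation when one of n equal segments carries factor (1+delta)
closed_form_hot <- function(delta, n) ((1 + delta) / (1 + delta / n) - 1) * 100
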