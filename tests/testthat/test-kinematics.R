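test_that("mu_per_cp matches the cumulative-difference oracle and conserves MU", {
  cases <- list(
    list(meterset = 100, w = c(0, 0.25, 1.0), final = 1.0, expect = c(25, 75)),
    list(meterset = 100, w = c(0, 1, 2), final = 2.0, expect = c(50, 50)),
    list(meterset = 250, w = c(0, 0.1, 0.3, 0.6, 1.0), final = 1.0,
         expect = oracle_mu(250, c(0, 0.1, 0.3, 0.6, 1.0), 1.0))
  )
  for (cs in cases) {
    beam <- mk_beam(seq(0, by = 2, length.out = length(cs$w)), cs$w,
                    meterset = cs$meterset, final = cs$final)
    got <- mu_per_cp(beam)
    expect_equal(got, cs$expect)
    delivered <- cs$meterset * (cs$w[length(cs$w)] - cs$w[1]) / cs$final
    expect_equal(sum(got), delivered, tolerance = 1e-9)
  }
  expect_equal(oracle_mu(250, c(0, 0.1, 0.3, 0.6, 1.0), 1.0),
               c(25, 50, 75, 100))
  expect_error(mu_per_cp(mk_beam(0, 0)), "fewer than 2")
})

test_that("deg_per_cp unwraps the 0/360 boundary directionally", {
  expect_equal(deg_per_cp(mk_beam(c(350, 10), c(0, 1), direction = "CW")), 20)
  expect_equal(oracle_deg(c(350, 10), "CW"), 20)
  expect_equal(deg_per_cp(mk_beam(c(181, 179), c(0, 1), direction = "CC")), 2)
  expect_equal(deg_per_cp(mk_beam(c(90, 90), c(0, 1), direction = "CW")), 0)
  expect_error(deg_per_cp(mk_beam(c(0, 0), c(0, 1), direction = "NONE")),
               "static")
})

test_that("deg_per_cp agrees with the exhaustive unwrapping oracle on random beams", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    dir <- sample(c("CW", "CC"), 1)
    angles <- round(runif(n, 0, 359.999), 3)
    beam <- mk_beam(angles, seq(0, 1, length.out = n), direction = dir)
    expect_equal(deg_per_cp(beam), oracle_deg(angles, dir))
  }
})

test_that("deg_per_cp is invariant under a constant rotation offset", {
  set.seed(7)
  angles <- round(runif(6, 0, 359.9), 2)
  beam <- mk_beam(angles, seq(0, 1, length.out = 6), direction = "CW")
  base <- deg_per_cp(beam)
  for (off in c(13.5, 101, 247.25)) {
    shifted <- mk_beam((angles + off) %% 360, seq(0, 1, length.out = 6),
                       direction = "CW")
    expect_equal(deg_per_cp(shifted), base, tolerance = 1e-9)
  }
})

test_that("mu_per_deg combines the two rates and flags zero-arc segments", {
  beam <- mk_beam(c(0, 2, 2, 6), c(0, 0.5, 0.7, 1.0), meterset = 100)
  k <- mu_per_deg(beam)
  expect_equal(k$mu_per_deg[1], 50 / 2)  # 50 MU over 2 degrees
  expect_true(k$undefined[2])            # gantry held still
  expect_true(is.na(k$mu_per_deg[2]))
  expect_equal(k$mu_per_deg[3], 30 / 4)
  expect_equal(nrow(k), 3)               # never silently dropped

  # vendor replica: hand arithmetic on the fixture segment table
  plan <- make_vendor_replica_plan()
  karc <- mu_per_deg(plan$beams[[1]])
  expect_equal(karc$mu_per_cp, c(10, 15, 20, 25, 30, 43.2, 56.8))
  expect_equal(karc$deg_per_cp, rep(25, 7))
  expect_equal(max(karc$mu_per_deg), 2.272)

  # uniform arc: 180 MU over 180 degrees in 10 CPs -> 1.0 MU/deg everywhere
  uni <- mk_beam(seq(90, 270, length.out = 10), seq(0, 1, length.out = 10),
                 meterset = 180)
  expect_equal(mu_per_deg(uni)$mu_per_deg, rep(1, 9), tolerance = 1e-12)
})

test_that("critical MU/deg is dose rate over 60x gantry speed", {
  expect_equal(round(critical_mu_per_deg(machine_limits(600, 6)), 2), 1.67)
  expect_equal(critical_mu_per_deg(machine_limits(60, 1)), 1.0)
  expect_equal(round(critical_mu_per_deg(machine_limits(1400, 6)), 2),
               round(1400 / 360, 2))
  # linear in dose rate, inverse in gantry speed
  base <- critical_mu_per_deg(machine_limits(600, 6))
  expect_equal(critical_mu_per_deg(machine_limits(1200, 6)), 2 * base)
  expect_equal(critical_mu_per_deg(machine_limits(600, 12)), base / 2)
  expect_error(machine_limits(-600, 6), "max_dose_rate")
})

test_that("scaling the meterset scales every defined MU/deg by the same factor", {
  plan <- make_sbrt_like_plan(n_cps = 30, seed = 9)
  beam <- plan$beams[[1]]
  k1 <- mu_per_deg(beam)
  beam$beam_meterset <- beam$beam_meterset * 3.5
  k2 <- mu_per_deg(beam)
  expect_equal(k2$mu_per_deg, 3.5 * k1$mu_per_deg, tolerance = 1e-12)
})

test_that("cohort_summary pools segments and counts exceedances", {
  one <- treatment_plan("p", list(
    mk_beam(c(0, 10, 20, 30), c(0, 10/60, 30/60, 1), meterset = 60)))
  s <- cohort_summary(one, thresholds = 1.5)
  expect_equal(s$n_segments, 3)            # segments 1, 2, 3 MU/deg
  expect_equal(unname(s$fraction_above[[1]]), 2 / 3)
  expect_equal(s$max_mu_per_deg, 3)
  expect_equal(sum(s$histogram$count), s$n_segments)

  s0 <- cohort_summary(one)
  expect_length(s0$fraction_above, 0)
  expect_gt(nrow(s0$histogram), 0)

  static_only <- treatment_plan("s", list(
    mk_beam(c(0, 0), c(0, 1), direction = "NONE")))
  expect_error(cohort_summary(static_only), "no arc segments")
})

test_that("undefined segments are tallied separately, not binned", {
  plan <- treatment_plan("p", list(
    mk_beam(c(0, 5, 5, 10), c(0, 0.3, 0.6, 1), meterset = 10)))
  s <- cohort_summary(plan)
  expect_equal(s$n_undefined, 1)
  expect_equal(s$n_segments, 2)
  expect_equal(sum(s$histogram$count), 2)
})

test_that("machine limits round-trip through config files", {
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    cfg <- list(max_dose_rate_mu_min = 600, max_gantry_speed_deg_s = 6,
                max_mu_per_deg = 60)
    if (ext == ".yaml") yaml::write_yaml(cfg, path)
    else jsonlite::write_json(cfg, path, auto_unbox = TRUE)
    lim <- read_machine_limits(path)
    expect_equal(lim$max_dose_rate, 600)
    expect_equal(lim$max_gantry_speed, 6)
    expect_equal(lim$max_mu_per_deg, 60)
  }
})
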