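test_that("coronary waveform is non-negative, periodic, and mean-preserving", {
  for (q in c(50, 150, 250)) {
    tt <- seq(0, 1, length.out = 2001)
    w <- coronary_waveform(tt, q)
    expect_true(all(w >= 0))
    expect_equal(coronary_waveform(0.3, q), coronary_waveform(1.3, q))
    # quadrature oracle for the time average
    m <- stats::integrate(function(t) coronary_waveform(t, q), 0, 1,
                          subdivisions = 500L)$value
    expect_lt(abs(m - q), 0.001 * q)
  }
  # zero pulsatility collapses to the mean
  expect_equal(coronary_waveform(c(0, .2, .7), 150, pulsatility = 0),
               rep(150, 3))
})

test_that("prescribed velocity honours the flux contract and no-slip trend", {
  g <- vessel_geometry()
  p <- flow_protocol(150, 15, "side_hole")
  for (t in c(0, 0.37)) {
    vs <- velocity_snapshot(g, p, t = t)
    lat <- vs$lattice
    A <- matrix(rep(lat$r * lat$dr * lat$dth, lat$nth), lat$nr, lat$nth)
    # independent quadrature of the flux at an upstream and downstream slab
    conv <- 1000 / 60
    for (i in c(5, lat$nz - 3)) {
      ui <- vs$u[i, , ]
      flux <- sum(ui * A, na.rm = TRUE) / conv
      target <- vs$flow_ml_min + if (i >= lat$i_src) p$infusion_rate else 0
      expect_lt(abs(flux - target) / target, 0.005)
    }
    # no-slip: outermost ring is the slowest open ring, masked cells carry NA
    ui <- vs$u[lat$nz - 3, , ]
    expect_true(all(is.na(ui[1, ])))  # central wire
    open_rows <- rowMeans(ui, na.rm = TRUE)
    expect_lt(open_rows[lat$nr], min(open_rows[3:(lat$nr - 1)]))
    # axially aligned geometry gives an angularly symmetric profile
    expect_equal(ui[4, ], rep(ui[4, 1], lat$nth))
  }
})

test_that("analytic velocity profile vanishes at the vessel wall", {
  g <- vessel_geometry()
  R <- g$vessel_diameter / 2
  a <- g$wire_diameter / 2
  shape <- function(r) pmax(0, (R - r) * (r - a))
  expect_equal(shape(R), 0)
  expect_equal(shape(a), 0)
  expect_gt(shape((R + a) / 2), 0)
})

test_that("injection sources split the infusion by topology", {
  g <- vessel_geometry()
  side <- injection_sources(g, flow_protocol(150, 15, "side_hole"))
  expect_equal(nrow(side), 4)
  expect_equal(side$flow_ml_min, rep(15 / 4, 4))
  expect_equal(sort(diff(sort(side$theta_deg))), c(90, 90, 90))
  ends <- injection_sources(g, flow_protocol(250, 20, "end_hole"))
  expect_equal(sum(ends$flow_ml_min), 20)
  expect_true(all(ends$r_mm < g$catheter_outer_diameter / 2 +
                    g$vessel_diameter / 16))
  expect_equal(unique(ends$temperature_c), 29)
})

test_that("zero infusion leaves the field at blood temperature", {
  p <- flow_protocol(150, 0, "side_hole", check = FALSE)
  f <- simulate_mixing(p, config = small_config("side_hole"))
  expect_equal(f$lumen_min_c, 37)
  expect_equal(f$lumen_max_c, 37)
  expect_true(all(f$snapshots[!is.na(f$snapshots)] == 37))
  expect_equal(f$outlet_mixed_cup_c, 37)
})

test_that("solver is deterministic and respects the scalar bounds", {
  p <- flow_protocol(150, 15, "end_hole")
  f1 <- simulate_mixing(p, config = small_config("end_hole"))
  f2 <- simulate_mixing(p, config = small_config("end_hole"))
  expect_identical(f1$snapshots, f2$snapshots)
  expect_gte(f1$lumen_min_c, 29)
  expect_lte(f1$lumen_max_c, 37)
})

test_that("solver rejects unstable and degenerate configurations", {
  p <- flow_protocol(150, 15, "side_hole")
  expect_error(
    simulate_mixing(p, config = small_config("side_hole", dt = 0.05)),
    "stability")
  g_tight <- vessel_geometry(vessel_diameter = 1.05,
                             catheter_outer_diameter = 1)
  expect_error(
    simulate_mixing(flow_protocol(150, 15, "side_hole"), geometry = g_tight,
                    config = small_config("side_hole")),
    "degenerate")
  expect_error(
    simulate_mixing(p, config = small_config("end_hole")),
    "does not match")
})

test_that("virtual pullback reparametrises kinematically across durations", {
  f <- cached_field(150, 15, "side_hole")
  # freeze the stored cycle to a purely axial steady pattern, so the two
  # pullback speeds must sample identical temperature-vs-position profiles
  fz <- f
  ax <- 30 + 0.05 * f$lattice$z
  for (k in seq_along(fz$times))
    fz$snapshots[, , , k] <- array(rep(ax, f$lattice$nr * f$lattice$nth),
                                   dim(f$snapshots)[1:3])
  t15 <- virtual_pullback(fz, duration_s = 15)
  t30 <- virtual_pullback(fz, duration_s = 30)
  r15 <- resample_to_n(t15, 400)
  r30 <- resample_to_n(t30, 400)
  expect_equal(r15$temperature_c, r30$temperature_c, tolerance = 1e-10)
  # uniform field gives a constant trace
  fu <- f
  fu$snapshots[!is.na(fu$snapshots)] <- 36.27
  tu <- virtual_pullback(fu)
  expect_true(all(abs(tu$temperature_c - 36.27) < 1e-9))
})

test_that("end-hole pullback is colder near the tip than 6 cm distal", {
  f <- cached_field(150, 15, "end_hole")
  tr <- virtual_pullback(f)
  near_tip <- mean(tr$temperature_c[tr$position_cm < 0.5])
  distal <- mean(tr$temperature_c[tr$position_cm > 5])
  expect_lt(near_tip, distal)
})

test_that("pullback sensor noise is seeded and reproducible", {
  f <- cached_field(150, 15, "side_hole")
  t1 <- virtual_pullback(f, noise_sd = 0.05, seed = 42)
  t2 <- virtual_pullback(f, noise_sd = 0.05, seed = 42)
  t3 <- virtual_pullback(f, noise_sd = 0.05, seed = 43)
  expect_identical(t1$temperature_c, t2$temperature_c)
  expect_false(identical(t1$temperature_c, t3$temperature_c))
})

test_that("sensor paths outside the lumen are rejected", {
  f <- cached_field(150, 15, "side_hole")
  expect_error(virtual_pullback(f, radial_offset_mm = 2.5), "geometry")
  expect_error(virtual_pullback(f, radial_offset_mm = 0.05), "geometry")
})

test_that("grid refinement leaves the mixing measures stable", {
  p <- flow_protocol(150, 15, "side_hole")
  fc <- simulate_mixing(p, config = solver_config("side_hole", nz = 70,
                                                  nr = 6, ntheta = 8,
                                                  n_store = 20))
  ff <- simulate_mixing(p, config = solver_config("side_hole", nz = 140,
                                                  nr = 12, ntheta = 16,
                                                  n_store = 20))
  mc <- mixing_measures(fc, 1.2)
  mf <- mixing_measures(ff, 1.2)
  # the deviation statistic is nearly zero at both resolutions: require
  # either 15% relative agreement or both below the 0.05 degC uniformity
  # floor (0.6% of the thermal contrast)
  ok <- abs(mc$sd_t - mf$sd_t) / mf$sd_t < 0.15 ||
    (mc$sd_t < 0.05 && mf$sd_t < 0.05)
  expect_true(ok)
  expect_lt(abs(mc$entropy_ratio - mf$entropy_ratio) / mf$entropy_ratio, 0.15)
})
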