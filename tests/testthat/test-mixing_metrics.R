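test_that("sample lattice covers the lumen uniformly with wire exclusion", {
  g <- vessel_geometry()
  s <- sample_grid(g, 1.2, catheter = "side_hole")
  expect_equal(nrow(s), 128)
  expect_true(all(s$r_mm < g$vessel_diameter / 2))
  # central 0.36 mm wire lies inside the innermost sample ring: no exclusion
  expect_equal(sum(s$wire_mask), 0)
  # a thicker central obstacle masks the innermost ring
  gw <- vessel_geometry(wire_diameter = 1.2, catheter_outer_diameter = 1.3)
  sw <- sample_grid(gw, 1.2, catheter = "side_hole")
  expect_true(all(sw$wire_mask[sw$r_mm == min(sw$r_mm)]))
  expect_false(any(sw$wire_mask[sw$r_mm > 0.5]))
  # alongside wire (end-hole) masks the points at its footprint
  se <- sample_grid(g, 1.2, catheter = "end_hole")
  expect_gt(sum(se$wire_mask), 0)
  expect_true(all(sqrt((se$x_mm[se$wire_mask] - 0.6)^2 +
                         se$y_mm[se$wire_mask]^2) < 0.18))
  expect_error(sample_grid(g, 7), "range")
})

test_that("equal-area radii give area-uniform coverage", {
  g <- vessel_geometry()
  s <- sample_grid(g, 1.2, n_radial = 8, n_angular = 16)
  radii <- sort(unique(s$r_mm))
  R <- g$vessel_diameter / 2
  expect_equal(radii, R * sqrt((1:8 - 0.5) / 8))
})

test_that("time averaging matches analytic means", {
  f <- cached_field(150, 15, "side_hole")
  s <- sample_grid(f$geometry, 1.2, catheter = "side_hole")
  # constant-in-time synthetic snapshots reproduce the snapshot itself
  fc <- f
  for (k in seq_along(fc$times)) fc$snapshots[, , , k] <- f$snapshots[, , , 1]
  ta <- time_averaged_temperatures(fc, s)
  one <- sample_field(fc, s)$temperatures[, 1]
  expect_equal(ta$t_mk, one)
  # a sinusoidal fluctuation about 36 degC averages to 36
  fs <- f
  for (k in seq_along(fs$times)) {
    ph <- 2 * pi * (k - 1) / length(fs$times)
    fs$snapshots[, , , k] <- 36 + 0.8 * sin(ph)
  }
  ta2 <- time_averaged_temperatures(fs, s)
  expect_equal(unname(ta2$t_bar), 36, tolerance = 1e-6)
  # two stored steps are the minimum
  f1 <- f
  f1$snapshots <- f$snapshots[, , , 1, drop = FALSE]
  f1$times <- f$times[1]
  expect_error(time_averaged_temperatures(f1, s), "insufficient")
})

test_that("cross-section deviation statistic has its closed-form values", {
  expect_equal(cross_section_sd(c(36, 38)), 1)
  expect_equal(cross_section_sd(c(36, 38), method = "mad"), 1)
  expect_equal(cross_section_sd(rep(35.2, 10)), 0)
  x <- c(34.8, 35.9, 36.4, 36.6)
  expect_equal(cross_section_sd(x + 5), cross_section_sd(x))
  expect_equal(cross_section_sd(x), sqrt(mean((x - mean(x))^2)))
  expect_equal(cross_section_sd(x, method = "mad"), mean(abs(x - mean(x))))
  expect_error(cross_section_sd(36.2), "insufficient")
})

test_that("dilution probability maps the temperature scale to [0, 1]", {
  expect_equal(dilution_probability(37, 37, 29), 0)
  expect_equal(dilution_probability(29, 37, 29), 1)
  expect_equal(dilution_probability(36.272727, 37, 29), 15 / 165,
               tolerance = 1e-5)
  expect_warning(p <- dilution_probability(38, 37, 29), "clamped")
  expect_equal(p, 0)
  expect_error(dilution_probability(30, 29, 37), "invalid")
})

test_that("entropy ratio calibrates to 1 at perfect mixing", {
  expect_equal(entropy_ratio(rep(0.09, 16), 0.09)$value, 1)
  e <- entropy_ratio(c(0.05, 0.13), 0.09)
  expect_equal(e$value, 0.957520, tolerance = 1e-4)
  nc <- entropy_ratio(rep(0, 8), 0.09)
  expect_false(nc$calculable)
  expect_true(is.na(nc$value))
  expect_error(entropy_ratio(c(0.1, 0.2), 1.2), "invalid")
  expect_error(entropy_ratio(0.5, 0.09), "insufficient")
})

test_that("entropy ratio is base-invariant and order/duplication-invariant", {
  set.seed(11)
  p <- runif(128)
  ps <- 0.12
  e_ln <- entropy_ratio(p, ps)$value
  e_10 <- mean(ifelse(p > 0, -p * log10(p), 0)) / (-ps * log10(ps))
  expect_equal(e_ln, e_10, tolerance = 1e-12)
  expect_equal(entropy_ratio(sample(p), ps)$value, e_ln)
  expect_equal(entropy_ratio(c(p, p), ps)$value, e_ln)
  x <- 30 + runif(64) * 7
  expect_equal(cross_section_sd(sample(x)), cross_section_sd(x))
  expect_equal(cross_section_sd(c(x, x)), cross_section_sd(x))
})

test_that("vectorised statistics match a naive per-point loop", {
  set.seed(21)
  for (rep in 1:5) {
    tm <- 29 + 8 * runif(128)
    tb <- mean(tm)
    sd_loop <- 0
    for (v in tm) sd_loop <- sd_loop + (v - tb)^2
    sd_loop <- sqrt(sd_loop / length(tm))
    expect_equal(cross_section_sd(tm), sd_loop, tolerance = 1e-13)
    p <- dilution_probability(tm, 37, 29)
    num <- 0
    for (v in p) num <- num + (if (v > 0) -v * log(v) else 0)
    e_loop <- (num / length(p)) / (-0.09 * log(0.09))
    expect_equal(entropy_ratio(p, 0.09)$value, e_loop, tolerance = 1e-13)
  }
})

test_that("two-level fields evaluate identically by brute force", {
  g <- vessel_geometry()
  s <- sample_grid(g, 2, catheter = "side_hole")
  f <- 0.25  # fraction of points at infusate temperature
  tm <- ifelse(seq_len(nrow(s)) %% 4 == 0, 29, 37)
  p <- dilution_probability(tm, 37, 29)
  expect_equal(mean(p), f)
  # p is exactly 0 or 1 at every point, so -p log p vanishes identically
  expect_equal(entropy_ratio(p, 0.09)$raw_mean_entropy, 0)
  expect_equal(cross_section_sd(tm), sqrt(f * (1 - f)) * 8)
})

test_that("longitudinal profile flags the homogenisation distance", {
  f <- cached_field(150, 15, "side_hole")
  prof <- longitudinal_profile(f, stations_cm = seq(0.2, 2, by = 0.2))
  expect_equal(nrow(prof), 10)
  expect_true(all(prof$sd_t >= 0))
  st <- attr(prof, "sd_threshold_station_cm")
  expect_lte(st, 1)   # side-hole deviation collapses by ~1 cm
  # a uniform field scores SD 0 and E 1 at every station
  fu <- f
  fu$snapshots[!is.na(fu$snapshots)] <- perfect_mix_temperature(f$protocol)
  pu <- longitudinal_profile(fu, stations_cm = c(1, 3))
  expect_equal(pu$sd_t, c(0, 0))
  expect_equal(pu$entropy_ratio, c(1, 1), tolerance = 1e-12)
  expect_error(longitudinal_profile(f, stations_cm = c(1, 9)), "range")
})
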