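make_trace <- function(temp_fun, duration = 20, rate = 20, span = 6) {
  tt <- seq(0, duration, by = 1 / rate)
  pos <- span * (1 - tt / duration)
  pullback_trace(tt, temp_fun(pos), position_cm = pos, sample_rate_hz = rate)
}

test_that("trace construction enforces pullback kinematics", {
  tr <- make_trace(function(p) 36 + 0 * p)
  expect_equal(tr$position_cm[1], 6)
  expect_equal(tr$position_cm[length(tr$position_cm)], 0)
  expect_error(pullback_trace(c(0, 1, 1), c(36, 36, 36)), "increasing")
  expect_error(pullback_trace(c(0, 10, 20), c(36, 36, 36),
                              position_cm = c(0, 3, 6)), "monotone")
  expect_warning(pullback_trace(seq(0, 5, by = 0.5), rep(36, 11)),
                 "plausibility")
})

test_that("rolling mean smooths as a centred convolution", {
  tr <- make_trace(function(p) rep(36, length(p)))
  expect_equal(rolling_mean(tr)$temperature_c, tr$temperature_c)
  # unit step smears into a linear ramp of the window width
  step <- make_trace(function(p) ifelse(p > 3, 30, 34))
  sm <- rolling_mean(step, window_s = 2)
  w <- 41  # 2 s at 20 Hz, rounded up to odd
  conv <- stats::filter(step$temperature_c, rep(1 / w, w), sides = 2)
  interior <- !is.na(conv)
  expect_equal(sm$temperature_c[interior], as.numeric(conv[interior]))
  ramp <- which(sm$temperature_c > 30.05 & sm$temperature_c < 33.95)
  expect_close(length(ramp) / step$sample_rate_hz, 2, 0.2)
  expect_error(rolling_mean(tr, window_s = 25), "window")
  expect_error(rolling_mean(tr, window_s = 0), "window")
})

test_that("rolling a white-noise trace shrinks its variance by the window size", {
  set.seed(31)
  tt <- seq(0, 30, by = 0.05)
  tr <- pullback_trace(tt, 36 + stats::rnorm(length(tt)),
                       sample_rate_hz = 20)
  sm <- rolling_mean(tr, 2)
  core <- seq(50, length(tt) - 50)
  ratio <- stats::var(sm$temperature_c[core]) / stats::var(tr$temperature_c[core])
  expect_gt(ratio, 1 / 90)
  expect_lt(ratio, 1 / 18)
})

test_that("resampling to N preserves endpoints and linear structure", {
  tr <- make_trace(function(p) rep(35.5, length(p)))
  rs <- resample_to_n(tr, 1000)
  expect_equal(nrow(rs), 1000)
  expect_equal(unique(rs$temperature_c), 35.5)
  lin <- make_trace(function(p) 30 + p)
  rl <- resample_to_n(lin, 1000)
  expect_equal(rl$temperature_c[1], 36)       # distal end first
  expect_equal(rl$temperature_c[1000], 30)
  expect_equal(rl$temperature_c, 30 + rl$position_cm, tolerance = 1e-12)
  # 15 s and 30 s recordings of one spatial profile coincide after resampling
  prof <- function(p) 37 - 5 * exp(-p / 2)
  r15 <- resample_to_n(make_trace(prof, duration = 15), 500)
  r30 <- resample_to_n(make_trace(prof, duration = 30), 500)
  expect_equal(r15$temperature_c, r30$temperature_c, tolerance = 1e-6)
})

test_that("relative deviations are zero-mean percentages of the trace mean", {
  # alternating 36/38 degC normalised points: deviations are exactly
  # -/+ (1/37)*100 about the 37 degC mean
  alt <- structure(
    data.frame(position_cm = seq(6, 0, length.out = 1000),
               temperature_c = rep(c(36, 38), 500)),
    class = c("resampled_trace", "data.frame"))
  prof <- relative_deviation_profile(alt)
  expect_equal(attr(prof, "mean_temperature_c"), 37)
  expect_equal(mean(prof$rel_dev_pct), 0, tolerance = 1e-12)
  expect_equal(max(prof$rel_dev_pct), 100 / 37)
  expect_equal(min(prof$rel_dev_pct), -100 / 37)
  const <- relative_deviation_profile(resample_to_n(
    make_trace(function(p) rep(36, length(p))), 1000))
  expect_true(all(const$rel_dev_pct == 0))
  # the pipeline shape rejects un-normalised traces
  expect_error(relative_deviation_profile(
    make_trace(function(p) 30 + p)), "resample")
})

test_that("exceedance counts points beyond the threshold and is monotone", {
  dev <- c(rep(25, 55), rep(-25, 55), rep(0, 890))
  expect_equal(exceedance_fraction(dev, 15), 11)
  expect_equal(exceedance_fraction(dev, 20), 11)
  expect_equal(exceedance_fraction(rep(0, 1000), 15), 0)
  th <- c(5, 10, 15, 20, 30)
  set.seed(5)
  rnd <- stats::rnorm(1000, 0, 12)
  ex <- vapply(th, function(t) exceedance_fraction(rnd, t), 1)
  expect_true(all(diff(ex) <= 0))
  expect_error(exceedance_fraction(dev, -1), "positive")
})

test_that("CSV round trip preserves a recorded trace", {
  tr <- make_trace(function(p) 37 - 3 * exp(-p))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = tr$time_s,
                              temperature_C = tr$temperature_c,
                              position_cm = tr$position_cm),
                   path, row.names = FALSE)
  back <- read_pullback_csv(path)
  expect_equal(back$temperature_c, tr$temperature_c)
  expect_equal(back$position_cm, tr$position_cm)
  # position column optional: constant-speed reconstruction
  utils::write.csv(data.frame(time_s = tr$time_s,
                              temperature_C = tr$temperature_c),
                   path, row.names = FALSE)
  back2 <- read_pullback_csv(path)
  expect_equal(back2$position_cm[1], 6)
  expect_error(read_pullback_csv({
    p2 <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1:3), p2, row.names = FALSE)
    p2
  }), "columns")
})

test_that("synthetic cold-core trace recovers the expected exceedance contrast", {
  # deterministic synthetic bench trace: near-pure infusate over the first
  # 1.5 cm, sharp transition to blood temperature distally
  prof <- function(p) 23.5 + (37 - 23.5) / (1 + exp(-(3 - p) * -4))
  tr <- make_trace(prof)
  res <- analyze_pullback(tr)
  e15 <- res$exceedance[["exceedance_15"]]
  e20 <- res$exceedance[["exceedance_20"]]
  expect_gt(e15, e20)
  expect_gt(e20, 10)
  flat <- analyze_pullback(make_trace(function(p) rep(35.7, length(p))))
  expect_equal(unname(flat$exceedance), c(0, 0))
})
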