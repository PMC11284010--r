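#' Time-stamped pullback temperature trace
#'
#' Container for one sensor pullback recording: temperature versus time
#' while the pressure/temperature sensor is withdrawn from ~6 cm distal to
#' the catheter tip back to the tip. Position is monotone non-increasing in
#' time; when absent it is reconstructed assuming constant pullback speed
#' over the 6 cm span (the bench pullbacks were manual, so recorded position
#' is optional).
#'
#' @param time_s Time stamps, s (strictly increasing).
#' @param temperature_c Temperatures, degC.
#' @param position_cm Sensor position, cm distal to the catheter tip;
#'   `NULL` assumes constant speed from `span_cm` to 0.
#' @param sample_rate_hz Sampling rate; inferred from the time stamps when
#'   `NULL`.
#' @param span_cm Pullback span used when reconstructing position. Default 6.
#' @param metadata Free-form list (catheter id, protocol, ...).
#' @param check_duration Warn when the duration falls outside the
#'   plausibility window `[10, 60]` s (bench practice was 15-30 s).
#' @return An object of class `pullback_trace`.
#' @export
pullback_trace <- function(time_s, temperature_c, position_cm = NULL,
                           sample_rate_hz = NULL, span_cm = 6,
                           metadata = list(), check_duration = TRUE) {
  stopifnot(length(time_s) == length(temperature_c), length(time_s) >= 2)
  if (any(diff(time_s) <= 0))
    stop("time stamps must be strictly increasing", call. = FALSE)
  dur <- time_s[length(time_s)] - time_s[1]
  if (check_duration && (dur < 10 || dur > 60))
    warning(sprintf("pullback duration %.1f s outside plausibility window [10, 60] s",
                    dur))
  if (is.null(position_cm)) {
    position_cm <- span_cm * (1 - (time_s - time_s[1]) / dur)
  } else {
    stopifnot(length(position_cm) == length(time_s))
    if (any(diff(position_cm) > 1e-9))
      stop("position must be monotone non-increasing during a pullback",
           call. = FALSE)
  }
  if (is.null(sample_rate_hz))
    sample_rate_hz <- (length(time_s) - 1) / dur
  structure(list(time_s = time_s, temperature_c = temperature_c,
                 position_cm = position_cm, sample_rate_hz = sample_rate_hz,
                 metadata = metadata),
            class = "pullback_trace")
}

#' @export
print.pullback_trace <- function(x, ...) {
  cat(sprintf(
    "<pullback_trace> %d samples, %.1f s, %.2f -> %.2f cm, T in [%.2f, %.2f] degC\n",
    length(x$time_s), diff(range(x$time_s)), x$position_cm[1],
    x$position_cm[length(x$position_cm)], min(x$temperature_c),
    max(x$temperature_c)))
  invisible(x)
}

#' Read a recorded pullback from CSV
#'
#' Expects columns `time_s` and `temperature_C` (case-insensitive; an
#' optional `position_cm` column is used when present, otherwise constant
#' pullback speed over 6 cm is assumed).
#'
#' @param path CSV file path.
#' @param ... Passed to [pullback_trace()].
#' @return A [pullback_trace()].
#' @export
read_pullback_csv <- function(path, ...) {
  df <- utils::read.csv(path)
  names(df) <- tolower(names(df))
  if (!all(c("time_s", "temperature_c") %in% names(df)))
    stop("CSV must contain columns time_s and temperature_C", call. = FALSE)
  pos <- if ("position_cm" %in% names(df)) df$position_cm else NULL
  pullback_trace(df$time_s, df$temperature_c, position_cm = pos, ...)
}

#' Centred rolling mean of a pullback trace
#'
#' Smooths the temperature channel with a centred moving average over an
#' odd number of samples spanning the requested time window (default 2 s,
#' matching clinical practice). Windows shrink symmetrically at the trace
#' ends; positions and time stamps are unchanged.
#'
#' @param trace A [pullback_trace()].
#' @param window_s Averaging window, s. Must be positive and shorter than
#'   the trace.
#' @return A smoothed [pullback_trace()].
#' @export
rolling_mean <- function(trace, window_s = 2) {
  stopifnot(inherits(trace, "pullback_trace"))
  dur <- diff(range(trace$time_s))
  if (window_s <= 0) stop("window error: window must be positive", call. = FALSE)
  if (window_s >= dur)
    stop("window error: window must be shorter than the trace", call. = FALSE)
  w <- round(window_s * trace$sample_rate_hz)
  if (w %% 2 == 0) w <- w + 1
  w <- max(w, 1)
  sm <- zoo::rollapply(trace$temperature_c, width = w, FUN = mean,
                       align = "center", partial = TRUE)
  out <- trace
  out$temperature_c <- as.numeric(sm)
  out$metadata$smoothed_window_s <- window_s
  out
}

#' Normalise a trace to N points
#'
#' Linear interpolation of the temperature onto `n` positions uniformly
#' spaced over the recorded pullback span, compensating for differing
#' pullback durations. Endpoints are preserved.
#'
#' @param trace A [pullback_trace()].
#' @param n Number of points. Default 1000.
#' @return An object of class `resampled_trace`: data.frame with
#'   `position_cm` (descending, distal end first) and `temperature_c`.
#' @export
resample_to_n <- function(trace, n = 1000) {
  stopifnot(inherits(trace, "pullback_trace"), n >= 2)
  if (length(trace$time_s) < 2)
    stop("degenerate trace: need at least 2 points", call. = FALSE)
  pos <- trace$position_cm
  span <- range(pos)
  if (diff(span) <= 0)
    stop("degenerate trace: sensor did not move", call. = FALSE)
  target <- seq(span[2], span[1], length.out = n)
  # position may contain ties (clamped path ends); average temperatures there
  temp <- stats::approx(x = pos, y = trace$temperature_c, xout = target,
                        ties = mean)$y
  structure(data.frame(position_cm = target, temperature_c = temp),
            class = c("resampled_trace", "data.frame"),
            n = n, metadata = trace$metadata)
}

#' Relative temperature-deviation profile
#'
#' Expresses each of the N normalised temperatures as its percentage
#' deviation from the pullback mean:
#' `dT_rel,i = (T_i - Tbar_pb) / Tbar_pb * 100` for i = 1..N, with
#' `Tbar_pb` the arithmetic mean over the N points. The deviations average
#' to zero by construction. Deviations are computed on the recorded degC
#' scale (the percentages are only meaningful on the measured scale).
#'
#' @param resampled A [resample_to_n()] result (the pipeline order is
#'   smooth, then resample, then deviations; passing an un-resampled trace
#'   is an error).
#' @return An object of class `deviation_profile`: data.frame with
#'   `position_cm` and `rel_dev_pct`, attributes `mean_temperature_c` and
#'   `n`.
#' @export
relative_deviation_profile <- function(resampled) {
  if (!inherits(resampled, "resampled_trace"))
    stop("deviations are computed on a resampled trace; call resample_to_n() first",
         call. = FALSE)
  tm <- mean(resampled$temperature_c)
  if (!is.finite(tm) || tm == 0)
    stop("scale error: mean pullback temperature is zero", call. = FALSE)
  structure(data.frame(position_cm = resampled$position_cm,
                       rel_dev_pct = (resampled$temperature_c - tm) / tm * 100),
            class = c("deviation_profile", "data.frame"),
            mean_temperature_c = tm, n = nrow(resampled),
            metadata = attr(resampled, "metadata"))
}

#' Exceedance fraction of a deviation profile
#'
#' Percentage of the N profile points whose absolute relative deviation
#' exceeds the threshold. Non-increasing in the threshold.
#'
#' @param profile A [relative_deviation_profile()] result, or a numeric
#'   vector of relative deviations in percent.
#' @param threshold_pct Threshold, percent (> 0). Default 15.
#' @return Exceedance, percent of points.
#' @export
exceedance_fraction <- function(profile, threshold_pct = 15) {
  if (threshold_pct <= 0)
    stop("threshold must be positive", call. = FALSE)
  dev <- if (inherits(profile, "deviation_profile")) profile$rel_dev_pct
         else as.numeric(profile)
  100 * mean(abs(dev) > threshold_pct)
}

#' Full pullback analysis pipeline
#'
#' Applies the fixed analysis order to a recorded or simulated trace:
#' rolling mean (2 s window), normalisation to N = 1000 points, relative
#' deviations from the pullback mean, and 15%/20% exceedance fractions.
#'
#' @param trace A [pullback_trace()].
#' @param window_s Rolling-mean window, s. Default 2.
#' @param n Resampling size. Default 1000.
#' @param thresholds_pct Exceedance thresholds, percent. Default `c(15, 20)`.
#' @return A list: `profile` (deviation profile), `mean_temperature_c`,
#'   `exceedance` (named vector, percent of points per threshold).
#' @export
analyze_pullback <- function(trace, window_s = 2, n = 1000,
                             thresholds_pct = c(15, 20)) {
  prof <- relative_deviation_profile(
    resample_to_n(rolling_mean(trace, window_s), n))
  exc <- vapply(thresholds_pct, function(th) exceedance_fraction(prof, th),
                numeric(1))
  names(exc) <- paste0("exceedance_", thresholds_pct)
  list(profile = prof,
       mean_temperature_c = attr(prof, "mean_temperature_c"),
       exceedance = exc)
}
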