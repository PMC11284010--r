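#' Uniform cross-section sample lattice
#'
#' Deterministic polar lattice of `n_radial x n_angular` points covering the
#' lumen uniformly by area: point radii sit at the area centroids of
#' `n_radial` equal-area rings (`R * sqrt((k - 1/2) / n_radial)`), with
#' `n_angular` equally spaced angles. Points falling inside the
#' pressure/temperature wire footprint at that station are flagged in
#' `wire_mask` and excluded from the mixing statistics.
#'
#' @param geometry A [vessel_geometry()].
#' @param station_cm Axial distance distal to the infusion site, cm (used
#'   only to locate the wire footprint; the wire runs the vessel length).
#' @param n_radial,n_angular Lattice size. Default 8 x 16 (128 points).
#' @param catheter Catheter topology; determines the wire position (central
#'   for side-hole, alongside at the catheter wall for end-hole) unless the
#'   geometry fixes `wire_placement`.
#' @return An object of class `cross_section_sample`: data.frame of points
#'   (`r_mm`, `theta_rad`, `x_mm`, `y_mm`, `wire_mask`) plus attributes.
#' @export
sample_grid <- function(geometry, station_cm = 1.2,
                        n_radial = 8, n_angular = 16,
                        catheter = c("side_hole", "end_hole")) {
  catheter <- match.arg(catheter)
  stopifnot(inherits(geometry, "vessel_geometry"),
            n_radial >= 1, n_angular >= 2)
  z_mm <- geometry$outlet_axial_position + 10 * station_cm
  if (station_cm < 0 || z_mm > geometry$vessel_length)
    stop("range error: station outside the vessel", call. = FALSE)
  R <- geometry$vessel_diameter / 2
  rw <- geometry$wire_diameter / 2
  radii <- R * sqrt((seq_len(n_radial) - 0.5) / n_radial)
  angles <- (seq_len(n_angular) - 1) * 2 * pi / n_angular
  pts <- expand.grid(r_mm = radii, theta_rad = angles)
  pts$x_mm <- pts$r_mm * cos(pts$theta_rad)
  pts$y_mm <- pts$r_mm * sin(pts$theta_rad)
  placement <- .wire_placement(geometry, catheter)
  if (placement == "inside") {
    wx <- 0; wy <- 0
  } else {
    wx <- geometry$catheter_outer_diameter / 2 + rw; wy <- 0
  }
  pts$wire_mask <- (pts$x_mm - wx)^2 + (pts$y_mm - wy)^2 < rw^2
  structure(pts, class = c("cross_section_sample", "data.frame"),
            station_cm = station_cm, z_mm = z_mm, catheter = catheter,
            geometry = geometry)
}

#' Extract sampled temperatures from a simulated field
#'
#' Looks up the stored snapshots at the nearest lattice cell for each sample
#' point of a cross-section. Points whose nearest cell is solid (catheter or
#' wire) are added to the wire mask.
#'
#' @param field A [simulate_mixing()] result.
#' @param sample A [sample_grid()] result (its station must lie within the
#'   stored field).
#' @return A list: `temperatures` (points x stored time steps, `NA` on
#'   masked points), updated logical `mask`, `times`.
#' @export
sample_field <- function(field, sample) {
  stopifnot(inherits(field, "temperature_field"),
            inherits(sample, "cross_section_sample"))
  lat <- field$lattice
  z_mm <- attr(sample, "z_mm")
  if (z_mm < lat$z[lat$i_src] - lat$dz / 2 || z_mm > lat$z[lat$nz] + lat$dz / 2)
    stop("range error: station outside the stored field", call. = FALSE)
  zi <- which.min(abs(lat$z - z_mm))
  nc <- .nearest_cell(lat, sample$r_mm, sample$theta_rad)
  mask <- sample$wire_mask | (field$mask[cbind(zi, nc$ring, nc$sector)] != 0L)
  nt <- length(field$times)
  temps <- matrix(NA_real_, nrow(sample), nt)
  for (k in seq_len(nt))
    temps[, k] <- field$snapshots[cbind(zi, nc$ring, nc$sector, k)]
  temps[mask, ] <- NA_real_
  list(temperatures = temps, mask = mask, times = field$times)
}

#' Time-averaged sample temperatures over the analysis cycle
#'
#' Per-point mean temperature over the stored steps of the analysis cardiac
#' cycle, and the cross-section mean over unmasked points.
#'
#' @inheritParams sample_field
#' @return List with `t_mk` (per-point time averages, `NA` where masked),
#'   `t_bar` (mean over unmasked points), `mask`, `n_used`.
#' @export
time_averaged_temperatures <- function(field, sample) {
  s <- sample_field(field, sample)
  if (ncol(s$temperatures) < 2)
    stop("insufficient sampling: need at least 2 stored time steps",
         call. = FALSE)
  t_mk <- rowMeans(s$temperatures)
  n_used <- sum(!s$mask)
  if (n_used < 2)
    stop("insufficient sample: fewer than 2 unmasked points", call. = FALSE)
  list(t_mk = t_mk, t_bar = mean(t_mk[!s$mask]), mask = s$mask,
       n_used = n_used)
}

#' Cross-section temperature deviation statistic
#'
#' Spread of the time-averaged temperatures over a cross-section. The
#' default is the root-mean-square deviation
#' `sqrt(sum((T_mk - Tbar)^2) / n)`; `method = "mad"` gives the mean
#' absolute deviation `sum(|T_mk - Tbar|) / n`. A value of 0 means the
#' temperature is uniform over the cross-section.
#'
#' @param t_mk Time-averaged temperatures (`NA` entries are excluded).
#' @param t_bar Cross-section mean; computed from `t_mk` if `NULL`.
#' @param method `"rms"` (default) or `"mad"`.
#' @return Deviation statistic, degC.
#' @export
cross_section_sd <- function(t_mk, t_bar = NULL, method = c("rms", "mad")) {
  method <- match.arg(method)
  t_mk <- t_mk[!is.na(t_mk)]
  if (length(t_mk) < 2)
    stop("insufficient sample: need at least 2 values", call. = FALSE)
  if (is.null(t_bar)) t_bar <- mean(t_mk)
  dev <- t_mk - t_bar
  if (method == "rms") sqrt(mean(dev^2)) else mean(abs(dev))
}

#' Dilution probability of a measured temperature
#'
#' Fractional thermal contribution of the infusate at a point:
#' `P = (Tb - T) / (Tb - Ti)`. P is 0 for pure blood and 1 for pure
#' infusate. Values numerically outside `[0, 1]` (e.g. sensor noise) are
#' clamped with a warning.
#'
#' @param temperature Measured temperature(s), degC.
#' @param tb Blood temperature, degC.
#' @param ti Infusate temperature, degC (must be below `tb`).
#' @return Probabilities in `[0, 1]`.
#' @export
dilution_probability <- function(temperature, tb, ti) {
  if (!(tb > ti))
    stop("invalid protocol: blood temperature must exceed infusate temperature",
         call. = FALSE)
  p <- (tb - temperature) / (tb - ti)
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
    warning("dilution probabilities outside [0, 1] clamped")
  pmin(1, pmax(0, p))
}

#' Shannon-entropy mixing ratio of a cross-section
#'
#' Homogeneity index based on the Shannon entropy of the dilution
#' probabilities, normalised by the entropy of the perfect-mixing
#' probability:
#' `E = mean(-P_k ln P_k) / (-P* ln P*)`, with `0 ln 0 := 0`.
#' `E = 1` when every point sits exactly at the perfect-mixing dilution
#' `P*`; values slightly above 1 can occur when the local probabilities
#' cluster nearer the entropy maximum than `P*` does. When no tracer has
#' reached any sample point (all `P_k = 0`) the ratio is not calculable.
#' The ratio is invariant to the logarithm base.
#'
#' @param p Dilution probabilities in `[0, 1]` (`NA` excluded).
#' @param p_star Perfect-mixing dilution fraction, in (0, 1); see
#'   [perfect_mix_fraction()].
#' @return List: `value` (E, `NA` when not calculable), `calculable`,
#'   `raw_mean_entropy` (the un-normalised mean `-P ln P`), `n_used`.
#' @export
entropy_ratio <- function(p, p_star) {
  if (!(length(p_star) == 1 && p_star > 0 && p_star < 1))
    stop("invalid protocol: perfect-mixing fraction must lie in (0, 1)",
         call. = FALSE)
  p <- p[!is.na(p)]
  if (length(p) < 2)
    stop("insufficient sample: need at least 2 probabilities", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  plogp <- ifelse(p > 0, -p * log(p), 0)
  num <- mean(plogp)
  den <- -p_star * log(p_star)
  if (all(p == 0))
    return(list(value = NA_real_, calculable = FALSE,
                raw_mean_entropy = num, n_used = length(p)))
  list(value = num / den, calculable = TRUE, raw_mean_entropy = num,
       n_used = length(p))
}

#' Mixing measures at one axial station
#'
#' Computes the time-averaged cross-section deviation statistic and the
#' entropy ratio of a simulated field at one station distal to the infusion
#' site, on the standard sample lattice with wire exclusion.
#'
#' @inheritParams sample_field
#' @param station_cm Station, cm distal to the infusion site.
#' @param n_radial,n_angular Sample lattice size.
#' @param sd_method Passed to [cross_section_sd()].
#' @return One-row data.frame: `station_cm`, `sd_t`, `entropy_ratio`,
#'   `n_used`, `calculable`.
#' @export
mixing_measures <- function(field, station_cm, n_radial = 8, n_angular = 16,
                            sd_method = "rms") {
  sample <- sample_grid(field$geometry, station_cm, n_radial, n_angular,
                        catheter = field$protocol$catheter)
  ta <- time_averaged_temperatures(field, sample)
  keep <- !ta$mask
  sd_t <- cross_section_sd(ta$t_mk[keep], ta$t_bar, method = sd_method)
  p <- dilution_probability(ta$t_mk[keep],
                            field$protocol$blood_temperature,
                            field$protocol$infusate_exit_temperature)
  ps <- perfect_mix_fraction(field$protocol$coronary_flow_mean,
                             field$protocol$infusion_rate)
  e <- entropy_ratio(p, ps)
  data.frame(station_cm = station_cm, sd_t = sd_t,
             entropy_ratio = e$value, n_used = ta$n_used,
             calculable = e$calculable)
}

#' Longitudinal profile of the mixing measures
#'
#' Evaluates [mixing_measures()] at a sequence of stations between the
#' infusion site and (by default) 4.8 cm distal, and reports the first
#' station at which the deviation statistic drops below a threshold (the
#' homogenisation distance).
#'
#' @inheritParams mixing_measures
#' @param stations_cm Stations, cm distal to the infusion site.
#' @param sd_threshold Threshold for the homogenisation distance, degC.
#'   Default 0.1.
#' @return A data.frame (one row per station) with attribute
#'   `sd_threshold_station_cm` (`NA` if never reached).
#' @export
longitudinal_profile <- function(field, stations_cm = seq(0.2, 4.8, by = 0.2),
                                 n_radial = 8, n_angular = 16,
                                 sd_method = "rms", sd_threshold = 0.1) {
  rows <- lapply(stations_cm, function(s)
    mixing_measures(field, s, n_radial, n_angular, sd_method))
  out <- do.call(rbind, rows)
  below <- which(out$sd_t < sd_threshold)
  attr(out, "sd_threshold") <- sd_threshold
  attr(out, "sd_threshold_station_cm") <-
    if (length(below)) out$station_cm[min(below)] else NA_real_
  out
}
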