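#' Read a pipeline run configuration from YAML
#'
#' The configuration mirrors the study design: a `geometry` block
#' ([vessel_geometry()] fields), a `protocols` block (either
#' `set: cfd`/`set: clinical` plus `mode: cfd`/`mode: bench`, or an explicit
#' list of flow/infusion/catheter entries), a `solver` block
#' ([solver_config()] overrides), `stations_cm` for the point metrics,
#' `profile_stations_cm`, and `seed` for stochastic sensor noise. A bundled
#' default (`system.file("extdata", "default_config.yaml", package =
#' "coromix")`) reproduces the study geometry and flow table.
#'
#' @param path YAML file; default the bundled configuration.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path = system.file("extdata",
                                               "default_config.yaml",
                                               package = "coromix")) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    protocols = list(set = "cfd", mode = "cfd"),
    geometry = list(), solver = list(),
    stations_cm = c(1.2, 4.4),
    profile_stations_cm = seq(0.2, 4.8, by = 0.2),
    pullback = list(duration_s = 20, sample_rate_hz = 20, noise_sd = 0.02),
    ink = list(cv_threshold = 0.35, window_cm = c(1, 3)),
    seed = 1L)
  merged <- utils::modifyList(defaults, cfg)
  # an explicit protocol list replaces the default preset outright
  if (!is.null(cfg$protocols)) merged$protocols <- cfg$protocols
  class(merged) <- "run_config"
  merged
}

.config_protocols <- function(cfg) {
  pr <- cfg$protocols
  if (!is.null(pr$set)) {
    mode <- if (is.null(pr$mode)) "cfd" else pr$mode
    if (pr$set == "cfd") return(cfd_combinations(mode = mode))
    if (pr$set == "clinical")
      return(clinically_relevant_combinations(mode = mode))
    stop("unknown protocol set: ", pr$set, call. = FALSE)
  }
  lapply(pr, function(p)
    flow_protocol(p$coronary_flow_mean, p$infusion_rate,
                  catheter = p$catheter,
                  blood_temperature = p$blood_temperature %||% 37,
                  infusate_exit_temperature =
                    p$infusate_exit_temperature %||% 29))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full mixing-assessment pipeline
#'
#' For every configured protocol: simulate the temperature field, compute
#' the cross-section mixing measures at the requested stations plus the
#' longitudinal profile, run a virtual sensor pullback through the deviation
#' analysis, and classify the projected dilution image. Deterministic given
#' the configuration and seed. When `outdir` is given, per-protocol CSV
#' summaries, the metrics table (the machine-readable analogue of a
#' per-station results table) and a JSON summary are written, each stamped
#' with the configuration hash, seed and package version.
#'
#' @param config A [read_run_config()] result (default: bundled config).
#' @param outdir Output directory, or `NULL` (default) to skip file output.
#' @param dry_run If `TRUE`, validate the plan and return it without
#'   computing.
#' @return A list of class `mixing_report`: `metrics` (one row per
#'   protocol x station), `profiles`, `pullbacks` (exceedance summaries),
#'   `ink` (verdicts), `provenance`.
#' @export
run_pipeline <- function(config = read_run_config(), outdir = NULL,
                         dry_run = FALSE) {
  protocols <- .config_protocols(config)
  geometry <- do.call(vessel_geometry, config$geometry)
  plan <- protocols_as_data_frame(protocols)
  provenance <- list(config_hash = .config_hash(unclass(config)),
                     seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("coromix")))
  if (dry_run)
    return(structure(list(plan = plan, provenance = provenance),
                     class = "mixing_report"))

  metrics <- list(); profiles <- list(); pulls <- list(); inks <- list()
  for (k in seq_along(protocols)) {
    p <- protocols[[k]]
    sc <- do.call(solver_config, c(list(catheter = p$catheter), config$solver))
    field <- simulate_mixing(p, geometry, sc)
    id <- sprintf("%s_%s_%g", p$catheter, p$coronary_category, p$infusion_rate)

    m <- do.call(rbind, lapply(config$stations_cm,
                               function(s) mixing_measures(field, s)))
    m <- cbind(catheter = p$catheter, coronary_flow = p$coronary_flow_mean,
               infusion_rate = p$infusion_rate, m)
    metrics[[id]] <- m

    prof <- longitudinal_profile(field,
                                 stations_cm = config$profile_stations_cm)
    profiles[[id]] <- cbind(catheter = p$catheter,
                            coronary_flow = p$coronary_flow_mean,
                            infusion_rate = p$infusion_rate, prof)

    tr <- virtual_pullback(field,
                           duration_s = config$pullback$duration_s,
                           sample_rate_hz = config$pullback$sample_rate_hz,
                           noise_sd = config$pullback$noise_sd,
                           seed = config$seed + k)
    pa <- analyze_pullback(tr)
    pulls[[id]] <- data.frame(catheter = p$catheter,
                              coronary_flow = p$coronary_flow_mean,
                              infusion_rate = p$infusion_rate,
                              mean_temperature_c = pa$mean_temperature_c,
                              exceedance_15 = pa$exceedance[["exceedance_15"]],
                              exceedance_20 = pa$exceedance[["exceedance_20"]])

    img <- project_field(field)
    v <- classify_mixing(img, window_cm = config$ink$window_cm,
                         cv_threshold = config$ink$cv_threshold)
    inks[[id]] <- data.frame(catheter = p$catheter,
                             category = p$coronary_category,
                             coronary_flow = p$coronary_flow_mean,
                             infusion_rate = p$infusion_rate,
                             verdict = v$verdict,
                             max_cv = max(v$uniformity$cv))
  }
  report <- structure(list(
    metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
    profiles = do.call(rbind, c(profiles, list(make.row.names = FALSE))),
    pullbacks = do.call(rbind, c(pulls, list(make.row.names = FALSE))),
    ink = do.call(rbind, c(inks, list(make.row.names = FALSE))),
    provenance = provenance), class = "mixing_report")
  if (!is.null(outdir)) write_mixing_report(report, outdir)
  report
}

#' Write a mixing report to CSV/JSON files
#'
#' @param report A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_mixing_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config_hash=%s seed=%s coromix=%s",
                   report$provenance$config_hash, report$provenance$seed,
                   report$provenance$package_version)
  paths <- character(0)
  for (nm in c("metrics", "profiles", "pullbacks", "ink")) {
    if (is.null(report[[nm]])) next
    path <- file.path(outdir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.csv(report[[nm]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  jpath <- file.path(outdir, "summary.json")
  jsonlite::write_json(list(provenance = report$provenance,
                            pullbacks = report$pullbacks,
                            ink = report$ink),
                       jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, jpath))
}

#' Export one stored snapshot as a legacy-ASCII VTK structured grid
#'
#' Writes the lattice cell centres (Cartesian coordinates) with the
#' temperature and domain mask as point data, readable by ParaView/VTK.
#'
#' @param field A [simulate_mixing()] result.
#' @param path Output `.vtk` file.
#' @param time_index Snapshot index (default: last stored step).
#' @return Invisibly, `path`.
#' @export
write_vtk_field <- function(field, path, time_index = length(field$times)) {
  stopifnot(inherits(field, "temperature_field"),
            time_index >= 1, time_index <= length(field$times))
  lat <- field$lattice
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("coromix temperature field t=%.4fs hash=%s",
                       field$times[time_index],
                       .config_hash(unclass(field$config))),
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d %d", lat$nz, lat$nr, lat$nth)), con)
  npts <- lat$nz * lat$nr * lat$nth
  writeLines(sprintf("POINTS %d float", npts), con)
  # index order: z fastest, then r, then theta (matches the snapshot layout)
  coords <- expand.grid(z = lat$z, r = lat$r, th = lat$theta)
  write(t(cbind(coords$r * cos(coords$th), coords$r * sin(coords$th),
                coords$z)), con, ncolumns = 3)
  temp <- as.vector(field$snapshots[, , , time_index])
  temp[is.na(temp)] <- -1
  writeLines(c(sprintf("POINT_DATA %d", npts),
               "SCALARS temperature float 1", "LOOKUP_TABLE default"), con)
  write(temp, con, ncolumns = 9)
  writeLines(c("SCALARS domain_mask int 1", "LOOKUP_TABLE default"), con)
  write(as.vector(field$mask), con, ncolumns = 9)
  invisible(path)
}

#' Export per-station cross-section samples as CSV
#'
#' @param field A [simulate_mixing()] result.
#' @param stations_cm Stations, cm distal to the infusion site.
#' @param path Output CSV file.
#' @return Invisibly, `path`.
#' @export
write_station_csv <- function(field, stations_cm, path) {
  rows <- lapply(stations_cm, function(s) {
    smp <- sample_grid(field$geometry, s,
                       catheter = field$protocol$catheter)
    ta <- time_averaged_temperatures(field, smp)
    data.frame(station_cm = s, r_mm = smp$r_mm, theta_rad = smp$theta_rad,
               wire_mask = ta$mask, t_mean_c = ta$t_mk)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
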