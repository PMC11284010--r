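#' Flow/infusion protocol for one bench or simulated condition
#'
#' A `flow_protocol` bundles one combination of mean coronary flow, continuous
#' saline infusion rate, the two fluid temperatures and the catheter injection
#' topology. Coronary flow category (LOW/MED/HIGH) is derived from the mean
#' flow: 50, 150 and 250 mL/min map one-to-one to the three categories, the
#' range spanning resting to maximal hyperaemic coronary flow.
#'
#' Two temperature presets are in use: on the bench, room-temperature saline
#' (23 degC) is infused into 37 degC blood analog; in simulation mode the
#' infusate has warmed to 29 degC by the time it exits the catheter (transit
#' through the body). `protocol_mode()` presets select between them.
#'
#' @param coronary_flow_mean Mean coronary flow, mL/min. One of 50, 150, 250.
#' @param infusion_rate Continuous infusion rate, mL/min. One of 8, 10, 15,
#'   20, 25, 30, and the (category, rate) pair must be one of the nine
#'   clinically used combinations (see [clinically_relevant_combinations()]).
#' @param catheter `"side_hole"` (distributed injection through four 100 um
#'   side holes, pressure/temperature wire inside the catheter) or
#'   `"end_hole"` (single coaxial end hole, wire alongside).
#' @param blood_temperature Blood (analog) temperature, degC. Default 37.
#' @param infusate_exit_temperature Infusate temperature where it leaves the
#'   catheter, degC. Default 29 (simulation preset); the bench preset is 23.
#' @param cardiac_period Cardiac period, s. Default 1.
#' @param check If `TRUE` (default) enforce membership in the clinical grid;
#'   set `FALSE` to build exploratory off-grid protocols.
#' @return An object of class `flow_protocol` (a named list).
#' @seealso [clinically_relevant_combinations()], [cfd_combinations()],
#'   [perfect_mix_temperature()]
#' @export
flow_protocol <- function(coronary_flow_mean, infusion_rate,
                          catheter = c("side_hole", "end_hole"),
                          blood_temperature = 37,
                          infusate_exit_temperature = 29,
                          cardiac_period = 1,
                          check = TRUE) {
  catheter <- match.arg(catheter)
  stopifnot(is.numeric(coronary_flow_mean), length(coronary_flow_mean) == 1,
            is.numeric(infusion_rate), length(infusion_rate) == 1)
  if (coronary_flow_mean <= 0)
    stop("invalid protocol: coronary_flow_mean must be positive", call. = FALSE)
  if (infusion_rate < 0)
    stop("invalid protocol: infusion_rate must be non-negative", call. = FALSE)
  if (!(infusate_exit_temperature > 0 &&
        infusate_exit_temperature < blood_temperature))
    stop("invalid protocol: need 0 < infusate temperature < blood temperature",
         call. = FALSE)
  if (cardiac_period <= 0)
    stop("invalid protocol: cardiac_period must be positive", call. = FALSE)
  category <- .flow_category(coronary_flow_mean)
  if (check) {
    if (is.na(category))
      stop("invalid protocol: coronary_flow_mean must be 50, 150 or 250 mL/min",
           call. = FALSE)
    grid <- .clinical_grid()
    ok <- any(grid$coronary_flow_mean == coronary_flow_mean &
                grid$infusion_rate == infusion_rate)
    if (!ok)
      stop(sprintf(
        "invalid protocol: (%s, %g mL/min) is not a clinically used combination",
        category, infusion_rate), call. = FALSE)
  }
  structure(list(
    coronary_category = category,
    coronary_flow_mean = coronary_flow_mean,
    infusion_rate = infusion_rate,
    blood_temperature = blood_temperature,
    infusate_exit_temperature = infusate_exit_temperature,
    catheter = catheter,
    cardiac_period = cardiac_period
  ), class = "flow_protocol")
}

.flow_category <- function(q) {
  c(`50` = "LOW", `150` = "MED", `250` = "HIGH")[as.character(q)]
}

# the nine clinically used (category, infusion rate) cells; asterisked cells
# are the ones carried into simulation
.clinical_grid <- function() {
  data.frame(
    coronary_category = rep(c("LOW", "MED", "HIGH"), each = 3),
    coronary_flow_mean = rep(c(50, 150, 250), each = 3),
    infusion_rate = c(8, 10, 15, 15, 20, 25, 20, 25, 30),
    simulated = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}

#' @export
print.flow_protocol <- function(x, ...) {
  cat(sprintf(
    "<flow_protocol> %s (%g mL/min) + %g mL/min infusion, %s catheter\n",
    x$coronary_category, x$coronary_flow_mean, x$infusion_rate, x$catheter))
  cat(sprintf("  blood %g degC, infusate exit %g degC, period %g s\n",
              x$blood_temperature, x$infusate_exit_temperature,
              x$cardiac_period))
  invisible(x)
}

#' Infusate temperature preset for bench vs simulation mode
#'
#' The bench experiments infuse saline at room temperature (23 degC); in the
#' simulations the infusate is taken at 29 degC at the catheter exit because
#' it warms on its way through the catheter inside the body.
#'
#' @param mode `"cfd"` (29 degC exit temperature) or `"bench"` (23 degC).
#' @return Infusate exit temperature, degC.
#' @export
infusate_temperature <- function(mode = c("cfd", "bench")) {
  switch(match.arg(mode), cfd = 29, bench = 23)
}

#' The nine clinically used flow/infusion combinations
#'
#' Enumerates the clinically used combinations of coronary flow category and
#' infusion rate: LOW (50 mL/min) with 8/10/15, MED (150) with 15/20/25, and
#' HIGH (250) with 20/25/30 mL/min. Of the 18 possible (3 x 6) combinations
#' these nine are the ones used in practice: very high relative infusion
#' perturbs the physiology in small vessels, very low relative infusion gives
#' poor signal-to-noise at hyperaemic flow.
#'
#' @param catheter Catheter topologies to enumerate; default both, giving
#'   9 protocols per catheter (18 total).
#' @param mode Temperature preset, see [infusate_temperature()].
#' @param cardiac_period Cardiac period, s.
#' @return A list of [flow_protocol()] objects.
#' @export
clinically_relevant_combinations <- function(
    catheter = c("side_hole", "end_hole"),
    mode = c("cfd", "bench"),
    cardiac_period = 1) {
  catheter <- match.arg(catheter, several.ok = TRUE)
  ti <- infusate_temperature(mode)
  grid <- .clinical_grid()
  out <- list()
  for (cath in catheter)
    for (i in seq_len(nrow(grid)))
      out[[length(out) + 1L]] <- flow_protocol(
        grid$coronary_flow_mean[i], grid$infusion_rate[i], catheter = cath,
        infusate_exit_temperature = ti, cardiac_period = cardiac_period)
  out
}

#' The four combinations carried into transport simulation
#'
#' Of the nine clinical combinations, four were singled out for quantitative
#' simulation per catheter: (LOW, 8), (LOW, 15), (MED, 15) and (HIGH, 25)
#' mL/min.
#'
#' @inheritParams clinically_relevant_combinations
#' @return A list of [flow_protocol()] objects (4 per requested catheter).
#' @export
cfd_combinations <- function(catheter = c("side_hole", "end_hole"),
                             mode = c("cfd", "bench"),
                             cardiac_period = 1) {
  catheter <- match.arg(catheter, several.ok = TRUE)
  ti <- infusate_temperature(mode)
  grid <- .clinical_grid()
  grid <- grid[grid$simulated, , drop = FALSE]
  out <- list()
  for (cath in catheter)
    for (i in seq_len(nrow(grid)))
      out[[length(out) + 1L]] <- flow_protocol(
        grid$coronary_flow_mean[i], grid$infusion_rate[i], catheter = cath,
        infusate_exit_temperature = ti, cardiac_period = cardiac_period)
  out
}

#' Coerce a list of protocols to a data frame
#'
#' @param protocols List of [flow_protocol()] objects.
#' @return A data.frame, one row per protocol.
#' @export
protocols_as_data_frame <- function(protocols) {
  do.call(rbind, lapply(protocols, function(p)
    data.frame(coronary_category = p$coronary_category,
               coronary_flow_mean = p$coronary_flow_mean,
               infusion_rate = p$infusion_rate,
               blood_temperature = p$blood_temperature,
               infusate_exit_temperature = p$infusate_exit_temperature,
               catheter = p$catheter,
               cardiac_period = p$cardiac_period)))
}

#' Well-mixed dilution fraction
#'
#' The infusate volume fraction downstream of the injection site under
#' perfect mixing, `Qi / (Qb + Qi)`. This is also the dilution probability
#' P* at the perfect-mixing temperature.
#'
#' @param coronary_flow Mean coronary flow Qb, mL/min (> 0).
#' @param infusion_rate Infusion rate Qi, mL/min (>= 0).
#' @return Dimensionless fraction in `[0, 1)`.
#' @export
perfect_mix_fraction <- function(coronary_flow, infusion_rate) {
  if (any(coronary_flow <= 0))
    stop("invalid protocol: coronary_flow must be positive", call. = FALSE)
  if (any(infusion_rate < 0))
    stop("invalid protocol: infusion_rate must be non-negative", call. = FALSE)
  infusion_rate / (coronary_flow + infusion_rate)
}

#' Perfect-mixing (mixed-cup) temperature
#'
#' Flow-weighted mean of blood and infusate temperature:
#' `Tmix = Tb - P* (Tb - Ti)` with P* the well-mixed dilution fraction.
#' This is the temperature a perfectly homogeneous cross-section downstream
#' of the injection site attains by energy balance.
#'
#' @param protocol A [flow_protocol()].
#' @return Temperature, degC.
#' @export
perfect_mix_temperature <- function(protocol) {
  stopifnot(inherits(protocol, "flow_protocol"))
  p <- perfect_mix_fraction(protocol$coronary_flow_mean, protocol$infusion_rate)
  protocol$blood_temperature -
    p * (protocol$blood_temperature - protocol$infusate_exit_temperature)
}

#' Vessel and catheter geometry
#'
#' Geometry of the idealised catheterised coronary segment: a straight
#' 4 mm x 70 mm vessel, a 0.84 mm (outer diameter) infusion catheter whose
#' outlet(s) sit 10 mm into the vessel, and a 0.36 mm pressure/temperature
#' wire. For the side-hole topology the wire runs inside the catheter and
#' continues along the vessel axis distal to the tip; for the end-hole
#' topology the wire runs alongside the catheter, making the cross-section
#' non-axisymmetric.
#'
#' @param vessel_diameter mm, default 4.
#' @param vessel_length mm, default 70.
#' @param catheter_outer_diameter mm, default 0.84.
#' @param wire_diameter mm, default 0.36.
#' @param outlet_axial_position mm from the vessel inlet, default 10.
#' @param side_hole_diameter_um um, default 100.
#' @param side_hole_count Default 4 (at 90 degree spacing).
#' @param wire_placement `"inside"` or `"alongside"`; if `NULL` it is derived
#'   later from the catheter topology (inside for side-hole, alongside for
#'   end-hole).
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(vessel_diameter = 4, vessel_length = 70,
                            catheter_outer_diameter = 0.84,
                            wire_diameter = 0.36,
                            outlet_axial_position = 10,
                            side_hole_diameter_um = 100,
                            side_hole_count = 4,
                            wire_placement = NULL) {
  if (!(wire_diameter < catheter_outer_diameter &&
        catheter_outer_diameter < vessel_diameter))
    stop("invalid geometry: need wire < catheter < vessel diameter",
         call. = FALSE)
  if (!(outlet_axial_position > 0 && outlet_axial_position < vessel_length))
    stop("invalid geometry: outlet must lie strictly inside the vessel",
         call. = FALSE)
  if (!is.null(wire_placement))
    wire_placement <- match.arg(wire_placement, c("inside", "alongside"))
  structure(list(
    vessel_diameter = vessel_diameter,
    vessel_length = vessel_length,
    catheter_outer_diameter = catheter_outer_diameter,
    wire_diameter = wire_diameter,
    outlet_axial_position = outlet_axial_position,
    side_hole_diameter_um = side_hole_diameter_um,
    side_hole_count = side_hole_count,
    wire_placement = wire_placement
  ), class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(
    "<vessel_geometry> vessel %g x %g mm, catheter %g mm, wire %g mm\n",
    x$vessel_diameter, x$vessel_length, x$catheter_outer_diameter,
    x$wire_diameter))
  cat(sprintf("  outlet at %g mm, wire %s\n", x$outlet_axial_position,
              if (is.null(x$wire_placement)) "(per catheter)"
              else x$wire_placement))
  invisible(x)
}

# derive wire placement for a catheter topology unless fixed in the geometry
.wire_placement <- function(geometry, catheter) {
  if (!is.null(geometry$wire_placement)) return(geometry$wire_placement)
  if (catheter == "side_hole") "inside" else "alongside"
}
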