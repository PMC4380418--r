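#' Thermophysical material definition
#'
#' A material is the basic carrier of thermophysical properties used by the
#' lumped-capacitance thermal network: thermal conductivity (for conductive
#' resistances), and density times specific heat (for capacitances).
#'
#' @param name Character label, e.g. `"water"` or `"FEP"`.
#' @param k Thermal conductivity, W/(m K). May be `NA` for materials only
#'   ever used for their heat capacity (e.g. a sample liquid).
#' @param rho Density, kg/m^3.
#' @param cp Specific heat capacity at constant pressure, J/(kg K).
#' @return An object of class `rz_material`.
#' @examples
#' material("water", k = 0.6, rho = 997, cp = 4181)
#' @export
material <- function(name, k = NA_real_, rho, cp) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.na(k) && k <= 0) stop("thermal conductivity must be > 0")
  if (!is.numeric(rho) || rho <= 0) stop("density must be > 0")
  if (!is.numeric(cp) || cp <= 0) stop("specific heat must be > 0")
  structure(list(name = name, k = as.numeric(k), rho = as.numeric(rho),
                 cp = as.numeric(cp)),
            class = "rz_material")
}

#' Default material property table
#'
#' Handbook values for the materials of the reference hardware: water sample,
#' FEP and polycarbonate capillary tubing, aluminum heater blocks, and
#' K-type thermocouple wire (averaged chromel/alumel). Any entry can be
#' overridden through the cycler configuration file.
#'
#' @return Named list of [material()] objects.
#' @export
default_materials <- function() {
  list(
    water         = material("water",         k = 0.606, rho = 997,  cp = 4181),
    FEP           = material("FEP",           k = 0.195, rho = 2150, cp = 1172),
    polycarbonate = material("polycarbonate", k = 0.20,  rho = 1200, cp = 1200),
    aluminum      = material("aluminum",      k = 205,   rho = 2700, cp = 897),
    thermocouple  = material("thermocouple",  k = 25,    rho = 8700, cp = 450)
  )
}

#' Capillary tube geometry
#'
#' @param inner_diameter Bore diameter, m.
#' @param outer_diameter Outer diameter, m; must exceed `inner_diameter`.
#' @param wall_material An [material()] for the tube wall (its `k` is used
#'   for the wall resistance, `rho`/`cp` for the wall capacitance).
#' @return An object of class `rz_capillary`.
#' @export
capillary_spec <- function(inner_diameter, outer_diameter, wall_material) {
  stopifnot(inherits(wall_material, "rz_material"))
  if (!(inner_diameter > 0 && outer_diameter > inner_diameter))
    stop("require 0 < inner_diameter < outer_diameter")
  if (is.na(wall_material$k))
    stop("wall material needs a thermal conductivity")
  structure(list(inner_diameter = inner_diameter,
                 outer_diameter = outer_diameter,
                 wall_material = wall_material),
            class = "rz_capillary")
}

#' Contents of the capillary bore
#'
#' The bore is filled with a sample liquid; optional cylindrical inclusions
#' (e.g. the two legs of a fine-gauge thermocouple threaded along the bore)
#' displace sample and substitute their own volumetric heat capacity.
#'
#' @param sample_material [material()] of the sample liquid (default water).
#' @param inclusions List of `list(diameter =, material =)` entries, each a
#'   cylinder running the engaged length of the bore.
#' @return An object of class `rz_bore_contents`.
#' @export
bore_contents <- function(sample_material = default_materials()$water,
                          inclusions = list()) {
  stopifnot(inherits(sample_material, "rz_material"))
  for (inc in inclusions) {
    stopifnot(is.list(inc), inherits(inc$material, "rz_material"))
    if (!is.numeric(inc$diameter) || inc$diameter <= 0)
      stop("inclusion diameter must be > 0")
  }
  structure(list(sample_material = sample_material, inclusions = inclusions),
            class = "rz_bore_contents")
}

#' Capillary-to-block engagement geometry
#'
#' @param contact_length Length of tubing held against the heater block, m.
#' @return An object of class `rz_engagement`.
#' @export
engagement <- function(contact_length) {
  if (!is.numeric(contact_length) || contact_length <= 0)
    stop("contact_length must be > 0")
  structure(list(contact_length = contact_length), class = "rz_engagement")
}

#' Heater block specification
#'
#' @param mass Block mass, kg.
#' @param material Block [material()] (its `cp` sets the capacitance).
#' @param setpoint Controlled block temperature, degrees C, or `NA` for an
#'   unheated block.
#' @param arc_span Angular span of the block's curved contact surface, degrees.
#' @return An object of class `rz_block`.
#' @export
heater_block <- function(mass, material, setpoint = NA_real_, arc_span = 73.6) {
  stopifnot(inherits(material, "rz_material"))
  if (!is.numeric(mass) || mass < 0) stop("mass must be >= 0")
  if (arc_span <= 0 || arc_span > 360) stop("arc_span must be in (0, 360]")
  structure(list(mass = mass, material = material,
                 setpoint = as.numeric(setpoint), arc_span = arc_span),
            class = "rz_block")
}

#' A lumped thermal capacitance
#'
#' @param capacitance Heat capacity, J/K.
#' @param label Character label.
#' @return An object of class `rz_lump`.
#' @export
thermal_lump <- function(capacitance, label = "") {
  if (!is.numeric(capacitance) || capacitance < 0)
    stop("capacitance must be >= 0")
  structure(list(capacitance = capacitance, label = label), class = "rz_lump")
}

#' First-order bounded-exponential response model
#'
#' The sample/capillary lump responds to a block step change as
#' `T(t) = T_B + (T_start - T_B) * exp(-(t - t0)/tau)`: `tau` is the RC time
#' constant (the 70.7% rise/fall time), `t0` an optional time offset.
#'
#' @param tau Time constant, s; must be > 0.
#' @param t0 Time offset, s.
#' @return An object of class `rz_response`.
#' @export
response_model <- function(tau, t0 = 0) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  structure(list(tau = tau, t0 = t0), class = "rz_response")
}

#' Half-cylinder radial conductive resistance of the capillary wall
#'
#' Conduction from the heater block groove through the tube wall into the
#' bore, treating the engaged wall as a half cylinder:
#' `R = ln(d_o/d_i) / (pi * L * k_c)`.
#'
#' @param cap A [capillary_spec()].
#' @param eng An [engagement()].
#' @param contact_resistance Optional additive series contact resistance,
#'   expressed per unit length as K m/W (so that the RC product stays
#'   independent of `L`); default 0, i.e. perfect groove contact.
#' @return Thermal resistance, K/W.
#' @export
wall_resistance <- function(cap, eng, contact_resistance = 0) {
  d_i <- cap$inner_diameter; d_o <- cap$outer_diameter
  L <- eng$contact_length
  if (!is.numeric(L) || L <= 0) stop("contact length must be > 0")
  if (d_i <= 0 || d_o <= 0) stop("diameters must be > 0")
  if (contact_resistance < 0) stop("contact_resistance must be >= 0")
  log(d_o / d_i) / (pi * L * cap$wall_material$k) + contact_resistance / L
}

# cross-sectional areas of bore, wall and inclusions (m^2); shared by the
# capacitance and validation paths
.bore_areas <- function(cap, contents) {
  a_bore <- pi / 4 * cap$inner_diameter^2
  a_wall <- pi / 4 * (cap$outer_diameter^2 - cap$inner_diameter^2)
  a_inc <- vapply(contents$inclusions,
                  function(i) pi / 4 * i$diameter^2, numeric(1))
  if (sum(a_inc) >= a_bore)
    stop("inclusions overflow the bore cross-section")
  list(bore = a_bore, wall = a_wall, inclusions = a_inc)
}

#' Lumped capacitance of the engaged sample + capillary
#'
#' `C = L * (pi/4) * [rho_s c_s d_i^2 + rho_c c_c (d_o^2 - d_i^2)]`, with any
#' bore inclusions substituting their own `rho c_p` for the sample liquid
#' they displace.
#'
#' @inheritParams wall_resistance
#' @param contents A [bore_contents()].
#' @return A [thermal_lump()] labelled `"sample+capillary"`.
#' @export
lump_capacitance <- function(cap, contents = bore_contents(), eng) {
  a <- .bore_areas(cap, contents)
  s <- contents$sample_material
  w <- cap$wall_material
  per_len <- s$rho * s$cp * (a$bore - sum(a$inclusions)) +
    w$rho * w$cp * a$wall
  if (length(a$inclusions)) {
    rc <- vapply(contents$inclusions,
                 function(i) i$material$rho * i$material$cp, numeric(1))
    per_len <- per_len + sum(rc * a$inclusions)
  }
  thermal_lump(eng$contact_length * per_len, "sample+capillary")
}

#' Heater block thermal capacitance
#'
#' @param block A [heater_block()].
#' @return A [thermal_lump()] with `C = mass * c_p`.
#' @export
block_capacitance <- function(block) {
  thermal_lump(block$mass * block$material$cp, "block")
}

#' A priori RC time constant of the sample/capillary lump
#'
#' The product of the wall resistance and the sample+capillary capacitance.
#' The engaged length cancels (R scales as 1/L, C as L), so the time constant
#' is a property of the tube cross-section and its contents alone.
#'
#' @inheritParams lump_capacitance
#' @param contact_resistance Per-length contact resistance, K m/W (see
#'   [wall_resistance()]).
#' @return A [response_model()] with the predicted `tau` and `t0 = 0`.
#' @export
predict_time_constant <- function(cap, contents = bore_contents(),
                                  contact_resistance = 0) {
  eng <- engagement(1)  # cancels in the RC product
  R <- wall_resistance(cap, eng, contact_resistance)
  C <- lump_capacitance(cap, contents, eng)$capacitance
  response_model(R * C)
}

#' Two-lump equilibrium temperature after block engagement
#'
#' When a finite block of capacitance `C_B` at `T_B` engages the
#' sample/capillary lump `C_SC` at `T_SC` and active heating is ignored, the
#' pair relaxes to `T_eq = (T_B + T_SC * r) / (1 + r)` with `r = C_SC / C_B`
#' -- a convex combination of the two temperatures that tends to `T_B` as the
#' block dwarfs the sample.
#'
#' @param T_B Block temperature, degrees C.
#' @param T_SC Initial sample/capillary temperature, degrees C.
#' @param sample A [thermal_lump()] for the sample + capillary.
#' @param block A [thermal_lump()] for the block; capacitance must be > 0.
#' @return Equilibrium temperature, degrees C.
#' @export
equilibrium_temperature <- function(T_B, T_SC, sample, block) {
  if (block$capacitance <= 0) stop("block capacitance must be > 0")
  r <- sample$capacitance / block$capacitance
  (T_B + T_SC * r) / (1 + r)
}

#' @export
print.rz_response <- function(x, ...) {
  cat(sprintf("first-order response: tau = %.4g s, t0 = %.4g s\n", x$tau, x$t0))
  invisible(x)
}

#' @export
print.rz_lump <- function(x, ...) {
  cat(sprintf("thermal lump%s: C = %.4g J/K\n",
              if (nzchar(x$label)) paste0(" (", x$label, ")") else "",
              x$capacitance))
  invisible(x)
}
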