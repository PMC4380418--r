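#' Synthetic thermocouple trace specification
#'
#' Emulates an in-capillary thermocouple logging a cycling run: a known
#' first-order response to a drive schedule, sampled at a nominal ~10 Hz,
#' with i.i.d. Gaussian sensor noise and optional slow sensor drift.
#'
#' @param tau True time constant, s.
#' @param schedule A [drive_schedule()].
#' @param noise_sd Gaussian noise standard deviation, degrees C (>= 0).
#' @param rate Sampling rate, Hz (> 0).
#' @param seed Integer seed; all randomness in the generator flows through it.
#' @param drift_C_per_s Optional linear sensor drift slope.
#' @param T_initial Sample temperature at schedule start; defaults to the
#'   first non-gap drive temperature.
#' @return An object of class `rz_trace_spec`.
#' @export
synthetic_trace_spec <- function(tau, schedule, noise_sd = 0.3, rate = 10,
                                 seed = 1L, drift_C_per_s = 0,
                                 T_initial = NULL) {
  stopifnot(inherits(schedule, "rz_schedule"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (rate <= 0) stop("rate must be > 0")
  structure(list(tau = tau, schedule = schedule, noise_sd = noise_sd,
                 rate = rate, seed = as.integer(seed),
                 drift_C_per_s = drift_C_per_s, T_initial = T_initial),
            class = "rz_trace_spec")
}

# run code under a local RNG state seeded from `seed`, restoring the
# caller's stream afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic temperature trace
#'
#' Closed-form simulation of the spec's schedule and time constant, plus
#' seeded Gaussian noise and optional drift. Bit-identical for a fixed seed.
#'
#' @param spec A [synthetic_trace_spec()].
#' @return A [temperature_trace()] with attribute `truth` (the spec).
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "rz_trace_spec"))
  T0 <- spec$T_initial
  if (is.null(T0)) T0 <- spec$schedule$temp[which(!is.na(spec$schedule$temp))[1]]
  # log through one full final dwell so the last transition has a complete
  # settled plateau on both sides
  bt <- spec$schedule$time
  t_end <- if (length(bt) >= 2)
    bt[length(bt)] + stats::median(diff(bt)) else NULL
  clean <- simulate_trace(spec$schedule, response_model(spec$tau), T0,
                          dt = 1 / spec$rate, t_end = t_end)
  noise <- if (spec$noise_sd > 0)
    .with_seed(spec$seed, stats::rnorm(nrow(clean), 0, spec$noise_sd))
  else 0
  drift <- spec$drift_C_per_s * (clean$time_s - clean$time_s[1])
  tr <- temperature_trace(clean$time_s, clean$temp_C + noise + drift,
                          sampling_rate = spec$rate)
  attr(tr, "truth") <- spec
  tr
}

#' Write a temperature trace as CSV
#'
#' Comma-separated, header `time_s,temp_C`, `'#'` comment lines, UTF-8,
#' `.` decimal separator.
#'
#' @param trace A [temperature_trace()] (or data frame with those columns).
#' @param path Output file path.
#' @param comment Optional comment line(s) written above the header.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  writeLines("time_s,temp_C", con)
  utils::write.table(data.frame(trace$time_s, trace$temp_C), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a temperature trace from CSV
#'
#' @param path CSV file with columns `time_s` and `temp_C`; `'#'` lines are
#'   comments.
#' @return A [temperature_trace()].
#' @export
read_trace <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", strip.white = TRUE),
    error = function(e) stop("cannot read trace '", path, "': ",
                             conditionMessage(e)))
  for (col in c("time_s", "temp_C"))
    if (!col %in% names(df))
      stop("trace file '", path, "' is missing required column '", col, "'")
  bad <- which(!is.finite(df$time_s) | !is.finite(df$temp_C))
  if (length(bad))
    stop("trace file '", path, "' has non-numeric values at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  temperature_trace(df$time_s, df$temp_C)
}

#' Read a cycler configuration file
#'
#' A versioned YAML description of the machine: a materials table, the
#' capillary and engagement geometry, the heater blocks, the wheel layout,
#' and the stepper motion profile. Cross-references (block and capillary
#' materials) are checked against the materials table; entries absent from
#' the file fall back to [default_materials()].
#'
#' @param path YAML file; `NULL` loads the shipped default configuration,
#'   which reproduces the reference hardware (4 segments, 73.6 degree block
#'   arc, 55 g aluminum blocks, FEP 406/794 um capillary, ~4 uL engaged
#'   sample).
#' @return An object of class `rz_config`: list with `materials`,
#'   `capillary`, `contents`, `engagement`, `blocks`, `layout`, `motion`.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cycler_default.yaml", package = "rzcycler")
  y <- yaml::read_yaml(path)
  if (is.null(y$schema_version)) stop("config '", path, "' has no schema_version")
  mats <- default_materials()
  for (nm in names(y$materials)) {
    m <- y$materials[[nm]]
    mats[[nm]] <- material(nm, k = if (is.null(m$k)) NA_real_ else m$k,
                           rho = m$rho, cp = m$cp)
  }
  mat_of <- function(nm, where) {
    if (is.null(mats[[nm]]))
      stop("config '", path, "': ", where, " references unknown material '",
           nm, "'")
    mats[[nm]]
  }
  cp <- y$capillary
  capillary <- capillary_spec(cp$inner_diameter_m, cp$outer_diameter_m,
                              mat_of(cp$material, "capillary"))
  contents <- bore_contents(
    mat_of(if (is.null(cp$sample_material)) "water" else cp$sample_material,
           "sample"),
    inclusions = lapply(cp$inclusions, function(i)
      list(diameter = i$diameter_m, material = mat_of(i$material, "inclusion"))))
  eng <- engagement(y$engagement$contact_length_m)
  blocks <- lapply(y$blocks, function(b)
    heater_block(b$mass_kg, mat_of(b$material, "block"),
                 setpoint = if (is.null(b$setpoint_C)) NA_real_ else b$setpoint_C,
                 arc_span = y$wheel$arc_span_deg))
  motion <- motion_profile(y$motion$acceleration_usteps_s2,
                           y$motion$max_velocity_usteps_s)
  sps <- y$wheel$steps_per_segment
  if (is.null(sps))
    sps <- calibrate_steps_per_segment(y$wheel$observed_single_transition_s,
                                       motion)
  layout <- wheel_layout(y$wheel$num_segments, sps,
                         arc_span = y$wheel$arc_span_deg,
                         harness_twist_limit = y$wheel$harness_twist_limit_deg)
  structure(list(materials = mats, capillary = capillary, contents = contents,
                 engagement = eng, blocks = blocks, layout = layout,
                 motion = motion, path = path),
            class = "rz_config")
}

#' Read a PCR protocol file
#'
#' @param path YAML protocol definition; see the shipped files under
#'   `extdata/protocols/` for the schema.
#' @return A [pcr_protocol()].
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$schema_version)) stop("protocol '", path, "' has no schema_version")
  as_step <- function(s) data.frame(temp = s$temp_C, dwell = s$dwell_s)
  stages <- lapply(y$stages, function(sg)
    list(cycles = sg$cycles, steps = do.call(rbind, lapply(sg$steps, as_step))))
  opt <- function(x) if (is.null(x)) NULL else
    list(temp = x$temp_C, duration = x$duration_s)
  changes <- lapply(y$setpoint_changes, function(sc)
    list(from_temp = sc$from_temp_C, to_temp = sc$to_temp_C,
         after_stage = as.integer(sc$after_stage),
         stabilization_s = sc$stabilization_s))
  pcr_protocol(stages, hot_start = opt(y$hot_start),
               final_step = opt(y$final_step),
               setpoint_changes = changes,
               id = if (is.null(y$id)) "" else y$id)
}

#' Load a shipped PCR protocol by name
#'
#' Shipped protocols: `"phusion_gapdh"` (26-cycle single-plex),
#' `"powerplex16"` (32-cycle two-stage STR with an in-run 96 to 90 degC
#' block setpoint change), `"cdna_second_strand"` (second-strand cDNA
#' synthesis cycling).
#'
#' @param name Protocol name.
#' @return A [pcr_protocol()].
#' @export
load_protocol <- function(name = c("phusion_gapdh", "powerplex16",
                                   "cdna_second_strand")) {
  name <- match.arg(name)
  read_protocol(system.file("extdata", "protocols", paste0(name, ".yaml"),
                            package = "rzcycler"))
}

#' Read a cleaning protocol file
#'
#' @param path YAML cleaning-protocol definition (see
#'   `extdata/cleaning/protocol_A.yaml` for the schema).
#' @return A [cleaning_protocol()].
#' @export
read_cleaning_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$schema_version))
    stop("cleaning protocol '", path, "' has no schema_version")
  steps <- do.call(rbind, lapply(y$steps, function(s)
    fluid_step(s$action,
               reagent = if (is.null(s$reagent)) "none" else s$reagent,
               volume_ul = if (is.null(s$volume_ul)) 0 else s$volume_ul,
               duration_s = if (is.null(s$duration_s)) NA_real_ else s$duration_s,
               repetitions = if (is.null(s$repetitions)) 1 else s$repetitions,
               flow_class = if (is.null(s$flow_class)) "normal" else s$flow_class,
               phase = if (is.null(s$phase)) "frame" else s$phase,
               note = if (is.null(s$note)) "" else s$note)))
  cleaning_protocol(y$id, steps, y$flags)
}

#' Read a cleaning timing configuration
#'
#' @param path YAML file with `flow_ul_per_s` (normal/fast),
#'   `per_step_overhead_s`, `valve_actuation_s`; `NULL` loads the shipped
#'   calibration.
#' @return Timing list as used by [duration_estimate()].
#' @export
read_timing <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "timing_default.yaml", package = "rzcycler")
  y <- yaml::read_yaml(path)
  list(flow_ul_per_s = unlist(y$flow_ul_per_s),
       per_step_overhead_s = y$per_step_overhead_s,
       valve_actuation_s = y$valve_actuation_s)
}
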