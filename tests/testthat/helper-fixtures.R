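# shared fixtures: reference hardware geometry and small builders

mats <- default_materials()

fep_capillary <- function() capillary_spec(406e-6, 794e-6, mats$FEP)

pc_capillary <- function() capillary_spec(562e-6, 750e-6, mats$polycarbonate)

# two 50-um thermocouple wires threaded along the bore
tc_contents <- function() {
  wire <- list(diameter = 50e-6, material = mats$thermocouple)
  bore_contents(mats$water, inclusions = list(wire, wire))
}

ref_motion <- function() motion_profile(6103.52, 4000)

ref_layout <- function() {
  wheel_layout(4, calibrate_steps_per_segment(1.32, ref_motion()))
}

# noiseless single heating step 60 -> 96 degC with a pre-step plateau,
# sampled at `rate`; exact first-order response with time offset t0
step_segment <- function(tau, t0 = 0, rate = 10, t_pre = 5, t_post = 20,
                         T_start = 60, T_end = 96) {
  tt <- seq(-t_pre, t_post, by = 1 / rate)
  TT <- ifelse(tt < t0, T_start,
               T_end + (T_start - T_end) * exp(-(tt - t0) / tau))
  list(time_s = tt, temp_C = TT,
       direction = if (T_end > T_start) "heating" else "cooling",
       plateau_low = min(T_start, T_end), plateau_high = max(T_start, T_end))
}

# reference characterisation run: square-wave cycling between 60 and 96 degC
characterisation_spec <- function(tau = 0.57, noise_sd = 0.3, seed = 1,
                                  n_cycles = 5, dwell = 60, rate = 10) {
  synthetic_trace_spec(tau, square_wave_schedule(60, 96, dwell, n_cycles),
                       noise_sd = noise_sd, rate = rate, seed = seed,
                       T_initial = 60)
}
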