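#' Piecewise-constant drive-temperature schedule
#'
#' The forcing seen by the sample: at each breakpoint the drive switches to a
#' new block temperature, or to a gap-hold interval (`NA`) during which the
#' sample is over insulation and keeps its current temperature.
#'
#' @param times Strictly increasing breakpoint times, s.
#' @param temps Drive temperature from each breakpoint onward, degrees C;
#'   `NA` marks a gap-hold interval.
#' @return An object of class `rz_schedule` (a data frame `time`, `temp`).
#' @export
drive_schedule <- function(times, temps) {
  stopifnot(length(times) == length(temps))
  if (length(times) == 0) stop("schedule must have at least one breakpoint")
  if (any(diff(times) <= 0)) stop("breakpoint times must be strictly increasing")
  if (any(!is.finite(times))) stop("breakpoint times must be finite")
  structure(data.frame(time = as.numeric(times), temp = as.numeric(temps)),
            class = c("rz_schedule", "data.frame"))
}

#' Square-wave cycling schedule
#'
#' Convenience constructor for the alternating two-temperature drive used in
#' thermal characterisation: `n_cycles` alternations between `T_low` and
#' `T_high` with a fixed dwell at each.
#'
#' @param T_low,T_high The two block temperatures, degrees C.
#' @param dwell Dwell at each temperature, s.
#' @param n_cycles Number of full low/high cycles.
#' @param start_high Start at `T_high` (default) or `T_low`.
#' @return A [drive_schedule()].
#' @export
square_wave_schedule <- function(T_low, T_high, dwell, n_cycles,
                                 start_high = TRUE) {
  lv <- if (start_high) c(T_high, T_low) else c(T_low, T_high)
  temps <- rep(lv, n_cycles)
  drive_schedule(seq_along(temps) * dwell - dwell, temps)
}

#' Closed-form simulation of the sample temperature history
#'
#' Within each constant-drive interval the sample relaxes toward the drive
#' temperature as `T(t) = T_B + (T_start - T_B) * exp(-(t - t_i)/tau)`;
#' the temperature is continuous across breakpoints, and gap-hold intervals
#' (`NA` drive) keep the sample temperature constant. Because each interval
#' is evaluated in closed form, the sampling interval `dt` affects only
#' where the trace is sampled, not its accuracy.
#'
#' @param schedule A [drive_schedule()].
#' @param model A [response_model()] (its `tau`; `t0` is a fitting artefact
#'   and ignored here). For asymmetric response pass `tau_cool` to use a
#'   different time constant on cooling intervals.
#' @param T_initial Sample temperature at the first breakpoint, degrees C.
#' @param dt Sampling interval, s (default 0.1 s, i.e. 10 Hz logging).
#' @param t_end End of the simulation, s; default one extra dwell-free 5*tau
#'   tail after the last breakpoint.
#' @param tau_cool Optional cooling time constant, s; default `model$tau`
#'   (symmetric response).
#' @return A `rz_trace` data frame (`time_s`, `temp_C`) with attributes
#'   `tau` and `schedule`.
#' @export
simulate_trace <- function(schedule, model, T_initial, dt = 0.1,
                           t_end = NULL, tau_cool = NULL) {
  stopifnot(inherits(schedule, "rz_schedule"), inherits(model, "rz_response"))
  if (dt <= 0) stop("dt must be > 0")
  tau_h <- model$tau
  tau_c <- if (is.null(tau_cool)) tau_h else tau_cool
  bt <- schedule$time; bT <- schedule$temp
  if (is.null(t_end)) t_end <- bt[length(bt)] + 5 * max(tau_h, tau_c)
  t_out <- seq(bt[1], t_end, by = dt)
  # temperature at the start of each interval (continuity across breakpoints)
  k <- length(bt)
  T_at <- numeric(k)
  T_at[1] <- T_initial
  iv_end <- c(bt[-1], t_end)
  for (i in seq_len(k)) {
    if (i < k) {
      span <- iv_end[i] - bt[i]
      if (is.na(bT[i])) {
        T_at[i + 1] <- T_at[i]
      } else {
        tau_i <- if (bT[i] >= T_at[i]) tau_h else tau_c
        T_at[i + 1] <- bT[i] + (T_at[i] - bT[i]) * exp(-span / tau_i)
      }
    }
  }
  idx <- findInterval(t_out, bt)
  drv <- bT[idx]
  t0i <- bt[idx]
  Ts <- T_at[idx]
  tau_v <- ifelse(is.na(drv), NA_real_, ifelse(drv >= Ts, tau_h, tau_c))
  temp <- ifelse(is.na(drv), Ts, drv + (Ts - drv) * exp(-(t_out - t0i) / tau_v))
  structure(data.frame(time_s = t_out, temp_C = temp),
            class = c("rz_trace", "data.frame"),
            tau = c(heat = tau_h, cool = tau_c), schedule = schedule)
}

#' Time to approach within a band of the final temperature
#'
#' For a first-order response starting `dT_initial` away from the asymptote,
#' the time to come within `dT_target` is `tau * log(dT_initial/dT_target)`.
#' Symmetric for heating and cooling.
#'
#' @param model A [response_model()].
#' @param dT_initial Initial temperature offset magnitude, K.
#' @param dT_target Target band, K; `0 < dT_target <= dT_initial`.
#' @return Time, s.
#' @export
time_to_within <- function(model, dT_initial, dT_target) {
  stopifnot(inherits(model, "rz_response"))
  if (dT_target <= 0) stop("dT_target must be > 0")
  if (dT_target > dT_initial)
    stop("dT_target must not exceed dT_initial")
  model$tau * log(dT_initial / dT_target)
}

#' Combined rotation + settling transition metrics
#'
#' The effective ramp of a spatial cycler is the commanded temperature change
#' divided by the total transition time: wheel rotation plus thermal
#' settling.
#'
#' @param rotation_time Wheel rotation time, s.
#' @param settle_time Thermal settling time, s.
#' @param dT Temperature change achieved, K.
#' @return List with `total_time` (s) and `effective_rate` (K/s).
#' @export
ramp_metrics <- function(rotation_time, settle_time, dT) {
  if (rotation_time < 0 || settle_time < 0) stop("times must be >= 0")
  total <- rotation_time + settle_time
  if (total == 0) stop("total transition time is zero")
  list(total_time = total, effective_rate = dT / total)
}

#' @export
print.rz_schedule <- function(x, ...) {
  cat(sprintf("drive schedule: %d breakpoints over %.4g s\n",
              nrow(x), x$time[nrow(x)] - x$time[1]))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
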