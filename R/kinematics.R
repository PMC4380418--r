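#' Stepper-motor motion profile
#'
#' Trapezoidal velocity profile of the wheel drive: constant acceleration to
#' a cruise velocity, cruise, then symmetric deceleration. Short moves that
#' never reach cruise degenerate to a triangular profile. Units are motor
#' microsteps; the wheel geometry converts them to degrees.
#'
#' @param acceleration Acceleration, microsteps/s^2.
#' @param max_velocity Cruise velocity, microsteps/s.
#' @return An object of class `rz_motion`.
#' @export
motion_profile <- function(acceleration = 6103.52, max_velocity = 4000) {
  if (acceleration <= 0 || max_velocity <= 0)
    stop("acceleration and max_velocity must be > 0")
  structure(list(acceleration = acceleration, max_velocity = max_velocity),
            class = "rz_motion")
}

#' Wheel segment layout
#'
#' @param num_segments Number of equal wheel segments (default 4).
#' @param steps_per_segment Microsteps per one-segment rotation; normally
#'   obtained with [calibrate_steps_per_segment()] from one observed
#'   single-segment transition time.
#' @param arc_span Angular span of each block's contact surface, degrees;
#'   must not exceed the segment pitch `360/num_segments`.
#' @param harness_twist_limit Maximum magnitude of cumulative rotation
#'   permitted by the fixed wire harness, degrees (default 270).
#' @param gear_ratio Gearbox reduction, metadata only.
#' @return An object of class `rz_layout`.
#' @export
wheel_layout <- function(num_segments = 4, steps_per_segment,
                         arc_span = 73.6, harness_twist_limit = 270,
                         gear_ratio = 26.85) {
  if (num_segments < 2) stop("num_segments must be >= 2")
  if (steps_per_segment <= 0) stop("steps_per_segment must be > 0")
  pitch <- 360 / num_segments
  if (arc_span <= 0 || arc_span > pitch)
    stop("arc_span must be in (0, 360/num_segments]")
  if (harness_twist_limit <= 0) stop("harness_twist_limit must be > 0")
  structure(list(num_segments = num_segments,
                 steps_per_segment = steps_per_segment,
                 arc_span = arc_span,
                 harness_twist_limit = harness_twist_limit,
                 gear_ratio = gear_ratio,
                 segment_pitch = pitch),
            class = "rz_layout")
}

#' Wheel transition time for an n-segment rotation
#'
#' Closed-form trapezoidal travel time for distance `d = n * steps_per_segment`:
#' `t = d/v + v/a` when the move reaches cruise (`d >= v^2/a`), else the
#' triangular `t = 2*sqrt(d/a)`.
#'
#' @param n_segments Number of segments rotated (>= 0; vectorised).
#' @param motion A [motion_profile()].
#' @param layout A [wheel_layout()].
#' @return Transition time(s), s.
#' @export
transition_time <- function(n_segments, motion, layout) {
  if (any(n_segments < 0)) stop("n_segments must be >= 0")
  d <- n_segments * layout$steps_per_segment
  v <- motion$max_velocity; a <- motion$acceleration
  ifelse(d == 0, 0,
         ifelse(d >= v^2 / a, d / v + v / a, 2 * sqrt(d / a)))
}

#' Calibrate microsteps per segment from an observed transition
#'
#' Inverts the trapezoidal time formula, `d = v * (t - v/a)`, so that the
#' motion model reproduces one measured (or published) single-segment
#' transition time. The motor's microstep resolution and gearbox ratio never
#' need to be known.
#'
#' @param observed_single_transition Observed one-segment transition time, s.
#' @param motion A [motion_profile()].
#' @return Microsteps per segment.
#' @export
calibrate_steps_per_segment <- function(observed_single_transition, motion) {
  v <- motion$max_velocity; a <- motion$acceleration
  t <- observed_single_transition
  if (t < v / a)
    stop(sprintf("observed time %.4g s is below the minimum %.4g s (= v/a); %s",
                 t, v / a, "no trapezoidal move is that fast"))
  if (t < 2 * v / a)
    warning("observed time falls in the triangular regime; ",
            "trapezoidal inversion extrapolates")
  v * (t - v / a)
}

#' Plan one wheel rotation under the harness twist constraint
#'
#' Chooses the rotation direction between two wheel positions that minimises
#' the segment count; ties are broken toward the direction that reduces the
#' magnitude of the cumulative harness twist. If the short way would exceed
#' the twist limit, the planner takes the long way around; if both directions
#' would, it errors, naming the twist state.
#'
#' Direction +1 increases the wheel angle (counterclockwise), -1 decreases it.
#'
#' @param from_pos,to_pos Segment indices, 0-based, in `0:(num_segments-1)`.
#' @param layout A [wheel_layout()].
#' @param current_twist Cumulative wheel rotation so far, degrees.
#' @return A list with `from_pos`, `to_pos`, `direction`, `n_segments`,
#'   `degrees` (signed), and `twist_after`.
#' @export
plan_rotation <- function(from_pos, to_pos, layout, current_twist = 0) {
  n <- layout$num_segments
  stopifnot(from_pos %in% 0:(n - 1), to_pos %in% 0:(n - 1))
  pitch <- layout$segment_pitch
  k_ccw <- (to_pos - from_pos) %% n        # segments going +
  k_cw <- (from_pos - to_pos) %% n         # segments going -
  cand <- data.frame(direction = c(1, -1),
                     n_segments = c(k_ccw, k_cw))
  cand <- cand[cand$n_segments > 0 | (k_ccw == 0 & k_cw == 0), , drop = FALSE]
  if (k_ccw == 0) {  # no move needed
    return(list(from_pos = from_pos, to_pos = to_pos, direction = 0L,
                n_segments = 0L, degrees = 0,
                twist_after = current_twist))
  }
  cand$twist_after <- current_twist + cand$direction * cand$n_segments * pitch
  legal <- abs(cand$twist_after) <= layout$harness_twist_limit + 1e-9
  if (!any(legal))
    stop(sprintf(paste0("no legal rotation from segment %d to %d: cumulative ",
                        "twist is %g deg and both directions exceed the ",
                        "%g deg harness limit"),
                 from_pos, to_pos, current_twist, layout$harness_twist_limit))
  cand <- cand[legal, , drop = FALSE]
  cand <- cand[order(cand$n_segments, abs(cand$twist_after)), , drop = FALSE]
  sel <- cand[1, ]
  list(from_pos = from_pos, to_pos = to_pos,
       direction = as.integer(sel$direction),
       n_segments = as.integer(sel$n_segments),
       degrees = sel$direction * sel$n_segments * pitch,
       twist_after = sel$twist_after)
}

# unsigned microstep distance travelled at time t into a trapezoidal move of
# total distance d (closed form; t clamped to [0, duration])
.trapezoid_distance <- function(t, d, motion) {
  v <- motion$max_velocity; a <- motion$acceleration
  if (d == 0) return(0 * t)
  if (d >= v^2 / a) {
    t_a <- v / a                      # acceleration (= deceleration) time
    t_tot <- d / v + v / a
    t_c <- t_tot - 2 * t_a            # cruise time
    t <- pmin(pmax(t, 0), t_tot)
    ifelse(t <= t_a, 0.5 * a * t^2,
           ifelse(t <= t_a + t_c, 0.5 * a * t_a^2 + v * (t - t_a),
                  d - 0.5 * a * (t_tot - t)^2))
  } else {
    t_pk <- sqrt(d / a)               # triangular: peak at half distance
    t_tot <- 2 * t_pk
    t <- pmin(pmax(t, 0), t_tot)
    ifelse(t <= t_pk, 0.5 * a * t^2, d - 0.5 * a * (t_tot - t)^2)
  }
}

#' Wheel angular displacement during a planned move
#'
#' Signed wheel angle (degrees) travelled `t` seconds after the start of a
#' rotation step, under the trapezoidal (or degenerate triangular) velocity
#' profile: quadratic during acceleration, linear at cruise, quadratic during
#' deceleration.
#'
#' @param t Time(s) since the start of the move, s.
#' @param step A rotation step from [plan_rotation()].
#' @param motion A [motion_profile()].
#' @param layout A [wheel_layout()].
#' @return Signed angular displacement, degrees.
#' @export
angular_position <- function(t, step, motion, layout) {
  d <- step$n_segments * layout$steps_per_segment
  deg_per_step <- layout$segment_pitch / layout$steps_per_segment
  step$direction * .trapezoid_distance(t, d, motion) * deg_per_step
}

#' Drive-temperature schedule seen by a point on the sample bolus
#'
#' During a rotation the capillary point offset from the bolus centre by
#' `bolus_offset` degrees leaves the departing block, traverses the insulated
#' inter-block gap, and engages the arriving block; points on opposite sides
#' of the bolus centre (leading vs trailing ends) switch blocks at times
#' offset by `2 * offset / omega` at cruise angular rate `omega`. Gap
#' intervals carry `NA` temperature, meaning "hold the last temperature"
#' (the gaps are felt-insulated and traversal lasts well under a second).
#'
#' @param steps A list of rotation steps from [plan_rotation()], each with a
#'   `start_time` element (s); steps must be chronological.
#' @param layout A [wheel_layout()].
#' @param motion A [motion_profile()].
#' @param block_temps Numeric vector of block temperatures (degrees C) by
#'   wheel position (position 0 first); `NA` for unheated segments.
#' @param bolus_offset Angular offset of the capillary point from the bolus
#'   centre, degrees; must satisfy `|offset| < arc_span/2`.
#' @param t_start Schedule start time, s.
#' @return A [drive_schedule()]: breakpoints `(time, temp)` with `NA` temp
#'   marking gap-hold (or unheated-block) intervals.
#' @export
drive_temperature_schedule <- function(steps, layout, motion, block_temps,
                                       bolus_offset = 0, t_start = 0) {
  half_arc <- layout$arc_span / 2
  if (abs(bolus_offset) >= half_arc)
    stop(sprintf("bolus_offset %g deg lies outside the half arc span %g deg",
                 bolus_offset, half_arc))
  n <- layout$num_segments
  stopifnot(length(block_temps) == n)
  pitch <- layout$segment_pitch
  times <- t_start
  temps <- block_temps[steps[[1]]$from_pos + 1]
  for (st in steps) {
    if (st$n_segments == 0) next
    d_steps <- st$n_segments * layout$steps_per_segment
    dur <- transition_time(st$n_segments, motion, layout)
    deg_per_step <- pitch / layout$steps_per_segment
    total_deg <- d_steps * deg_per_step
    # in the wheel frame the point sits at p = direction * bolus_offset ahead
    # of the engaged segment centre; it crosses a block edge when the
    # unsigned rotation angle phi reaches p + (j-1)*pitch + arc/2 (exit) and
    # p + j*pitch - arc/2 (entry), j = 1..n_segments
    p <- st$direction * bolus_offset
    phi_of_t <- function(t) .trapezoid_distance(t, d_steps, motion) * deg_per_step
    cross_time <- function(phi) {
      if (phi <= 0) return(st$start_time)
      if (phi >= total_deg) return(st$start_time + dur)
      st$start_time +
        stats::uniroot(function(t) phi_of_t(t) - phi,
                       lower = 0, upper = dur, tol = 1e-9)$root
    }
    for (j in seq_len(st$n_segments)) {
      t_exit <- cross_time(p + (j - 1) * pitch + half_arc)
      t_enter <- cross_time(p + j * pitch - half_arc)
      pos_j <- (st$from_pos + j * st$direction) %% n
      times <- c(times, t_exit, t_enter)
      temps <- c(temps, NA_real_, block_temps[pos_j + 1])
    }
  }
  drive_schedule(times, temps)
}
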