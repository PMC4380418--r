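#' PCR thermal protocol
#'
#' A thermal program: an optional hot start, one or more cycled stages, an
#' optional final step, and optional in-run block setpoint changes (used when
#' a protocol needs more distinct temperatures than the wheel has segments,
#' e.g. a 96 degC hot start block later re-targeted to 90 degC).
#'
#' @param stages List of stages, each `list(cycles =, steps =)` where
#'   `steps` is a data frame with columns `temp` (degrees C) and `dwell` (s),
#'   in cycling order (typically denature, anneal, extend).
#' @param hot_start Optional `list(temp =, duration =)`.
#' @param final_step Optional `list(temp =, duration =)`.
#' @param setpoint_changes Optional list of
#'   `list(from_temp =, to_temp =, after_stage =, stabilization_s =)`:
#'   the block initially at `from_temp` is re-targeted to `to_temp` once the
#'   given stage index (0 = after the hot start) completes, and must be given
#'   `stabilization_s` seconds before it is next engaged.
#' @param id Optional protocol label.
#' @return An object of class `rz_protocol`.
#' @export
pcr_protocol <- function(stages, hot_start = NULL, final_step = NULL,
                         setpoint_changes = list(), id = "") {
  stopifnot(is.list(stages), length(stages) >= 0)
  for (sg in stages) {
    stopifnot(is.numeric(sg$cycles), sg$cycles >= 0,
              is.data.frame(sg$steps),
              all(c("temp", "dwell") %in% names(sg$steps)))
    if (any(sg$steps$dwell <= 0)) stop("step dwells must be > 0")
  }
  for (h in list(hot_start, final_step))
    if (!is.null(h)) stopifnot(is.numeric(h$temp), h$duration > 0)
  structure(list(stages = stages, hot_start = hot_start,
                 final_step = final_step,
                 setpoint_changes = setpoint_changes, id = id),
            class = "rz_protocol")
}

# the set of block temperature "slots" a protocol needs: setpoint-change
# pairs share one slot, keyed and ordered by their final temperature
.protocol_slots <- function(protocol) {
  temps <- c(if (!is.null(protocol$hot_start)) protocol$hot_start$temp,
             unlist(lapply(protocol$stages, function(s) s$steps$temp)),
             if (!is.null(protocol$final_step)) protocol$final_step$temp)
  temps <- unique(temps)
  slots <- lapply(temps, function(tp) list(temps = tp, final = tp))
  for (sc in protocol$setpoint_changes) {
    i_from <- which(vapply(slots, function(s) sc$from_temp %in% s$temps,
                           logical(1)))
    i_to <- which(vapply(slots, function(s) sc$to_temp %in% s$temps,
                         logical(1)))
    if (!length(i_from) || !length(i_to))
      stop("setpoint change refers to a temperature not in the protocol")
    merged <- list(temps = c(slots[[i_from]]$temps, slots[[i_to]]$temps),
                   final = sc$to_temp)
    slots[[min(i_from, i_to)]] <- merged
    slots[[max(i_from, i_to)]] <- NULL
  }
  slots[order(vapply(slots, `[[`, numeric(1), "final"))]
}

#' Assign protocol temperatures to wheel positions
#'
#' Heated blocks are arranged around the wheel in order of increasing (final)
#' temperature. If the protocol needs fewer distinct temperatures than the
#' wheel has segments, the first segment (position 0) is reserved as an
#' unheated load/unload block; otherwise every segment is heated and the run
#' starts at the hot-start block.
#'
#' @param protocol A [pcr_protocol()].
#' @param layout A [wheel_layout()].
#' @return An object of class `rz_assignment`: a data frame with one row per
#'   wheel position (`position`, `role`, `initial_temp`, `final_temp`) plus a
#'   `slot_of` lookup (protocol temperature -> position) as an attribute.
#' @export
assign_blocks <- function(protocol, layout) {
  slots <- .protocol_slots(protocol)
  n_needed <- length(slots)
  if (n_needed > layout$num_segments)
    stop(sprintf(paste0("protocol needs %d simultaneous block temperatures ",
                        "but the wheel has %d segments; consider a setpoint ",
                        "change to reuse a block between stages"),
                 n_needed, layout$num_segments))
  has_load <- n_needed < layout$num_segments
  first_pos <- if (has_load) 1L else 0L
  rows <- data.frame(position = 0:(layout$num_segments - 1),
                     role = "unused", initial_temp = NA_real_,
                     final_temp = NA_real_, stringsAsFactors = FALSE)
  if (has_load) rows$role[1] <- "load"
  lookup <- list()
  for (i in seq_along(slots)) {
    pos <- first_pos + i - 1L
    rows$role[pos + 1L] <- "heated"
    rows$initial_temp[pos + 1L] <- slots[[i]]$temps[1]
    rows$final_temp[pos + 1L] <- slots[[i]]$final
    for (tp in slots[[i]]$temps) lookup[[format(tp)]] <- pos
  }
  structure(rows, class = c("rz_assignment", "data.frame"),
            slot_of = lookup, has_load = has_load)
}

# wheel position serving a protocol temperature
.position_of <- function(assignment, temp) {
  pos <- attr(assignment, "slot_of")[[format(temp)]]
  if (is.null(pos)) stop(sprintf("no block assigned to %g degC", temp))
  pos
}

#' Compile a protocol into a rotation plan and dwell timeline
#'
#' Walks the protocol in order, planning each wheel rotation under the
#' harness twist constraint and interleaving dwells. The dwell clock starts
#' when the rotation stops (thermal settling is reported separately by
#' [validate_protocol()], not folded into the dwell). Setpoint-change
#' stabilization runs concurrently with cycling; a wait event is inserted
#' only if the re-targeted block would be engaged before it has stabilized.
#' The initial rotation from the load segment is included; the final unload
#' rotation is not part of the amplification time.
#'
#' @param protocol A [pcr_protocol()].
#' @param assignment An [assign_blocks()] result.
#' @param layout A [wheel_layout()].
#' @param motion A [motion_profile()].
#' @return An object of class `rz_run`: list with `events` (data frame
#'   `type`, `start`, `duration`, `position`, `temp`), `total_duration` (s),
#'   and `final_twist` (degrees).
#' @export
compile_protocol <- function(protocol, assignment, layout, motion) {
  ev_type <- character(); ev_start <- ev_dur <- ev_pos <- ev_temp <- numeric()
  t_now <- 0; twist <- 0
  pos_now <- if (isTRUE(attr(assignment, "has_load"))) 0L else NULL
  pending <- list()  # active stabilizations: position -> ready time

  add <- function(type, dur, pos, temp) {
    ev_type <<- c(ev_type, type); ev_start <<- c(ev_start, t_now)
    ev_dur <<- c(ev_dur, dur); ev_pos <<- c(ev_pos, pos)
    ev_temp <<- c(ev_temp, temp)
    t_now <<- t_now + dur
  }
  goto <- function(temp) {
    pos <- .position_of(assignment, temp)
    if (is.null(pos_now)) { pos_now <<- pos }  # run starts on this block
    ready <- pending[[as.character(pos)]]
    if (!is.null(ready) && t_now < ready) {
      add("wait", ready - t_now, pos_now, NA_real_)
      pending[[as.character(pos)]] <<- NULL
    }
    if (pos != pos_now) {
      step <- plan_rotation(pos_now, pos, layout, twist)
      dur <- transition_time(step$n_segments, motion, layout)
      add("rotation", dur, pos, temp)
      twist <<- step$twist_after
      pos_now <<- pos
    }
    pos
  }
  dwell <- function(temp, dur) add("dwell", dur, pos_now, temp)

  if (!is.null(protocol$hot_start)) {
    goto(protocol$hot_start$temp)
    dwell(protocol$hot_start$temp, protocol$hot_start$duration)
  }
  arm_changes <- function(stage_idx) {
    for (sc in protocol$setpoint_changes) {
      if (identical(sc$after_stage, stage_idx))
        pending[[as.character(.position_of(assignment, sc$to_temp))]] <<-
          t_now + sc$stabilization_s
    }
  }
  arm_changes(0L)
  for (si in seq_along(protocol$stages)) {
    sg <- protocol$stages[[si]]
    for (cy in seq_len(sg$cycles)) {
      for (k in seq_len(nrow(sg$steps))) {
        goto(sg$steps$temp[k])
        dwell(sg$steps$temp[k], sg$steps$dwell[k])
      }
    }
    arm_changes(si)
  }
  if (!is.null(protocol$final_step)) {
    goto(protocol$final_step$temp)
    dwell(protocol$final_step$temp, protocol$final_step$duration)
  }
  events <- data.frame(type = ev_type, start = ev_start, duration = ev_dur,
                       position = ev_pos, temp = ev_temp,
                       stringsAsFactors = FALSE)
  structure(list(events = events, total_duration = t_now,
                 final_twist = twist, protocol_id = protocol$id),
            class = "rz_run")
}

#' Validate a protocol against the wheel's thermal constraints
#'
#' Checks that adjacent wheel segments are not asked to sustain more than a
#' 60 K temperature differential (the practical limit between felt-insulated
#' neighbours in still air), and that each dwell is at least `3 * tau` so the
#' sample settles within about 5% of the commanded change before the step
#' ends. Errors (impossible assignments) are reported alongside warnings.
#'
#' @param protocol A [pcr_protocol()].
#' @param assignment An [assign_blocks()] result.
#' @param tau Sample/capillary time constant, s, for the settle check;
#'   `NULL` skips it.
#' @param max_adjacent_dT Largest sustainable adjacent-segment differential,
#'   K (default 60).
#' @return Character vector of messages, each prefixed `"warning:"` or
#'   `"error:"`; empty when the protocol is clean.
#' @export
validate_protocol <- function(protocol, assignment, tau = NULL,
                              max_adjacent_dT = 60) {
  msgs <- character()
  n <- nrow(assignment)
  temps <- assignment$final_temp
  for (i in seq_len(n)) {
    j <- i %% n + 1L  # ring neighbour
    if (!is.na(temps[i]) && !is.na(temps[j])) {
      dT <- abs(temps[i] - temps[j])
      if (dT > max_adjacent_dT)
        msgs <- c(msgs, sprintf(
          "warning: adjacent segments %d and %d differ by %g K (> %g K sustainable)",
          assignment$position[i], assignment$position[j], dT, max_adjacent_dT))
    }
  }
  if (!is.null(tau)) {
    for (sg in protocol$stages) {
      short <- sg$steps$dwell < 3 * tau
      for (k in which(short))
        msgs <- c(msgs, sprintf(
          "warning: %g s dwell at %g degC is shorter than 3*tau = %g s; sample will not settle within ~5%% of the step",
          sg$steps$dwell[k], sg$steps$temp[k], 3 * tau))
    }
  }
  msgs
}

#' @export
print.rz_run <- function(x, ...) {
  n_rot <- sum(x$events$type == "rotation")
  cat(sprintf("compiled run%s: %d events (%d rotations), total %.1f s (%.2f min)\n",
              if (nzchar(x$protocol_id)) paste0(" '", x$protocol_id, "'") else "",
              nrow(x$events), n_rot, x$total_duration, x$total_duration / 60))
  invisible(x)
}
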