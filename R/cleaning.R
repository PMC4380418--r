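#' A fluidic cleaning step
#'
#' @param action One of `aspirate`, `dispense`, `flush`, `incubate`,
#'   `actuate_valve`, `manual`.
#' @param reagent One of `water`, `bleach`, `air`, `none`.
#' @param volume_ul Volume moved per repetition, microlitres.
#' @param duration_s Explicit duration per repetition, s; `NA` means the
#'   duration is derived from the volume and a flow rate at estimation time.
#' @param repetitions Number of repetitions (>= 1).
#' @param flow_class `"normal"` or `"fast"` syringe flow.
#' @param phase Which part of the protocol the step belongs to: `frame`,
#'   `inlet_wash`, `wheel_wash`, `valve_wash`, or `final_flush`.
#' @param note Free-text description.
#' @return One-row data frame.
#' @export
fluid_step <- function(action, reagent = "none", volume_ul = 0,
                       duration_s = NA_real_, repetitions = 1,
                       flow_class = "normal", phase = "frame", note = "") {
  action <- match.arg(action, c("aspirate", "dispense", "flush", "incubate",
                                "actuate_valve", "manual"))
  reagent <- match.arg(reagent, c("water", "bleach", "air", "none"))
  if (volume_ul < 0) stop("volume must be >= 0")
  if (repetitions < 1) stop("repetitions must be >= 1")
  data.frame(action = action, reagent = reagent, volume_ul = volume_ul,
             duration_s = duration_s, repetitions = as.integer(repetitions),
             flow_class = flow_class, phase = phase, note = note,
             stringsAsFactors = FALSE)
}

#' Between-run cleaning protocol
#'
#' @param id Protocol letter (`"A"` to `"E"`).
#' @param steps Data frame of [fluid_step()] rows, in execution order.
#' @param flags Named list of feature flags: `valve_rotation_wash` (logical),
#'   `final_inlet_flush` (logical), `dedicated_wheel_wash` (`"full"`,
#'   `"shorter"`, `"none"`), `inlet_wash` (logical). Checked for consistency
#'   against the step list.
#' @return An object of class `rz_cleaning`.
#' @export
cleaning_protocol <- function(id, steps, flags) {
  stopifnot(is.data.frame(steps), nrow(steps) >= 1)
  has <- function(ph) any(steps$phase == ph)
  if (!identical(flags$valve_rotation_wash, has("valve_wash")))
    stop("valve_rotation_wash flag inconsistent with step list")
  if (!identical(flags$final_inlet_flush, has("final_flush")))
    stop("final_inlet_flush flag inconsistent with step list")
  if ((flags$dedicated_wheel_wash != "none") != has("wheel_wash"))
    stop("dedicated_wheel_wash flag inconsistent with step list")
  if (!identical(flags$inlet_wash, has("inlet_wash")))
    stop("inlet_wash flag inconsistent with step list")
  structure(list(id = id, steps = steps, flags = flags),
            class = "rz_cleaning")
}

# expand repetitions into one row per executed action
.expand_steps <- function(steps) {
  steps[rep(seq_len(nrow(steps)), steps$repetitions), , drop = FALSE]
}

#' Reagent consumption ledger for a cleaning protocol
#'
#' Sums delivered volumes per reagent over all steps and repetitions.
#' Delivery actions are `dispense` and `flush`; `aspirate` withdrawals move
#' already-delivered liquid and consume nothing new.
#'
#' @param protocol A [cleaning_protocol()].
#' @return An object of class `rz_ledger`: list with `bleach_ul`, `water_ul`,
#'   `water_ml`, and the per-reagent table `totals`.
#' @export
reagent_totals <- function(protocol) {
  ex <- .expand_steps(protocol$steps)
  del <- ex[ex$action %in% c("dispense", "flush"), , drop = FALSE]
  tot <- tapply(del$volume_ul, del$reagent, sum)
  get <- function(r) if (r %in% names(tot)) unname(tot[[r]]) else 0
  structure(list(protocol = protocol$id,
                 bleach_ul = get("bleach"),
                 water_ul = get("water"),
                 water_ml = get("water") / 1000,
                 totals = tot),
            class = "rz_ledger")
}

#' Default per-step timing calibration
#'
#' Syringe flow rates, a fixed per-operation overhead (valve switching,
#' syringe refills, plumbing latency), and the duration of one shear-valve
#' actuation. Calibrated once against the reference run times of the five
#' shipped protocols; override any entry to re-time a protocol.
#'
#' @return Named list: `flow_ul_per_s` (named vector, normal/fast),
#'   `per_step_overhead_s`, `valve_actuation_s`.
#' @export
default_timing <- function() {
  list(flow_ul_per_s = c(normal = 12.3, fast = 25),
       per_step_overhead_s = 21,
       valve_actuation_s = 3)
}

#' Duration estimate for a cleaning protocol
#'
#' Fluid-moving steps (`aspirate`, `dispense`, `flush`) take
#' `volume / flow_rate + overhead` per repetition; `incubate` and `manual`
#' steps take their explicit durations; `actuate_valve` takes the configured
#' actuation time per repetition.
#'
#' @param protocol A [cleaning_protocol()].
#' @param timing Timing configuration, see [default_timing()].
#' @return Total duration, s.
#' @export
duration_estimate <- function(protocol, timing = default_timing()) {
  need <- c("flow_ul_per_s", "per_step_overhead_s", "valve_actuation_s")
  missing <- setdiff(need, names(timing))
  if (length(missing))
    stop("timing config is missing entries: ", paste(missing, collapse = ", "))
  ex <- .expand_steps(protocol$steps)
  per_row <- function(i) {
    s <- ex[i, ]
    switch(s$action,
      aspirate = , dispense = , flush = {
        fl <- timing$flow_ul_per_s[[s$flow_class]]
        if (is.null(fl) || is.na(fl))
          stop("timing config has no flow rate for class ", s$flow_class)
        s$volume_ul / fl + timing$per_step_overhead_s
      },
      incubate = , manual = {
        if (is.na(s$duration_s))
          stop("step '", s$note, "' has no explicit duration")
        s$duration_s
      },
      actuate_valve = timing$valve_actuation_s)
  }
  sum(vapply(seq_len(nrow(ex)), per_row, numeric(1)))
}

#' Difference report between two cleaning protocols
#'
#' @param p1,p2 [cleaning_protocol()] objects.
#' @return An object of class `rz_cleaning_diff`: list with `flags_changed`
#'   (named list of `c(from, to)` pairs), `bleach_ul` and `water_ul` deltas,
#'   and `phases_added`/`phases_removed`.
#' @export
diff_protocols <- function(p1, p2) {
  flags_changed <- list()
  for (nm in union(names(p1$flags), names(p2$flags))) {
    if (!identical(p1$flags[[nm]], p2$flags[[nm]]))
      flags_changed[[nm]] <- list(from = p1$flags[[nm]], to = p2$flags[[nm]])
  }
  l1 <- reagent_totals(p1); l2 <- reagent_totals(p2)
  ph1 <- unique(p1$steps$phase); ph2 <- unique(p2$steps$phase)
  structure(list(from = p1$id, to = p2$id,
                 flags_changed = flags_changed,
                 bleach_ul = c(from = l1$bleach_ul, to = l2$bleach_ul),
                 water_ul = c(from = l1$water_ul, to = l2$water_ul),
                 phases_added = setdiff(ph2, ph1),
                 phases_removed = setdiff(ph1, ph2)),
            class = "rz_cleaning_diff")
}

#' Load a shipped cleaning protocol (A through E)
#'
#' The five between-run cleaning protocols are shipped as data files,
#' ordered from the conservative baseline (A) to the minimal water-only
#' rinse (E). Step volumes not individually published were reconstructed so
#' that the per-protocol reagent totals match the reference feature table;
#' see the file comments.
#'
#' @param id Protocol letter, `"A"`..`"E"`.
#' @return A [cleaning_protocol()].
#' @export
load_cleaning_protocol <- function(id) {
  id <- match.arg(toupper(id), LETTERS[1:5])
  path <- system.file("extdata", "cleaning",
                      paste0("protocol_", id, ".yaml"), package = "rzcycler")
  if (!nzchar(path)) stop("no shipped definition for protocol ", id)
  read_cleaning_protocol(path)
}

#' All five shipped cleaning protocols
#'
#' @return Named list `A`..`E` of [cleaning_protocol()] objects.
#' @export
cleaning_protocol_library <- function() {
  stats::setNames(lapply(LETTERS[1:5], load_cleaning_protocol), LETTERS[1:5])
}

#' @export
print.rz_ledger <- function(x, ...) {
  cat(sprintf("cleaning protocol %s: bleach %g uL, water %g mL\n",
              x$protocol, x$bleach_ul, x$water_ml))
  invisible(x)
}

#' @export
print.rz_cleaning_diff <- function(x, ...) {
  cat(sprintf("protocol %s -> %s\n", x$from, x$to))
  for (nm in names(x$flags_changed))
    cat(sprintf("  flag %s: %s -> %s\n", nm,
                format(x$flags_changed[[nm]]$from),
                format(x$flags_changed[[nm]]$to)))
  cat(sprintf("  bleach: %g -> %g uL; water: %g -> %g uL\n",
              x$bleach_ul["from"], x$bleach_ul["to"],
              x$water_ul["from"], x$water_ul["to"]))
  if (length(x$phases_removed))
    cat("  phases removed:", paste(x$phases_removed, collapse = ", "), "\n")
  if (length(x$phases_added))
    cat("  phases added:", paste(x$phases_added, collapse = ", "), "\n")
  invisible(x)
}
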