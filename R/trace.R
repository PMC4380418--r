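#' Sampled temperature trace
#'
#' @param time_s Monotonically increasing sample times, s.
#' @param temp_C Temperatures, degrees C.
#' @param sampling_rate Nominal sampling rate, Hz; inferred from the median
#'   time step when omitted.
#' @return An object of class `rz_trace` (a data frame `time_s`, `temp_C`).
#' @export
temperature_trace <- function(time_s, temp_C, sampling_rate = NULL) {
  if (length(time_s) < 2) stop("a trace needs at least 2 samples")
  if (length(time_s) != length(temp_C)) stop("time and temperature lengths differ")
  if (any(!is.finite(time_s)) || any(!is.finite(temp_C)))
    stop("trace values must be finite")
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(diff(time_s))
  structure(data.frame(time_s = as.numeric(time_s), temp_C = as.numeric(temp_C)),
            class = c("rz_trace", "data.frame"), sampling_rate = sampling_rate)
}

# plateau temperatures of a two-level cycling trace: trimmed means of the
# samples in the lower and upper thirds of the observed range
.plateau_levels <- function(temp, trim = 0.1) {
  rng <- range(temp)
  lo <- temp[temp <= rng[1] + diff(rng) / 3]
  hi <- temp[temp >= rng[2] - diff(rng) / 3]
  c(low = mean(lo, trim = trim), high = mean(hi, trim = trim))
}

#' Partition a cycling trace into rising and falling transitions
#'
#' Splits the trace at crossings of two thresholds (by default 10% and 90%
#' of the span between the low and high plateau temperatures) into
#' alternating rising and falling segments. Each returned segment extends
#' from the midpoint of the preceding plateau to the midpoint of the
#' following one, so that the fitter can estimate both asymptotes from the
#' flanking plateau data.
#'
#' @param trace A [temperature_trace()].
#' @param T_low,T_high Segmentation thresholds, degrees C; defaults are the
#'   10%/90% points between the detected plateau levels.
#' @return List of segments; each is a list with `time_s`, `temp_C`,
#'   `direction` (`"heating"`/`"cooling"`), and the detected plateau levels.
#'   Empty list when the trace never crosses both thresholds.
#' @export
segment_cycles <- function(trace, T_low = NULL, T_high = NULL) {
  tt <- trace$time_s; TT <- trace$temp_C
  lv <- .plateau_levels(TT)
  if (is.null(T_low)) T_low <- lv["low"] + 0.1 * (lv["high"] - lv["low"])
  if (is.null(T_high)) T_high <- lv["low"] + 0.9 * (lv["high"] - lv["low"])
  if (T_low >= T_high) stop("T_low must be below T_high")
  state <- ifelse(TT <= T_low, -1L, ifelse(TT >= T_high, 1L, 0L))
  # indices where the trace sits on a plateau
  plat <- which(state != 0L)
  if (!length(plat) || length(unique(state[plat])) < 2) return(list())
  # collapse plateau samples into runs, then merge consecutive runs of the
  # same state (noise wiggle around a threshold must not fragment a plateau)
  runs <- split(plat, cumsum(c(1, diff(plat) > 1 | diff(state[plat]) != 0)))
  run_state <- vapply(runs, function(ix) state[ix[1]], integer(1))
  merged <- list(); merged_state <- integer()
  for (i in seq_along(runs)) {
    k <- length(merged)
    if (k > 0 && merged_state[k] == run_state[i]) {
      merged[[k]] <- c(merged[[k]][1], runs[[i]][length(runs[[i]])])
    } else {
      merged[[k + 1]] <- range(runs[[i]])
      merged_state <- c(merged_state, run_state[i])
    }
  }
  segs <- list()
  for (i in seq_len(length(merged) - 1)) {
    pre <- merged[[i]][1]:merged[[i]][2]
    post <- merged[[i + 1]][1]:merged[[i + 1]][2]
    i0 <- pre[ceiling(length(pre) / 2)]         # midpoint of flanking plateaus
    i1 <- post[ceiling(length(post) / 2)]
    segs[[length(segs) + 1]] <- list(
      time_s = tt[i0:i1], temp_C = TT[i0:i1],
      direction = if (merged_state[i + 1] > merged_state[i]) "heating"
                  else "cooling",
      plateau_low = unname(lv["low"]), plateau_high = unname(lv["high"]))
  }
  segs
}

# trimmed-mean asymptotes of one segment from its flanking plateau samples;
# only samples both in the flanking region and within 10% of span of the
# trace-level plateau temperature count, so settling samples cannot
# contaminate the estimate
.segment_asymptotes <- function(seg, trim = 0.1) {
  rising <- seg$direction == "heating"
  span <- seg$plateau_high - seg$plateau_low
  start_lv <- if (rising) seg$plateau_low else seg$plateau_high
  end_lv <- if (rising) seg$plateau_high else seg$plateau_low
  near_start <- abs(seg$temp_C - start_lv) < 0.2 * span
  near_end <- abs(seg$temp_C - end_lv) < 0.2 * span
  i_dep <- which(!near_start)[1]
  i_arr <- rev(which(!near_end))[1]
  if (is.na(i_dep)) i_dep <- 2L
  if (is.na(i_arr)) i_arr <- length(seg$temp_C) - 1L
  n <- length(seg$temp_C)
  plateau_mean <- function(idx, level) {
    idx <- idx[abs(seg$temp_C[idx] - level) < 0.1 * span]
    if (!length(idx)) return(level)  # no usable plateau: trust the trace level
    mean(seg$temp_C[idx], trim = trim)
  }
  c(start = plateau_mean(seq_len(max(i_dep - 1, 1)), start_lv),
    end = plateau_mean(seq(min(i_arr + 1, n), n), end_lv))
}

# time at which a segment's interpolated temperature crosses a level
.crossing_time <- function(time_s, temp_C, level, rising) {
  s <- if (rising) temp_C else -temp_C
  lv <- if (rising) level else -level
  i <- which(s[-1] >= lv & s[-length(s)] < lv)[1]
  if (is.na(i)) return(NA_real_)
  f <- (lv - s[i]) / (s[i + 1] - s[i])
  time_s[i] + f * (time_s[i + 1] - time_s[i])
}

#' Baseline-correct, time-shift align, and average same-direction segments
#'
#' Each segment is linearly rescaled so its plateau asymptotes match the
#' across-segment mean asymptotes (baseline correction), time-shifted so the
#' segments overlap (initialised at the mid-span crossing and refined by
#' maximising the overlap correlation against the first segment), then
#' interpolated onto a common grid and pointwise averaged.
#'
#' @param segments List of segments from [segment_cycles()], all of the same
#'   direction.
#' @param rate Grid sampling rate, Hz (default 10).
#' @return A segment-like list (`time_s`, `temp_C`, `direction`,
#'   `T_start`, `T_end`, `n_averaged`, `lags`); `time_s` is relative to the
#'   common mid-span crossing at `t = 0`.
#' @export
baseline_align_average <- function(segments, rate = 10) {
  if (!length(segments)) stop("no segments to average")
  dirs <- vapply(segments, `[[`, character(1), "direction")
  if (length(unique(dirs)) != 1)
    stop("segments mix heating and cooling directions")
  rising <- dirs[1] == "heating"
  asy <- t(vapply(segments, .segment_asymptotes, numeric(2)))
  # medians: robust to one segment with a truncated flanking plateau
  T_start <- stats::median(asy[, "start"])
  T_end <- stats::median(asy[, "end"])
  corrected <- lapply(seq_along(segments), function(i) {
    sg <- segments[[i]]
    scale <- (T_end - T_start) / (asy[i, "end"] - asy[i, "start"])
    list(time_s = sg$time_s,
         temp_C = T_start + (sg$temp_C - asy[i, "start"]) * scale)
  })
  mid <- (T_start + T_end) / 2
  lags <- vapply(corrected, function(sg)
    .crossing_time(sg$time_s, sg$temp_C, mid, rising), numeric(1))
  if (any(is.na(lags))) stop("a segment never crosses the mid-span level")
  shifted <- lapply(seq_along(corrected), function(i)
    list(time_s = corrected[[i]]$time_s - lags[i],
         temp_C = corrected[[i]]$temp_C))
  # refine alignment against the first segment by maximising overlap
  # correlation (pure time shift; recovers constructed lags exactly for
  # shape-identical segments)
  ref <- shifted[[1]]
  refine <- function(sg) {
    if (length(sg$time_s) < 4) return(0)
    obj <- function(dl) {
      ti <- sg$time_s - dl
      keep <- ti >= ref$time_s[1] & ti <= ref$time_s[length(ref$time_s)]
      if (sum(keep) < 4) return(Inf)
      ri <- stats::approx(ref$time_s, ref$temp_C, xout = ti[keep])$y
      mean((ri - sg$temp_C[keep])^2)
    }
    stats::optimize(obj, interval = c(-0.5, 0.5))$minimum
  }
  extra <- c(0, vapply(shifted[-1], refine, numeric(1)))
  shifted <- lapply(seq_along(shifted), function(i)
    list(time_s = shifted[[i]]$time_s - extra[i], temp_C = shifted[[i]]$temp_C))
  t_min <- max(vapply(shifted, function(s) s$time_s[1], numeric(1)))
  t_max <- min(vapply(shifted, function(s) s$time_s[length(s$time_s)], numeric(1)))
  grid <- seq(t_min, t_max, by = 1 / rate)
  mat <- vapply(shifted, function(s)
    stats::approx(s$time_s, s$temp_C, xout = grid)$y, numeric(length(grid)))
  avg <- if (is.matrix(mat)) rowMeans(mat) else mat
  list(time_s = grid, temp_C = avg,
       direction = dirs[1], T_start = T_start, T_end = T_end,
       n_averaged = length(segments), lags = lags + extra)
}

#' Two-parameter bounded-exponential fit of one transition
#'
#' Fits `T(t) = T_end + (T_start - T_end) * exp(-(t - t0)/tau)` to a rising
#' or falling segment. The pair `(tau, t0)` is initialised exactly by
#' solving the model at two points of the transition (by default where it
#' has completed 33% and 80% of its span -- robust to noise at both ends),
#' then refined by derivative-free maximisation of R-squared over the fit
#' range. The refined fit never has lower R-squared than the
#' initialisation.
#'
#' @param segment A segment (from [segment_cycles()] or
#'   [baseline_align_average()]) with `time_s`, `temp_C`, `direction`.
#' @param T_start,T_end Asymptote temperatures, degrees C; estimated from
#'   the flanking plateaus (trimmed means) when omitted.
#' @param anchor_fractions The two span fractions used for the exact
#'   two-point initialisation.
#' @return An object of class `rz_fit`: list with `model`
#'   ([response_model()]), `r_squared`, `direction`, `T_start`, `T_end`,
#'   `fit_range` (s), `n_points`, and `warnings`.
#' @export
fit_exponential <- function(segment, T_start = NULL, T_end = NULL,
                            anchor_fractions = c(0.33, 0.80)) {
  tt <- segment$time_s; TT <- segment$temp_C
  if (length(tt) < 5) stop("segment needs at least 5 points")
  warnings <- character()
  # averaged segments carry their asymptotes; raw segments get trimmed-mean
  # plateau estimates
  if (is.null(T_start)) T_start <- segment$T_start
  if (is.null(T_end)) T_end <- segment$T_end
  if (is.null(T_start) || is.null(T_end)) {
    asy <- .segment_asymptotes(segment)
    if (is.null(T_start)) T_start <- unname(asy["start"])
    if (is.null(T_end)) T_end <- unname(asy["end"])
  }
  rising <- T_end > T_start
  span <- T_end - T_start
  # exact two-point initialisation: solve the model through the two samples
  # nearest the anchor progress levels; remaining fraction
  # r = (T - T_end)/(T_start - T_end) = exp(-(t - t0)/tau)
  lv <- T_start + anchor_fractions * span
  i1 <- which.min(abs(TT - lv[1]))
  i2 <- which.min(abs(TT - lv[2]))
  r1 <- (TT[i1] - T_end) / (T_start - T_end)
  r2 <- (TT[i2] - T_end) / (T_start - T_end)
  if (i2 > i1 && r1 > r2 && r2 > 1e-6) {
    tau0 <- (tt[i2] - tt[i1]) / (log(r1) - log(r2))
    t00 <- tt[i1] + tau0 * log(r1)
  } else {
    # fallback: interpolated threshold crossings
    t_anchor <- vapply(lv, function(l) .crossing_time(tt, TT, l, rising),
                       numeric(1))
    if (any(is.na(t_anchor)))
      stop("segment does not span the anchor levels; cannot initialise fit")
    lr <- log(1 - anchor_fractions)
    tau0 <- (t_anchor[2] - t_anchor[1]) / (lr[1] - lr[2])
    t00 <- t_anchor[1] + tau0 * lr[1]
  }
  if (!is.finite(tau0) || tau0 <= 0) stop("two-point initialisation failed")
  # fit range: from transition onset (departure beyond 2% of span) to the
  # end of the segment, i.e. the full transition plus the settled tail
  dep <- which(abs(TT - T_start) > 0.02 * abs(span))[1]
  i_fit <- seq(max(dep, 1), length(tt))
  tf <- tt[i_fit]; Tf <- TT[i_fit]
  ss_tot <- sum((Tf - mean(Tf))^2)
  r2_of <- function(par) {
    tau <- par[1]; t0 <- par[2]
    if (tau <= 0) return(-Inf)
    pred <- T_end + (T_start - T_end) * exp(-pmax(tf - t0, 0) / tau)
    1 - sum((Tf - pred)^2) / ss_tot
  }
  r2_init <- r2_of(c(tau0, t00))
  opt <- stats::optim(c(tau0, t00), function(p) -r2_of(p),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000,
                                     warn.1d.NelderMead = FALSE))
  if (-opt$value >= r2_init) {
    tau <- opt$par[1]; t0 <- opt$par[2]; r2 <- -opt$value
  } else {
    tau <- tau0; t0 <- t00; r2 <- r2_init
  }
  # flag non-monotonicity beyond noise
  d <- diff(TT[tt >= t00 & tt <= t00 + 3 * tau])
  bad <- if (rising) d < 0 else d > 0
  resid_sd <- stats::sd(Tf - (T_end + (T_start - T_end) * exp(-pmax(tf - t0, 0) / tau)))
  if (mean(bad) > 0.25 && resid_sd > 0.05 * abs(span))
    warnings <- c(warnings, "segment is non-monotone beyond noise tolerance")
  structure(list(model = response_model(tau, t0), r_squared = r2,
                 direction = if (rising) "heating" else "cooling",
                 T_start = T_start, T_end = T_end,
                 fit_range = range(tf), n_points = length(tf),
                 r_squared_init = r2_init, warnings = warnings),
            class = "rz_fit")
}

#' Rise/fall report in the reference-table layout
#'
#' For a fitted (or predicted) time constant, tabulates the time to approach
#' within 1 K and 0.1 K of the final temperature and the corresponding
#' effective sample ramp rates, for a transition starting `dT_initial` away
#' from the asymptote.
#'
#' @param fit An `rz_fit` or a [response_model()].
#' @param dT_initial Initial offset magnitude, K (36 K for a 60 to 96 degC
#'   transition).
#' @param bands Target bands, K.
#' @return Data frame with columns `band_K`, `time_s`, `rate_K_per_s`.
#' @export
rise_fall_report <- function(fit, dT_initial, bands = c(1, 0.1)) {
  model <- if (inherits(fit, "rz_fit")) fit$model else fit
  stopifnot(inherits(model, "rz_response"))
  bands <- bands[bands <= dT_initial]
  times <- vapply(bands, function(b) time_to_within(model, dT_initial, b),
                  numeric(1))
  rate <- ifelse(times > 0, (dT_initial - bands) / times, NA_real_)
  data.frame(band_K = bands, time_s = times, rate_K_per_s = rate)
}

#' @export
print.rz_fit <- function(x, ...) {
  cat(sprintf("%s fit: tau = %.4g s, t0 = %.4g s, R^2 = %.5f (n = %d)\n",
              x$direction, x$model$tau, x$model$t0, x$r_squared, x$n_points))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
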