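#' Tube geometry of the ten-unit dynamic colon model
#'
#' @param n_units Number of haustral units (default 10).
#' @param unit_length Length of one unit in m (default 0.020).
#' @param lumen_diameter Luminal diameter in m (default 0.040).
#' @param lumen_volume Total luminal volume in m^3 (default 290e-6).
#' @param fill_volume Fluid fill volume in m^3 (default 100e-6, the
#'   half-filled operating condition).
#' @param max_membrane_displacement Maximum inward membrane travel in m
#'   (default 0.012).
#' @return An object of class `tube_geometry`. `total_length` is derived as
#'   `n_units * unit_length`.
#' @export
tube_geometry <- function(n_units = 10, unit_length = 0.020,
                          lumen_diameter = 0.040, lumen_volume = 290e-6,
                          fill_volume = 100e-6,
                          max_membrane_displacement = 0.012) {
  stopifnot(n_units >= 1, unit_length > 0, lumen_diameter > 0,
            fill_volume > 0, fill_volume <= lumen_volume,
            max_membrane_displacement > 0,
            max_membrane_displacement < lumen_diameter)
  structure(list(n_units = as.integer(n_units), unit_length = unit_length,
                 total_length = n_units * unit_length,
                 lumen_diameter = lumen_diameter,
                 lumen_volume = lumen_volume, fill_volume = fill_volume,
                 max_membrane_displacement = max_membrane_displacement),
            class = "tube_geometry")
}

#' Per-unit contraction kinematics
#'
#' One haustral actuation cycle: the membrane inflates at
#' `contraction_speed` until the programmed occlusion degree is reached,
#' holds for `hold_time`, then deflates at the slower `relaxation_speed`
#' (the slow return mimics the viscoelastic recovery of the colonic wall).
#' Occlusion degree is expressed as the fraction of the maximum membrane
#' displacement.
#'
#' @param occlusion_degree Fraction of full membrane travel, in [0, 1]
#'   (default 0.40).
#' @param contraction_speed Membrane inflation speed, m s^-1 (default 0.016).
#' @param hold_time Dwell at maximum occlusion, s (default 1).
#' @param relaxation_speed Membrane deflation speed, m s^-1 (default 0.0035).
#' @return An object of class `unit_kinematics`.
#' @export
unit_kinematics <- function(occlusion_degree = 0.40,
                            contraction_speed = 0.016, hold_time = 1,
                            relaxation_speed = 0.0035) {
  stopifnot(occlusion_degree >= 0, occlusion_degree <= 1,
            contraction_speed > 0, relaxation_speed > 0, hold_time >= 0)
  structure(list(occlusion_degree = occlusion_degree,
                 contraction_speed = contraction_speed,
                 hold_time = hold_time,
                 relaxation_speed = relaxation_speed),
            class = "unit_kinematics")
}

#' Propagating-wave protocol
#'
#' @param direction "antegrade" (unit 1 towards unit 10) or "retrograde".
#' @param wave_speed Propagation speed of the contraction front, m s^-1
#'   (default 0.020).
#' @param inter_wave_delay Quiescent delay after a wave fully relaxes before
#'   the next wave starts, s (default 10, so the fluid becomes static).
#' @param n_waves Number of waves (default 1).
#' @param paired_expansion If `TRUE` (default), the unit downstream of each
#'   contracting unit expands at the contraction speed, mimicking the
#'   coordinated contraction/relaxation of the intestine law; the final
#'   unit has no downstream partner and none is applied there.
#' @return An object of class `wave_protocol`.
#' @export
wave_protocol <- function(direction = c("antegrade", "retrograde"),
                          wave_speed = 0.020, inter_wave_delay = 10,
                          n_waves = 1, paired_expansion = TRUE) {
  direction <- match.arg(direction)
  stopifnot(wave_speed > 0, inter_wave_delay >= 0, n_waves >= 0)
  structure(list(direction = direction, wave_speed = wave_speed,
                 inter_wave_delay = inter_wave_delay,
                 n_waves = as.integer(n_waves),
                 paired_expansion = isTRUE(paired_expansion)),
            class = "wave_protocol")
}

# Paired-expansion profile: the membrane deflates below neutral at the
# contraction speed when its upstream partner starts contracting, holds
# the expanded state, and re-inflates back to neutral at the same speed
# from its own contraction onset (`recovery_onset`).
expansion_profile <- function(kin, geometry, onset, recovery_onset, time) {
  g <- kin$occlusion_degree
  if (g == 0) return(numeric(length(time)))
  travel <- g * geometry$max_membrane_displacement
  ramp <- travel / kin$contraction_speed
  recovery_onset <- max(recovery_onset, onset + ramp)
  out <- numeric(length(time))
  tt <- time - onset
  down <- tt >= 0 & tt < ramp
  hold <- tt >= ramp & time < recovery_onset
  up <- time >= recovery_onset & time < recovery_onset + ramp
  out[down] <- -g * tt[down] / ramp
  out[hold] <- -g
  out[up] <- -g * (recovery_onset + ramp - time[up]) / ramp
  out
}

# Ramp/hold/ramp durations of one actuation event, in seconds.
event_durations <- function(kin, geometry) {
  travel <- kin$occlusion_degree * geometry$max_membrane_displacement
  ramp_up <- travel / kin$contraction_speed
  ramp_down <- travel / kin$relaxation_speed
  c(ramp_up = ramp_up, hold = kin$hold_time, ramp_down = ramp_down,
    total = ramp_up + kin$hold_time + ramp_down)
}

#' Occlusion profile of a single unit
#'
#' Piecewise-linear occlusion fraction: linear rise from 0 to
#' `occlusion_degree` over `(occlusion_degree * max_displacement) /
#' contraction_speed` seconds, a hold, then a linear return at the
#' relaxation speed; zero elsewhere.
#'
#' @param kin A [unit_kinematics()].
#' @param geometry A [tube_geometry()].
#' @param onset Contraction onset time, s.
#' @param time Numeric vector of evaluation times, s.
#' @return Occlusion fraction at each element of `time`.
#' @export
unit_occlusion_profile <- function(kin, geometry, onset, time) {
  stopifnot(inherits(kin, "unit_kinematics"),
            inherits(geometry, "tube_geometry"))
  travel <- kin$occlusion_degree * geometry$max_membrane_displacement
  if (travel > geometry$lumen_diameter)
    stop("programmed occlusion exceeds the lumen", call. = FALSE)
  d <- event_durations(kin, geometry)
  tt <- time - onset
  g <- kin$occlusion_degree
  out <- numeric(length(tt))
  if (g == 0) return(out)
  up <- tt >= 0 & tt < d["ramp_up"]
  hold <- tt >= d["ramp_up"] & tt < d["ramp_up"] + d["hold"]
  down <- tt >= d["ramp_up"] + d["hold"] & tt < d["total"]
  out[up] <- g * tt[up] / d["ramp_up"]
  out[hold] <- g
  out[down] <- g * (d["total"] - tt[down]) / d["ramp_down"]
  out
}

#' Propagate a wave protocol into a per-unit occlusion field
#'
#' Unit onsets are staggered by `unit_length / wave_speed` along the wave
#' direction; with paired expansion the next unit in the direction of travel
#' carries the negative of the contracting unit's profile (omitted at the
#' last unit, which faces the rigid siphon). Successive waves start
#' `inter_wave_delay` seconds after the previous wave's final unit has
#' fully relaxed. Superposed contributions are clipped to
#' [-occlusion_degree, occlusion_degree]; a warning is raised if waves
#' overlap.
#'
#' @param protocol A [wave_protocol()].
#' @param kin A [unit_kinematics()].
#' @param geometry A [tube_geometry()].
#' @param dt Time-grid step, s (default 0.01, resolving the 0.3 s ramp).
#' @param t_end Optional end of the grid, s; defaults to the end of the
#'   last wave's relaxation plus one inter-wave delay.
#' @return An object of class `occlusion_field`: list with `time`, a
#'   `n_units x n_time` matrix `occlusion`, per-wave per-unit `onsets`,
#'   `geometry`, `kin`, `protocol`.
#' @export
propagate_wave <- function(protocol, kin = unit_kinematics(),
                           geometry = tube_geometry(), dt = 0.01,
                           t_end = NULL) {
  stopifnot(inherits(protocol, "wave_protocol"), dt > 0)
  n <- geometry$n_units
  d <- event_durations(kin, geometry)
  stagger <- geometry$unit_length / protocol$wave_speed
  # first onset -> last unit fully relaxed (the final unit's contraction
  # is delayed by one ramp when it recovers from a paired expansion)
  wave_span <- (n - 1) * stagger + d["total"] +
    if (protocol$paired_expansion) d["ramp_up"] else 0
  period <- wave_span + protocol$inter_wave_delay
  if (protocol$inter_wave_delay < d["total"] && protocol$n_waves > 1)
    warning("inter-wave delay shorter than one actuation cycle; ",
            "superposed contributions are clipped")
  if (is.null(t_end))
    t_end <- max(protocol$n_waves, 1) * period
  time <- seq(0, t_end, by = dt)
  occ <- matrix(0, nrow = n, ncol = length(time))
  order_units <- if (protocol$direction == "antegrade") seq_len(n) else rev(seq_len(n))
  onsets <- matrix(NA_real_, nrow = max(protocol$n_waves, 0), ncol = n)
  ramp_up <- unname(d["ramp_up"])
  if (protocol$n_waves >= 1) {
    for (w in seq_len(protocol$n_waves)) {
      wave_start <- (w - 1) * period
      for (k in seq_len(n)) {
        u <- order_units[k]
        onset <- wave_start + (k - 1) * stagger
        onsets[w, u] <- onset
        # a unit that was expanded as the previous unit's partner starts
        # its own cycle from below neutral: the membrane re-inflates at
        # the contraction speed, crossing neutral after one ramp time,
        # so the contraction proper is delayed by ramp_up
        expanded_before <- protocol$paired_expansion && k > 1
        c_onset <- onset + if (expanded_before) ramp_up else 0
        occ[u, ] <- occ[u, ] +
          unit_occlusion_profile(kin, geometry, c_onset, time)
        if (protocol$paired_expansion && k < n) {
          partner <- order_units[k + 1]
          occ[partner, ] <- occ[partner, ] +
            expansion_profile(kin, geometry, onset, onset + stagger, time)
        }
      }
    }
  }
  g <- kin$occlusion_degree
  occ <- pmin(pmax(occ, -g), g)
  structure(list(time = time, occlusion = occ, onsets = onsets,
                 geometry = geometry, kin = kin, protocol = protocol),
            class = "occlusion_field")
}

#' Wave-front traversal time of the tube
#'
#' Time for the contraction front to cross the whole tube: the onset lag
#' between the first and last unit plus one inter-unit interval, i.e.
#' `total_length / wave_speed`.
#'
#' @param field An `occlusion_field` from [propagate_wave()], or a
#'   [wave_protocol()] together with `geometry`.
#' @param geometry A [tube_geometry()] (only needed when `field` is a
#'   protocol).
#' @return Traversal time in seconds.
#' @export
wave_traversal_time <- function(field, geometry = tube_geometry()) {
  if (inherits(field, "occlusion_field")) {
    on <- field$onsets[1, ]
    stagger <- field$geometry$unit_length / field$protocol$wave_speed
    return(abs(on[field$geometry$n_units] - on[1]) + stagger)
  }
  stopifnot(inherits(field, "wave_protocol"))
  geometry$total_length / field$wave_speed
}

#' Colonic motility index of an activity schedule
#'
#' The recording is divided into bins of `bin_width` seconds. In each bin,
#' `Dr` is the total time (the union across segments, capped at the bin
#' width) during which any contraction activity occurs, and `No_seg` is the
#' number of segments active at any instant in the bin. The index is
#' `sum(Dr * No_seg)` over bins, in segment-seconds. A trailing partial bin
#' is dropped.
#'
#' @param activity A list with one element per segment; each element is a
#'   two-column matrix or data.frame of activity intervals (start, end) in
#'   seconds. Empty elements (`NULL` or zero rows) mean no activity.
#' @param recording_length Recording length in s (default 120).
#' @param bin_width Bin width in s (default 20).
#' @return Motility index in segment x s.
#' @export
motility_index <- function(activity, recording_length = 120,
                           bin_width = 20) {
  stopifnot(bin_width > 0, recording_length >= bin_width)
  n_bins <- floor(recording_length / bin_width)
  ivals <- lapply(activity, function(a) {
    if (is.null(a) || NROW(a) == 0)
      return(matrix(numeric(0), ncol = 2))
    a <- as.matrix(a)[, 1:2, drop = FALSE]
    if (any(a[, 2] < a[, 1]))
      stop("activity interval with end before start", call. = FALSE)
    if (any(a[, 1] < 0) || any(a[, 2] > recording_length)) {
      warning("activity outside the recording clipped")
      a[, 1] <- pmax(a[, 1], 0)
      a[, 2] <- pmin(a[, 2], recording_length)
      a <- a[a[, 2] > a[, 1], , drop = FALSE]
    }
    a
  })
  total <- 0
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) * bin_width
    hi <- b * bin_width
    clipped <- lapply(ivals, function(a) {
      s <- pmax(a[, 1], lo); e <- pmin(a[, 2], hi)
      keep <- e > s
      cbind(s[keep], e[keep])
    })
    active <- vapply(clipped, function(a) NROW(a) > 0, logical(1))
    no_seg <- sum(active)
    if (no_seg == 0) next
    pooled <- do.call(rbind, clipped)
    dr <- interval_union_measure(pooled)
    total <- total + min(dr, bin_width) * no_seg
  }
  total
}

# Lebesgue measure of a union of intervals given as a 2-column matrix.
interval_union_measure <- function(ivals) {
  if (NROW(ivals) == 0) return(0)
  o <- order(ivals[, 1])
  s <- ivals[o, 1]; e <- ivals[o, 2]
  tot <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else cur_e <- max(cur_e, e[i])
  }
  tot + (cur_e - cur_s)
}

#' Segment activity intervals from an occlusion field
#'
#' Maps the tube's units onto `n_segments` contiguous spans and marks a
#' segment active whenever any of its units has occlusion above
#' `threshold` or its occlusion is changing (ramping).
#'
#' @param field An `occlusion_field`.
#' @param n_segments Number of segments (default 5); `n_units` must be
#'   divisible by it.
#' @param threshold Occlusion fraction above which a unit counts as active
#'   (default 0.05).
#' @return A list of per-segment interval matrices suitable for
#'   [motility_index()].
#' @export
field_to_segment_activity <- function(field, n_segments = 5,
                                      threshold = 0.05) {
  stopifnot(inherits(field, "occlusion_field"))
  n <- field$geometry$n_units
  if (n %% n_segments != 0)
    stop("n_units must be divisible by n_segments", call. = FALSE)
  per_seg <- n / n_segments
  dt <- field$time[2] - field$time[1]
  lapply(seq_len(n_segments), function(s) {
    units <- ((s - 1) * per_seg + 1):(s * per_seg)
    sub <- field$occlusion[units, , drop = FALSE]
    ramping <- cbind(abs(sub[, -1, drop = FALSE] -
                           sub[, -ncol(sub), drop = FALSE]) > 0, FALSE)
    active <- apply(sub > threshold | (ramping & sub > 0), 2, any)
    runs_to_intervals(active, field$time, dt)
  })
}

# Convert a logical activity vector on a uniform grid to (start, end)
# intervals; each active sample covers [t, t + dt).
runs_to_intervals <- function(active, time, dt) {
  if (!any(active)) return(matrix(numeric(0), ncol = 2))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  cbind(time[starts[keep]], time[ends[keep]] + dt)
}

#' Write / read an occlusion field as delimited text
#'
#' One row per time point: time plus one occlusion column per unit.
#'
#' @param field An `occlusion_field`.
#' @param path Output file path.
#' @export
write_occlusion_field <- function(field, path) {
  d <- data.frame(time = field$time, t(field$occlusion))
  names(d) <- c("time", paste0("unit", seq_len(field$geometry$n_units)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occlusion_field
#' @param geometry A [tube_geometry()] matching the file's unit count.
#' @return For the reader, an `occlusion_field` (onsets/kinematics unknown).
#' @export
read_occlusion_field <- function(path, geometry = tube_geometry()) {
  d <- utils::read.csv(path)
  structure(list(time = d$time,
                 occlusion = t(as.matrix(d[, -1, drop = FALSE])),
                 onsets = NULL, geometry = geometry, kin = NULL,
                 protocol = NULL),
            class = "occlusion_field")
}
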