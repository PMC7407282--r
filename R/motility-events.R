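#' Per-haustrum time-series container
#'
#' Holds the extracted cine-MRI measurements: one row per haustrum, one
#' column per frame. Values are either straight-line lengths across the
#' haustrum (cm, baseline conditions) or ROI surface areas (cm^2,
#' stimulated conditions with good wall contrast).
#'
#' @param values Numeric matrix, haustra x time, strictly positive.
#' @param positions Haustral centroid positions along the colon in cm from
#'   the caecal end; strictly increasing, one per row.
#' @param mode "length_cm" or "area_cm2".
#' @param dt Sampling interval in s (default 1, the cine frame rate).
#' @return An object of class `haustral_series`.
#' @export
haustral_series <- function(values, positions,
                            mode = c("length_cm", "area_cm2"), dt = 1) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(positions), dt > 0)
  if (any(values <= 0))
    stop("haustral measurements must be positive", call. = FALSE)
  if (is.unsorted(positions, strictly = TRUE))
    stop("haustral positions must be strictly increasing", call. = FALSE)
  structure(list(values = values, positions = positions, mode = mode,
                 dt = dt,
                 time = (seq_len(ncol(values)) - 1) * dt),
            class = "haustral_series")
}

#' Read a haustral series from delimited text
#'
#' First column is time in seconds; remaining columns are haustra. The
#' header encodes positions as `h<k>@<cm>` (e.g. `h1@2.0`).
#'
#' @param path File path.
#' @param mode Measurement mode (see [haustral_series()]).
#' @param sep Field separator (default comma).
#' @return A `haustral_series`.
#' @export
read_haustral_series <- function(path, mode = c("length_cm", "area_cm2"),
                                 sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         check.names = FALSE)
  tm <- d[[1]]
  vals <- t(as.matrix(d[, -1, drop = FALSE]))
  pos <- as.numeric(sub("^.*@", "", colnames(d)[-1]))
  if (anyNA(pos))
    stop("header must encode positions as h<k>@<cm>", call. = FALSE)
  dt <- if (length(tm) > 1) tm[2] - tm[1] else 1
  haustral_series(vals, pos, mode = match.arg(mode), dt = dt)
}

# Centered moving median; endpoints use the available part of the window.
moving_median <- function(x, window) {
  if (window <= 1) return(x)
  half <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# Equivalent haustral length for metric reporting: identity in length mode,
# diameter of the equal-area circle in area mode (so occlusion velocities
# are cm/s in both modes).
equivalent_length <- function(v, mode) {
  if (mode == "area_cm2") sqrt(4 * v / pi) else v
}

#' Detect haustral contraction events
#'
#' A contraction is a maximal interval where the series drops below
#' `baseline * (1 - min_occlusion/100)` and subsequently recovers towards
#' baseline. Candidate intervals are found on a centred moving-median
#' smoothed copy; onset/peak/end and all metrics are measured on the raw
#' series. The per-event baseline is the median of the 10 samples
#' preceding the onset (or the leading samples for early events).
#'
#' Reported metrics per event: occlusion degree (percent reduction from
#' baseline to the minimum), occlusion velocity in cm/s (equivalent-length
#' rate in area mode), contraction duration `t_c` (onset to minimum) and
#' relaxation duration `t_r` (minimum to recovery).
#'
#' @param series A [haustral_series()].
#' @param min_occlusion Percent reduction required to call an event
#'   (default 10).
#' @param smooth_window Moving-median window in samples (default 5).
#' @param recovery_tol Relative tolerance for the return to baseline
#'   (default 0.05).
#' @return A data.frame of events, one row each, with columns `haustrum`,
#'   `position_cm`, `onset`, `t_min`, `end`, `baseline`, `minimum`,
#'   `occlusion_degree`, `occlusion_velocity`, `t_c`, `t_r`.
#' @export
detect_contraction_events <- function(series, min_occlusion = 10,
                                      smooth_window = 5,
                                      recovery_tol = 0.05) {
  stopifnot(inherits(series, "haustral_series"))
  if (ncol(series$values) < 10)
    stop("need at least 10 samples per haustrum", call. = FALSE)
  out <- list()
  for (h in seq_len(nrow(series$values))) {
    x <- series$values[h, ]
    sm <- moving_median(x, smooth_window)
    ev <- detect_events_one(x, sm, series$time, min_occlusion,
                            recovery_tol, series$mode)
    if (NROW(ev)) {
      ev$haustrum <- h
      ev$position_cm <- series$positions[h]
      out[[length(out) + 1]] <- ev
    }
  }
  if (!length(out)) {
    return(data.frame(haustrum = integer(0), position_cm = numeric(0),
                      onset = numeric(0), t_min = numeric(0),
                      end = numeric(0), baseline = numeric(0),
                      minimum = numeric(0), occlusion_degree = numeric(0),
                      occlusion_velocity = numeric(0), t_c = numeric(0),
                      t_r = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("haustrum", "position_cm", "onset", "t_min", "end", "baseline",
          "minimum", "occlusion_degree", "occlusion_velocity",
          "t_c", "t_r")]
}

detect_events_one <- function(x, sm, time, min_occlusion, recovery_tol,
                              mode) {
  n <- length(x)
  lead_base <- stats::median(x[seq_len(min(10, n))])
  below <- sm < lead_base * (1 - min_occlusion / 100)
  if (!any(below)) return(NULL)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  events <- list()
  used_until <- 0
  for (k in seq_len(nrow(runs))) {
    if (runs[k, 1] <= used_until) next
    i_min <- runs[k, 1] - 1 + which.min(x[runs[k, 1]:runs[k, 2]])
    # onset: last raw sample at/above the recovery band before the minimum
    near <- lead_base * (1 - recovery_tol)
    pre <- which(x[seq_len(i_min)] >= near)
    i_on <- if (length(pre)) max(pre) else 1
    # extend backwards over the initial falling limb so the whole
    # contraction is attributed (mirror of the end extension below)
    while (i_on > 1 && x[i_on - 1] > x[i_on] && x[i_on] < lead_base)
      i_on <- i_on - 1
    baseline <- stats::median(x[max(1, i_on - 10):max(1, i_on - 1)])
    if (i_on == 1) baseline <- lead_base
    near <- baseline * (1 - recovery_tol)
    # end: first recovery after the minimum, extended while still rising
    # towards baseline (so the full relaxation limb is attributed)
    post <- which(x[i_min:n] >= near)
    if (length(post)) {
      i_end <- i_min + post[1] - 1
      while (i_end < n && x[i_end + 1] > x[i_end] && x[i_end] < baseline)
        i_end <- i_end + 1
    } else i_end <- n
    used_until <- i_end
    occ <- 100 * (baseline - x[i_min]) / baseline
    if (occ < min_occlusion) next
    t_c <- time[i_min] - time[i_on]
    t_r <- time[i_end] - time[i_min]
    vel <- if (t_c > 0) {
      (equivalent_length(baseline, mode) -
         equivalent_length(x[i_min], mode)) / t_c
    } else NA_real_
    events[[length(events) + 1]] <- data.frame(
      onset = time[i_on], t_min = time[i_min], end = time[i_end],
      baseline = baseline, minimum = x[i_min], occlusion_degree = occ,
      occlusion_velocity = vel, t_c = t_c, t_r = t_r)
  }
  if (!length(events)) return(NULL)
  do.call(rbind, events)
}

#' Relaxation-to-contraction timing ratio
#'
#' mean(t_r) / mean(t_c) over a set of contraction events: the degree to
#' which the wall returns to its neutral state more slowly than it
#' contracts.
#'
#' @param events Event table from [detect_contraction_events()], or any
#'   data.frame with `t_c` and `t_r` columns.
#' @return Dimensionless ratio.
#' @export
relaxation_contraction_ratio <- function(events) {
  if (NROW(events) == 0)
    stop("no events: timing ratio undefined", call. = FALSE)
  mean(events$t_r) / mean(events$t_c)
}

#' Link contraction events into propagating waves
#'
#' Events on adjacent haustra whose onset lags are positive and at most
#' `max_onset_lag` are chained greedily (earliest onset first). A gap of
#' one haustrum is tolerated when the skipped haustrum shows a
#' sub-threshold dip. Direction is antegrade when position order follows
#' time order (caecum towards hepatic flexure). Travel distance is the
#' position span of the chain; travel velocity is the inverse
#' least-squares slope of onset against position (equal to span over
#' first-to-last lag when onsets are collinear). Events in no chain are
#' isolated contractions.
#'
#' @param events Event table from [detect_contraction_events()].
#' @param series The originating [haustral_series()] (used to test skipped
#'   haustra for sub-threshold dips); may be `NULL` to disallow gaps.
#' @param max_onset_lag Maximum onset lag between consecutive members, s
#'   (default 15).
#' @param min_occlusion Event threshold used for the sub-threshold gap
#'   test (default 10).
#' @return A list with `waves` (data.frame: `direction`, `travel_distance`,
#'   `travel_velocity`, `n_events`, `onset`, `haustra`) and `isolated`
#'   (rows of `events` in no wave).
#' @export
link_waves <- function(events, series = NULL, max_onset_lag = 15,
                       min_occlusion = 10) {
  if (NROW(events) < 2)
    return(list(waves = empty_wave_table(), isolated = events))
  ev <- events[order(events$onset, events$haustrum), ]
  used <- rep(FALSE, nrow(ev))
  waves <- list()
  for (i in seq_len(nrow(ev))) {
    if (used[i]) next
    chain <- i
    repeat {
      last <- chain[length(chain)]
      cand <- which(!used & seq_len(nrow(ev)) != last &
                      !(seq_len(nrow(ev)) %in% chain))
      lag <- ev$onset[cand] - ev$onset[last]
      step <- ev$haustrum[cand] - ev$haustrum[last]
      dirsign <- if (length(chain) >= 2)
        sign(ev$haustrum[chain[2]] - ev$haustrum[chain[1]]) else 0
      gap_ok <- vapply(step, function(s) {
        abs(s) == 2 && gap_has_dip(series, ev$haustrum[last], s,
                                   min_occlusion)
      }, logical(1))
      ok <- lag > 0 & lag <= max_onset_lag & (abs(step) == 1 | gap_ok)
      if (dirsign != 0) ok <- ok & sign(step) == dirsign
      cand <- cand[ok]
      if (!length(cand)) break
      nxt <- cand[order(ev$onset[cand])][1]
      chain <- c(chain, nxt)
    }
    if (length(chain) >= 2) {
      used[chain] <- TRUE
      pos <- ev$position_cm[chain]
      on <- ev$onset[chain]
      dir <- if (pos[length(pos)] > pos[1]) "antegrade" else "retrograde"
      # velocity from the least-squares onset-position slope: identical
      # to span/lag for collinear onsets, robust to the 1 Hz sampling
      # quantisation otherwise
      slope <- sum((pos - mean(pos)) * (on - mean(on))) /
        sum((pos - mean(pos))^2)
      waves[[length(waves) + 1]] <- data.frame(
        direction = dir,
        travel_distance = abs(pos[length(pos)] - pos[1]),
        travel_velocity = 1 / abs(slope),
        n_events = length(chain), onset = on[1],
        haustra = paste(ev$haustrum[chain], collapse = "-"))
    }
  }
  waves <- if (length(waves)) do.call(rbind, waves) else empty_wave_table()
  list(waves = waves, isolated = ev[!used, ])
}

empty_wave_table <- function() {
  data.frame(direction = character(0), travel_distance = numeric(0),
             travel_velocity = numeric(0), n_events = integer(0),
             onset = numeric(0), haustra = character(0))
}

# TRUE when the haustrum between `from` and `from + step` dips below its
# leading baseline by 2 percent or more (but stayed under the event
# threshold, or it would carry its own event).
gap_has_dip <- function(series, from, step, min_occlusion) {
  if (is.null(series)) return(FALSE)
  mid <- from + step %/% 2
  if (mid < 1 || mid > nrow(series$values)) return(FALSE)
  x <- series$values[mid, ]
  base <- stats::median(x[seq_len(min(10, length(x)))])
  drop <- 100 * (base - min(x)) / base
  drop >= 2
}

#' Fold changes between two condition summaries
#'
#' Elementwise stimulated/baseline ratio for travel distance and travel
#' velocity (or any named numeric summaries).
#'
#' @param baseline,stimulated Named numeric vectors with the same names.
#' @return Named vector of fold changes.
#' @export
fold_change_summary <- function(baseline, stimulated) {
  if (!length(baseline) || !length(stimulated))
    stop("empty summary", call. = FALSE)
  nm <- intersect(names(stimulated), names(baseline))
  if (length(nm)) {
    baseline <- baseline[nm]; stimulated <- stimulated[nm]
  }
  if (any(baseline == 0))
    stop("zero baseline: fold change undefined", call. = FALSE)
  stimulated / baseline
}

#' In vivo motility index from detected events
#'
#' Maps haustra to `n_segments` equal spans of the position range, builds
#' per-segment activity intervals from each event's [onset, end] window,
#' and evaluates the segment-based motility index.
#'
#' @param events Event table from [detect_contraction_events()].
#' @param series The originating [haustral_series()].
#' @param n_segments Number of colon segments (default 5).
#' @param bin_width Bin width in s (default 20).
#' @return Motility index in segment x s.
#' @export
in_vivo_motility_index <- function(events, series, n_segments = 5,
                                   bin_width = 20) {
  stopifnot(inherits(series, "haustral_series"))
  rec_len <- series$time[length(series$time)] + series$dt
  if (NROW(events) == 0)
    return(0)
  rng <- range(series$positions)
  brks <- seq(rng[1], rng[2], length.out = n_segments + 1)
  seg_of <- pmin(findInterval(events$position_cm, brks,
                              rightmost.closed = TRUE), n_segments)
  activity <- lapply(seq_len(n_segments), function(s) {
    rows <- events[seg_of == s, , drop = FALSE]
    if (!NROW(rows)) return(NULL)
    cbind(rows$onset, rows$end)
  })
  motility_index(activity, recording_length = rec_len,
                 bin_width = bin_width)
}

#' Write an event or wave table as delimited text
#'
#' @param x A data.frame (events from [detect_contraction_events()] or
#'   waves from [link_waves()]).
#' @param path Output path.
#' @export
write_motility_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
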