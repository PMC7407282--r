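#' Particle trajectory container
#'
#' Time-ordered 3-D positions in tube coordinates: x axial (0 at the
#' proximal face of unit 1, increasing towards the siphon), y transverse
#' horizontal, z vertical. SI units (s, m).
#'
#' @param t Strictly increasing sample times, s.
#' @param x,y,z Coordinates, m.
#' @param particle Optional [particle_spec()].
#' @param fluid_label Optional fluid label.
#' @return An object of class `trajectory` (a data.frame with attributes).
#' @export
trajectory <- function(t, x, y = rep(0, length(t)), z = rep(0, length(t)),
                       particle = NULL, fluid_label = NA_character_) {
  stopifnot(length(t) == length(x), length(t) == length(y),
            length(t) == length(z))
  if (is.unsorted(t, strictly = TRUE))
    stop("sample times must be strictly increasing", call. = FALSE)
  if (!all(is.finite(c(t, x, y, z))))
    stop("non-finite trajectory samples", call. = FALSE)
  structure(data.frame(t = t, x = x, y = y, z = z),
            particle = particle, fluid_label = fluid_label,
            offsets = c(x = 0, y = 0, z = 0),
            class = c("trajectory", "data.frame"))
}

#' Read / write a trajectory as delimited text
#'
#' Column header `t,x,y,z`; seconds and metres (set `units = "mm"` when the
#' coordinates are millimetres).
#'
#' @param path File path.
#' @param units "m" (default) or "mm".
#' @param ... Passed to [trajectory()].
#' @return A `trajectory`.
#' @export
read_track <- function(path, units = c("m", "mm"), ...) {
  units <- match.arg(units)
  d <- utils::read.csv(path)
  stopifnot(all(c("t", "x", "y", "z") %in% names(d)))
  s <- if (units == "mm") 1e-3 else 1
  trajectory(d$t, d$x * s, d$y * s, d$z * s, ...)
}

#' @rdname read_track
#' @param traj A `trajectory`.
#' @export
write_track <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("t", "x", "y", "z")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Savitzky-Golay smoothing of a trajectory
#'
#' Each coordinate is filtered independently with a second-order (by
#' default) Savitzky-Golay filter; timestamps are unchanged. Endpoints are
#' handled by the filter's own polynomial fits on the truncated windows, so
#' polynomials up to the filter order pass through unchanged.
#'
#' @param traj A [trajectory()].
#' @param window Odd window length in samples (default 11).
#' @param polyorder Polynomial order (default 2).
#' @return The smoothed `trajectory`.
#' @export
smooth_track <- function(traj, window = 11, polyorder = 2) {
  stopifnot(inherits(traj, "trajectory"))
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window <= polyorder)
    stop("window must exceed the polynomial order", call. = FALSE)
  if (nrow(traj) < window)
    stop("track shorter than the smoothing window; use a smaller window",
         call. = FALSE)
  for (cc in c("x", "y", "z"))
    traj[[cc]] <- as.numeric(signal::sgolayfilt(traj[[cc]], p = polyorder,
                                                n = window))
  traj
}

#' Register a trajectory to tube coordinates
#'
#' The particle dwells at the centre of the first unit before each run; the
#' median of the first `n_dwell` samples is mapped onto the reference
#' position. In z the reference depends on buoyancy: a floating particle
#' maps to the free surface, a neutrally buoyant one to 5 mm below it.
#' After registration the dwell must lie within +/- 2 mm in x and +/- 3 mm
#' in y; if not, a registration warning is recorded on the trajectory
#' (attribute `registration_warning`).
#'
#' @param traj A [trajectory()].
#' @param reference Numeric `c(x, y)` reference of the first-unit centre
#'   (default `c(0, 0)`).
#' @param surface_z z of the free surface in m (default 0).
#' @param n_dwell Number of initial dwell samples (default 5).
#' @return The registered `trajectory` with attribute `offsets`.
#' @export
register_track <- function(traj, reference = c(0, 0), surface_z = 0,
                           n_dwell = 5) {
  stopifnot(inherits(traj, "trajectory"), nrow(traj) >= n_dwell)
  part <- attr(traj, "particle")
  z_ref <- surface_z
  if (!is.null(part) && part$buoyancy == "neutrally_buoyant")
    z_ref <- surface_z - 0.005
  idx <- seq_len(n_dwell)
  off <- c(x = stats::median(traj$x[idx]) - reference[1],
           y = stats::median(traj$y[idx]) - reference[2],
           z = stats::median(traj$z[idx]) - z_ref)
  traj$x <- traj$x - off["x"]
  traj$y <- traj$y - off["y"]
  traj$z <- traj$z - off["z"]
  attr(traj, "offsets") <- off
  dx <- traj$x[idx] - reference[1]
  dy <- traj$y[idx] - reference[2]
  if (any(abs(dx) > 0.002) || any(abs(dy) > 0.003)) {
    attr(traj, "registration_warning") <-
      "initial dwell outside the +/-2 mm (x) / +/-3 mm (y) start region"
  }
  traj
}

#' Segment a trajectory into passes
#'
#' A pass starts when the particle is in the start region (within the first
#' unit) and is complete when it reaches the distal margin
#' (`x >= total_length - margin`); a jump back into the start region after
#' progressing down the tube (the tracer being collected and replaced)
#' starts a new pass. Incomplete passes are retained and flagged.
#'
#' @param traj A registered [trajectory()].
#' @param geometry A [tube_geometry()].
#' @param margin Distal margin in m (default 0.010).
#' @return A list of `pass` objects: each a list with `track` (the slice),
#'   `start`, `end` (times, s), `complete`.
#' @export
segment_passes <- function(traj, geometry = tube_geometry(),
                           margin = 0.010) {
  stopifnot(inherits(traj, "trajectory"))
  L <- geometry$total_length
  start_region <- geometry$unit_length
  x <- traj$x
  n <- length(x)
  passes <- list()
  i <- 1
  while (i <= n) {
    # find the next entry into the start region
    while (i <= n && x[i] > start_region) i <- i + 1
    if (i > n) break
    j <- i
    done <- FALSE
    while (j < n) {
      if (x[j] >= L - margin) { done <- TRUE; break }
      # a discontinuous jump back to the start after real progress ends
      # the pass (manual replacement of the tracer)
      if (j > i && x[j + 1] <= start_region &&
          x[j] - x[j + 1] > geometry$unit_length) break
      j <- j + 1
    }
    if (!done && j == n && x[j] >= L - margin) done <- TRUE
    slice <- traj[i:j, , drop = FALSE]
    passes[[length(passes) + 1]] <- structure(
      list(track = slice, start = traj$t[i], end = traj$t[j],
           complete = done),
      class = "pass")
    i <- j + 1
  }
  passes
}

#' Detect propulsive displacements in a pass
#'
#' Scans the axial coordinate for maximal monotone excursions, tolerating
#' counter-movements up to `reversal_tol`; excursions with |dx| at or above
#' `threshold` (10 mm, about three particle diameters) are propulsive
#' displacements. The mean velocity of each is `U_x = dx/dt` over the
#' excursion; positive is antegrade.
#'
#' @param pass A `pass` from [segment_passes()], or a [trajectory()].
#' @param threshold Minimum |dx| in m (default 0.010).
#' @param reversal_tol Tolerated counter-movement in m (default 0.003, the
#'   particle size).
#' @return Data.frame with `dx` (m, signed), `dt` (s), `U_x` (m/s),
#'   `direction`, `t_start`, `t_end`.
#' @export
detect_propulsive_displacements <- function(pass, threshold = 0.010,
                                            reversal_tol = 0.003) {
  tr <- if (inherits(pass, "pass")) pass$track else pass
  x <- tr$x; t <- tr$t
  ex <- excursion_turning_points(x, reversal_tol)
  out <- list()
  if (length(ex) >= 2) {
    for (k in seq_len(length(ex) - 1)) {
      i <- ex[k]; j <- ex[k + 1]
      dx <- x[j] - x[i]
      if (abs(dx) >= threshold) {
        dt <- t[j] - t[i]
        out[[length(out) + 1]] <- data.frame(
          dx = dx, dt = dt, U_x = dx / dt,
          direction = if (dx > 0) "antegrade" else "retrograde",
          t_start = t[i], t_end = t[j])
      }
    }
  }
  if (!length(out))
    return(data.frame(dx = numeric(0), dt = numeric(0), U_x = numeric(0),
                      direction = character(0), t_start = numeric(0),
                      t_end = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Indices of the turning points partitioning x into maximal monotone
# excursions, where reversals <= tol do not break an excursion. Zigzag
# state machine: track the running extremum since the last turning point;
# a counter-move beyond tol confirms that extremum as a turning point.
excursion_turning_points <- function(x, tol) {
  n <- length(x)
  if (n < 2) return(integer(0))
  dir <- 0L          # +1 rising, -1 falling, 0 undecided
  mx <- 1L; mn <- 1L # running max / min since the last turning point
  pts <- integer(0)
  for (i in 2:n) {
    if (x[i] > x[mx]) mx <- i
    if (x[i] < x[mn]) mn <- i
    if (dir == 0L) {
      if (x[i] - x[mn] > tol) {
        pts <- mn; dir <- 1L; mx <- i
      } else if (x[mx] - x[i] > tol) {
        pts <- mx; dir <- -1L; mn <- i
      }
    } else if (dir == 1L) {
      if (x[mx] - x[i] > tol) {
        pts <- c(pts, mx); dir <- -1L; mn <- i
      }
    } else {
      if (x[i] - x[mn] > tol) {
        pts <- c(pts, mn); dir <- 1L; mx <- i
      }
    }
  }
  if (dir == 0L) return(integer(0))
  c(pts, if (dir == 1L) mx else mn)
}

#' Per-unit residence times of a pass
#'
#' Accumulates the time spent with x in each unit's half-open interval
#' `[(i-1) * unit_length, i * unit_length)`. Each inter-sample interval is
#' attributed to the unit of its left sample, so the per-unit times sum
#' exactly to the pass duration.
#'
#' @param pass A `pass` or [trajectory()].
#' @param geometry A [tube_geometry()].
#' @return Data.frame with `unit` and `residence_s`.
#' @export
residence_times <- function(pass, geometry = tube_geometry()) {
  tr <- if (inherits(pass, "pass")) pass$track else pass
  n <- geometry$n_units
  unit <- pmin(pmax(floor(tr$x / geometry$unit_length) + 1, 1), n)
  dt <- diff(tr$t)
  res <- vapply(seq_len(n), function(u) {
    sum(dt[unit[-length(unit)] == u])
  }, numeric(1))
  data.frame(unit = seq_len(n), residence_s = res)
}

#' Cross-sectional occupancy density
#'
#' 2-D histogram of the (y, z) samples pooled over passes, normalised to
#' total mass 1: where in the cross-section the tracer spends its time.
#'
#' @param passes A list of `pass` objects (or trajectories).
#' @param bin Bin width in m (default 0.001).
#' @return List with `y_breaks`, `z_breaks`, and matrix `density`
#'   (rows = y bins, cols = z bins) summing to 1.
#' @export
occupancy_density <- function(passes, bin = 0.001) {
  if (!length(passes)) stop("no passes", call. = FALSE)
  if (inherits(passes, c("pass", "trajectory"))) passes <- list(passes)
  tr <- do.call(rbind, lapply(passes, function(p) {
    d <- if (inherits(p, "pass")) p$track else p
    as.data.frame(d)[, c("y", "z")]
  }))
  ybr <- seq(floor(min(tr$y) / bin) * bin,
             ceiling(max(tr$y) / bin + 1e-12) * bin + bin, by = bin)
  zbr <- seq(floor(min(tr$z) / bin) * bin,
             ceiling(max(tr$z) / bin + 1e-12) * bin + bin, by = bin)
  yi <- findInterval(tr$y, ybr, rightmost.closed = TRUE)
  zi <- findInterval(tr$z, zbr, rightmost.closed = TRUE)
  dens <- matrix(0, nrow = length(ybr) - 1, ncol = length(zbr) - 1)
  for (k in seq_along(yi))
    dens[yi[k], zi[k]] <- dens[yi[k], zi[k]] + 1
  list(y_breaks = ybr, z_breaks = zbr, density = dens / sum(dens))
}

#' Distance-at-velocity histogram of propulsive displacements
#'
#' Bins the signed displacement velocities and reports, per bin, the total
#' distance covered (sum of |dx|), antegrade and retrograde separately.
#'
#' @param displacements Data.frame from
#'   [detect_propulsive_displacements()] (rows from several passes may be
#'   concatenated).
#' @param velocity_bin Velocity bin width in cm/s (default 0.1).
#' @return Data.frame with `velocity_cm_s` (bin centre, signed),
#'   `direction`, `distance_cm`.
#' @export
distance_velocity_histogram <- function(displacements,
                                        velocity_bin = 0.1) {
  if (!NROW(displacements))
    return(data.frame(velocity_cm_s = numeric(0), direction = character(0),
                      distance_cm = numeric(0)))
  v <- displacements$U_x * 100           # cm/s
  ctr <- round(v / velocity_bin) * velocity_bin
  agg <- stats::aggregate(abs(displacements$dx) * 100,
                          by = list(velocity_cm_s = ctr,
                                    direction = displacements$direction),
                          FUN = sum)
  names(agg)[3] <- "distance_cm"
  agg[order(agg$velocity_cm_s), ]
}
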