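#' Simulation configuration
#'
#' Collects everything the seeded generators need. All generators are pure
#' functions of (config, seed): the same configuration and seed reproduce
#' identical output.
#'
#' @param geometry A [tube_geometry()].
#' @param kin A [unit_kinematics()].
#' @param protocol A [wave_protocol()].
#' @param fluid A [fluid_spec()].
#' @param particle A [particle_spec()].
#' @param sampling_rate Track sampling rate in Hz (default 4, several
#'   samples per second as in the tracking experiments).
#' @param noise_sigma Isotropic localisation noise s.d. in m (default
#'   5e-4, sub-millimetre).
#' @param D0 Axial dispersion coefficient of the reference fluid (fluid M)
#'   in m^2 s^-1 (default 2e-6); the actual coefficient scales as
#'   `D0 * mu_ref / mu_A`, so thinner fluids disperse more.
#' @param k_mix0 Inter-unit diffusive-exchange volume rate of the
#'   reference fluid, m^3 s^-1 (default 3e-8); scales as `1/mu_A` likewise.
#' @param exchange_rate0 Free-surface levelling conductance `G0` in
#'   m^3 s^-1 (default 6e-6, a levelling time of roughly two seconds for
#'   two adjacent half-filled units in the reference fluid); the actual
#'   conductance scales with `sqrt(mu_ref / mu_A)` and with the square of
#'   the narrower neighbouring lumen fraction.
#' @param backflow_coherence Fraction of the free-surface levelling flow
#'   that a tracked particle follows coherently (default 0.3). The
#'   membrane-driven expulsion is a focused jet the particle rides fully;
#'   the gravity-driven return runs as a bottom-concentrated recirculation
#'   of which a particle in the upper bulk samples only part, the
#'   remainder acting as dispersion.
#' @param area_map How an occlusion fraction maps to the lumen area:
#'   `"proportional"` (default; an occlusion degree of 0.4 removes 40 % of
#'   the luminal cross-section, matching how luminal occlusion is quoted)
#'   or `"chord"` (circular-segment area of a flat wall displaced
#'   `occlusion * max_membrane_displacement` into the lumen).
#' @param surface_factor Multiplier on the axial velocity of a floating
#'   particle (default 1; the preset 1.15 reproduces surface transport
#'   slightly faster than the wave).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(geometry = tube_geometry(),
                       kin = unit_kinematics(),
                       protocol = wave_protocol(),
                       fluid = fluid_presets()$M,
                       particle = particle_presets()$neutrally_buoyant,
                       sampling_rate = 4, noise_sigma = 5e-4,
                       D0 = 2e-6, k_mix0 = 3e-8, exchange_rate0 = 6e-6,
                       backflow_coherence = 0.3,
                       area_map = c("proportional", "chord"),
                       surface_factor = 1, seed = 1L) {
  area_map <- match.arg(area_map)
  stopifnot(sampling_rate > 0, noise_sigma >= 0, D0 >= 0, k_mix0 >= 0,
            exchange_rate0 >= 0, surface_factor > 0,
            backflow_coherence >= 0, backflow_coherence <= 1)
  structure(list(geometry = geometry, kin = kin, protocol = protocol,
                 fluid = fluid, particle = particle,
                 sampling_rate = sampling_rate, noise_sigma = noise_sigma,
                 D0 = D0, k_mix0 = k_mix0,
                 exchange_rate0 = exchange_rate0,
                 backflow_coherence = backflow_coherence,
                 area_map = area_map,
                 surface_factor = surface_factor,
                 mu_ref = fluid_presets()$M$apparent_viscosity_ref,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Cross-sectional area lost to a flat wall displaced a depth h into a
# circular lumen of radius r (circular-segment area); negative h bulges
# outwards and adds area.
segment_area <- function(h, r) {
  a <- abs(h)
  a <- pmin(a, 2 * r)
  seg <- r^2 * acos((r - a) / r) - (r - a) * sqrt(pmax(2 * r * a - a^2, 0))
  sign(h) * seg
}

#' Section-averaged flow from an occlusion field
#'
#' Reduces the wall motion in the half-filled tube to a 1-D compartment
#' model with exact volume bookkeeping. Each unit has a time-varying lumen
#' capacity (occlusion fraction mapped to a lumen area, proportionally by
#' default) and holds a fluid volume. Two exchange mechanisms move fluid
#' between adjacent units:
#'
#' * forced displacement: an inflating membrane displaces the fluid it
#'   contacts immediately; the displaced volume leaves through the two
#'   neighbouring interfaces in proportion to their openness (a constricted
#'   neighbour throttles its share, the peristaltic valve action);
#' * free-surface levelling: differences in fill fraction relax by a
#'   gravity-driven flux `G0 * gate^2 * (mu_ref / mu_A)^(1/2) * delta_f`,
#'   so a deflating membrane refills slowly — quickly in thin media
#'   (sloshing and backflow) and slowly in thick ones (plug flow).
#'
#' Both tube ends are closed (no flux) and total fluid volume is conserved
#' to machine precision. The reported `A` is the wetted cross-section
#' `V / unit_length`, so the discrete continuity relation
#' `dA/dt + dQ/dx = 0` holds exactly; `u = Q / A` is the section-mean
#' velocity at each interface. The two flux components are also reported
#' separately (`u_forced`, `u_level`): the membrane-driven component is a
#' coherent jet through the constriction that a tracked particle rides in
#' full, while the levelling component is a broad recirculating gravity
#' current of which a point particle samples only a fraction (see
#' `backflow_coherence` in [sim_config()]).
#'
#' @param field An `occlusion_field` from [propagate_wave()].
#' @param config A [sim_config()].
#' @return An object of class `flow_field`: `time`, interface positions
#'   `x` (length n_units + 1), matrices `Q` (m^3/s) and `u` (m/s)
#'   (interfaces x time), wetted areas `A` (units x time), lumen
#'   capacities `C` (m^3), `geometry`, `config`.
#' @export
flow_from_occlusion <- function(field, config = sim_config()) {
  stopifnot(inherits(field, "occlusion_field"))
  geo <- field$geometry
  r <- geo$lumen_diameter / 2
  A0 <- pi * r^2
  if (config$area_map == "chord") {
    h <- field$occlusion * geo$max_membrane_displacement
    A_lum <- A0 - segment_area(h, r)
    A_pist <- A0 - segment_area(pmax(h, 0), r)
  } else {
    A_lum <- A0 * (1 - field$occlusion)
    # only the membrane rising into the lumen acts as a piston; an
    # expanded pouch returning to neutral merely removes empty headroom
    A_pist <- A0 * (1 - pmax(field$occlusion, 0))
  }
  if (any(A_lum <= 0.01 * A0))
    stop("occlusion closes the lumen; reduce the occlusion degree",
         call. = FALSE)
  time <- field$time
  dt <- time[2] - time[1]
  nT <- length(time)
  n <- geo$n_units
  C <- A_lum * geo$unit_length              # capacities, n x nT
  Cp <- A_pist * geo$unit_length            # piston (floor-membrane) capacity
  C0 <- A0 * geo$unit_length
  mob <- sqrt(config$mu_ref / config$fluid$apparent_viscosity_ref)
  G <- config$exchange_rate0 * mob
  V <- rep(geo$fill_volume / n, n)
  Vt <- matrix(0, n, nT); Vt[, 1] <- V
  Qf <- matrix(0, n + 1, nT)                # forced (membrane jet) flux
  Ql <- matrix(0, n + 1, nT)                # free-surface levelling flux
  for (k in seq_len(nT - 1)) {
    flux_f <- numeric(n - 1)                # interior interfaces, i <-> i+1
    gate <- (pmin(C[-n, k], C[-1, k]) / C0)^2
    # forced displacement by inflating membranes
    dC <- Cp[, k + 1] - Cp[, k]
    for (i in which(dC < 0 & V > 0)) {
      # the membrane rises from the tube floor where the fluid lies, so
      # it displaces fluid volume one-to-one until the unit is drained
      disp <- min(-dC[i], V[i])
      wl <- if (i > 1) gate[i - 1] else 0
      wr <- if (i < n) gate[i] else 0
      if (wl + wr <= 0) next
      V[i] <- V[i] - disp
      if (i > 1) {
        dl <- disp * wl / (wl + wr)
        V[i - 1] <- V[i - 1] + dl
        flux_f[i - 1] <- flux_f[i - 1] - dl
      }
      if (i < n) {
        dr <- disp * wr / (wl + wr)
        V[i + 1] <- V[i + 1] + dr
        flux_f[i] <- flux_f[i] + dr
      }
    }
    # overfull units (membrane squeezing out the last fluid) spill over
    for (s in 1:3) {
      over <- which(V > C[, k + 1])
      if (!length(over)) break
      for (i in over) {
        ex <- V[i] - C[i, k + 1]
        wl <- if (i > 1) gate[i - 1] else 0
        wr <- if (i < n) gate[i] else 0
        if (wl + wr <= 0) next
        V[i] <- V[i] - ex
        if (i > 1) {
          dl <- ex * wl / (wl + wr)
          V[i - 1] <- V[i - 1] + dl
          flux_f[i - 1] <- flux_f[i - 1] - dl
        }
        if (i < n) {
          dr <- ex * wr / (wl + wr)
          V[i + 1] <- V[i + 1] + dr
          flux_f[i] <- flux_f[i] + dr
        }
      }
    }
    # gravity-driven levelling of fill fractions
    f <- V / C[, k + 1]
    q <- G * gate * (f[-n] - f[-1]) * dt
    q <- pmax(pmin(q, V[-n]), -V[-1])       # never overdraw a unit
    V <- V - c(q, 0) + c(0, q)
    Vt[, k + 1] <- V
    Qf[2:n, k] <- flux_f / dt
    Ql[2:n, k] <- q / dt
  }
  A_wet <- Vt / geo$unit_length
  A_if <- rbind(A_wet[1, , drop = FALSE],
                (A_wet[-1, , drop = FALSE] + A_wet[-n, , drop = FALSE]) / 2,
                A_wet[n, , drop = FALSE])
  A_if <- pmax(A_if, 1e-6)
  Q <- Qf + Ql
  # the levelling return runs as a shallow gravity current along the tube
  # floor; a particle in the bulk never sees it faster than the half-fill
  # section-mean speed, so its wetted area is floored at the resting value
  A_rest <- geo$fill_volume / (n * geo$unit_length)
  structure(list(time = time, x = seq(0, geo$total_length,
                                      by = geo$unit_length),
                 Q = Q, u = Q / A_if, u_forced = Qf / A_if,
                 u_level = Ql / pmax(A_if, A_rest), A = A_wet, C = C,
                 geometry = geo, config = config),
            class = "flow_field")
}

# Axial velocity at (x, time-index k) by linear interpolation between
# interfaces of a given interface-velocity matrix.
interp_velocity <- function(umat, xs, x, k) {
  x <- min(max(x, xs[1]), xs[length(xs)])
  i <- min(max(findInterval(x, xs), 1), length(xs) - 1)
  w <- (x - xs[i]) / (xs[i + 1] - xs[i])
  (1 - w) * umat[i, k] + w * umat[i + 1, k]
}

#' Simulate a Lagrangian particle track
#'
#' Advects a particle with the section-mean velocity plus a random-walk
#' axial dispersion `D = D0 * mu_ref / mu_A` (thinner fluids slosh and
#' disperse more; thicker fluids move as a plug). A floating particle
#' rides the free surface (z = 0) and moves axially at
#' `u * surface_factor`; a neutrally buoyant particle sits near 5 mm below
#' the surface and diffuses transversally within the lumen. The track is
#' sampled at `sampling_rate` with isotropic Gaussian localisation noise.
#' The tube is closed: the particle is clamped to the ends.
#'
#' @param flow A `flow_field` from [flow_from_occlusion()].
#' @param config A [sim_config()].
#' @param x0 Initial axial position in m (default: centre of unit 1).
#' @param t_end End of the simulation, s (default: end of the flow grid).
#' @return A [trajectory()] with the particle and fluid recorded.
#' @export
simulate_particle_track <- function(flow, config = sim_config(),
                                    x0 = NULL, t_end = NULL) {
  stopifnot(inherits(flow, "flow_field"))
  geo <- flow$geometry
  set.seed(config$seed)
  if (is.null(x0)) x0 <- geo$unit_length / 2
  time <- flow$time
  dt <- time[2] - time[1]
  if (is.null(t_end)) t_end <- time[length(time)]
  n_steps <- min(length(time), floor(t_end / dt) + 1)
  mu <- config$fluid$apparent_viscosity_ref
  D <- config$D0 * config$mu_ref / mu
  Dt <- D / 4                       # transverse dispersion, weaker
  floating <- config$particle$buoyancy == "floating"
  r <- geo$lumen_diameter / 2
  x <- numeric(n_steps); y <- numeric(n_steps); z <- numeric(n_steps)
  x[1] <- x0
  z[1] <- if (floating) 0 else -0.005
  sdx <- sqrt(2 * D * dt)
  sdt <- sqrt(2 * Dt * dt)
  xi <- stats::rnorm(n_steps - 1)
  if (!floating) {
    ey <- stats::rnorm(n_steps - 1); ez <- stats::rnorm(n_steps - 1)
  }
  fac <- if (floating) config$surface_factor else 1
  u_eff <- flow$u_forced + config$backflow_coherence * flow$u_level
  for (k in seq_len(n_steps - 1)) {
    u <- interp_velocity(u_eff, flow$x, x[k], k) * fac
    x[k + 1] <- reflect(x[k] + u * dt + sdx * xi[k], 0, geo$total_length)
    if (floating) {
      y[k + 1] <- y[k]
      z[k + 1] <- 0
    } else {
      y[k + 1] <- reflect(y[k] + sdt * ey[k], -r + 1e-3, r - 1e-3)
      z[k + 1] <- reflect(z[k] + sdt * ez[k], -r + 1e-3, 0)
    }
  }
  stride <- max(1, round(1 / (config$sampling_rate * dt)))
  idx <- seq(1, n_steps, by = stride)
  ns <- length(idx)
  noise <- function() stats::rnorm(ns, sd = config$noise_sigma)
  trajectory(time[idx], x[idx] + noise(), y[idx] + noise(),
             z[idx] + noise(), particle = config$particle,
             fluid_label = config$fluid$label)
}

reflect <- function(v, lo, hi) {
  if (v < lo) return(2 * lo - v)
  if (v > hi) return(2 * hi - v)
  v
}

#' Simulate compartmental tracer mixing
#'
#' Evolves the mass of a dissolved tracer over the ten units by upwind
#' advective exchange (driven by the interface fluxes of the flow field)
#' plus diffusive inter-unit exchange with volume rate
#' `k_mix0 * mu_ref / mu_A` (mixing weakens with viscosity, giving plug
#' flow and persistent hot spots in thick media). Mass transfers are
#' antisymmetric, so total mass is conserved to machine precision.
#'
#' @param flow A `flow_field`.
#' @param config A [sim_config()].
#' @param injection Unit receiving the initial unit mass (default 1, next
#'   to the simulated terminal ileum).
#' @param record_dt Interval at which compartment masses are recorded, s
#'   (default 1).
#' @return An object of class `tracer_state`: `time` (recorded frames),
#'   `mass` (units x frames), `config`.
#' @export
simulate_tracer <- function(flow, config = sim_config(), injection = 1,
                            record_dt = 1) {
  stopifnot(inherits(flow, "flow_field"))
  geo <- flow$geometry
  n <- geo$n_units
  time <- flow$time
  dt <- time[2] - time[1]
  m <- numeric(n); m[injection] <- 1
  V <- pmax(flow$A * geo$unit_length, 1e-9)  # guard nearly drained units
  mu <- config$fluid$apparent_viscosity_ref
  k_mix <- config$k_mix0 * config$mu_ref / mu
  every <- max(1, round(record_dt / dt))
  rec_idx <- seq(1, length(time), by = every)
  rec <- matrix(NA_real_, nrow = n, ncol = length(rec_idx))
  rec[, 1] <- m
  ri <- 2
  for (k in seq_len(length(time) - 1)) {
    c_unit <- m / V[, k]
    for (j in seq_len(n - 1)) {        # interior interfaces
      q <- flow$Q[j + 1, k]
      adv <- q * dt * if (q > 0) c_unit[j] else c_unit[j + 1]
      mix <- k_mix * dt * (c_unit[j + 1] - c_unit[j])
      amt <- adv - mix                 # net transfer j -> j+1
      amt <- max(min(amt, m[j]), -m[j + 1])
      m[j] <- m[j] - amt
      m[j + 1] <- m[j + 1] + amt
    }
    if (ri <= length(rec_idx) && (k + 1) == rec_idx[ri]) {
      rec[, ri] <- m
      ri <- ri + 1
    }
  }
  structure(list(time = time[rec_idx], mass = rec, config = config),
            class = "tracer_state")
}

#' Heterogeneity of a tracer distribution
#'
#' Coefficient of variation of the compartment masses at the final
#' recorded frame: 0 for a perfectly mixed tube, large when the tracer
#' sits in a few hot spots.
#'
#' @param state A `tracer_state`.
#' @return Dimensionless CV.
#' @export
tracer_heterogeneity <- function(state) {
  m <- state$mass[, ncol(state$mass)]
  stats::sd(m) / mean(m)
}

#' Simulate an in vivo-like haustral series
#'
#' Builds per-haustrum series (1 Hz, 120 s by default) containing
#' trapezoidal contraction events propagated across the haustra at a given
#' travel velocity, plus Gaussian measurement noise. The ground truth used
#' to generate each wave is attached as attribute `truth`.
#'
#' @param waves Data.frame with columns `direction` ("antegrade" or
#'   "retrograde"), `velocity_cm_s`, `occlusion_pct`, `onset` (s).
#' @param positions Haustral positions in cm (default 10 haustra spaced
#'   2.5 cm along a 25 cm caecum-ascending segment).
#' @param baseline Baseline measurement per haustrum (default 10, cm).
#' @param t_c Contraction (drop) duration, s (default 6).
#' @param hold Dwell at maximum occlusion, s (default 2).
#' @param t_r Relaxation (recovery) duration, s (default 20).
#' @param noise_sigma Measurement noise s.d. in the series units
#'   (default 0.1).
#' @param recording_length Recording length, s (default 120).
#' @param dt Sampling interval, s (default 1).
#' @param mode Measurement mode (default "length_cm").
#' @param seed RNG seed.
#' @return A [haustral_series()] with attribute `truth = waves`.
#' @export
simulate_haustral_series <- function(waves,
                                     positions = seq(1.25, by = 2.5,
                                                     length.out = 10),
                                     baseline = 10, t_c = 6, hold = 2,
                                     t_r = 20, noise_sigma = 0.1,
                                     recording_length = 120, dt = 1,
                                     mode = "length_cm", seed = 1L) {
  set.seed(seed)
  nh <- length(positions)
  time <- seq(0, recording_length - dt, by = dt)
  base <- rep_len(baseline, nh)
  vals <- matrix(rep(base, each = length(time)), nrow = nh, byrow = TRUE)
  if (NROW(waves)) {
    for (w in seq_len(nrow(waves))) {
      v <- waves$velocity_cm_s[w]
      stopifnot(v > 0)
      g <- waves$occlusion_pct[w] / 100
      p0 <- if (waves$direction[w] == "antegrade") min(positions)
            else max(positions)
      for (h in seq_len(nh)) {
        onset <- waves$onset[w] + abs(positions[h] - p0) / v
        if (onset > recording_length) next
        tt <- time - onset
        depth <- base[h] * g
        drop <- numeric(length(tt))
        up <- tt >= 0 & tt < t_c
        fl <- tt >= t_c & tt < t_c + hold
        dn <- tt >= t_c + hold & tt < t_c + hold + t_r
        drop[up] <- depth * tt[up] / t_c
        drop[fl] <- depth
        drop[dn] <- depth * (t_c + hold + t_r - tt[dn]) / t_r
        vals[h, ] <- vals[h, ] - drop
      }
    }
  }
  vals <- pmax(vals, 0.1 * min(base))  # floor: the lumen never vanishes
  if (noise_sigma > 0)
    vals <- vals + matrix(stats::rnorm(length(vals), sd = noise_sigma),
                          nrow = nh)
  vals <- pmax(vals, 0.05 * min(base))
  out <- haustral_series(vals, positions, mode = mode, dt = dt)
  attr(out, "truth") <- waves
  out
}
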