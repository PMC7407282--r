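#' Fluid specification
#'
#' Describes a test medium by its Herschel-Bulkley parameters and density.
#' The apparent viscosity stored in `apparent_viscosity_ref` is the value at
#' the reference shear rate (10 s^-1 by default throughout the package) and
#' is kept as an independent field: the preset fluids carry the apparent
#' viscosity as printed for them alongside the consistency/flow indices,
#' without forcing the two to be mutually consistent.
#'
#' @param label Short name, e.g. "L".
#' @param cmc_fraction NaCMC mass fraction (dimensionless), e.g. 0.0025 for
#'   0.25 % w/w.
#' @param yield_stress Yield stress tau_y in Pa (>= 0).
#' @param consistency Consistency index K in Pa s^n (>= 0).
#' @param flow_index Flow (power-law) index n, 0 < n <= 1.
#' @param density Fluid density in kg m^-3.
#' @param apparent_viscosity_ref Apparent viscosity at the reference shear
#'   rate, Pa s.
#' @return An object of class `fluid_spec`.
#' @export
fluid_spec <- function(label, cmc_fraction = NA_real_, yield_stress = 0,
                       consistency, flow_index, density = 1030,
                       apparent_viscosity_ref = NULL) {
  stopifnot(consistency >= 0, yield_stress >= 0,
            flow_index > 0, flow_index <= 1, density > 0)
  if (is.null(apparent_viscosity_ref)) {
    apparent_viscosity_ref <-
      (yield_stress + consistency * 10^flow_index) / 10
  }
  stopifnot(apparent_viscosity_ref > 0)
  structure(list(label = label, cmc_fraction = cmc_fraction,
                 yield_stress = yield_stress, consistency = consistency,
                 flow_index = flow_index, density = density,
                 apparent_viscosity_ref = apparent_viscosity_ref),
            class = "fluid_spec")
}

#' Particle specification
#'
#' @param label Short name.
#' @param density Particle density in kg m^-3.
#' @param diameter Particle diameter in m.
#' @param buoyancy One of "floating", "neutrally_buoyant", "sinking".
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(label, density, diameter,
                          buoyancy = c("neutrally_buoyant", "floating",
                                       "sinking")) {
  buoyancy <- match.arg(buoyancy)
  stopifnot(density > 0, diameter >= 0)
  structure(list(label = label, density = density, diameter = diameter,
                 buoyancy = buoyancy),
            class = "particle_spec")
}

#' Flow specification for a Reynolds-number calculation
#'
#' @param hydraulic_diameter Hydraulic diameter d_h in m.
#' @param mean_velocity Section-mean flow velocity in m s^-1.
#' @param fluid A [fluid_spec()].
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(hydraulic_diameter, mean_velocity, fluid) {
  stopifnot(hydraulic_diameter > 0, mean_velocity >= 0,
            inherits(fluid, "fluid_spec"))
  structure(list(hydraulic_diameter = hydraulic_diameter,
                 mean_velocity = mean_velocity, fluid = fluid),
            class = "flow_spec")
}

#' Herschel-Bulkley shear stress
#'
#' tau = tau_y + K * gamma_dot^n. At zero shear rate the yield stress is
#' returned.
#'
#' @param fluid A [fluid_spec()].
#' @param shear_rate Shear rate(s) in s^-1, >= 0.
#' @return Shear stress in Pa (vectorised over `shear_rate`).
#' @export
shear_stress <- function(fluid, shear_rate) {
  stopifnot(inherits(fluid, "fluid_spec"))
  if (any(shear_rate < 0))
    stop("shear_rate must be non-negative", call. = FALSE)
  fluid$yield_stress + fluid$consistency * shear_rate^fluid$flow_index
}

#' Apparent viscosity at a shear rate
#'
#' mu_A(gamma_dot) = tau(gamma_dot) / gamma_dot. The conventional reference
#' shear rate is 10 s^-1.
#'
#' @inheritParams shear_stress
#' @param shear_rate Shear rate in s^-1, strictly positive (default 10).
#' @return Apparent viscosity in Pa s.
#' @export
apparent_viscosity <- function(fluid, shear_rate = 10) {
  if (any(shear_rate <= 0))
    stop("apparent viscosity is undefined at zero shear rate",
         call. = FALSE)
  shear_stress(fluid, shear_rate) / shear_rate
}

#' Particle relaxation time
#'
#' t_o = rho_d d_d^2 / (18 mu_A): the timescale on which a particle adapts
#' to the surrounding fluid motion; smaller values mean a more faithful
#' flow tracer.
#'
#' @param particle A [particle_spec()].
#' @param mu_A Apparent viscosity in Pa s (strictly positive), or a
#'   [fluid_spec()] whose stored `apparent_viscosity_ref` is used.
#' @return Relaxation time in seconds.
#' @export
relaxation_time <- function(particle, mu_A) {
  stopifnot(inherits(particle, "particle_spec"))
  if (inherits(mu_A, "fluid_spec")) mu_A <- mu_A$apparent_viscosity_ref
  if (any(mu_A <= 0))
    stop("apparent viscosity must be positive", call. = FALSE)
  particle$density * particle$diameter^2 / (18 * mu_A)
}

#' Reynolds number of the tube flow
#'
#' Re = d_h * u_bar * rho / mu_A, with mu_A the fluid's apparent viscosity
#' at the reference shear rate.
#'
#' @param flow A [flow_spec()].
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(flow) {
  stopifnot(inherits(flow, "flow_spec"))
  mu <- flow$fluid$apparent_viscosity_ref
  if (mu <= 0) stop("apparent viscosity must be positive", call. = FALSE)
  flow$hydraulic_diameter * flow$mean_velocity * flow$fluid$density / mu
}

#' Fit a Herschel-Bulkley model to a flow curve
#'
#' Constrained nonlinear least squares of tau = tau_y + K gamma^n with
#' tau_y >= 0, K >= 0, 0 < n <= 1.5. Because the fit is non-convex in n, a
#' multi-start over n in {0.3, 0.6, 0.9} is used; ties are broken by lowest
#' residual norm, then lowest n.
#'
#' @param shear_rate Shear rates in s^-1 (>= 0, at least 4 distinct values).
#' @param shear_stress Measured shear stresses in Pa.
#' @return A list with `yield_stress`, `consistency`, `flow_index`,
#'   `residual_norm`, and the `fit` object of the winning start.
#' @export
fit_herschel_bulkley <- function(shear_rate, shear_stress) {
  if (length(shear_rate) != length(shear_stress))
    stop("shear_rate and shear_stress lengths differ", call. = FALSE)
  if (any(shear_rate < 0))
    stop("shear rates must be non-negative", call. = FALSE)
  if (length(unique(shear_rate)) < 4)
    stop("need at least 4 distinct shear rates to fit", call. = FALSE)
  if (diff(range(shear_stress)) <= .Machine$double.eps * max(abs(shear_stress), 1))
    stop("degenerate flow curve: shear stress is constant", call. = FALSE)
  dat <- data.frame(g = shear_rate, tau = shear_stress)
  k0 <- max(shear_stress) / max(max(shear_rate), 1)
  fits <- lapply(c(0.3, 0.6, 0.9), function(n0) {
    tryCatch(
      minpack.lm::nlsLM(
        tau ~ ty + K * g^n, data = dat,
        start = list(ty = 0, K = k0, n = n0),
        lower = c(0, 0, 1e-6), upper = c(Inf, Inf, 1.5),
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("Herschel-Bulkley fit failed", call. = FALSE)
  rn <- vapply(fits, function(f) sqrt(sum(stats::resid(f)^2)), numeric(1))
  nn <- vapply(fits, function(f) stats::coef(f)[["n"]], numeric(1))
  best <- order(rn, nn)[1]
  cf <- stats::coef(fits[[best]])
  list(yield_stress = unname(cf["ty"]), consistency = unname(cf["K"]),
       flow_index = unname(cf["n"]), residual_norm = rn[best],
       fit = fits[[best]])
}

#' Read a flow curve from delimited text
#'
#' Expects a header and two columns: shear rate (s^-1) and shear stress (Pa).
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return A data.frame with columns `shear_rate`, `shear_stress`.
#' @export
read_flow_curve <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(d) < 2) stop("flow curve needs two columns", call. = FALSE)
  stats::setNames(d[, 1:2], c("shear_rate", "shear_stress"))
}

#' Preset test fluids
#'
#' The three NaCMC media used in the tracking experiments: L (0.25 % w/w),
#' M (0.50 %) and H (0.75 %), with their measured consistency/flow indices
#' and printed apparent viscosities at 10 s^-1 (8, 106, 200 mPa s). The
#' printed apparent viscosity and the K/n pair are kept as independent
#' fields (see the methods vignette).
#'
#' @return Named list of [fluid_spec()] objects `L`, `M`, `H`.
#' @export
fluid_presets <- function() {
  list(
    L = fluid_spec("L", cmc_fraction = 0.0025, consistency = 0.04,
                   flow_index = 0.9, apparent_viscosity_ref = 0.008),
    M = fluid_spec("M", cmc_fraction = 0.0050, consistency = 0.20,
                   flow_index = 0.7, apparent_viscosity_ref = 0.106),
    H = fluid_spec("H", cmc_fraction = 0.0075, consistency = 0.83,
                   flow_index = 0.6, apparent_viscosity_ref = 0.200))
}

#' Preset tracer and reference particles
#'
#' The two 3 x 3 mm resin tracers (floating and neutrally buoyant) and the
#' two published magnetic capsules used for in vivo comparison: the 5.5 mm
#' diameter, 1.8 g cm^-3 pill and the 21 x 8 mm, 1.6 g cm^-3 capsule. For
#' the cylindrical tracers the relaxation-time diameter is taken as the
#' 3 mm particle size; for the capsules the printed transverse diameter.
#'
#' @return Named list of [particle_spec()] objects.
#' @export
particle_presets <- function() {
  list(
    floating = particle_spec("floating tracer", density = 946,
                             diameter = 3e-3, buoyancy = "floating"),
    neutrally_buoyant = particle_spec("neutrally buoyant tracer",
                                      density = 1050, diameter = 3e-3,
                                      buoyancy = "neutrally_buoyant"),
    magnetic_pill = particle_spec("magnetic pill", density = 1800,
                                  diameter = 5.5e-3, buoyancy = "sinking"),
    magnetic_capsule = particle_spec("magnetic capsule", density = 1600,
                                     diameter = 8e-3, buoyancy = "sinking"))
}
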