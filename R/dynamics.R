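#' Integrator settings
#'
#' All integrators are velocity-Verlet based with particle mass m = 1.
#' `thermostatted` couples the system to a single-chain Nose-Hoover
#' thermostat at `target_T`; `damped_zero_T` runs underdamped Langevin
#' dynamics at zero temperature (viscous force `-damping * v`, keeping the
#' inertia of the colloidal units); `conservative` applies no thermostat or
#' damping and is used to validate energy conservation.
#'
#' @param dt timestep, units tau.
#' @param mode one of `"damped_zero_T"`, `"thermostatted"`, `"conservative"`.
#' @param target_T target temperature (eps/k_B), thermostatted mode only.
#' @param damping drag coefficient (units zeta); the reduced time unit is
#'   defined with zeta = 1.
#' @param nh_tau Nose-Hoover relaxation time; defaults to `100 * dt`.
#' @param seed integer seed used wherever the integrator needs randomness
#'   (velocity initialization).
#' @return An object of class `integrator_settings`.
#' @export
integrator_settings <- function(dt = 0.005,
                                mode = c("damped_zero_T", "thermostatted",
                                         "conservative"),
                                target_T = NA_real_, damping = 1,
                                nh_tau = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(dt > 0, damping >= 0)
  if (mode == "thermostatted" && (is.na(target_T) || target_T <= 0))
    stop("thermostatted mode needs target_T > 0")
  if (!is.na(target_T) && target_T < 0) stop("target_T must be >= 0")
  if (is.null(nh_tau)) nh_tau <- 100 * dt
  structure(list(dt = dt, mode = mode, target_T = target_T,
                 damping = damping, nh_tau = nh_tau, seed = seed),
            class = "integrator_settings")
}

#' Kinetic temperature of a configuration
#'
#' Defined as `2 KE / (3 N k_B)` with no constraint-DOF correction.
#'
#' @param config a [gel_configuration()].
#' @return temperature in eps/k_B.
#' @export
kinetic_temperature <- function(config) {
  n <- nrow(config$velocities)
  if (n == 0) return(0)
  sum(config$velocities^2) / (3 * n)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Samples velocities at temperature `T` and removes the centre-of-mass
#' drift, so the total momentum is exactly zero.
#'
#' @param config a [gel_configuration()].
#' @param T temperature (eps/k_B).
#' @param seed optional integer seed.
#' @return the configuration with new velocities.
#' @export
initialize_velocities <- function(config, T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(config$positions)
  v <- matrix(rnorm(3 * n, sd = sqrt(T)), n, 3)
  if (n > 0) v <- sweep(v, 2, colMeans(v))
  config$velocities <- v
  config
}

# Shared driver around the C++ integrator. Returns the evolved config with
# attributes: "log" (data.frame time/T/PE/sigma_zx), "converged",
# "steps_done", "xi".
run_md <- function(config, table, settings, nsteps, mode_code,
                   strain_inc = numeric(0), log_stride = 0L,
                   anchors = NULL, tether_k = numeric(0),
                   stop_T = 0, check_stride = 100L, xi0 = 0) {
  stopifnot(inherits(config, "gel_config"),
            inherits(settings, "integrator_settings"))
  cm <- compile_table(table)
  sp <- species_codes(config, cm)
  anc <- if (is.null(anchors)) matrix(0, 0, 3) else as.matrix(anchors)
  n <- nrow(config$positions)
  if (nrow(anc) > 0 && length(tether_k) == 1L) tether_k <- rep(tether_k, n)
  if (nrow(anc) == 0) tether_k <- numeric(0)
  res <- cpp_md_run(config$positions, config$velocities, sp,
                    config$L, config$le_offset, config$accumulated_strain,
                    cm, mode_code, settings$dt, as.integer(nsteps),
                    if (is.na(settings$target_T)) 1 else settings$target_T,
                    settings$nh_tau, settings$damping, xi0,
                    strain_inc, as.integer(log_stride),
                    anc, tether_k, stop_T, as.integer(check_stride))
  out <- gel_configuration(res$positions, config$species, config$L,
                           res$velocities, res$le_offset,
                           res$accumulated_strain)
  log <- as.data.frame(res$log)
  names(log) <- c("time", "T", "PE", "sigma_zx")
  attr(out, "log") <- log
  attr(out, "converged") <- res$converged
  attr(out, "steps_done") <- res$steps_done
  attr(out, "xi") <- res$xi
  attr(out, "potential_energy") <- res$potential_energy
  attr(out, "sigma_zx") <- res$sigma_zx
  out
}

#' Run thermostatted dynamics
#'
#' Evolves the configuration for `duration` at the Nose-Hoover target
#' temperature of `settings`. If all velocities are zero they are first
#' drawn from the Maxwell-Boltzmann distribution at the target temperature
#' (seeded from `settings$seed`), so that the run is reproducible given the
#' seed. Over the second half of a sufficiently long run the time-averaged
#' kinetic temperature tracks the target to within a few percent.
#'
#' @param config a [gel_configuration()].
#' @param table an [interaction_table()].
#' @param settings an [integrator_settings()] with mode `"thermostatted"`.
#' @param duration simulated time, units tau (>= dt).
#' @param log_stride sample the run log every this many steps (0 = none).
#' @return the evolved configuration; attributes `log` (data.frame with
#'   time, T, PE, sigma_zx), `converged`, `steps_done`.
#' @export
run_thermostatted <- function(config, table, settings, duration,
                              log_stride = 0L) {
  stopifnot(settings$mode == "thermostatted", duration >= settings$dt)
  if (all(config$velocities == 0) && nrow(config$positions) > 0)
    config <- initialize_velocities(config, settings$target_T, settings$seed)
  run_md(config, table, settings, nsteps = round(duration / settings$dt),
         mode_code = 1L, log_stride = log_stride)
}

#' Drain kinetic energy at zero temperature
#'
#' Underdamped dissipative dynamics (viscous force `-damping * v`) run until
#' the kinetic temperature falls below `stop_T`; the returned structure is
#' an inherent-structure proxy, i.e. a local minimum of the energy
#' landscape with small residual per-particle forces.
#'
#' @inheritParams run_thermostatted
#' @param stop_T kinetic temperature threshold (eps/k_B).
#' @param max_time step budget expressed as simulated time (tau); failing to
#'   reach `stop_T` within it raises an error reporting the final T.
#' @param anchors optional N x 3 matrix of harmonic tether anchor points.
#' @param tether_k tether stiffness (eps/d^2), used when `anchors` given.
#' @return the relaxed configuration (attributes as in
#'   [run_thermostatted()]).
#' @export
run_damped_zero_T <- function(config, table, settings, stop_T = 1e-10,
                              max_time = 5e3, log_stride = 0L,
                              anchors = NULL, tether_k = 1) {
  stopifnot(settings$mode == "damped_zero_T", settings$damping > 0)
  out <- run_md(config, table, settings,
                nsteps = round(max_time / settings$dt), mode_code = 2L,
                log_stride = log_stride, anchors = anchors,
                tether_k = tether_k, stop_T = stop_T, check_stride = 50L)
  if (!attr(out, "converged"))
    stop(sprintf(paste0("damped drain did not reach stop_T = %g within %g tau",
                        " (final T = %g eps/k_B)"),
                 stop_T, max_time, kinetic_temperature(out)))
  out
}

#' Run conservative dynamics
#'
#' Plain velocity-Verlet with no thermostat or damping; total energy is
#' conserved to O(dt^2) and the drift shrinks ~4x when the timestep is
#' halved.
#'
#' @inheritParams run_thermostatted
#' @export
run_conservative <- function(config, table, settings, duration,
                             log_stride = 0L) {
  stopifnot(settings$mode == "conservative", duration >= settings$dt)
  run_md(config, table, settings, nsteps = round(duration / settings$dt),
         mode_code = 0L, log_stride = log_stride)
}
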