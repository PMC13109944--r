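#' Optimally windowed chirp strain signal
#'
#' Builds the exponentially swept oscillatory strain used to extract a
#' broadband viscoelastic spectrum from a single run: the instantaneous
#' frequency grows exponentially from `omega_lo` to `omega_hi` over
#' `T_total`, and the amplitude is enclosed in a symmetric raised-cosine
#' (Tukey) taper covering `taper_fraction` of each end, so the strain
#' starts and ends at zero. The signal is normalized so its maximum
#' amplitude is exactly `gamma0`.
#'
#' @param T_total total signal duration (tau); must cover at least one
#'   period of `omega_lo`.
#' @param gamma0 peak strain amplitude (dimensionless); the default 0.01 is
#'   within the linear regime of the gels modeled here.
#' @param omega_lo,omega_hi frequency sweep range (1/tau), `omega_lo <
#'   omega_hi`.
#' @param taper_fraction fraction of each end covered by the raised-cosine
#'   taper.
#' @param dt sampling interval = integrator timestep (tau).
#' @return An object of class `chirp_signal`: list with `times`, `gamma`
#'   and the generating parameters.
#' @export
owch_strain_signal <- function(T_total, gamma0 = 0.01, omega_lo = 0.05,
                               omega_hi = 5, taper_fraction = 0.1,
                               dt = 0.005) {
  stopifnot(omega_lo > 0, omega_hi > omega_lo, gamma0 > 0,
            taper_fraction > 0, taper_fraction <= 0.5)
  if (T_total < 2 * pi / omega_lo)
    stop("T_total shorter than one period of omega_lo")
  times <- seq(0, T_total, by = dt)
  Te <- T_total / log(omega_hi / omega_lo)
  phase <- omega_lo * Te * (exp(times / Te) - 1)
  a <- taper_fraction * T_total
  win <- rep(1, length(times))
  lo <- times < a
  hi <- times > T_total - a
  win[lo] <- 0.5 * (1 - cos(pi * times[lo] / a))
  win[hi] <- 0.5 * (1 - cos(pi * (T_total - times[hi]) / a))
  g <- win * sin(phase)
  g <- gamma0 * g / max(abs(g))
  structure(list(times = times, gamma = g, gamma0 = gamma0,
                 omega_lo = omega_lo, omega_hi = omega_hi,
                 taper_fraction = taper_fraction, dt = dt,
                 T_total = T_total),
            class = "chirp_signal")
}

#' @export
print.chirp_signal <- function(x, ...) {
  cat(sprintf(paste0("<chirp_signal> %g tau, gamma0 = %g, ",
                     "omega %g -> %g 1/tau, taper %g\n"),
              x$T_total, x$gamma0, x$omega_lo, x$omega_hi, x$taper_fraction))
  invisible(x)
}

#' Viscoelastic spectrum under Lees-Edwards oscillatory shear
#'
#' Drives the configuration with the chirp strain at zero temperature with
#' viscous damping, records the zx virial stress, Fourier transforms stress
#' and strain, and reports the storage and loss moduli as the real and
#' imaginary parts of the transform ratio,
#' \eqn{G^*(\omega) = \tilde\sigma(\omega)/\tilde\gamma(\omega)},
#' on a log-spaced subsample of frequency bins inside the sweep range. The
#' spectrum is truncated at the crossover frequency `omega_c` where G''
#' first crosses G' (inertial resonance lies beyond); if no crossover is
#' found the spectrum is returned untruncated with `omega_c = NA`.
#'
#' @param config a [gel_configuration()], normally an inherent structure.
#' @param table an [interaction_table()].
#' @param signal an [owch_strain_signal()]; its `dt` becomes the timestep.
#' @param settings an [integrator_settings()] with mode `"damped_zero_T"`;
#'   only `damping` is used (the timestep comes from the signal).
#' @param n_freq number of log-spaced frequency bins to report.
#' @param truncate if `FALSE`, keep frequencies beyond the crossover.
#' @param anchors,tether_k optional harmonic tethers to fixed lab-frame
#'   points (N x 3 matrix; scalar or per-particle stiffness, eps/d^2).
#'   Their virial enters the recorded stress; used e.g. to validate the
#'   rheometer against a single tethered particle with a closed-form
#'   response.
#' @return An object of class `viscoelastic_spectrum`: `omega`, `G_prime`,
#'   `G_double_prime` (eps/d^3), `omega_c`, plus the raw sampled time
#'   series in `series`.
#' @export
measure_spectrum <- function(config, table, signal,
                             settings = integrator_settings(dt = signal$dt),
                             n_freq = 60, truncate = TRUE,
                             anchors = NULL, tether_k = 0) {
  stopifnot(inherits(signal, "chirp_signal"),
            settings$mode == "damped_zero_T")
  settings$dt <- signal$dt
  nsteps <- length(signal$gamma) - 1L
  stride <- max(1L, floor((2 * pi / signal$omega_hi) / 16 / signal$dt))
  out <- run_md(config, table, settings, nsteps = nsteps, mode_code = 2L,
                strain_inc = diff(signal$gamma), log_stride = stride,
                anchors = anchors,
                tether_k = if (is.null(anchors)) numeric(0) else tether_k,
                stop_T = 0)
  log <- attr(out, "log")
  ts <- log$time
  sig <- log$sigma_zx - log$sigma_zx[1]
  gam <- approx(signal$times, signal$gamma, xout = ts, rule = 2)$y
  n <- length(ts)
  ds <- stride * signal$dt
  sig_f <- fft(sig)
  gam_f <- fft(gam)
  omega_all <- 2 * pi * (seq_len(n) - 1) / (n * ds)
  want <- exp(seq(log(signal$omega_lo), log(signal$omega_hi),
                  length.out = n_freq))
  idx <- unique(vapply(want, function(w) which.min(abs(omega_all - w)), 1L))
  idx <- idx[idx > 1 & omega_all[idx] <= pi / ds]  # skip DC, below Nyquist
  Gstar <- sig_f[idx] / gam_f[idx]
  spec <- new_spectrum(omega_all[idx], Re(Gstar), Im(Gstar))
  spec$omega_c <- crossover_frequency(spec)
  if (truncate && !is.na(spec$omega_c)) {
    keep <- spec$omega <= spec$omega_c
    spec$omega <- spec$omega[keep]
    spec$G_prime <- spec$G_prime[keep]
    spec$G_double_prime <- spec$G_double_prime[keep]
  }
  spec$series <- data.frame(time = ts, strain = gam, stress = sig)
  spec$gamma0 <- signal$gamma0
  spec
}

new_spectrum <- function(omega, G_prime, G_double_prime, omega_c = NA_real_) {
  o <- order(omega)
  structure(list(omega = omega[o], G_prime = G_prime[o],
                 G_double_prime = G_double_prime[o], omega_c = omega_c),
            class = "viscoelastic_spectrum")
}

#' @export
print.viscoelastic_spectrum <- function(x, ...) {
  cat(sprintf("<viscoelastic_spectrum> %d frequencies in [%.3g, %.3g] 1/tau\n",
              length(x$omega), min(x$omega), max(x$omega)))
  cat(sprintf("  omega_c = %s 1/tau, low-frequency G' = %.3g eps/d^3\n",
              if (is.na(x$omega_c)) "not found" else format(x$omega_c,
                                                            digits = 3),
              if (length(x$G_prime)) x$G_prime[1] else NA))
  invisible(x)
}

#' @export
plot.viscoelastic_spectrum <- function(x, ...) {
  keep <- x$G_prime > 0 | x$G_double_prime > 0
  matplot(x$omega[keep],
          cbind(pmax(x$G_prime[keep], NA), pmax(x$G_double_prime[keep], NA)),
          log = "xy", type = "b", pch = c(16, 1), lty = 1,
          xlab = "omega (1/tau)", ylab = "G', G'' (eps/d^3)", ...)
  if (!is.na(x$omega_c)) abline(v = x$omega_c, lty = 3)
  legend("bottomright", c("G'", "G''"), pch = c(16, 1), bty = "n")
  invisible(x)
}

#' Crossover frequency of a viscoelastic spectrum
#'
#' Lowest frequency at which the loss modulus G'' crosses the storage
#' modulus G', located by log-log linear interpolation between the
#' bracketing samples (falling back to linear interpolation when a modulus
#' is non-positive at the bracket).
#'
#' @param spectrum a `viscoelastic_spectrum`, or anything with fields
#'   `omega`, `G_prime`, `G_double_prime`.
#' @return the crossover frequency (1/tau), or `NA` if the two moduli do
#'   not cross in the sampled range.
#' @examples
#' # synthetic Maxwell element with relaxation time 10 tau crosses at 0.1
#' om <- 10^seq(-3, 1, length.out = 200)
#' sp <- list(omega = om, G_prime = om^2 * 100 / (1 + om^2 * 100),
#'            G_double_prime = om * 10 / (1 + om^2 * 100))
#' crossover_frequency(sp)
#' @export
crossover_frequency <- function(spectrum) {
  om <- spectrum$omega
  d <- spectrum$G_double_prime - spectrum$G_prime
  s <- sign(d)
  ix <- which(s[-1] * s[-length(s)] < 0)
  if (!length(ix)) {
    if (any(d == 0)) return(om[which(d == 0)[1]])
    return(NA_real_)
  }
  i <- ix[1]
  g1 <- spectrum$G_prime[c(i, i + 1)]
  g2 <- spectrum$G_double_prime[c(i, i + 1)]
  if (all(g1 > 0) && all(g2 > 0)) {
    x <- log(om[c(i, i + 1)])
    f <- log(g2) - log(g1)
    exp(x[1] - f[1] * (x[2] - x[1]) / (f[2] - f[1]))
  } else {
    x <- om[c(i, i + 1)]
    f <- d[c(i, i + 1)]
    x[1] - f[1] * (x[2] - x[1]) / (f[2] - f[1])
  }
}

#' Quasistatic plateau modulus
#'
#' The zero-frequency (plateau) shear modulus of an inherent structure,
#' measured by applying strain steps of +gamma and -gamma, relaxing each
#' strained copy to the damped zero-temperature criterion, and taking the
#' symmetric stress difference: `G0 = (sigma(+gamma) - sigma(-gamma)) /
#' (2 gamma)`. For a gel this equals the low-frequency plateau of the
#' storage modulus G'.
#'
#' @param config a [gel_configuration()] (an inherent structure).
#' @param table an [interaction_table()].
#' @param gamma probe strain (linear regime).
#' @param settings an [integrator_settings()] with mode `"damped_zero_T"`.
#' @param stop_T relaxation threshold for the strained copies.
#' @param max_time relaxation budget per branch (tau).
#' @return plateau modulus in eps/d^3.
#' @export
plateau_modulus <- function(config, table, gamma = 0.01,
                            settings = integrator_settings(),
                            stop_T = 1e-8, max_time = 2e4) {
  stopifnot(settings$mode == "damped_zero_T")
  sig <- function(g) {
    c2 <- apply_strain_step(config, g)
    c2 <- run_damped_zero_T(c2, table, settings, stop_T = stop_T,
                            max_time = max_time)
    attr(c2, "sigma_zx")
  }
  (sig(gamma) - sig(-gamma)) / (2 * gamma)
}

#' Central-difference differential modulus
#'
#' Given post-relaxation stresses on the uniform strain grid `n *
#' delta_gamma`, returns `K(sigma_n) = (sigma_(n+1) - sigma_(n-1)) / (2
#' delta_gamma)` for the interior points.
#'
#' @param sigma stresses at strains `0, delta_gamma, 2 delta_gamma, ...`
#'   (eps/d^3).
#' @param delta_gamma strain-step size.
#' @return data.frame with `strain`, `sigma` and `K` for interior points.
#' @export
differential_modulus <- function(sigma, delta_gamma) {
  n <- length(sigma)
  if (n < 3) stop("need at least three stress samples")
  i <- 2:(n - 1)
  data.frame(strain = (i - 1) * delta_gamma, sigma = sigma[i],
             K = (sigma[i + 1] - sigma[i - 1]) / (2 * delta_gamma))
}

#' Start-up shear: differential modulus versus stress
#'
#' Applies alternating strain steps of size `delta_gamma` and zero-
#' temperature damped relaxations of duration `delta_t`, recording the
#' post-relaxation zx stress after each step, and computes the
#' differential modulus K(sigma_n) by central differences over the strain
#' grid. The effective rate `delta_gamma / delta_t` should stay below
#' `gamma0 * omega_c` of the system for the response to be quasistatic; if
#' `omega_c` is supplied and the condition is violated a warning is issued
#' and recorded in the result.
#'
#' @param config a [gel_configuration()] (an inherent structure).
#' @param table an [interaction_table()].
#' @param delta_gamma strain-step size.
#' @param delta_t relaxation time per step (tau).
#' @param n_steps number of strain steps.
#' @param settings an [integrator_settings()] with mode `"damped_zero_T"`.
#' @param omega_c optional crossover frequency used for the rate check.
#' @param gamma0 linear-regime amplitude used in the rate check.
#' @return An object of class `stiffening_curve`: `sigma` and `K` at the
#'   interior strain grid points, the full stress sequence `sigma_all`,
#'   `delta_gamma`, `delta_t`, and `rate_ok`.
#' @export
startup_shear <- function(config, table, delta_gamma = 0.01, delta_t = 1000,
                          n_steps = 10,
                          settings = integrator_settings(),
                          omega_c = NULL, gamma0 = 0.01) {
  stopifnot(settings$mode == "damped_zero_T", delta_gamma > 0, delta_t > 0,
            n_steps >= 3)
  rate_ok <- NA
  if (!is.null(omega_c) && is.finite(omega_c)) {
    rate_ok <- delta_gamma / delta_t < gamma0 * omega_c
    if (!rate_ok)
      warning("effective rate delta_gamma/delta_t exceeds gamma0 * omega_c; ",
              "the response may not be quasistatic")
  }
  fs <- compute_forces_stress(config, table)
  sigma <- numeric(n_steps + 1)
  sigma[1] <- fs$stress[3, 1]
  relax_steps <- round(delta_t / settings$dt)
  for (n in seq_len(n_steps)) {
    config <- apply_strain_step(config, delta_gamma)
    config <- run_md(config, table, settings, nsteps = relax_steps,
                     mode_code = 2L, stop_T = 0)
    sigma[n + 1] <- attr(config, "sigma_zx")
  }
  km <- differential_modulus(sigma, delta_gamma)
  structure(list(sigma = km$sigma, K = km$K, strain = km$strain,
                 sigma_all = sigma, delta_gamma = delta_gamma,
                 delta_t = delta_t, rate_ok = rate_ok,
                 final_config = config),
            class = "stiffening_curve")
}

#' @export
print.stiffening_curve <- function(x, ...) {
  cat(sprintf(paste0("<stiffening_curve> %d strain steps of %g ",
                     "(delta_t = %g tau)\n"),
              length(x$sigma_all) - 1, x$delta_gamma, x$delta_t))
  cat(sprintf("  K range: [%.3g, %.3g] eps/d^3\n", min(x$K), max(x$K)))
  invisible(x)
}

#' @export
plot.stiffening_curve <- function(x, ...) {
  keep <- x$sigma > 0 & x$K > 0
  plot(x$sigma[keep], x$K[keep], log = "xy", type = "b", pch = 16,
       xlab = "sigma (eps/d^3)", ylab = "K (eps/d^3)", ...)
  invisible(x)
}
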