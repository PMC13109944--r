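#' Reduced-to-physical unit mapping
#'
#' The simulation works in reduced units: particle size d (length), bond
#' energy eps (energy) and solvent drag zeta (momentum/velocity). The
#' derived time unit tau = zeta d^2 / eps is the time over which a particle
#' pulled with force eps/d against drag zeta moves a distance d, and the
#' stress unit is eps/d^3. With the defaults -- micron-sized building
#' blocks, eps = 100 k_B T at T = 300 K, and Stokes drag of a 1-micron
#' sphere in water (zeta = 3 pi eta d, eta = 1 mPa s) -- the stress unit is
#' about 0.4 Pa and tau about 2e-2 s.
#'
#' @param d_phys physical length of the reduced unit d, in metres.
#' @param eps_phys physical energy of the reduced unit eps, in joules.
#' @param zeta_phys physical drag coefficient, in kg/s.
#' @return An object of class `unit_system` with fields `d_phys`,
#'   `eps_phys`, `zeta_phys` and derived `tau_phys` (s) and `stress_unit`
#'   (Pa).
#' @examples
#' u <- unit_system()
#' u$stress_unit   # ~0.4 Pa
#' u$tau_phys      # ~2e-2 s
#' @export
unit_system <- function(d_phys = 1e-6,
                        eps_phys = 100 * 1.380649e-23 * 300,
                        zeta_phys = 3 * pi * 1e-3 * 1e-6) {
  if (d_phys <= 0 || eps_phys <= 0 || zeta_phys <= 0)
    stop("all unit primitives must be positive")
  structure(list(d_phys = d_phys, eps_phys = eps_phys, zeta_phys = zeta_phys,
                 tau_phys = zeta_phys * d_phys^2 / eps_phys,
                 stress_unit = eps_phys / d_phys^3),
            class = "unit_system")
}

#' @export
print.unit_system <- function(x, ...) {
  cat(sprintf("<unit_system> d = %.3g m, eps = %.3g J, zeta = %.3g kg/s\n",
              x$d_phys, x$eps_phys, x$zeta_phys))
  cat(sprintf("  tau = %.3g s, stress unit eps/d^3 = %.3g Pa\n",
              x$tau_phys, x$stress_unit))
  invisible(x)
}

#' Convert a reduced-unit value to SI
#'
#' @param value numeric vector in reduced units.
#' @param quantity one of `"length"`, `"energy"`, `"time"`, `"stress"`,
#'   `"frequency"`.
#' @param units a [unit_system()].
#' @return numeric vector in SI units (m, J, s, Pa, 1/s).
#' @examples
#' to_physical(1, "stress")     # ~0.4 Pa
#' to_physical(1, "time")       # ~2e-2 s
#' @export
to_physical <- function(value, quantity, units = unit_system()) {
  stopifnot(inherits(units, "unit_system"))
  fac <- switch(match.arg(quantity,
                          c("length", "energy", "time", "stress", "frequency")),
                length = units$d_phys,
                energy = units$eps_phys,
                time = units$tau_phys,
                stress = units$stress_unit,
                frequency = 1 / units$tau_phys)
  value * fac
}
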