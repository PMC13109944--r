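#' Two-body potential and radial force
#'
#' The pair interaction is a steep 18-16 potential,
#' \deqn{E_2(r) = A\,\epsilon\,[(d_2/r)^{18} - (d_2/r)^{16}]\,H(r_{cut}-r),}
#' with a strong repulsive core below its minimum at
#' \eqn{r_{min} = \sqrt{9/8}\, d_2 \approx 1.06\, d_2} (so beads of
#' diameter ~d for d2 = 0.922 d) and a short attractive tail cut off at
#' `r_cut`, beyond which the energy is exactly zero. The depth at the
#' minimum is about -0.043 A eps; the untruncated value at r_cut = 2 d is
#' about -3.3e-6 A eps.
#'
#' `pair_force()` returns the radial force \eqn{-dE_2/dr} (positive =
#' repulsive), zero beyond the cutoff.
#'
#' @param r separation(s), units d; must be > 0.
#' @param A two-body strength (dimensionless multiplier of eps).
#' @param geometry a [species_params()] (only `d2` and `r_cut` are used) or
#'   a list with `d2` and `r_cut`.
#' @return energy in eps (`pair_energy`) or radial force in eps/d
#'   (`pair_force`), vectorized over `r`.
#' @examples
#' r_min <- sqrt(9 / 8) * 0.922
#' pair_energy(r_min, A = 23)   # ~ -1 eps
#' pair_force(r_min, A = 23)    # 0 at the minimum
#' @export
pair_energy <- function(r, A, geometry = list(d2 = 0.922, r_cut = 2.0)) {
  if (any(r <= 0)) stop("separation r must be positive")
  x <- geometry$d2 / r
  ifelse(r <= geometry$r_cut, A * (x^18 - x^16), 0)
}

#' @rdname pair_energy
#' @export
pair_force <- function(r, A, geometry = list(d2 = 0.922, r_cut = 2.0)) {
  if (any(r <= 0)) stop("separation r must be positive")
  x <- geometry$d2 / r
  ifelse(r <= geometry$r_cut, (A / r) * (18 * x^18 - 16 * x^16), 0)
}

#' Radial weight of the three-body term
#'
#' \deqn{\Lambda(r) = (d_3/r)^{10}\,[1 - (r/r_{cut})^{10}]^2\,H(r_{cut}-r).}
#' It diverges at contact, decays over the bond length `d3` and vanishes
#' smoothly at the cutoff, restricting the angular repulsion to bonded
#' neighbours.
#'
#' @param r separation(s), units d; must be > 0.
#' @param geometry a [species_params()] or list with `d3` and `r_cut`.
#' @return dimensionless weight, vectorized over `r`.
#' @examples
#' lambda_radial(1.1)  # ~0.9948
#' @export
lambda_radial <- function(r, geometry = list(d3 = 1.1, r_cut = 2.0)) {
  if (any(r <= 0)) stop("separation r must be positive")
  u <- (r / geometry$r_cut)^10
  ifelse(r <= geometry$r_cut, (geometry$d3 / r)^10 * (1 - u)^2, 0)
}

#' Three-body angular energy of one triplet
#'
#' For a central particle i bonded to j and k through vectors `r_ij` and
#' `r_ik`,
#' \deqn{E_3 = B\,\epsilon\,\Lambda(r_{ij})\Lambda(r_{ik})
#'       \exp\{-[(\cos\theta_{ijk} - \cos\bar\theta)/w]^2\},}
#' a purely repulsive term that is strongest when the bond angle cosine is
#' within `w` of the preferred value, thereby carving out the favourable
#' bond angles in combination with the two-body attraction.
#'
#' @param r_ij,r_ik length-3 bond vectors from the central particle (units d).
#' @param B three-body strength.
#' @param cos_theta_bar preferred bond-angle cosine (ignored when `B = 0`).
#' @param w angular width.
#' @param geometry a [species_params()] or list with `d3` and `r_cut`.
#' @return energy in eps (always >= 0).
#' @export
triplet_energy <- function(r_ij, r_ik, B, cos_theta_bar, w = 0.3,
                           geometry = list(d3 = 1.1, r_cut = 2.0)) {
  r1 <- sqrt(sum(r_ij^2)); r2 <- sqrt(sum(r_ik^2))
  if (r1 == 0 || r2 == 0) stop("zero-length bond vector")
  if (B == 0) return(0)
  cth <- sum(r_ij * r_ik) / (r1 * r2)
  B * lambda_radial(r1, geometry) * lambda_radial(r2, geometry) *
    exp(-((cth - cos_theta_bar) / w)^2)
}

#' Forces, potential energy and virial stress of a configuration
#'
#' Evaluates the total energy (sum of the pair term over all i < j pairs
#' and the three-body term over every central particle with each unordered
#' neighbour pair counted once), the forces `-grad E`, and the 3 x 3 virial
#' stress tensor assembled from per-interaction relative coordinates, which
#' is exact under (Lees-Edwards) periodic boundaries. The zx component
#' equals the strain derivative of the energy per unit volume, so positive
#' shear stress means the configuration resists the applied strain.
#'
#' @param config a [gel_configuration()]; all cutoffs must satisfy
#'   `r_cut <= L / 2` for minimum-image validity.
#' @param table an [interaction_table()] covering every species present.
#' @return An object of class `forces_stress`: list with `forces` (N x 3,
#'   eps/d), `potential_energy` (eps) and `stress` (3 x 3, eps/d^3).
#' @examples
#' tab <- interaction_table(list(species_params("M0", 23, 10, 0.4226)))
#' r_min <- sqrt(9 / 8) * 0.922
#' cfg <- gel_configuration(rbind(c(2, 2, 2), c(2 + r_min, 2, 2)), "M0", L = 8)
#' compute_forces_stress(cfg, tab)$potential_energy  # ~ -1 eps
#' @export
compute_forces_stress <- function(config, table) {
  stopifnot(inherits(config, "gel_config"), is.interaction_table(table))
  cm <- compile_table(table)
  sp <- species_codes(config, cm)
  res <- cpp_forces_stress(config$positions, sp, config$L, config$le_offset, cm)
  structure(res, class = "forces_stress")
}

#' @export
print.forces_stress <- function(x, ...) {
  n <- nrow(x$forces)
  cat(sprintf("<forces_stress> N = %d, E = %.6g eps\n", n, x$potential_energy))
  if (n) cat(sprintf("  max |F| = %.3g eps/d, sigma_zx = %.3g eps/d^3\n",
                     max(sqrt(rowSums(x$forces^2))), x$stress[3, 1]))
  invisible(x)
}
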