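#' Particle configuration with a Lees-Edwards periodic box
#'
#' Holds positions, species labels and velocities of N particles in a cubic
#' periodic box of side `L`. Under shear the periodic images above/below the
#' box in the gradient direction (z) are shifted in the flow direction (x)
#' by `le_offset = gamma * L` modulo `L`; `accumulated_strain` tracks the
#' total applied strain.
#'
#' @param positions N x 3 matrix of coordinates (units d).
#' @param species character vector of N species labels.
#' @param L box side length (units d).
#' @param velocities N x 3 matrix (units d/tau); defaults to zeros.
#' @param le_offset Lees-Edwards image shift in x (units d), |le_offset| < L.
#' @param accumulated_strain total strain applied so far (dimensionless).
#' @return An object of class `gel_config`.
#' @export
gel_configuration <- function(positions, species, L, velocities = NULL,
                              le_offset = 0, accumulated_strain = 0) {
  positions <- as.matrix(positions)
  if (length(positions) == 0) positions <- matrix(0, 0, 3)
  stopifnot(ncol(positions) == 3, is.numeric(L), L > 0,
            is.finite(le_offset))
  n <- nrow(positions)
  species <- as.character(species)
  if (length(species) == 1L && n > 1L) species <- rep(species, n)
  stopifnot(length(species) == n)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  if (length(velocities) == 0) velocities <- matrix(0, 0, 3)
  stopifnot(nrow(velocities) == n, ncol(velocities) == 3)
  cfg <- structure(list(positions = unname(positions), species = species,
                        velocities = unname(velocities), L = L,
                        le_offset = le_offset,
                        accumulated_strain = accumulated_strain),
                   class = "gel_config")
  wrap_configuration(cfg)
}

#' @export
print.gel_config <- function(x, ...) {
  tab <- table(x$species)
  cat(sprintf("<gel_config> N = %d in L = %g d box", nrow(x$positions), x$L))
  if (length(tab))
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  cat("\n")
  cat(sprintf("  le_offset = %g d, accumulated strain = %g\n",
              x$le_offset, x$accumulated_strain))
  invisible(x)
}

#' @export
summary.gel_config <- function(object, ...) {
  print(object)
  cat(sprintf("  volume fraction (r = 0.5 d spheres): %.4f\n",
              volume_fraction(object)))
  invisible(object)
}

#' Volume fraction of a configuration
#'
#' Fraction of the box volume occupied by particle spheres of radius
#' `r_colloid`.
#'
#' @param config a [gel_configuration()].
#' @param r_colloid particle radius (units d).
#' @export
volume_fraction <- function(config, r_colloid = 0.5) {
  nrow(config$positions) * (4 / 3) * pi * r_colloid^3 / config$L^3
}

#' Minimum-image displacement under Lees-Edwards boundaries
#'
#' Wraps a displacement vector (or an N x 3 matrix of displacements) to its
#' nearest periodic image: the gradient (z) component is wrapped first,
#' shifting the flow (x) component by the sheared image offset, then x and
#' y are wrapped conventionally. This is the standard Lees-Edwards
#' convention: it agrees with the strict minimum over all sheared images
#' whenever that minimum is shorter than `L / 2`, i.e. everywhere within
#' interaction range (the two can differ for longer displacements, which
#' never enter the energy).
#'
#' @param displacement length-3 vector or N x 3 matrix (units d).
#' @param L box length.
#' @param le_offset Lees-Edwards image shift (units d).
#' @return wrapped displacement, same shape as the input.
#' @examples
#' minimum_image(c(0, 0, 6), L = 10)   # -> c(0, 0, -4)
#' @export
minimum_image <- function(displacement, L, le_offset = 0) {
  stopifnot(L > 0)
  v <- if (is.matrix(displacement)) displacement else matrix(displacement, 1)
  nz <- round(v[, 3] / L)
  v[, 3] <- v[, 3] - nz * L
  v[, 1] <- v[, 1] - nz * le_offset
  v[, 1] <- v[, 1] - L * round(v[, 1] / L)
  v[, 2] <- v[, 2] - L * round(v[, 2] / L)
  if (is.matrix(displacement)) v else drop(v)
}

#' Wrap particle positions into the primary cell
#'
#' Restores the position invariants after any displacement: particles
#' leaving the box through a z face re-enter shifted by the Lees-Edwards
#' offset in x.
#'
#' @param config a [gel_configuration()].
#' @return the configuration with wrapped positions and `le_offset` reduced
#'   modulo the box length into (-L/2, L/2].
#' @export
wrap_configuration <- function(config) {
  p <- config$positions
  L <- config$L
  le <- config$le_offset - L * round(config$le_offset / L)
  if (nrow(p)) {
    nz <- floor(p[, 3] / L)
    p[, 3] <- p[, 3] - nz * L
    p[, 1] <- p[, 1] - nz * le
    p[, 1] <- p[, 1] - L * floor(p[, 1] / L)
    p[, 2] <- p[, 2] - L * floor(p[, 2] / L)
  }
  config$positions <- p
  config$le_offset <- le
  config
}

#' Apply an affine strain step
#'
#' Remaps every particle affinely in the flow direction, `x <- x +
#' delta_gamma * z`, advances the Lees-Edwards offset by `delta_gamma * L`
#' and the accumulated strain by `delta_gamma`, then restores the wrap
#' invariants. Tethers and velocities are untouched.
#'
#' @param config a [gel_configuration()].
#' @param delta_gamma strain increment, |delta_gamma| < 1.
#' @return the strained configuration.
#' @export
apply_strain_step <- function(config, delta_gamma) {
  stopifnot(inherits(config, "gel_config"), abs(delta_gamma) < 1)
  if (delta_gamma == 0) return(config)
  config$positions[, 1] <- config$positions[, 1] +
    delta_gamma * config$positions[, 3]
  config$le_offset <- config$le_offset + delta_gamma * config$L
  config$accumulated_strain <- config$accumulated_strain + delta_gamma
  wrap_configuration(config)
}

#' Restrict a configuration to a subset of species
#'
#' @param config a [gel_configuration()].
#' @param species character vector of labels to keep.
#' @return a [gel_configuration()] containing only the selected particles.
#' @export
subset_species <- function(config, species) {
  keep <- config$species %in% species
  if (!any(keep)) stop("no particles of species ",
                       paste(species, collapse = ", "))
  gel_configuration(config$positions[keep, , drop = FALSE],
                    config$species[keep], config$L,
                    config$velocities[keep, , drop = FALSE],
                    config$le_offset, config$accumulated_strain)
}

# species labels -> 0-based integer codes against a compiled table
species_codes <- function(config, compiled) {
  idx <- match(config$species, compiled$names)
  if (anyNA(idx)) {
    bad <- unique(config$species[is.na(idx)])
    stop("species not in interaction table: ", paste(bad, collapse = ", "))
  }
  as.integer(idx - 1L)
}
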