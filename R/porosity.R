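#' Clearance field of a particle packing
#'
#' For every node of a regular `N_g^3` grid with spacing `L / N_g` and the
#' origin at the box corner, computes the radius of the largest sphere
#' centred at that node that does not clash with any particle of radius
#' `r_colloid`: `max(min_l |r_l - r_grid| - r_colloid, 0)` with periodic
#' distances. Nodes inside a particle get zero.
#'
#' @param config a [gel_configuration()] (nonempty).
#' @param N_g grid nodes per axis (>= 2).
#' @param r_colloid particle radius (units d).
#' @return numeric 3D array `N_g x N_g x N_g`; element `[i, j, k]`
#'   corresponds to the node at `(L/N_g) * (i-1, j-1, k-1)`.
#' @export
grid_clearance_field <- function(config, N_g = 25, r_colloid = 0.5) {
  stopifnot(inherits(config, "gel_config"), N_g >= 2)
  if (nrow(config$positions) == 0)
    stop("clearance field undefined for an empty configuration")
  v <- cpp_pore_clearance(config$positions, config$L, as.integer(N_g),
                          r_colloid)
  array(v, c(N_g, N_g, N_g))
}

# Build the survival curve P(r > R) and its area <R> from pore radii.
# For the probe method the radii are per accepted probe (volume weighted);
# for the census method one radius per identified pore.
pore_result <- function(R_samples, method, N_g, L, n_probes, n_rejected,
                        seed = NA_integer_, n_curve = 400) {
  Rmax <- max(R_samples)
  grid <- seq(0, Rmax * 1.02 + 1e-12, length.out = n_curve)
  P <- vapply(grid, function(r) mean(R_samples > r), 0)
  P[1] <- 1
  structure(list(R_values = grid, P_gt = P,
                 mean_R = mean(R_samples),
                 R_samples = R_samples,
                 R_grid_spacing = L / N_g, method = method,
                 n_probes = n_probes, n_rejected = n_rejected, seed = seed),
            class = "pore_size_result")
}

#' @export
print.pore_size_result <- function(x, ...) {
  cat(sprintf("<pore_size_result> method = %s, <R> = %.4g d\n",
              x$method, x$mean_R))
  cat(sprintf("  %d pores/probes (%d rejected), grid spacing %.3g d\n",
              x$n_probes, x$n_rejected, x$R_grid_spacing))
  invisible(x)
}

#' @export
plot.pore_size_result <- function(x, ...) {
  plot(x$R_values, x$P_gt, type = "l", xlab = "R (d)",
       ylab = "P(r > R)", ylim = c(0, 1), ...)
  abline(v = x$mean_R, lty = 3)
  invisible(x)
}

#' Pore-size distribution by random probe insertion
#'
#' Measures the pore-size distribution of a configuration: probe points
#' are placed uniformly at random in the box; each probe is assigned the
#' largest clearance sphere (over all grid nodes) that contains it, and
#' that sphere's radius is the probe's pore size. Probes that overlap a
#' particle or fall outside every clearance sphere are rejected and
#' resampled until `N_r` probes are accepted. Because probes sample space
#' uniformly, each pore is weighted by the volume assigned to it; the mean
#' pore size `<R>` equals the area under the survival curve `P(r > R)`.
#'
#' @param config a [gel_configuration()].
#' @param N_g grid nodes per axis (`>= 15` gives consistent results).
#' @param N_r number of accepted probes.
#' @param r_colloid particle radius (units d).
#' @param seed integer seed for probe placement.
#' @param species optional character vector: compute on this species subset
#'   only.
#' @return An object of class `pore_size_result` with the survival curve
#'   `P_gt` on the radius grid `R_values`, the mean pore size `mean_R`,
#'   per-probe radii `R_samples`, and rejection counts.
#' @export
pore_size_probe <- function(config, N_g = 25, N_r = 5e4, r_colloid = 0.5,
                            seed = 1L, species = NULL) {
  stopifnot(inherits(config, "gel_config"), N_r >= 1)
  if (!is.null(species)) config <- subset_species(config, species)
  clear <- cpp_pore_clearance(config$positions, config$L, as.integer(N_g),
                              r_colloid)
  set.seed(seed)
  acc <- numeric(0)
  n_rejected <- 0L
  total_tried <- 0L
  while (length(acc) < N_r) {
    batch <- max(1000L, ceiling((N_r - length(acc)) * 1.5))
    probes <- matrix(runif(3 * batch, 0, config$L), batch, 3)
    res <- cpp_pore_assign(clear, as.integer(N_g), config$L, probes,
                           config$positions, r_colloid)
    ok <- res$status == 0L
    n_rejected <- n_rejected + sum(!ok)
    total_tried <- total_tried + batch
    acc <- c(acc, res$R[ok])
    if (total_tried > 1000 && mean(length(acc) / total_tried) < 1e-3)
      stop("probe acceptance rate below 1e-3: system too dense for this grid")
  }
  acc <- acc[seq_len(N_r)]
  pore_result(acc, "probe_weighted", N_g, config$L,
              n_probes = N_r, n_rejected = n_rejected, seed = seed)
}

#' Pore-size distribution by grid census
#'
#' Variant of [pore_size_probe()] that visits every grid node instead of
#' random probes and counts each identified pore only once: a pore is
#' identified by the node carrying the largest clearance sphere that covers
#' the visiting node, distinct maximal nodes counting as distinct pores.
#' Pores with radius at or below the niche cutoff `r_c` are discarded, and
#' the mean is unweighted over the identified pores, which weights large
#' and small pores equally (closer to how imaging experiments report pore
#' size) instead of by volume.
#'
#' @inheritParams pore_size_probe
#' @param r_c niche cutoff (units d): pores with `R <= r_c` are excluded.
#' @return An object of class `pore_size_result`; `n_probes` is the number
#'   of identified pores.
#' @export
pore_size_census <- function(config, N_g = 25, r_colloid = 0.5, r_c = 0.25,
                             species = NULL) {
  stopifnot(inherits(config, "gel_config"))
  if (!is.null(species)) config <- subset_species(config, species)
  clear <- cpp_pore_clearance(config$positions, config$L, as.integer(N_g),
                              r_colloid)
  h <- config$L / N_g
  g <- (seq_len(N_g) - 1) * h
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))
  res <- cpp_pore_assign(clear, as.integer(N_g), config$L, nodes,
                         config$positions, r_colloid)
  ok <- res$status == 0L
  pores <- !duplicated(res$node[ok])
  R <- res$R[ok][pores]
  R <- R[R > r_c]
  if (!length(R))
    stop("no pores larger than the cutoff r_c = ", r_c, " d were identified")
  pore_result(R, "grid_census", N_g, config$L,
              n_probes = length(R), n_rejected = sum(!ok))
}

#' Mean pore size as the area under the survival curve
#'
#' Integrates `P(r > R)` over R by the trapezoidal rule; for a valid
#' survival curve this equals the mean of the pore-size distribution.
#'
#' @param result a `pore_size_result`, or any list with `R_values` and
#'   `P_gt`.
#' @return mean pore size (units d).
#' @export
mean_pore_size <- function(result) {
  R <- result$R_values
  P <- result$P_gt
  stopifnot(length(R) == length(P), length(R) >= 2)
  if (any(diff(P) > 1e-12))
    stop("survival curve must be non-increasing")
  sum(diff(R) * (head(P, -1) + tail(P, -1)) / 2)
}
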