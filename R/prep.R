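#' Number of particles realizing a volume fraction
#'
#' @param phi target volume fraction (0 < phi < 0.64).
#' @param L box side length (units d).
#' @param r_colloid particle radius (units d).
#' @return integer N = round(phi L^3 / ((4/3) pi r_colloid^3)); an error if
#'   the rounded count is zero.
#' @examples
#' particle_count(0.05, 10)  # 95
#' @export
particle_count <- function(phi, L, r_colloid = 0.5) {
  stopifnot(phi > 0, L > 0, r_colloid > 0)
  n <- round(phi * L^3 / ((4 / 3) * pi * r_colloid^3))
  if (n < 1) stop("volume fraction too small: zero particles in this box")
  as.integer(n)
}

#' Gel preparation protocol
#'
#' The three-stage protocol used to self-assemble a network: (1) particles
#' are placed on a simple-cubic lattice and randomized at `T_hot`; (2) the
#' system is quenched and relaxed at `T_quench` under the thermostat; (3)
#' the kinetic energy is drained by zero-temperature damped dynamics until
#' the temperature drops below `stop_T`, leaving an inherent structure.
#' For two-component mixtures, `order = "simultaneous"` inserts the second
#' species into the randomized first and quenches both together, while
#' `order = "sequential"` gels the first species completely, restrains each
#' of its particles with a harmonic tether of stiffness `tether_stiffness`
#' while the second species is quenched in, then removes the tethers and
#' drains the joint system.
#'
#' @param phi volume fraction per species.
#' @param T_hot,T_quench randomization and quench temperatures (eps/k_B).
#' @param t_hot,t_quench stage durations (tau).
#' @param order `"simultaneous"` or `"sequential"` (mixtures only).
#' @param tether_stiffness harmonic tether constant (eps/d^2), sequential
#'   mode.
#' @param stop_T drain termination temperature (eps/k_B).
#' @param drain_max_time step budget for the drain stage (tau).
#' @param ramp if `TRUE` the quench stage lowers the thermostat target from
#'   `T_hot` to `T_quench` in five equal-duration substages instead of
#'   setting it instantaneously.
#' @param dt integrator timestep (tau).
#' @param seed integer seed; all stage randomness (velocities, insertion)
#'   derives from it through named substreams.
#' @return An object of class `prep_protocol`.
#' @export
prep_protocol <- function(phi = 0.05, T_hot = 0.5, T_quench = 0.05,
                          t_hot = 1000, t_quench = 1000,
                          order = c("simultaneous", "sequential"),
                          tether_stiffness = 1.0, stop_T = 1e-10,
                          drain_max_time = 5e3, ramp = FALSE,
                          dt = 0.005, seed = 1L) {
  order <- match.arg(order)
  stopifnot(phi > 0, phi < 0.64, T_hot > T_quench, T_quench > 0,
            t_hot > 0, t_quench > 0, stop_T > 0, dt > 0)
  if (order == "sequential" && tether_stiffness <= 0)
    stop("sequential order needs tether_stiffness > 0")
  structure(list(phi = phi, T_hot = T_hot, T_quench = T_quench,
                 t_hot = t_hot, t_quench = t_quench, order = order,
                 tether_stiffness = tether_stiffness, stop_T = stop_T,
                 drain_max_time = drain_max_time, ramp = ramp,
                 dt = dt, seed = as.integer(seed)),
            class = "prep_protocol")
}

# Independent deterministic seeds per named stage, all below 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

# First N sites of a simple-cubic lattice filling the box.
lattice_positions <- function(N, L) {
  n <- ceiling(N^(1 / 3))
  a <- L / n
  g <- seq_len(n) - 0.5
  sites <- as.matrix(expand.grid(x = g, y = g, z = g)) * a
  unname(sites[seq_len(N), , drop = FALSE])
}

quench_stage <- function(config, table, protocol) {
  if (protocol$ramp) {
    temps <- seq(protocol$T_hot, protocol$T_quench, length.out = 6)[-1]
    for (Tt in temps) {
      st <- integrator_settings(protocol$dt, "thermostatted", target_T = Tt)
      config <- run_thermostatted(config, table, st,
                                  protocol$t_quench / length(temps))
    }
    config
  } else {
    st <- integrator_settings(protocol$dt, "thermostatted",
                              target_T = protocol$T_quench)
    run_thermostatted(config, table, st, protocol$t_quench)
  }
}

drain_stage <- function(config, table, protocol) {
  sd_ <- integrator_settings(protocol$dt, "damped_zero_T")
  run_damped_zero_T(config, table, sd_, stop_T = protocol$stop_T,
                    max_time = protocol$drain_max_time)
}

#' Prepare a single-species gel
#'
#' Runs the three-stage protocol (randomize at `T_hot`, quench at
#' `T_quench`, damped drain) on `particle_count(phi, L)` particles of one
#' species placed on a simple-cubic lattice. The returned configuration is
#' an inherent structure: its kinetic temperature is below the protocol's
#' `stop_T`.
#'
#' @param species a [species_params()] or a species name with a preset
#'   parameterization (see [gel_species()]).
#' @param protocol a [prep_protocol()].
#' @param L box side length (units d), at least twice the cutoff.
#' @return a [gel_configuration()]; attribute `"protocol"` records the
#'   protocol used.
#' @export
prepare_single_gel <- function(species, protocol = prep_protocol(), L = 15) {
  if (is.character(species)) species <- gel_species(species)
  stopifnot(inherits(species, "species_params"),
            inherits(protocol, "prep_protocol"))
  if (L < 2 * species$r_cut) stop("box must be at least twice the cutoff")
  table <- interaction_table(list(species))
  N <- particle_count(protocol$phi, L)
  cfg <- gel_configuration(lattice_positions(N, L), species$name, L)
  cfg <- initialize_velocities(cfg, protocol$T_hot,
                               substream_seed(protocol$seed, "prep"))
  st_hot <- integrator_settings(protocol$dt, "thermostatted",
                                target_T = protocol$T_hot)
  cfg <- run_thermostatted(cfg, table, st_hot, protocol$t_hot)
  cfg <- quench_stage(cfg, table, protocol)
  cfg <- drain_stage(cfg, table, protocol)
  attr(cfg, "protocol") <- protocol
  cfg
}

# Uniform random insertion with overlap rejection at r < r_min_sep.
insert_random <- function(existing, n_new, L, le, r_min_sep = 1,
                          seed = NULL, max_tries = 1e5) {
  if (!is.null(seed)) set.seed(seed)
  placed <- matrix(NA_real_, n_new, 3)
  npl <- 0L
  tries <- 0L
  while (npl < n_new) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("insertion failed: could not place ", n_new,
           " particles without overlap in ", max_tries, " tries")
    p <- runif(3, 0, L)
    others <- rbind(existing, placed[seq_len(npl), , drop = FALSE])
    if (nrow(others)) {
      dv <- minimum_image(sweep(others, 2, p), L, le)
      if (min(rowSums(dv^2)) < r_min_sep^2) next
    }
    npl <- npl + 1L
    placed[npl, ] <- p
  }
  placed
}

#' Prepare a two-component gel network
#'
#' Builds a mixture of two species at volume fraction `phi` *per species*.
#' Simultaneous order: species A is randomized at `T_hot`, species B is
#' inserted at random overlap-free positions, and the joint system is
#' quenched and drained. Sequential order: species A is fully gelled first,
#' each of its particles is anchored to its position by a harmonic tether
#' while species B is inserted and quenched in, then the tethers are
#' removed and the joint system is drained.
#'
#' @param speciesA,speciesB [species_params()] objects or preset names.
#' @param table an [interaction_table()] containing both species and their
#'   cross row; defaults to the preset table for the pair.
#' @param protocol a [prep_protocol()]; its `order` field selects the mode.
#' @param L box side length (units d).
#' @return a [gel_configuration()] with both species. Attributes:
#'   `"protocol"`, and for sequential order `"tether_max_disp"` /
#'   `"tether_rms_disp"`, the maximum and RMS displacement of any species-A
#'   particle over the tethered stage (units d).
#' @export
prepare_mixture <- function(speciesA, speciesB, table = NULL,
                            protocol = prep_protocol(), L = 15) {
  if (is.character(speciesA)) speciesA <- gel_species(speciesA)
  if (is.character(speciesB)) speciesB <- gel_species(speciesB)
  if (is.null(table))
    table <- preset_interaction_table(c(speciesA$name, speciesB$name))
  stopifnot(is.interaction_table(table),
            speciesA$name %in% names(table$species),
            speciesB$name %in% names(table$species))
  key <- paste(sort(c(speciesA$name, speciesB$name)), collapse = ":")
  if (!key %in% names(table$cross))
    stop("interaction table lacks the cross row for ", key)
  N <- particle_count(protocol$phi, L)
  st_hot <- integrator_settings(protocol$dt, "thermostatted",
                                target_T = protocol$T_hot)

  if (protocol$order == "simultaneous") {
    cfgA <- gel_configuration(lattice_positions(N, L), speciesA$name, L)
    cfgA <- initialize_velocities(cfgA, protocol$T_hot,
                                  substream_seed(protocol$seed, "prep"))
    cfgA <- run_thermostatted(cfgA, table, st_hot, protocol$t_hot)
    posB <- insert_random(cfgA$positions, N, L, cfgA$le_offset,
                          seed = substream_seed(protocol$seed, "insert"))
    cfg <- gel_configuration(rbind(cfgA$positions, posB),
                             c(cfgA$species, rep(speciesB$name, N)), L,
                             rbind(cfgA$velocities,
                                   matrix(rnorm(3 * N,
                                                sd = sqrt(protocol$T_quench)),
                                          N, 3)),
                             cfgA$le_offset, cfgA$accumulated_strain)
    cfg <- quench_stage(cfg, table, protocol)
    cfg <- drain_stage(cfg, table, protocol)
  } else {
    gelA <- prepare_single_gel(speciesA, protocol, L)
    posB <- insert_random(gelA$positions, N, L, gelA$le_offset,
                          seed = substream_seed(protocol$seed, "insert"))
    set.seed(substream_seed(protocol$seed, "insert-vel"))
    cfg <- gel_configuration(rbind(gelA$positions, posB),
                             c(gelA$species, rep(speciesB$name, N)), L,
                             rbind(matrix(0, N, 3),
                                   matrix(rnorm(3 * N,
                                                sd = sqrt(protocol$T_quench)),
                                          N, 3)))
    anchors <- rbind(gelA$positions, posB)  # B anchors inert (stiffness 0)
    kvec <- c(rep(protocol$tether_stiffness, N), rep(0, N))
    st_q <- integrator_settings(protocol$dt, "thermostatted",
                                target_T = protocol$T_quench)
    cfg <- run_md(cfg, table, st_q,
                  nsteps = round(protocol$t_quench / protocol$dt),
                  mode_code = 1L, anchors = anchors, tether_k = kvec)
    dv <- minimum_image(cfg$positions[seq_len(N), , drop = FALSE] -
                          gelA$positions, L, cfg$le_offset)
    tether_max <- sqrt(max(rowSums(dv^2)))
    tether_rms <- sqrt(mean(dv^2))
    cfg <- drain_stage(cfg, table, protocol)
    attr(cfg, "tether_max_disp") <- tether_max
    attr(cfg, "tether_rms_disp") <- tether_rms
  }
  attr(cfg, "protocol") <- protocol
  cfg
}
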