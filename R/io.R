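#' Write / read configurations as extended XYZ
#'
#' The canonical on-disk format is extended XYZ: a count line, a comment
#' line carrying `Lattice="L 0 0 0 L 0 0 0 L"`,
#' `Properties=species:S:1:pos:R:3:vel:R:3` and the Lees-Edwards state
#' (`le_offset`, `accumulated_strain`), then one `species x y z vx vy vz`
#' row per particle. Round-trips are lossless to the printed precision
#' (17 significant digits).
#'
#' @param config a [gel_configuration()].
#' @param path file path.
#' @return `write_configuration()` returns `path` invisibly;
#'   `read_configuration()` returns a [gel_configuration()].
#' @export
write_configuration <- function(config, path) {
  stopifnot(inherits(config, "gel_config"))
  n <- nrow(config$positions)
  header <- sprintf(
    paste0('Lattice="%.17g 0 0 0 %.17g 0 0 0 %.17g" ',
           'Properties=species:S:1:pos:R:3:vel:R:3 ',
           'le_offset=%.17g accumulated_strain=%.17g'),
    config$L, config$L, config$L, config$le_offset,
    config$accumulated_strain)
  rows <- sprintf("%s %.17g %.17g %.17g %.17g %.17g %.17g",
                  config$species,
                  config$positions[, 1], config$positions[, 2],
                  config$positions[, 3],
                  config$velocities[, 1], config$velocities[, 2],
                  config$velocities[, 3])
  writeLines(c(as.character(n), header, rows), path)
  invisible(path)
}

#' @rdname write_configuration
#' @export
read_configuration <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("not an extended-XYZ file: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("line 1: expected particle count, got '", lines[1], "'")
  if (length(lines) < 2 + n)
    stop("file ends at line ", length(lines), " but ", n, " particles declared")
  header <- lines[2]
  lat <- regmatches(header, regexec('Lattice="([^"]+)"', header))[[1]]
  if (length(lat) < 2)
    stop("line 2: missing Lattice=\"...\" box record")
  latv <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
  if (length(latv) != 9 || anyNA(latv))
    stop("line 2: malformed Lattice record")
  if (latv[1] != latv[5] || latv[5] != latv[9])
    stop("line 2: only cubic boxes are supported")
  key_num <- function(key, default) {
    m <- regmatches(header,
                    regexec(paste0(key, "=([-+0-9.eE]+)"), header))[[1]]
    if (length(m) < 2) default else as.numeric(m[2])
  }
  le <- key_num("le_offset", 0)
  gam <- key_num("accumulated_strain", 0)
  if (n == 0)
    return(gel_configuration(matrix(0, 0, 3), character(0), latv[1],
                             le_offset = le, accumulated_strain = gam))
  fields <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("line ", 2 + which(nf < 4)[1], ": expected 'species x y z [vx vy vz]'")
  species <- vapply(fields, `[[`, "", 1)
  num <- t(vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    c(v, rep(0, 6 - length(v)))[1:6]
  }, numeric(6)))
  if (anyNA(num[, 1:3]))
    stop("line ", 2 + which(is.na(rowSums(num[, 1:3, drop = FALSE])))[1],
         ": malformed coordinates")
  gel_configuration(num[, 1:3, drop = FALSE], species, latv[1],
                    num[, 4:6, drop = FALSE], le, gam)
}

#' Read a LAMMPS-style dump frame
#'
#' Minimal reader for text dump files with `ITEM: TIMESTEP`, `ITEM: BOX
#' BOUNDS` (orthogonal or with an `xy xz yz` tilt record) and `ITEM: ATOMS
#' id type x y z ...` sections. The `xz` tilt of a triclinic box maps to
#' the Lees-Edwards offset (tilt = strain * L). Integer types are mapped
#' to species labels through `types`.
#'
#' @param path dump file path.
#' @param types character vector: `types[i]` is the species label of atom
#'   type `i`.
#' @param frame which frame to read (default: the last one).
#' @return a [gel_configuration()].
#' @export
read_lammps_dump <- function(path, types, frame = NULL) {
  lines <- readLines(path)
  starts <- grep("^ITEM: TIMESTEP", lines)
  if (!length(starts)) stop("no 'ITEM: TIMESTEP' record found")
  if (is.null(frame)) frame <- length(starts)
  stopifnot(frame >= 1, frame <= length(starts))
  lo <- starts[frame]
  hi <- if (frame < length(starts)) starts[frame + 1] - 1 else length(lines)
  blk <- lines[lo:hi]
  nat_i <- grep("^ITEM: NUMBER OF ATOMS", blk)
  box_i <- grep("^ITEM: BOX BOUNDS", blk)
  atm_i <- grep("^ITEM: ATOMS", blk)
  if (!length(nat_i) || !length(box_i) || !length(atm_i))
    stop("incomplete dump frame at line ", lo)
  n <- as.integer(trimws(blk[nat_i + 1]))
  tilted <- grepl("xy xz yz", blk[box_i])
  box_rows <- lapply(blk[box_i + 1:3],
                     function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  Ls <- vapply(box_rows, function(r) r[2] - r[1], 0)
  if (max(abs(Ls - Ls[1])) > 1e-9 * Ls[1])
    stop("only cubic boxes are supported")
  le <- if (tilted) box_rows[[2]][3] else 0  # xz tilt, second bounds row
  cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", blk[atm_i]), "\\s+")[[1]]
  need <- c("type", "x", "y", "z")
  if (!all(need %in% cols))
    stop("dump must provide columns: ", paste(need, collapse = ", "))
  dat <- do.call(rbind,
                 lapply(blk[atm_i + seq_len(n)],
                        function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  typ <- dat[, match("type", cols)]
  if (any(typ > length(types)))
    stop("atom type ", max(typ), " has no species label in `types`")
  gel_configuration(dat[, match(c("x", "y", "z"), cols), drop = FALSE],
                    types[typ], Ls[1], le_offset = le)
}

#' Deterministic test configurations
#'
#' Small hand-constructable configurations used throughout the test-suite
#' and documentation:
#' * `"lattice"`: simple-cubic lattice at volume fraction `phi` in a box of
#'   side `L` (params: `L`, `phi`, `species`).
#' * `"single_fiber"`: a straight fiber of `n` touching beads along x at
#'   separation `spacing` (default: the pair-potential minimum), centred in
#'   a box padded well beyond the cutoff (params: `n`, `spacing`,
#'   `species`).
#' * `"two_pore"`: a dense lattice filling the box except two spherical
#'   cavities of radii `R1 > R2` (cavity radius = exclusion radius for
#'   particle centres; params: `L`, `R1`, `R2`, `spacing`, `species`).
#' * `"corner_cube"`: eight particles at the corners of a cube of side `s`
#'   centred in a dilute box (params: `L`, `s`, `species`).
#'
#' @param kind fixture name, see above.
#' @param params named list overriding the per-kind defaults.
#' @param seed integer; kept for interface uniformity (all fixtures are
#'   deterministic).
#' @return a [gel_configuration()].
#' @export
generate_fixture <- function(kind = c("lattice", "single_fiber", "two_pore",
                                      "corner_cube"),
                             params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default
  species <- p("species", "M0")
  switch(kind,
    lattice = {
      L <- p("L", 10); phi <- p("phi", 0.05)
      N <- particle_count(phi, L)
      gel_configuration(lattice_positions(N, L), species, L)
    },
    single_fiber = {
      n <- p("n", 7)
      spacing <- p("spacing", sqrt(9 / 8) * 0.922)
      L <- max(2 * 2.0 + 1, n * spacing + 4)
      x0 <- (L - (n - 1) * spacing) / 2
      pos <- cbind(x0 + (seq_len(n) - 1) * spacing, L / 2, L / 2)
      gel_configuration(pos, species, L)
    },
    two_pore = {
      L <- p("L", 14); R1 <- p("R1", 4.5); R2 <- p("R2", 3.0)
      spacing <- p("spacing", 0.7)
      c1 <- p("c1", c(L / 4, L / 2, L / 2))
      c2 <- p("c2", c(3 * L / 4, L / 2, L / 2))
      n <- floor(L / spacing)
      g <- (seq_len(n) - 0.5) * (L / n)
      pos <- as.matrix(expand.grid(x = g, y = g, z = g))
      d1 <- sqrt(rowSums(minimum_image(sweep(pos, 2, c1), L)^2))
      d2 <- sqrt(rowSums(minimum_image(sweep(pos, 2, c2), L)^2))
      pos <- pos[d1 >= R1 & d2 >= R2, , drop = FALSE]
      gel_configuration(pos, species, L)
    },
    corner_cube = {
      L <- p("L", 10); s <- p("s", 4)
      corner <- c(-s / 2, s / 2)
      pos <- as.matrix(expand.grid(x = corner, y = corner, z = corner)) + L / 2
      gel_configuration(pos, species, L)
    })
}

# Scenario files -------------------------------------------------------------

#' Read and run scenario files
#'
#' A scenario is a YAML (or JSON) description of a full pipeline run:
#' species (preset names or explicit parameter blocks), box size, volume
#' fraction, preparation protocol, optional rheology (chirp spectrum and/or
#' start-up shear) and porosity analyses, and a seed. `run_scenario()`
#' executes prepare -> rheology -> porosity, writes every output plus a
#' `manifest.json` recording parameters, seeds and outputs, and returns the
#' results. Re-running a manifest's scenario with the same seed reproduces
#' all outputs exactly.
#'
#' @param path scenario file path.
#' @return `read_scenario()`: the scenario as a named list (class
#'   `gel_scenario`).
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  if (is.null(sc$species)) stop("scenario must name at least one species")
  sc$species <- as.character(unlist(sc$species))
  defaults <- list(L = 15, phi = 0.05, seed = 1L, order = NULL,
                   prep = list(), rheology = list(), porosity = list(),
                   name = paste(sc$species, collapse = "+"))
  sc <- modifyList(defaults, sc)
  class(sc) <- "gel_scenario"
  sc
}

scenario_table <- function(scenario) {
  if (!is.null(scenario$species_params)) {
    sp <- lapply(scenario$species_params, function(b)
      species_params(b$name, b$A, b$B,
                     if (is.null(b$cos_theta_bar)) NA_real_ else b$cos_theta_bar))
    cr <- lapply(scenario$cross_params, function(b)
      cross_params(b$a, b$b, b$A, b$B,
                   if (is.null(b$cos_theta_bar)) NA_real_ else b$cos_theta_bar))
    interaction_table(sp, cr)
  } else {
    preset_interaction_table(scenario$species)
  }
}

scenario_protocol <- function(scenario) {
  pr <- scenario$prep
  order <- scenario$order
  if (is.null(order) && length(scenario$species) == 2) {
    key <- paste(sort(scenario$species), collapse = ":")
    order <- if (key %in% names(.gel_cross_presets))
      .gel_cross_presets[[key]]$order else "simultaneous"
  }
  if (is.null(order)) order <- "simultaneous"
  do.call(prep_protocol,
          modifyList(list(phi = scenario$phi, order = order,
                          seed = scenario$seed), pr))
}

#' @rdname read_scenario
#' @param scenario a scenario list from [read_scenario()] (or an equivalent
#'   named list).
#' @param outdir output directory, created if needed.
#' @return `run_scenario()`: invisibly, a list with the prepared
#'   configuration and any spectrum / stiffening / porosity results.
#' @export
run_scenario <- function(scenario, outdir = scenario$outdir) {
  if (is.null(outdir)) outdir <- "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  table <- scenario_table(scenario)
  protocol <- scenario_protocol(scenario)
  res <- list()
  outputs <- character(0)

  stage <- "prepare"
  res$config <- tryCatch({
    if (length(scenario$species) == 1) {
      prepare_single_gel(table$species[[scenario$species]], protocol,
                         scenario$L)
    } else if (length(scenario$species) == 2) {
      prepare_mixture(table$species[[scenario$species[1]]],
                      table$species[[scenario$species[2]]],
                      table, protocol, scenario$L)
    } else stop("scenarios support one or two species")
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  f <- file.path(outdir, "structure.xyz")
  write_configuration(res$config, f)
  outputs <- c(outputs, f)

  rh <- scenario$rheology
  if (isTRUE(rh$spectrum)) {
    stage <- "spectrum"
    sig <- owch_strain_signal(
      T_total = if (is.null(rh$T_total)) 500 else rh$T_total,
      gamma0 = if (is.null(rh$gamma0)) 0.01 else rh$gamma0,
      omega_lo = if (is.null(rh$omega_lo)) 0.05 else rh$omega_lo,
      omega_hi = if (is.null(rh$omega_hi)) 5 else rh$omega_hi,
      dt = protocol$dt)
    res$spectrum <- tryCatch(
      measure_spectrum(res$config, table, sig),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    f <- file.path(outdir, "spectrum.tsv")
    write.table(data.frame(omega = res$spectrum$omega,
                           G_prime = res$spectrum$G_prime,
                           G_double_prime = res$spectrum$G_double_prime),
                f, sep = "\t", row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, f)
  }
  if (isTRUE(rh$stiffen)) {
    stage <- "stiffen"
    res$stiffening <- tryCatch(
      startup_shear(res$config, table,
                    delta_gamma = if (is.null(rh$delta_gamma)) 0.01
                                  else rh$delta_gamma,
                    delta_t = if (is.null(rh$delta_t)) 1000 else rh$delta_t,
                    n_steps = if (is.null(rh$n_steps)) 10 else rh$n_steps,
                    settings = integrator_settings(dt = protocol$dt)),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    f <- file.path(outdir, "stiffening.tsv")
    write.table(data.frame(strain = res$stiffening$strain,
                           sigma = res$stiffening$sigma,
                           K = res$stiffening$K),
                f, sep = "\t", row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, f)
  }
  po <- scenario$porosity
  if (length(po)) {
    stage <- "porosity"
    method <- if (is.null(po$method)) "probe" else po$method
    N_g <- if (is.null(po$N_g)) 25 else po$N_g
    res$porosity <- tryCatch({
      if (method == "probe")
        pore_size_probe(res$config, N_g = N_g,
                        N_r = if (is.null(po$N_r)) 5e4 else po$N_r,
                        seed = substream_seed(scenario$seed, "porosity"),
                        species = po$species_filter)
      else
        pore_size_census(res$config, N_g = N_g,
                         r_c = if (is.null(po$r_c)) 0.25 else po$r_c,
                         species = po$species_filter)
    }, error = function(e) stop("stage '", stage, "' failed: ",
                                conditionMessage(e), call. = FALSE))
    f <- file.path(outdir, "porosity.tsv")
    write.table(data.frame(R = res$porosity$R_values,
                           P_gt = res$porosity$P_gt),
                f, sep = "\t", row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, f)
  }

  manifest <- list(
    scenario = unclass(scenario)[setdiff(names(scenario), "outdir")],
    package_version = as.character(utils::packageVersion("gelsim")),
    outputs = basename(outputs),
    mean_pore_size = if (!is.null(res$porosity)) res$porosity$mean_R,
    omega_c = if (!is.null(res$spectrum)) res$spectrum$omega_c)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(res)
}
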