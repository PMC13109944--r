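#' Per-species interaction parameters
#'
#' Bundles the energy-function parameters for one particle species. `A`
#' scales the two-body attraction depth (the minimum of the pair potential
#' is about -0.043*A*eps), `B` scales the three-body angular repulsion and
#' `cos_theta_bar` sets the preferred bond-angle cosine that the angular
#' term carves out of the repulsive landscape. The geometry constants
#' (`w`, `d2`, `d3`, `r_cut`) default to the reference parameterization and
#' are treated as species-independent throughout the package: mixtures vary
#' only `A`, `B` and `cos_theta_bar` across species and species pairs.
#'
#' @param name species label (character scalar).
#' @param A two-body strength, dimensionless multiplier of eps; > 0.
#' @param B three-body strength, dimensionless multiplier of eps; >= 0.
#' @param cos_theta_bar preferred bond-angle cosine, in \[-1, 1\]. May be `NA`
#'   when `B = 0` (the angular term is then never evaluated).
#' @param w angular width of the Gaussian selectivity (dimensionless).
#' @param d2 two-body length scale, units of d.
#' @param d3 three-body length scale, units of d.
#' @param r_cut interaction cutoff, units of d.
#' @return An object of class `species_params`.
#' @examples
#' species_params("PIC", A = 30, B = 10, cos_theta_bar = 0.4226)
#' @export
species_params <- function(name, A, B, cos_theta_bar,
                           w = 0.3, d2 = 0.922, d3 = 1.1, r_cut = 2.0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(A) || A <= 0) stop("A must be > 0")
  if (!is.numeric(B) || B < 0) stop("B must be >= 0")
  if (B > 0 && (is.na(cos_theta_bar) || cos_theta_bar < -1 || cos_theta_bar > 1))
    stop("cos_theta_bar must lie in [-1, 1] when B > 0")
  if (w <= 0) stop("w must be > 0")
  if (d2 <= 0 || d2 >= r_cut) stop("need 0 < d2 < r_cut")
  if (d3 <= 0 || d3 >= r_cut) stop("need 0 < d3 < r_cut")
  structure(list(name = name, A = A, B = B,
                 cos_theta_bar = if (B > 0) cos_theta_bar else NA_real_,
                 w = w, d2 = d2, d3 = d3, r_cut = r_cut),
            class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species %s>  A = %g  B = %g  cos(theta_bar) = %s\n",
              x$name, x$A, x$B,
              if (is.na(x$cos_theta_bar)) "unused" else format(x$cos_theta_bar)))
  cat(sprintf("  geometry: w = %g, d2 = %g d, d3 = %g d, r_cut = %g d\n",
              x$w, x$d2, x$d3, x$r_cut))
  invisible(x)
}

#' Cross-species interaction row
#'
#' Parameters for pairs and mixed triplets involving two different species.
#' When `B = 0` (e.g. for a colocalizing mixture where the angular repulsion
#' between unlike strands is switched off) the angle is flagged unused.
#'
#' @param a,b the two species names.
#' @param A cross two-body strength (> 0).
#' @param B cross three-body strength (>= 0); a mixed triplet (one containing
#'   both species) uses this value regardless of which particle is central.
#' @param cos_theta_bar cross bond-angle cosine, or `NA` when `B = 0`.
#' @return An object of class `cross_params`.
#' @export
cross_params <- function(a, b, A, B, cos_theta_bar = NA_real_) {
  stopifnot(is.character(a), is.character(b), a != b)
  if (A <= 0) stop("cross A must be > 0")
  if (B < 0) stop("cross B must be >= 0")
  if (B > 0 && (is.na(cos_theta_bar) || abs(cos_theta_bar) > 1))
    stop("cross cos_theta_bar must lie in [-1, 1] when B > 0")
  key <- paste(sort(c(a, b)), collapse = ":")
  structure(list(a = sort(c(a, b))[1], b = sort(c(a, b))[2], key = key,
                 A = A, B = B,
                 cos_theta_bar = if (B > 0) cos_theta_bar else NA_real_),
            class = "cross_params")
}

#' Interaction table for a multi-species system
#'
#' Collects the per-species parameters and, for every unordered pair of
#' distinct species, a cross row. Geometry constants (`w`, `d2`, `d3`,
#' `r_cut`) must agree across all species; only `A`, `B` and
#' `cos_theta_bar` vary between species and pairs. Triplet parameters are
#' resolved by the *set* of species in the triplet: a uniform triplet uses
#' the species row, a mixed triplet the cross row of the two species it
#' contains.
#'
#' @param species list of [species_params()] objects.
#' @param cross list of [cross_params()] objects, one per unordered pair of
#'   distinct declared species (may be empty for a single species).
#' @return An object of class `interaction_table`.
#' @examples
#' tab <- interaction_table(
#'   list(species_params("PIC", 30, 10, 0.4226),
#'        species_params("UPy", 55, 10, 0.34071)),
#'   list(cross_params("PIC", "UPy", A = 1, B = 0)))
#' @export
interaction_table <- function(species, cross = list()) {
  if (inherits(species, "species_params")) species <- list(species)
  if (inherits(cross, "cross_params")) cross <- list(cross)
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, TRUE, "species_params")))
  nm <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate species names")
  for (fld in c("w", "d2", "d3", "r_cut")) {
    v <- vapply(species, `[[`, 0, fld)
    if (any(v != v[1]))
      stop("geometry constant '", fld, "' must be identical across species")
  }
  keys <- vapply(cross, `[[`, "", "key")
  if (anyDuplicated(keys)) stop("duplicate cross rows")
  if (length(nm) > 1) {
    need <- utils::combn(sort(nm), 2, paste, collapse = ":")
    miss <- setdiff(need, keys)
    if (length(miss))
      stop("missing cross row(s): ", paste(miss, collapse = ", "))
    bad <- vapply(cross, function(cr) !(cr$a %in% nm) || !(cr$b %in% nm), TRUE)
    if (any(bad)) stop("cross row refers to undeclared species")
  }
  structure(list(species = setNames(species, nm),
                 cross = setNames(cross, keys)),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table: %d species, %d cross rows>\n",
              length(x$species), length(x$cross)))
  for (sp in x$species)
    cat(sprintf("  %-8s A = %-7g B = %-4g cos(theta_bar) = %s\n", sp$name,
                sp$A, sp$B,
                if (is.na(sp$cos_theta_bar)) "N/A" else format(sp$cos_theta_bar)))
  for (cr in x$cross)
    cat(sprintf("  %-8s A = %-7g B = %-4g cos(theta_bar) = %s\n",
                paste0(cr$a, "-", cr$b), cr$A, cr$B,
                if (is.na(cr$cos_theta_bar)) "N/A" else format(cr$cos_theta_bar)))
  invisible(x)
}

#' @rdname interaction_table
#' @param x object to test.
#' @export
is.interaction_table <- function(x) inherits(x, "interaction_table")

# Geometry constants shared by all species in a table.
table_geometry <- function(table) {
  sp <- table$species[[1]]
  list(w = sp$w, d2 = sp$d2, d3 = sp$d3, r_cut = sp$r_cut)
}

# Compile an interaction table into the flat numeric form the C++ kernels
# take: pair-strength matrix plus triplet B / cos_theta_bar cubes keyed by
# the species set. Triplets spanning three distinct species are not
# parameterized here and get B = 0.
compile_table <- function(table, skin = 0.3) {
  stopifnot(is.interaction_table(table))
  nm <- names(table$species)
  n <- length(nm)
  A <- matrix(0, n, n, dimnames = list(nm, nm))
  Bc <- array(0, c(n, n, n))
  cbc <- array(0, c(n, n, n))
  for (i in seq_len(n)) {
    A[i, i] <- table$species[[i]]$A
  }
  for (cr in table$cross) {
    ia <- match(cr$a, nm); ib <- match(cr$b, nm)
    A[ia, ib] <- A[ib, ia] <- cr$A
  }
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    set <- unique(c(i, j, k))
    if (length(set) == 1L) {
      sp <- table$species[[set]]
      Bc[i, j, k] <- sp$B
      cbc[i, j, k] <- if (is.na(sp$cos_theta_bar)) 0 else sp$cos_theta_bar
    } else if (length(set) == 2L) {
      key <- paste(sort(nm[set]), collapse = ":")
      cr <- table$cross[[key]]
      Bc[i, j, k] <- cr$B
      cbc[i, j, k] <- if (is.na(cr$cos_theta_bar)) 0 else cr$cos_theta_bar
    }  # three distinct species: B stays 0
  }
  g <- table_geometry(table)
  list(A = A, B = as.numeric(Bc), cb = as.numeric(cbc),
       d2 = g$d2, d3 = g$d3, rcut = g$r_cut, w = g$w, skin = skin,
       names = nm)
}

# Published parameter sets ---------------------------------------------------

.gel_presets <- list(
  PIC = list(A = 30,    B = 10, cos_theta_bar = 0.4226),
  UPy = list(A = 55,    B = 10, cos_theta_bar = 0.34071),
  BTA = list(A = 1.833, B = 10, cos_theta_bar = 0.4226)
)

.gel_cross_presets <- list(
  "PIC:UPy" = list(A = 1,     B = 0,  cos_theta_bar = NA_real_,
                   order = "simultaneous"),
  "BTA:PIC" = list(A = 1.833, B = 10, cos_theta_bar = 0.4226,
                   order = "sequential")
)

#' Reference parameter sets for the PIC / UPy / BTA gel model
#'
#' `gel_species()` returns the published single-species parameterization for
#' the polyisocyanide (PIC), ureido-pyrimidinone (UPy) or
#' benzene-tricarboxamide (BTA) networks; `gel_cross()` returns the
#' cross-species row for a supported pair, including the preparation order
#' used for that mixture ("simultaneous" or "sequential"). The PIC-UPy row
#' has `B = 0`: the angular repulsion is switched off for any triplet
#' containing both species, which favours interpenetrating, colocalized
#' strands.
#'
#' @param name species name, one of `"PIC"`, `"UPy"`, `"BTA"`.
#' @return `gel_species()`: a [species_params()]; `gel_cross()`: a
#'   [cross_params()] with an extra `order` field.
#' @examples
#' gel_species("UPy")
#' gel_cross("PIC", "BTA")$order
#' @export
gel_species <- function(name) {
  p <- .gel_presets[[name]]
  if (is.null(p)) stop("unknown species preset: ", name,
                       " (known: ", paste(names(.gel_presets), collapse = ", "), ")")
  species_params(name, A = p$A, B = p$B, cos_theta_bar = p$cos_theta_bar)
}

#' @rdname gel_species
#' @param a,b species names of the pair.
#' @export
gel_cross <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = ":")
  p <- .gel_cross_presets[[key]]
  if (is.null(p)) stop("no cross-parameter preset for pair ", a, "-", b)
  cr <- cross_params(a, b, A = p$A, B = p$B, cos_theta_bar = p$cos_theta_bar)
  cr$order <- p$order
  cr
}

#' @rdname gel_species
#' @param names character vector of preset species names (1 or 2).
#' @export
preset_interaction_table <- function(names) {
  sp <- lapply(names, gel_species)
  cr <- if (length(names) >= 2)
    lapply(utils::combn(names, 2, simplify = FALSE),
           function(p) gel_cross(p[1], p[2]))
  else list()
  interaction_table(sp, cr)
}
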