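# Energy function, forces, virial stress, units.

test_that("pair potential reproduces its analytic facts", {
  # minimum at sqrt(9/8) d2, found numerically
  opt <- optimize(pair_energy, c(0.8, 1.5), A = 1)
  expect_equal(opt$minimum, sqrt(9 / 8) * 0.922, tolerance = 1e-5)
  # depth coefficient -0.043 A eps (3 decimals); A = 23 gives about -1 eps
  expect_equal(round(pair_energy(r_min_m0, 1), 3), -0.043)
  expect_equal(pair_energy(r_min_m0, 23), -1, tolerance = 5e-3)
  # untruncated residual at r_cut = 2 d is about -3e-6 A eps
  expect_equal(pair_energy(2, 1), -3.26e-6, tolerance = 0.01)
  # exactly zero beyond the cutoff, repulsive below the minimum
  expect_identical(pair_energy(2.5, 23), 0)
  expect_identical(pair_force(2.5, 23), 0)
  expect_gt(pair_force(0.9 * 0.922, 23), 0)
  expect_equal(pair_force(r_min_m0, 23), 0, tolerance = 1e-10)
  expect_error(pair_energy(-1, 23), "positive")
  expect_error(pair_force(0, 23), "positive")
})

test_that("pair force matches the finite difference of the pair energy", {
  h <- 1e-7
  for (r in c(0.85, 0.95, r_min_m0, 1.3, 1.9)) {
    fd <- -(pair_energy(r + h, 7) - pair_energy(r - h, 7)) / (2 * h)
    expect_equal(pair_force(r, 7), fd, tolerance = 1e-6)
  }
})

test_that("radial weight of the angular term behaves as specified", {
  expect_identical(lambda_radial(2), 0)
  expect_identical(lambda_radial(2.4), 0)
  expect_equal(lambda_radial(1.1), (1 - (1.1 / 2)^10)^2, tolerance = 1e-12)
  expect_equal(lambda_radial(1.1), 0.9948, tolerance = 1e-3)
  expect_gt(lambda_radial(1e-3), 1e20)  # diverges at contact
  expect_error(lambda_radial(0), "positive")
})

test_that("triplet energy honours B = 0, the angular optimum and the cutoff", {
  rij <- c(1.0, 0, 0)
  rik <- c(0.3, 0.9, 0)
  expect_identical(triplet_energy(rij, rik, B = 0, cos_theta_bar = NA), 0)
  # at the preferred angle the Gaussian factor is exactly 1
  cb <- 0.4226
  th <- acos(cb)
  rik2 <- c(cos(th), sin(th), 0) * 1.05
  e <- triplet_energy(rij, rik2, B = 10, cos_theta_bar = cb)
  expect_equal(e, 10 * lambda_radial(1) * lambda_radial(1.05),
               tolerance = 1e-12)
  expect_identical(triplet_energy(rij, c(2.1, 0, 0), 10, cb), 0)
  expect_gte(triplet_energy(rij, rik, 10, cb), 0)
  expect_error(triplet_energy(c(0, 0, 0), rik, 10, cb), "zero-length")
})

test_that("total energy matches a brute-force resummation on clusters", {
  tab <- m0_table()
  for (seed in 1:4) {
    pos <- random_cluster(n = 5 + seed, seed = seed)
    cfg <- gel_configuration(pos, "M0", 8)
    fs <- compute_forces_stress(cfg, tab)
    expect_equal(fs$potential_energy,
                 brute_energy(cfg$positions, 8), tolerance = 1e-10)
  }
})

test_that("forces are minus the gradient and sum to zero", {
  tab <- m0_table()
  pos <- random_cluster(n = 7, seed = 11)
  cfg <- gel_configuration(pos, "M0", 8)
  fs <- compute_forces_stress(cfg, tab)
  expect_lt(max(abs(colSums(fs$forces))), 1e-10)
  h <- 1e-6
  en <- function(p) compute_forces_stress(gel_configuration(p, "M0", 8),
                                          tab)$potential_energy
  for (i in c(1, 4, 7)) for (k in 1:3) {
    pp <- cfg$positions; pp[i, k] <- pp[i, k] + h
    pm <- cfg$positions; pm[i, k] <- pm[i, k] - h
    fd <- -(en(pp) - en(pm)) / (2 * h)
    expect_equal(fs$forces[i, k], fd, tolerance = 1e-6)
  }
})

test_that("two particles at the pair minimum sit at depth -0.043 A eps", {
  tab <- m0_table(A = 23)
  cfg <- gel_configuration(rbind(c(2, 2, 2), c(2 + r_min_m0, 2, 2)),
                           "M0", 8)
  fs <- compute_forces_stress(cfg, tab)
  expect_equal(fs$potential_energy, -0.043 * 23, tolerance = 0.01)
  expect_lt(max(abs(fs$forces)), 1e-10)
})

test_that("virial shear stress equals the strain derivative of the energy", {
  tab <- m0_table()
  for (seed in c(2, 9)) {
    pos <- random_cluster(n = 8, seed = seed)
    cfg <- gel_configuration(pos, "M0", 8)
    fs <- compute_forces_stress(cfg, tab)
    en_g <- function(g) {
      p <- cfg$positions
      p[, 1] <- p[, 1] + g * p[, 3]
      compute_forces_stress(
        gel_configuration(p, "M0", 8, le_offset = g * 8),
        tab)$potential_energy
    }
    d <- 1e-6
    expect_equal(fs$stress[3, 1], (en_g(d) - en_g(-d)) / (2 * d) / 8^3,
                 tolerance = 1e-5)
    expect_lt(max(abs(fs$stress - t(fs$stress))), 1e-12)
  }
})

test_that("minimum image agrees with explicit sheared-image enumeration", {
  set.seed(8)
  L <- 7
  le <- 2.3
  checked <- 0
  for (t in 1:300) {
    v <- runif(3, -1.5 * L, 1.5 * L)
    w <- minimum_image(v, L, le)
    best <- Inf
    for (nz in -2:2) for (nx in -2:2) for (ny in -2:2) {
      cand <- v - nz * c(le, 0, L) - nx * c(L, 0, 0) - ny * c(0, L, 0)
      best <- min(best, sum(cand^2))
    }
    if (sqrt(best) < L / 2) {  # within interaction range the two coincide
      checked <- checked + 1
      expect_equal(sqrt(sum(w^2)), sqrt(best), tolerance = 1e-9)
    }
  }
  expect_gt(checked, 50)
  # conventional wrap without shear
  expect_equal(minimum_image(c(0, 0, 6), 10), c(0, 0, -4))
  expect_equal(minimum_image(c(1, -2, 3), 10), c(1, -2, 3))
})

test_that("unknown species and too-small boxes are rejected", {
  tab <- m0_table()
  cfg <- gel_configuration(rbind(c(1, 1, 1), c(2, 2, 2)), "XX", 8)
  expect_error(compute_forces_stress(cfg, tab), "species")
  cfg2 <- gel_configuration(rbind(c(1, 1, 1), c(2, 2, 2)), "M0", 3.5)
  expect_error(compute_forces_stress(cfg2, tab), "cutoff")
})

test_that("unit mapping reproduces the physical stress and time scales", {
  u <- unit_system()  # d = 1 um, eps = 100 kT at 300 K, Stokes drag in water
  expect_equal(to_physical(1, "stress", u), 0.4, tolerance = 0.05)
  expect_equal(to_physical(1, "time", u), 2e-2, tolerance = 0.15)
  expect_identical(to_physical(0, "length", u), 0)
  expect_equal(to_physical(1, "energy", u), u$eps_phys)
  expect_equal(to_physical(2, "frequency", u), 2 / u$tau_phys)
  expect_error(to_physical(1, "mass", u))
  expect_error(unit_system(d_phys = -1), "positive")
})

test_that("parameter presets match the published table", {
  expect_equal(unclass(gel_species("PIC"))[c("A", "B", "cos_theta_bar")],
               list(A = 30, B = 10, cos_theta_bar = 0.4226))
  expect_equal(unclass(gel_species("UPy"))[c("A", "B", "cos_theta_bar")],
               list(A = 55, B = 10, cos_theta_bar = 0.34071))
  expect_equal(unclass(gel_species("BTA"))[c("A", "B", "cos_theta_bar")],
               list(A = 1.833, B = 10, cos_theta_bar = 0.4226))
  pu <- gel_cross("PIC", "UPy")
  expect_equal(pu$A, 1)
  expect_equal(pu$B, 0)
  expect_true(is.na(pu$cos_theta_bar))
  expect_equal(pu$order, "simultaneous")
  pb <- gel_cross("PIC", "BTA")
  expect_equal(pb[c("A", "B", "cos_theta_bar")],
               list(A = 1.833, B = 10, cos_theta_bar = 0.4226))
  expect_equal(pb$order, "sequential")
  expect_error(gel_species("OBO"), "unknown")
})

test_that("mixed triplets involving the colocalizing pair contribute nothing", {
  # two PIC + one UPy in a tight triangle: only same-species triplets count
  tab <- preset_interaction_table(c("PIC", "UPy"))
  pos <- rbind(c(4, 4, 4), c(5, 4, 4), c(4.5, 4.87, 4))
  cfg <- gel_configuration(pos, c("PIC", "PIC", "UPy"), 8)
  fs <- compute_forces_stress(cfg, tab)
  # oracle: pair energies (PIC-PIC with A=30, PIC-UPy with A=1) plus the
  # single all-PIC-centered triplet... all triplets contain both species
  # except none (only 3 particles, every triplet has the UPy bead) -> no E3
  mi <- function(v) v
  r12 <- sqrt(sum((pos[2, ] - pos[1, ])^2))
  r13 <- sqrt(sum((pos[3, ] - pos[1, ])^2))
  r23 <- sqrt(sum((pos[3, ] - pos[2, ])^2))
  e_pairs <- pair_energy(r12, 30) + pair_energy(r13, 1) + pair_energy(r23, 1)
  expect_equal(fs$potential_energy, e_pairs, tolerance = 1e-12)
})

test_that("interaction tables validate their invariants", {
  expect_error(species_params("X", A = -1, B = 0, NA), "A must")
  expect_error(species_params("X", A = 1, B = -1, NA), "B must")
  expect_error(species_params("X", A = 1, B = 5, cos_theta_bar = 2), "cos")
  expect_error(interaction_table(list(gel_species("PIC"),
                                      gel_species("UPy"))),
               "missing cross row")
  tab <- preset_interaction_table(c("PIC", "UPy"))
  expect_true(is.na(tab$cross[["PIC:UPy"]]$cos_theta_bar))  # flagged unused
  # symmetric under pair swap
  expect_identical(gel_cross("UPy", "PIC")$key, gel_cross("PIC", "UPy")$key)
})
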