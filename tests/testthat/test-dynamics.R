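# Integrators: thermostat, zero-T damped drain, conservative mode,
# Lees-Edwards strain stepping.

test_that("thermostat holds the target temperature (ideal-gas limit)", {
  # negligible interactions: equipartition fixes the sampled temperature
  tab <- interaction_table(list(species_params("gas", 1e-9, 0, NA)))
  cfg <- gel_configuration(generate_fixture("lattice",
                                            list(L = 8, phi = 0.05,
                                                 species = "gas"))$positions,
                           "gas", 8)
  cfg <- initialize_velocities(cfg, 0.75, seed = 3)  # start off-target
  st <- integrator_settings(mode = "thermostatted", target_T = 0.5, seed = 3)
  out <- run_thermostatted(cfg, tab, st, duration = 100, log_stride = 10)
  log <- attr(out, "log")
  expect_equal(mean(log$T[log$time > 50]), 0.5, tolerance = 0.05)
  # thermostat acts on peculiar velocities: total momentum stays ~0
  expect_lt(max(abs(colSums(out$velocities))), 1e-10)
})

test_that("thermostatted runs track the target on an interacting system", {
  tab <- m0_table()
  cfg <- generate_fixture("lattice", list(L = 8, phi = 0.05))
  st <- integrator_settings(mode = "thermostatted", target_T = 0.5, seed = 7)
  out <- run_thermostatted(cfg, tab, st, duration = 50, log_stride = 10)
  log <- attr(out, "log")
  expect_equal(mean(log$T[log$time > 25]), 0.5, tolerance = 0.05)
})

test_that("identical seeds give identical trajectories", {
  tab <- m0_table()
  cfg <- generate_fixture("lattice", list(L = 8, phi = 0.05))
  st <- integrator_settings(mode = "thermostatted", target_T = 0.5, seed = 42)
  o1 <- run_thermostatted(cfg, tab, st, duration = 5)
  o2 <- run_thermostatted(cfg, tab, st, duration = 5)
  expect_identical(o1$positions, o2$positions)
  expect_identical(o1$velocities, o2$velocities)
})

test_that("damped drain reaches the inherent-structure criterion", {
  tab <- m0_table()
  cfg <- generate_fixture("lattice", list(L = 8, phi = 0.05))
  st <- integrator_settings(mode = "thermostatted", target_T = 0.5, seed = 7)
  cfg <- run_thermostatted(cfg, tab, st, duration = 30)
  stq <- integrator_settings(mode = "thermostatted", target_T = 0.05)
  cfg <- run_thermostatted(cfg, tab, stq, duration = 20)
  std <- integrator_settings(mode = "damped_zero_T")
  out <- run_damped_zero_T(cfg, tab, std, stop_T = 1e-10, max_time = 4e4,
                           log_stride = 500)
  expect_lt(kinetic_temperature(out), 1e-10)
  # total energy is non-increasing along the dissipative trajectory
  # (up to O(dt^2) integrator error, ~1e-4 against a ~6 eps total drop)
  log <- attr(out, "log")
  E <- log$PE + 1.5 * nrow(out$positions) * log$T
  expect_true(all(diff(E) < 1e-3))
  expect_lt(E[length(E)], E[1] - 1)
  # inherent structure: residual forces are small
  fs <- compute_forces_stress(out, tab)
  expect_lt(max(abs(fs$forces)), 1e-3)
  # potential energy did not increase over the drain
  expect_lte(log$PE[nrow(log)], log$PE[1] + 1e-8)
})

test_that("a displaced pair relaxes to the pair minimum under damping", {
  tab <- m0_table()
  cfg <- gel_configuration(rbind(c(3, 3, 3), c(4.3, 3, 3)), "M0", 8)
  std <- integrator_settings(mode = "damped_zero_T")
  out <- run_damped_zero_T(cfg, tab, std, stop_T = 1e-14)
  d <- sqrt(sum(minimum_image(out$positions[2, ] - out$positions[1, ],
                              8)^2))
  expect_equal(d, r_min_m0, tolerance = 1e-6)
})

test_that("drain errors out when the step budget is exhausted", {
  tab <- m0_table()
  cfg <- generate_fixture("lattice", list(L = 8, phi = 0.05))
  cfg <- initialize_velocities(cfg, 0.5, seed = 1)
  std <- integrator_settings(mode = "damped_zero_T")
  expect_error(run_damped_zero_T(cfg, tab, std, stop_T = 1e-12,
                                 max_time = 0.5),
               "did not reach")
})

test_that("conservative-mode energy drift shrinks ~4x when dt is halved", {
  tab <- m0_table()
  set.seed(11)
  f <- generate_fixture("single_fiber", list(n = 6))
  cfg <- gel_configuration(f$positions + matrix(rnorm(18, sd = 0.03), 6, 3),
                           "M0", f$L)
  drift <- function(dt) {
    st <- integrator_settings(dt = dt, mode = "conservative")
    o <- run_conservative(cfg, tab, st, duration = 20,
                          log_stride = max(1, round(0.05 / dt)))
    lg <- attr(o, "log")
    E <- lg$PE + 1.5 * nrow(cfg$positions) * lg$T
    max(abs(E - E[1]))
  }
  ratio <- drift(0.005) / drift(0.0025)
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6.5)
})

test_that("strain steps act affinely and accumulate", {
  set.seed(5)
  pos <- matrix(runif(30, 0, 8), 10, 3)
  cfg <- gel_configuration(pos, "M0", 8)
  out <- apply_strain_step(cfg, 0)
  expect_identical(out$positions, cfg$positions)
  dg <- 0.004  # small enough that no particle crosses a boundary
  out <- apply_strain_step(cfg, dg)
  expect_equal(out$positions[, 1], pos[, 1] + dg * pos[, 3])
  expect_equal(out$positions[, 2:3], pos[, 2:3])
  expect_equal(out$le_offset, dg * 8)
  for (i in 1:5) cfg <- apply_strain_step(cfg, 0.01)
  expect_equal(cfg$accumulated_strain, 5 * 0.01)
  expect_error(apply_strain_step(cfg, 1.2), "delta_gamma")
})

test_that("energy is invariant under full-image Lees-Edwards re-tiling", {
  tab <- m0_table()
  set.seed(5)
  pos <- matrix(runif(30, 0, 8), 10, 3)
  e <- function(le) compute_forces_stress(
    gel_configuration(pos, "M0", 8, le_offset = le), tab)$potential_energy
  expect_equal(e(1.7), e(1.7 - 8), tolerance = 1e-12)
  expect_equal(e(1.7), e(1.7 + 8), tolerance = 1e-12)
})

test_that("results are independent of neighbour-list rebuild frequency", {
  # same trajectory with a generous and with a tiny skin (frequent rebuilds)
  tabA <- m0_table()
  tabB <- tabA
  cfg <- generate_fixture("lattice", list(L = 8, phi = 0.05))
  cfg <- initialize_velocities(cfg, 0.5, seed = 9)
  st <- integrator_settings(mode = "thermostatted", target_T = 0.5)
  run_with_skin <- function(skin) {
    cm <- gelsim:::compile_table(tabA, skin = skin)
    sp <- gelsim:::species_codes(cfg, cm)
    gelsim:::cpp_md_run(cfg$positions, cfg$velocities, sp, cfg$L, 0, 0, cm,
                        1L, 0.005, 2000L, 0.5, 0.5, 1, 0, numeric(0), 0L,
                        matrix(0, 0, 3), numeric(0), 0, 100L)$positions
  }
  expect_equal(run_with_skin(0.3), run_with_skin(0.05), tolerance = 1e-9)
})
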