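# Pore-size analysis: clearance field, probe-weighted and census methods.

test_that("clearance field matches hand-computed periodic distances", {
  cfg <- gel_configuration(matrix(c(5, 5, 5), 1), "M0", 10)
  cl <- grid_clearance_field(cfg, N_g = 10)
  # corner node: periodic distance sqrt(3) * 5 to the central particle
  expect_equal(cl[1, 1, 1], sqrt(75) - 0.5, tolerance = 1e-12)
  # node at the particle centre is inside the particle -> zero
  expect_identical(cl[6, 6, 6], 0)
  expect_error(grid_clearance_field(
    gel_configuration(matrix(0, 0, 3), character(0), 10), 10),
    "empty")
})

test_that("probe assignment agrees with a plain-R brute-force oracle", {
  set.seed(9)
  cfg <- gel_configuration(rbind(c(2, 2, 2), c(6, 6, 6)), "M0", 8)
  clear <- grid_clearance_field(cfg, N_g = 8)
  L <- 8; Ng <- 8
  probes <- matrix(runif(450, 0, L), 150, 3)
  mi <- function(v) v - L * round(v / L)
  oracle <- function(p) {
    dmin <- min(sqrt(rowSums(mi(sweep(cfg$positions, 2, p))^2)))
    if (dmin < 0.5) return(NA_real_)
    best <- -1
    for (i in 0:(Ng - 1)) for (j in 0:(Ng - 1)) for (k in 0:(Ng - 1)) {
      cc <- clear[i + 1, j + 1, k + 1]
      if (cc <= best) next
      if (sum(mi(c(i, j, k) * (L / Ng) - p)^2) < cc^2) best <- cc
    }
    if (best < 0) NA_real_ else best
  }
  expected <- vapply(seq_len(150), function(q) oracle(probes[q, ]), 0)
  got <- gelsim:::cpp_pore_assign(as.numeric(clear), Ng, L, probes,
                                  cfg$positions, 0.5)
  got_R <- ifelse(got$status == 0L, got$R, NA_real_)
  expect_identical(is.na(expected), is.na(got_R))
  expect_equal(got_R[!is.na(got_R)], expected[!is.na(expected)],
               tolerance = 1e-12)
})

test_that("probe-weighted mean pore size matches the fine-grid brute force", {
  # reference values computed once by an exhaustive brute-force evaluation
  # of the same definitions on a much finer grid (N_g = 100 resp. 60,
  # 3e4 probes), independent of the package code
  cc <- generate_fixture("corner_cube")
  p <- pore_size_probe(cc, N_g = 25, N_r = 6000, seed = 2)
  expect_equal(p$mean_R, 4.3115, tolerance = 0.05)
  # curved cavity walls converge more slowly with the grid, so the
  # comparison uses a finer analysis grid than the open corner-cube box
  tp <- generate_fixture("two_pore")
  p2 <- pore_size_probe(tp, N_g = 40, N_r = 6000, seed = 2)
  expect_equal(p2$mean_R, 3.2138, tolerance = 0.05)
  expect_identical(p$P_gt[1], 1)
  expect_true(all(diff(p$P_gt) <= 1e-12))
})

test_that("defaults match the published analysis settings", {
  f <- formals(pore_size_probe)
  expect_equal(eval(f$N_r), 5e4)
  expect_equal(eval(f$N_g), 25)
  expect_equal(eval(f$r_colloid), 0.5)
  expect_equal(eval(formals(pore_size_census)$r_c), 0.25)
})

test_that("grid census counts each pore once and respects the niche
           cutoff", {
  tp <- generate_fixture("two_pore")
  cen <- pore_size_probe(tp, N_g = 20, N_r = 3000, seed = 1)
  ces <- pore_size_census(tp, N_g = 20)
  # volume weighting: the probe mean leans toward the big pore
  expect_gt(cen$mean_R, ces$mean_R)
  expect_true(all(ces$R_samples > 0.25))
  # two identical cavities: both estimators find the same largest pore,
  # and the probe mean concentrates on that common radius
  eq <- generate_fixture("two_pore", list(L = 12, R1 = 3.0, R2 = 3.0))
  pe <- pore_size_probe(eq, N_g = 20, N_r = 3000, seed = 1)
  ce <- pore_size_census(eq, N_g = 20)
  expect_equal(max(pe$R_samples), max(ce$R_samples), tolerance = 1e-9)
  expect_equal(pe$mean_R, max(pe$R_samples), tolerance = 0.15)
  # a space-filling packing leaves no pore above the cutoff
  g <- (1:16 - 0.5) * 0.5
  dense <- gel_configuration(as.matrix(expand.grid(g, g, g)), "M0", 8)
  expect_error(pore_size_census(dense, N_g = 10), "no pores")
  expect_error(pore_size_probe(dense, N_g = 10, N_r = 500, seed = 1),
               "acceptance rate")
})

test_that("mean pore size equals the area under the survival curve", {
  # step survival: all pores of radius R0
  R0 <- 1.7
  R <- seq(0, 3, length.out = 600)
  expect_equal(mean_pore_size(list(R_values = R, P_gt = as.numeric(R < R0))),
               R0, tolerance = 0.01)
  # exponential survival: mean equals the decay length
  lam <- 0.8
  R2 <- seq(0, 12, length.out = 2000)
  expect_equal(mean_pore_size(list(R_values = R2, P_gt = exp(-R2 / lam))),
               lam, tolerance = 0.01)
  expect_error(mean_pore_size(list(R_values = c(0, 1, 2),
                                   P_gt = c(0.5, 1, 0))),
               "non-increasing")
  # two-estimator consistency on a fixture
  cc <- generate_fixture("corner_cube")
  p <- pore_size_probe(cc, N_g = 20, N_r = 3000, seed = 5)
  expect_equal(mean_pore_size(p), mean(p$R_samples), tolerance = 0.02)
})

test_that("the mean is stable against grid resolution and probe seed", {
  cc <- generate_fixture("corner_cube")
  p15 <- pore_size_probe(cc, N_g = 15, N_r = 3000, seed = 3)
  p25 <- pore_size_probe(cc, N_g = 25, N_r = 3000, seed = 3)
  expect_equal(p15$mean_R, p25$mean_R, tolerance = 0.1)
  q <- pore_size_probe(cc, N_g = 25, N_r = 3000, seed = 77)
  expect_equal(q$mean_R, p25$mean_R, tolerance = 0.05)
})

test_that("species filtering equals analysing the stripped configuration", {
  set.seed(21)
  posA <- matrix(runif(45, 0, 9), 15, 3)
  posB <- matrix(runif(30, 0, 9), 10, 3)
  cfg <- gel_configuration(rbind(posA, posB),
                           rep(c("PIC", "UPy"), c(15, 10)), 9)
  full <- pore_size_probe(cfg, N_g = 12, N_r = 800, seed = 6,
                          species = "PIC")
  stripped <- pore_size_probe(subset_species(cfg, "PIC"), N_g = 12,
                              N_r = 800, seed = 6)
  expect_identical(full$R_samples, stripped$R_samples)
  expect_equal(full$mean_R, stripped$mean_R)
})
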