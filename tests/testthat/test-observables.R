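brownian_fixture <- function(n = 3000, D = 0.01, dt = 0.1, n_frames = 80,
                             seed = 21) {
  generate_tracers(tracer_spec(n, D, dt, n_frames, box = c(60, 60, 60),
                               seed = seed))
}

test_that("van Hove self part handles degenerate displacements and normalizes", {
  # static particles: all probability mass in the first r bin
  still <- generate_tracers(tracer_spec(200, 0, dt = 1, n_frames = 6,
                                        seed = 4))
  vh <- van_hove_self(still, t_list = 2, r_max = 1, n_bins = 20)
  mass <- vh$G[, 1] * 4 * pi * vh$r^2 * vh$dr
  expect_equal(mass[1], 1, tolerance = 1e-12)
  expect_equal(sum(mass[-1]), 0)
  # uniform displacement by exactly d: a single occupied bin at r = d
  coords <- array(0, dim = c(2, 100, 3))
  set.seed(9)
  coords[1, , ] <- matrix(runif(300, 0, 5), 100, 3)
  d <- c(0.3, 0.4, 0.1) # |d| = 0.5099, inside a bin
  coords[2, , ] <- coords[1, , ] + matrix(d, 100, 3, byrow = TRUE)
  traj <- trajectory_set(coords, times = c(0, 1))
  vh <- van_hove_self(traj, t_list = 1, r_max = 1, n_bins = 50)
  occ <- which(vh$G[, 1] > 0)
  expect_length(occ, 1)
  expect_lt(abs(vh$r[occ] - sqrt(sum(d^2))), vh$dr)
  # normalization holds on stochastic input too
  tr <- brownian_fixture(n = 500, n_frames = 30)
  vh <- van_hove_self(tr, t_list = c(0.5, 1), n_bins = 120)
  for (j in 1:2) {
    expect_equal(sum(vh$G[, j] * 4 * pi * vh$r^2 * vh$dr), 1,
                 tolerance = 1e-3)
  }
  expect_error(van_hove_self(tr, t_list = 1e6), "lag beyond")
})

test_that("Brownian van Hove matches the free-diffusion Gaussian", {
  D <- 0.01; t <- 1
  tr <- brownian_fixture(n = 4000, D = D, n_frames = 60)
  vh <- van_hove_self(tr, t_list = t, r_max = 1.6, n_bins = 80)
  gauss <- (4 * pi * D * t)^(-3 / 2) * exp(-vh$r^2 / (4 * D * t))
  # compare shell-integrated probabilities (binning-robust)
  p_emp <- vh$G[, 1] * 4 * pi * vh$r^2 * vh$dr
  p_th <- gauss * 4 * pi * vh$r^2 * vh$dr
  expect_lt(sum(abs(p_emp - p_th)), 0.05)
})

test_that("ISF satisfies exact identities and limits", {
  tr <- brownian_fixture(n = 300, n_frames = 40)
  q <- q_angstrom_to_nm(1.26)
  expect_equal(q, 12.6)
  curve <- isf_self(tr, NULL, q, t_grid = c(0, 0.5, 1))
  expect_identical(curve$F[1], 1)           # F_s(q, 0) = 1 exactly
  expect_true(all(abs(curve$F) <= 1 + 1e-9))
  # single particle displaced so q * dr = pi: sinc gives exactly 0
  coords <- array(0, dim = c(2, 1, 3))
  coords[2, 1, 1] <- pi / 2
  one <- trajectory_set(coords, times = c(0, 1))
  expect_equal(isf_self(one, NULL, q = 2, t_grid = 1)$F, sin(pi) / pi,
               tolerance = 1e-15)
  # q -> 0+ limit: F -> 1 for all t
  low <- isf_self(tr, NULL, q = 1e-4, t_grid = c(0, 1, 2))
  expect_equal(low$F, rep(1, 3), tolerance = 1e-6)
  expect_error(isf_self(tr, NULL, q = -1, t_grid = 0), "q must be positive")
})

test_that("Brownian ISF follows exp(-q^2 D t) and decays monotonically", {
  D <- 0.01
  tr <- brownian_fixture(n = 3000, D = D, n_frames = 80)
  q <- 12.6
  t_grid <- seq(0, 1.2, by = 0.1)   # q^2 D t up to ~1.9
  curve <- isf_self(tr, NULL, q, t_grid)
  theory <- exp(-q^2 * D * t_grid)
  expect_equal(curve$F, theory, tolerance = 0.02)
  expect_true(all(diff(curve$F) < 0))
})

test_that("transforming the van Hove function reproduces the ISF", {
  D <- 0.01
  tr <- brownian_fixture(n = 3000, D = D, n_frames = 80)
  q <- 12.6
  t_list <- c(0.3, 0.6, 1)
  vh <- van_hove_self(tr, t_list = t_list, r_max = 1.5, n_bins = 150)
  ft <- isf_from_van_hove(vh, q)
  direct <- isf_self(tr, NULL, q, t_grid = t_list)
  expect_equal(ft$F, direct$F, tolerance = 0.01)
})

test_that("compare_isf orders curves and finds the relaxation lag", {
  t_grid <- seq(0, 3, by = 0.5)
  mk <- function(Fv) structure(list(q = 1, t = t_grid, F = Fv),
                               class = "isf_curve")
  a <- mk(exp(-2 * t_grid)); b <- mk(exp(-t_grid))
  cmp <- compare_isf(a, b, threshold = 0.1)
  expect_false(cmp$indistinguishable)
  expect_true(all(cmp$sign[t_grid > 0] == -1))
  expect_equal(cmp$fraction_a_below, 1)
  # a < 0.1 from t = 1.5 on; b = exp(-t) first dips below 0.1 at t = 2.5
  expect_equal(cmp$first_relaxed_lag, 2.5)
  expect_true(compare_isf(a, a)$indistinguishable)
  shifted <- structure(list(q = 1, t = t_grid + 0.5, F = exp(-t_grid)),
                       class = "isf_curve")
  expect_error(compare_isf(a, shifted), "grids")
})

test_that("faster-diffusing tracers give the lower ISF at every positive lag", {
  q <- 12.6
  t_grid <- seq(0, 1, by = 0.2)
  slow <- isf_self(brownian_fixture(n = 2000, D = 0.005, seed = 31),
                   NULL, q, t_grid)
  fast <- isf_self(brownian_fixture(n = 2000, D = 0.010, seed = 32),
                   NULL, q, t_grid)
  cmp <- compare_isf(fast, slow)
  expect_true(all(cmp$sign[t_grid > 0] == -1))
  expect_equal(cmp$fraction_a_below, 1)
})

test_that("density profiles conserve mass and resolve localized planes", {
  lat <- build_lattice(lattice_spec(3, 6, "sheet", atoms_per_monomer = 5))
  lat <- add_ions(lat, n_mg = 300, n_cl = 200, box = c(20, 10, 32), seed = 6)
  coords <- array(0, dim = c(3, nrow(lat$topology$atoms), 3))
  for (f in 1:3) coords[f, , ] <- lat$reference
  traj <- trajectory_set(coords, times = 0:2, box = c(20, 10, 32))
  dp <- density_profile(traj, lat$topology, "z",
                        c("protein", "ion_Mg", "ion_Cl"), n_bins = 64)
  for (sp in colnames(dp$density)) {
    expect_equal(sum(dp$density[, sp]) * dp$slab_volume,
                 dp$total_mass[[sp]],
                 tolerance = 1e-6 * max(dp$total_mass[[sp]], 1))
  }
  # uniform ions: flat within 3 sigma Poisson bands per bin
  mg <- dp$density[, "ion_Mg"] * dp$slab_volume / 24.305  # counts per bin
  expected <- 300 / 64
  expect_true(all(abs(mg - expected) <= 3 * sqrt(expected) + 1e-9))
  # all mass of a species in one plane: single occupied bin
  plane <- lat
  sel <- plane$topology$atoms$species == "ion_Cl"
  plane$reference[sel, 3] <- 16
  coords2 <- coords
  for (f in 1:3) coords2[f, , ] <- plane$reference
  dp2 <- density_profile(trajectory_set(coords2, 0:2, box = c(20, 10, 32)),
                         plane$topology, "z", "ion_Cl", n_bins = 64)
  expect_equal(sum(dp2$density[, 1] > 0), 1)
  expect_error(density_profile(traj, lat$topology, "z", "plutonium"),
               "unknown species")
})
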