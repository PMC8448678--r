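test_that("center-of-mass and axis primitives satisfy their closed forms", {
  lat <- build_lattice(lattice_spec(1, 2, atoms_per_monomer = 4))
  topo <- lat$topology
  # unequal masses (1,3) at x = 0 and 4 -> COM at 3
  frame <- lat$reference
  frame[topo$atoms$monomer == 1, ] <- 0
  frame[which(topo$atoms$monomer == 1)[2], 1] <- 4
  w <- c(1, 3, 0, 0)
  expect_equal(monomer_com(frame, topo, 1, weights = w), c(3, 0, 0))
  # single-atom weight: that atom's position
  w1 <- c(1, 0, 0, 0)
  expect_equal(monomer_com(frame, topo, 1, weights = w1), c(0, 0, 0))
  expect_error(monomer_com(frame, topo, 1, weights = rep(0, 4)), "zero total")
  # straight reference dimer: axis along +z, unit norm
  ax <- dimer_axis(lat$reference, topo, 1)
  expect_equal(ax, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(sqrt(sum(ax^2)), 1, tolerance = 1e-12)
  # rigid rotation of the frame rotates the axis identically
  R <- random_rotation()
  expect_equal(dimer_axis(lat$reference %*% t(R), topo, 1),
               as.vector(R %*% ax), tolerance = 1e-12)
})

test_that("bending_angle matches closed forms and is symmetric", {
  expect_equal(bending_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(bending_angle(c(0, 0, 1), c(0, 1, 1) / sqrt(2)), 45,
               tolerance = 1e-12)
  expect_equal(bending_angle(c(0, 0, 1), c(0, 0, -1)), 180)
  a <- c(0.2, -0.3, 0.93); a <- a / sqrt(sum(a^2))
  b <- c(-0.5, 0.1, 0.86); b <- b / sqrt(sum(b^2))
  expect_equal(bending_angle(a, b), bending_angle(b, a))
})

test_that("imposed bends are recovered exactly without noise", {
  # straight lattice, no noise: all inter-dimer angles 0 +/- 1e-6 degrees
  sys <- make_planted_sheet(atoms = 8, n_frames = 3, seed = 2,
                            noise_override = 0,
                            fractions = c(1e-300, 1e-301))
  bs <- bending_series(sys$trajectory, sys$lattice$topology)
  expect_lt(max(bs$records$angle_deg), 1e-6)
  # 11-degree plus-end bend and 4-degree mid-lattice bend, noise-free
  plan <- list(list(pf = 1:3, layers = 3, angle_deg = 11),
               list(pf = 1:3, layers = 2, angle_deg = 4))
  sys <- make_planted_sheet(atoms = 8, n_frames = 3, seed = 2,
                            noise_override = 0,
                            fractions = c(1e-12, 1e-13), bend_plan = plan)
  bs <- bending_series(sys$trajectory, sys$lattice$topology)
  s <- bs$summary
  expect_equal(s$mean_deg[s$class == "plus_vs_central"], 11 - 4,
               tolerance = 0.5)
  expect_equal(s$mean_deg[s$class == "minus_vs_central"], 4, tolerance = 0.5)
  # a single bent layer recovers the imposed angle exactly
  plan1 <- list(list(pf = 1:3, layers = 3, angle_deg = 11))
  sys1 <- make_planted_sheet(atoms = 8, n_frames = 3, seed = 2,
                             noise_override = 0,
                             fractions = c(1e-12, 1e-13), bend_plan = plan1)
  s1 <- bending_series(sys1$trajectory, sys1$lattice$topology)$summary
  expect_equal(s1$mean_deg[s1$class == "plus_vs_central"], 11,
               tolerance = 1e-6)
})

test_that("under isotropic noise the class mean is unbiased within 3 standard errors", {
  plan <- list(list(pf = 1:3, layers = 3, angle_deg = 11))
  sys <- make_planted_sheet(atoms = 20, n_frames = 400, seed = 7,
                            fractions = c(1e-12, 1e-13),
                            noise_override = 0.0025, bend_plan = plan)
  bs <- bending_series(sys$trajectory, sys$lattice$topology)
  rec <- bs$records[bs$records$pair_class == "plus_vs_central", ]
  se <- sd(rec$angle_deg) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$angle_deg) - 11), 3 * se + 0.02)
})

test_that("bending angles are invariant under global rigid transforms", {
  plan <- list(list(pf = 1, layers = 2:3, angle_deg = 7))
  sys <- make_planted_sheet(atoms = 6, n_frames = 2, seed = 3,
                            bend_plan = plan)
  base <- bending_series(sys$trajectory, sys$lattice$topology)
  R <- random_rotation()
  moved <- sys$trajectory
  for (f in 1:2) {
    moved$coords[f, , ] <- sys$trajectory$coords[f, , ] %*% t(R) +
      matrix(c(5, -3, 2), dim(sys$trajectory$coords)[2], 3, byrow = TRUE)
  }
  rot <- bending_series(moved, sys$lattice$topology)
  expect_lt(max(abs(rot$records$angle_deg - base$records$angle_deg)), 1e-9)
})

test_that("records, histograms and aggregation modes are consistent", {
  plan <- list(list(pf = 2, layers = 3, angle_deg = 9))
  sys <- make_planted_sheet(atoms = 6, n_frames = 5, seed = 11,
                            bend_plan = plan)
  bs <- bending_series(sys$trajectory, sys$lattice$topology)
  # one record per frame per adjacent pair: 3 PFs x 2 pairs x 5 frames
  expect_equal(nrow(bs$records), 30)
  expect_equal(sum(vapply(bs$histograms, function(h) sum(h$count), 0)),
               nrow(bs$records))
  per_pair <- bending_series(sys$trajectory, sys$lattice$topology,
                             aggregate = "pair")
  expect_equal(nrow(per_pair$records), 6)
  # intra-dimer variant runs and reports one record per dimer per frame
  intra <- bending_series(sys$trajectory, sys$lattice$topology,
                          variant = "intra_dimer")
  expect_equal(nrow(intra$records), 9 * 5)
  # a PF with a single dimer yields no inter-dimer pairs, not an error
  tiny <- build_lattice(lattice_spec(1, 2, atoms_per_monomer = 5))
  pm <- planted_modes(random_orthonormal_modes(30, 1, seed = 1), 0.01, 0)
  ttraj <- generate_trajectory(tiny, pm, 2, seed = 1)
  empty <- bending_series(ttraj, tiny$topology)
  expect_equal(nrow(empty$records), 0)
})
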