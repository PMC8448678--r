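test_that("concatenation pools subunit frames with complete provenance", {
  sys <- make_planted_sheet(atoms = 5, n_frames = 20, seed = 3)
  ens <- make_ensemble(sys, "backbone")
  n_at <- length(dimer_atom_ids(sys$lattice$topology, 1, "backbone"))
  expect_equal(dim(ens$X), c(9 * 20, 3 * n_at))
  expect_equal(nrow(ens$labels), nrow(ens$X))
  expect_setequal(unique(ens$labels$dimer_id), 1:9)
  expect_true(all(c("system", "position_class", "time") %in%
                    names(ens$labels)))
  # single subunit, single frame: one row equal to the ensemble mean
  topo <- sys$lattice$topology
  one <- extract_subunit(sys$trajectory, topo, 1, "backbone")
  one$coords <- one$coords[1, , , drop = FALSE]
  one$times <- one$times[1]
  e1 <- concatenate_subunits(list(one),
                             dimer_reference(sys$lattice, 1, "backbone"))
  expect_equal(nrow(e1$X), 1)
  # mismatched selections refused
  other <- extract_subunit(sys$trajectory, topo, 2, "calpha")
  expect_error(concatenate_subunits(list(one, other),
                                    dimer_reference(sys$lattice, 1,
                                                    "backbone")),
               "mismatched")
})

test_that("covariance modes satisfy closed forms and the trace identity", {
  # two rows at +/- d along one direction: single eigenvalue d^2 (population)
  d <- 0.7
  dir <- c(3, 4, 0, 0, 0, 12) / 13
  X <- rbind(d * dir, -d * dir)
  ms <- covariance_modes(X)
  expect_equal(ms$values[1], d^2, tolerance = 1e-12)
  expect_equal(abs(sum(ms$vectors[, 1] * dir)), 1, tolerance = 1e-12)
  expect_lt(max(ms$values[-1]), 1e-14)
  # trace conservation and orthonormality on random data
  set.seed(8)
  X <- matrix(rnorm(400 * 12), 400, 12) %*% diag(sqrt(seq(0.1, 1.2, by = 0.1)))
  ms <- covariance_modes(X)
  pervar <- apply(X, 2, function(v) mean((v - mean(v))^2))
  expect_equal(sum(ms$values), sum(pervar), tolerance = 1e-10)
  expect_equal(crossprod(ms$vectors), diag(12), tolerance = 1e-8)
  expect_true(all(diff(ms$values) <= 1e-12))
  # zero-variance ensemble: all eigenvalues zero, no error
  ms0 <- covariance_modes(matrix(1, 5, 6))
  expect_equal(ms0$values, rep(0, 6))
})

test_that("recovered eigenvalues match a planted 6-D Gaussian within 3%", {
  set.seed(4)
  vars <- c(5, 3, 2, 1, 0.5, 0.2)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  X <- matrix(rnorm(1e5 * 6), ncol = 6) %*% diag(sqrt(vars)) %*% t(Q)
  ms <- covariance_modes(X)
  expect_equal(ms$values, vars, tolerance = 0.03)
})

test_that("eigendecomposition agrees with brute-force covariance assembly", {
  set.seed(15)
  X <- matrix(rnorm(60 * 30), 60, 30)
  ms <- covariance_modes(X)
  ee <- eigen(brute_covariance(X), symmetric = TRUE)
  expect_equal(ms$values, pmax(ee$values, 0), tolerance = 1e-8)
  for (j in 1:10) {
    expect_gt(abs(sum(ms$vectors[, j] * ee$vectors[, j])), 1 - 1e-8)
  }
})

test_that("modes agree with an established PCA implementation on a small ensemble", {
  sys <- make_planted_sheet(atoms = 5, n_frames = 150, seed = 6)
  ens <- make_ensemble(sys, "all")
  ms <- covariance_modes(ens)
  pc <- bio3d::pca.xyz(ens$X, use.svd = FALSE)
  # bio3d uses the sample (N-1) covariance convention
  n <- nrow(ens$X)
  expect_equal(ms$values[1:5], pc$L[1:5] * (n - 1) / n, tolerance = 1e-6)
  for (j in 1:3) {
    expect_gt(abs(sum(ms$vectors[, j] * pc$U[, j])), 1 - 1e-6)
  }
})

test_that("scree fractions, accumulated dynamics and Cattell kinks", {
  ms <- structure(list(values = c(3, 2, 1), mean = rep(0, 3),
                       vectors = diag(3), n_frames = 10, selection = NA),
                  class = "mode_set")
  sc <- scree(ms)
  expect_equal(sc$fraction, c(0.5, 1 / 3, 1 / 6))
  expect_equal(sc$accumulated, c(0.5, 5 / 6, 1))
  expect_equal(sc$accumulated[3], 1)
  # all-equal eigenvalues: accumulated linear in mode index
  ms$values <- rep(2, 5); ms$vectors <- diag(5); ms$mean <- rep(0, 5)
  sc <- scree(ms)
  expect_equal(sc$accumulated, (1:5) / 5)
  # constructed step spectrum: first kink at mode 3
  step <- data.frame(mode_index = 1:6, eigenvalue = c(10, 9, 8, 1, 0.9, 0.8))
  step$fraction <- step$eigenvalue / sum(step$eigenvalue)
  step$accumulated <- cumsum(step$fraction)
  expect_equal(cattell_kink(step)[1], 3)
  # geometric decay: constant log-second-difference, no kink
  geom <- data.frame(mode_index = 1:10, eigenvalue = 0.5^(1:10))
  expect_length(cattell_kink(geom), 0)
  expect_error(cattell_kink(geom[1:2, ]), "at least 3")
})

test_that("projections are centered, exact on constructed rows, and carry the eigenvalues", {
  sys <- make_planted_sheet(atoms = 8, n_frames = 100, seed = 13)
  ens <- make_ensemble(sys, "all")
  ms <- covariance_modes(ens)
  P <- project_ensemble(ens, ms, k = 4)
  # centering: mean projection is zero for every mode
  expect_lt(max(abs(colMeans(P))), 1e-8)
  # population variance of projections equals the eigenvalue
  for (j in 1:4) {
    expect_equal(mean(P[, j]^2) - mean(P[, j])^2, ms$values[j],
                 tolerance = 1e-6 * ms$values[j])
  }
  # constructed rows
  probe <- rbind(ms$mean, ms$mean + 0.25 * ms$vectors[, 1])
  Pp <- project_ensemble(probe, ms, k = 3)
  expect_equal(as.vector(Pp[1, ]), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(as.vector(Pp[2, ]), c(0.25, 0, 0), tolerance = 1e-10)
  # label subsetting
  Pe <- project_ensemble(ens, ms, k = 2, subset = "plus_end")
  expect_true(all(attr(Pe, "labels")$position_class == "plus_end"))
  expect_error(project_ensemble(ens$X[, 1:10], ms), "mismatched")
})

test_that("projection histograms conserve counts and flag empty bins", {
  # all rows identical: a single occupied bin holding log10(N)
  h <- projection_histogram(rep(0.3, 50), rep(-0.1, 50), bins = 21,
                            limits = c(1, 1))
  expect_equal(sum(h$counts), 50)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(max(h$log10_counts, na.rm = TRUE), log10(50))
  expect_true(all(is.na(h$log10_counts[h$counts == 0])))
  # symmetric edges about zero
  expect_equal(h$x, -rev(h$x))
  # isotropic Gaussian: the maximum-count bin contains the origin
  set.seed(77)
  x <- rnorm(2e4); y <- rnorm(2e4)
  h <- projection_histogram(x, y, bins = 11)
  i <- which(h$counts == max(h$counts), arr.ind = TRUE)[1, ]
  expect_lt(abs(h$x[i[1]]), 2 * diff(h$x[1:2]))
  expect_lt(abs(h$y[i[2]]), 2 * diff(h$y[1:2]))
  expect_equal(sum(h$counts), 2e4)
})

test_that("overlap matrices obey identity, permutation and rotation closed forms", {
  set.seed(19)
  V <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  a <- structure(list(vectors = V, values = 8:1, mean = rep(0, 8)),
                 class = "mode_set")
  O <- overlap_matrix(a, a, k = 3)
  expect_equal(unclass(O), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(O, "rmsip"), 1, tolerance = 1e-12)
  # swapped modes give a permutation matrix
  b <- a; b$vectors <- V[, c(2, 1, 3:8)]
  O <- overlap_matrix(a, b, k = 2)
  expect_equal(unclass(O), rbind(c(0, 1), c(1, 0)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # rotation by 45 degrees in the (1,2) plane: sqrt(2)/2 block
  c45 <- a
  c45$vectors[, 1] <- (V[, 1] + V[, 2]) / sqrt(2)
  c45$vectors[, 2] <- (V[, 2] - V[, 1]) / sqrt(2)
  O <- overlap_matrix(a, c45, k = 2)
  expect_equal(unclass(O), matrix(sqrt(2) / 2, 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rmsip(a, c45, 2), 1, tolerance = 1e-12)
  expect_error(overlap_matrix(a, structure(list(vectors = diag(4)),
                                           class = "mode_set")),
               "mismatched")
})

test_that("mode overlap between disjoint subsets grows with concatenation depth", {
  # heavier noise and few frames per subunit so single subunits are ambiguous
  sys <- make_planted_sheet(n_pf = 4, n_layers = 8, atoms = 6, n_frames = 40,
                            fractions = c(0.10, 0.07), seed = 23)
  ens <- make_ensemble(sys, "all")
  cc <- convergence_curve(ens, N_list = c(1, 2, 4, 8), replicates = 12,
                          seed = 5, k = 2)
  expect_equal(cc$N, c(1, 2, 4, 8))
  expect_true(all(cc$mean_overlap >= 0 & cc$mean_overlap <= 1))
  # monotone non-decreasing within replicate error
  slack <- sqrt(cc$se_overlap[-1]^2 + cc$se_overlap[-nrow(cc)]^2)
  expect_true(all(diff(cc$mean_overlap) >= -3 * slack))
  expect_lt(cc$mean_overlap[1], cc$mean_overlap[4])
  expect_error(convergence_curve(ens, N_list = c(1, 16)), "disjoint")
})

test_that("noise-free planted systems give near-perfect split overlap", {
  # zero noise confines all variance to the planted 3-mode span; the only
  # residual eigenvector rotation comes from finite-sample amplitude
  # cross-correlation within that span
  sys <- make_planted_sheet(atoms = 5, n_frames = 200, seed = 29,
                            fractions = c(0.4, 0.1, 0.02),
                            noise_override = 0)
  ens <- make_ensemble(sys, "all")
  cc <- convergence_curve(ens, N_list = c(2, 4), replicates = 4, seed = 2,
                          k = 3)
  expect_true(all(cc$mean_overlap > 0.995))
  expect_true(all(cc$mean_rmsip > 0.999))
})

test_that("block averaging downsamples with trailing partial blocks", {
  expect_equal(block_average(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(block_average(c(1, 2, 3, 4, 10), 2), c(1.5, 3.5, 10))
  expect_equal(block_average(1:7, 1), 1:7)
  expect_equal(block_average(rep(3.3, 9), 4), rep(3.3, 3))
  m <- block_average(cbind(1:4, c(2, 2, 4, 4)), 2)
  expect_equal(unname(m), rbind(c(1.5, 2), c(3.5, 4)), ignore_attr = TRUE)
  expect_error(block_average(1:3, 0), "block_size")
})
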