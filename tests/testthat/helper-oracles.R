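# Independent oracles and small fixture builders shared across tests.

# Brute-force population covariance: explicit outer-product accumulation,
# independent of the crossprod-based assembly in covariance_modes().
brute_covariance <- function(X) {
  N <- nrow(X)
  mu <- colMeans(X)
  C <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(N)) {
    v <- X[i, ] - mu
    C <- C + tcrossprod(v)
  }
  C / N
}

# Quaternion grid-search RMSD oracle: hierarchical refinement over rotations
# parameterized by unit quaternions, translations handled by centroid overlay.
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

quat_grid_rmsd <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  P <- sweep(mobile, 2, colSums(mobile * w))
  Q <- sweep(reference, 2, colSums(reference * w))
  score <- function(q) {
    R <- quat_to_rot(q)
    sqrt(sum(w * rowSums((P %*% t(R) - Q)^2)))
  }
  # coarse global stage: deterministic quasi-random quaternions
  set.seed(424242)
  cand <- matrix(rnorm(4 * 4000), ncol = 4)
  vals <- apply(cand, 1, score)
  best <- cand[which.min(vals), ]
  best <- best / sqrt(sum(best^2))
  width <- 0.5
  for (stage in 1:8) {
    jit <- matrix(rnorm(4 * 600, sd = width), ncol = 4)
    cand <- sweep(jit, 2, best, "+")
    vals <- apply(cand, 1, score)
    i <- which.min(vals)
    if (vals[i] < score(best)) best <- cand[i, ] / sqrt(sum(cand[i, ]^2))
    width <- width / 4
  }
  score(best)
}

# random proper rotation
random_rotation <- function() {
  quat_to_rot(rnorm(4))
}

# small sheet lattice with planted modes for recovery tests
make_planted_sheet <- function(n_pf = 3, n_layers = 6, atoms = 20,
                               fractions = c(0.15, 0.10, 0.08),
                               total_variance = 0.5, n_frames = 500,
                               seed = 1L, bend_plan = NULL,
                               noise_override = NULL) {
  lat <- build_lattice(lattice_spec(n_pf, n_layers, "sheet",
                                    atoms_per_monomer = atoms))
  n_coords <- 3L * 2L * atoms
  plan <- tryCatch(
    plant_variance_fractions(fractions, n_coords, total_variance),
    error = function(e) list(variances = fractions * total_variance,
                             noise_variance = 0))
  if (!is.null(noise_override)) plan$noise_variance <- noise_override
  dirs <- random_orthonormal_modes(n_coords, length(fractions),
                                   reference = dimer_reference(lat, 1, "all"),
                                   seed = seed + 1000L)
  pm <- planted_modes(dirs, plan$variances, plan$noise_variance,
                      bend_plan = bend_plan)
  traj <- generate_trajectory(lat, pm, n_frames, seed = seed)
  list(lattice = lat, planted = pm, trajectory = traj, plan = plan)
}

# concatenated ensemble over all dimers of a lattice trajectory
make_ensemble <- function(sys, selection = "all", fit = TRUE) {
  topo <- sys$lattice$topology
  subs <- lapply(topo$dimers$id, function(d) {
    extract_subunit(sys$trajectory, topo, d, selection)
  })
  concatenate_subunits(subs, dimer_reference(sys$lattice, 1, selection),
                       fit = fit)
}
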