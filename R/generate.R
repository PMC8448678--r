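#' Generate a synthetic assembly trajectory with planted dynamics
#'
#' Per dimer and frame, coordinates are built in the dimer's local frame as
#' `reference + sum_k a_k(frame) * mode_k + noise`, with amplitudes `a_k` drawn
#' independently per frame from a Gaussian of the planted variance (or from a
#' stationary Ornstein-Uhlenbeck process when `ou_tau` is set in the planted
#' spec), plus isotropic Gaussian noise on every coordinate.  An optional bend
#' plan then applies rigid rotations of whole dimers about a lateral axis
#' through the inter-dimer interface below the dimer.  The result is mapped
#' back to the global frame.  Identical seeds give bit-identical trajectories.
#'
#' @param lattice An `assembly_lattice` from [build_lattice()].
#' @param planted A [planted_modes()] whose directions have dimension
#'   3 x (atoms per dimer).
#' @param n_frames Number of frames.
#' @param dt Sampling interval in ps (default 10 ps).
#' @param seed Integer seed.
#' @return A [trajectory_set()] with a `manifest` attribute recording the
#'   lattice spec, planted variances and seed.
#' @export
generate_trajectory <- function(lattice, planted, n_frames, dt = 10,
                                seed = 1L) {
  stopifnot(inherits(lattice, "assembly_lattice"),
            inherits(planted, "planted_modes"))
  topo <- lattice$topology
  A <- lattice$spec$atoms_per_monomer
  M <- 2L * A                            # atoms per dimer
  if (nrow(planted$directions) != 3L * M) {
    stop(sprintf("planted mode dimension %d does not match 3 x %d atoms",
                 nrow(planted$directions), M))
  }
  k <- ncol(planted$directions)
  n_dimers <- nrow(topo$dimers)
  prot_atoms <- which(topo$atoms$species == "protein")
  n_atoms <- nrow(topo$atoms)
  coords <- array(0, dim = c(n_frames, n_atoms, 3))
  # solvent (if any) stays at its reference position
  for (i in setdiff(seq_len(n_atoms), prot_atoms)) {
    coords[, i, ] <- matrix(lattice$reference[i, ], n_frames, 3, byrow = TRUE)
  }
  s <- lattice$spec$monomer_spacing

  set.seed(seed)
  for (d in seq_len(n_dimers)) {
    ids <- dimer_atom_ids(topo, topo$dimers$id[d], "all")
    R <- dimer_rotation(topo, d)
    org <- unlist(topo$dimers[d, c("ox", "oy", "oz")])
    local_ref <- sweep(lattice$reference[ids, , drop = FALSE], 2, org) %*% R

    amp <- sample_amplitudes(n_frames, planted$variances, planted$ou_tau)
    disp <- amp %*% t(planted$directions)
    if (planted$noise_variance > 0) {
      disp <- disp + matrix(
        stats::rnorm(n_frames * 3 * M, sd = sqrt(planted$noise_variance)),
        n_frames, 3 * M)
    }
    bend <- bend_for_dimer(planted$bend_plan, topo$dimers$pf[d],
                           topo$dimers$layer[d], n_frames)
    for (f in seq_len(n_frames)) {
      local <- local_ref + matrix(disp[f, ], M, 3, byrow = TRUE)
      if (!is.null(bend) && bend[f] != 0) {
        local <- rotate_about_x(local, bend[f] * pi / 180, pivot = c(0, 0, -s))
      }
      coords[f, ids, ] <- local %*% t(R) +
        matrix(org, M, 3, byrow = TRUE)
    }
  }
  traj <- trajectory_set(coords, times = (seq_len(n_frames) - 1) * dt,
                         box = rep(NA_real_, 3),
                         provenance = sprintf("synthetic_%s",
                                              lattice$spec$geometry))
  attr(traj, "manifest") <- list(
    lattice_spec = unclass(lattice$spec),
    planted_variances = planted$variances,
    noise_variance = planted$noise_variance,
    mode_labels = planted$labels,
    bend_plan = planted$bend_plan,
    n_frames = n_frames, dt = dt, seed = seed
  )
  traj
}

# i.i.d. or stationary-OU Gaussian amplitudes, n_frames x k
sample_amplitudes <- function(n_frames, variances, ou_tau = NULL) {
  k <- length(variances)
  eps <- matrix(stats::rnorm(n_frames * k), n_frames, k)
  eps <- sweep(eps, 2, sqrt(variances), "*")
  if (is.null(ou_tau)) return(eps)
  rho <- exp(-1 / ou_tau)
  amp <- eps
  for (f in 2:n_frames) {
    amp[f, ] <- rho * amp[f - 1, ] + sqrt(1 - rho^2) * eps[f, ]
  }
  amp
}

# per-frame bend angle (degrees) for a dimer, or NULL when no bend applies
bend_for_dimer <- function(bend_plan, pf, layer, n_frames) {
  if (is.null(bend_plan)) return(NULL)
  for (b in bend_plan) {
    if (pf %in% b$pf && layer %in% b$layers) {
      ramp <- if (is.null(b$ramp_frames)) 0L else b$ramp_frames
      if (ramp <= 0) return(rep(b$angle_deg, n_frames))
      return(pmin(seq_len(n_frames) / ramp, 1) * b$angle_deg)
    }
  }
  NULL
}

# rotate rows of X about the local x axis through `pivot` by `angle` radians
rotate_about_x <- function(X, angle, pivot) {
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(angle), -sin(angle)),
              c(0, sin(angle), cos(angle)))
  sweep(sweep(X, 2, pivot) %*% t(Rx), 2, pivot, "+")
}

#' Specify a Brownian tracer system
#'
#' A fixture for validating displacement-based observables (mean squared
#' displacement, van Hove self-correlation, self-intermediate scattering):
#' independent ideal Brownian particles with known diffusion coefficient.
#'
#' @param n_particles Number of particles.
#' @param diffusion_coefficient D in nm^2/ps.
#' @param dt Frame interval, ps.
#' @param n_frames Number of frames.
#' @param box Box lengths, nm; must be large enough that the RMS displacement
#'   over the run is well below box/2 (warned otherwise).
#' @param seed Integer seed.
#' @return Object of class `tracer_spec`.
#' @export
tracer_spec <- function(n_particles, diffusion_coefficient, dt, n_frames,
                        box = c(50, 50, 50), seed = 1L) {
  if (n_particles < 1 || diffusion_coefficient < 0 || dt <= 0 || n_frames < 1 ||
      any(box <= 0)) {
    stop("all tracer_spec parameters must be positive")
  }
  rms <- sqrt(6 * diffusion_coefficient * dt * (n_frames - 1))
  if (rms > min(box) / 4) {
    warning("RMS displacement over the run approaches box/2; enlarge the box")
  }
  structure(list(n_particles = as.integer(n_particles),
                 diffusion_coefficient = diffusion_coefficient,
                 dt = dt, n_frames = as.integer(n_frames), box = box,
                 seed = as.integer(seed)),
            class = "tracer_spec")
}

#' Generate Brownian tracer trajectories
#'
#' Gaussian random-walk displacements with per-axis step variance 2*D*dt.
#' Stored coordinates are unwrapped (true displacements retained).
#'
#' @param spec A [tracer_spec()].
#' @return A [trajectory_set()].
#' @export
generate_tracers <- function(spec) {
  stopifnot(inherits(spec, "tracer_spec"))
  set.seed(spec$seed)
  N <- spec$n_particles
  f <- spec$n_frames
  start <- cbind(stats::runif(N, 0, spec$box[1]),
                 stats::runif(N, 0, spec$box[2]),
                 stats::runif(N, 0, spec$box[3]))
  coords <- array(0, dim = c(f, N, 3))
  coords[1, , ] <- start
  if (f > 1 && spec$diffusion_coefficient > 0) {
    sd_step <- sqrt(2 * spec$diffusion_coefficient * spec$dt)
    for (axis in 1:3) {
      steps <- matrix(stats::rnorm((f - 1) * N, sd = sd_step), f - 1, N)
      coords[, , axis] <- rbind(start[, axis],
                                matrix(start[, axis], f - 1, N,
                                       byrow = TRUE) + apply(steps, 2, cumsum))
    }
  } else if (f > 1) {
    for (fr in 2:f) coords[fr, , ] <- start
  }
  traj <- trajectory_set(coords, times = (seq_len(f) - 1) * spec$dt,
                         box = spec$box, provenance = "brownian_tracers")
  attr(traj, "manifest") <- unclass(spec)
  traj
}

#' Mean squared displacement
#'
#' Time-origin-averaged MSD of a trajectory at the requested frame lags; for
#' ideal Brownian motion MSD(t) = 6*D*t.
#'
#' @param trajectory A [trajectory_set()].
#' @param lags Integer frame lags.
#' @param origin_stride Use every `origin_stride`-th frame as a time origin.
#' @return data.frame with `lag_ps` and `msd_nm2`.
#' @export
mean_squared_displacement <- function(trajectory, lags, origin_stride = 1L) {
  n <- dim(trajectory$coords)[1]
  dt <- if (n > 1) trajectory$times[2] - trajectory$times[1] else 0
  msd <- vapply(lags, function(l) {
    origins <- seq(1L, n - l, by = origin_stride)
    mean(vapply(origins, function(o) {
      d <- trajectory$coords[o + l, , ] - trajectory$coords[o, , ]
      mean(rowSums(d^2))
    }, 0))
  }, 0)
  data.frame(lag_ps = lags * dt, msd_nm2 = msd)
}
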