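# one frame as an atoms x 3 matrix (robust to single-atom selections)
frame_mat <- function(coords, f) matrix(coords[f, , ], ncol = 3)

# frame lags corresponding to requested lag times, given uniform frame times
lag_frames <- function(times, t_lags) {
  n <- length(times)
  dt <- if (n > 1) times[2] - times[1] else 1
  lf <- round(t_lags / dt)
  if (any(abs(t_lags / dt - lf) > 1e-6)) {
    stop("requested lags are not multiples of the frame interval")
  }
  if (any(lf >= n)) stop("lag beyond trajectory length")
  as.integer(lf)
}

# time origins for a given frame lag: by default every frame in the first half
# of the trajectory, thinned by `stride`, always at least one origin
time_origins <- function(n_frames, lag, stride = 1L) {
  last <- min(max(floor(n_frames / 2), 1L), n_frames - lag)
  if (last < 1) last <- 1L
  seq(1L, last, by = stride)
}

#' Self part of the van Hove correlation function
#'
#' Distribution of single-particle displacement magnitudes over a lag time,
#' estimated by histogramming over particles and time origins and normalized
#' so that the self-part integral `sum G_s(r,t) 4 pi r^2 dr = 1`.  For free
#' Brownian diffusion the result is the Gaussian
#' `(4 pi D t)^(-3/2) exp(-r^2 / (4 D t))`.
#'
#' @param trajectory A [trajectory_set()] with unwrapped coordinates.
#' @param selection Atom indices (default all atoms).
#' @param t_list Lag times (ps), multiples of the frame interval.
#' @param r_max Upper edge of the displacement grid (nm); default chosen from
#'   the largest observed displacement.
#' @param n_bins Number of r bins (default 200).
#' @param origin_stride Use every `origin_stride`-th frame of the first half
#'   of the trajectory as a time origin (default 1).
#' @return Object of class `van_hove`: list with `r` (bin centers, nm), `dr`,
#'   `t` (ps), `G` (bins x lags matrix), `n_particles`, `n_time_origins`.
#' @export
van_hove_self <- function(trajectory, selection = NULL, t_list,
                          r_max = NULL, n_bins = 200, origin_stride = 1L) {
  coords <- trajectory$coords
  if (!is.null(selection)) coords <- coords[, selection, , drop = FALSE]
  n <- dim(coords)[1]
  lf <- lag_frames(trajectory$times, t_list)
  if (any(lf == 0)) stop("van Hove lags must be positive")
  if (is.null(r_max)) {
    l <- max(lf)
    o <- time_origins(n, l, origin_stride)[1]
    d <- sqrt(rowSums((frame_mat(coords, o + l) - frame_mat(coords, o))^2))
    r_max <- max(d) * 1.5 + 1e-9
  }
  breaks <- seq(0, r_max, length.out = n_bins + 1)
  dr <- breaks[2] - breaks[1]
  centers <- breaks[-1] - dr / 2
  G <- matrix(0, n_bins, length(lf))
  origins_used <- integer(length(lf))
  for (j in seq_along(lf)) {
    l <- lf[j]
    origins <- time_origins(n, l, origin_stride)
    origins_used[j] <- length(origins)
    counts <- numeric(n_bins)
    for (o in origins) {
      d <- sqrt(rowSums((frame_mat(coords, o + l) - frame_mat(coords, o))^2))
      d <- pmin(d, r_max - 1e-12)
      idx <- pmin(pmax(findInterval(d, breaks, all.inside = TRUE), 1L), n_bins)
      counts <- counts + tabulate(idx, nbins = n_bins)
    }
    n_samples <- length(origins) * dim(coords)[2]
    G[, j] <- counts / (n_samples * 4 * pi * centers^2 * dr)
  }
  structure(list(r = centers, dr = dr, t = t_list, G = G,
                 n_particles = dim(coords)[2],
                 n_time_origins = origins_used,
                 origin_stride = origin_stride),
            class = "van_hove")
}

#' Self-intermediate scattering function
#'
#' Isotropically averaged `F_s(q,t) = < sin(q dr) / (q dr) >` over particles
#' and time origins (the spatial Fourier transform of the self van Hove
#' function at scalar q); the sinc kernel is exact for isotropic systems and
#' `F_s(q,0) = 1` exactly.  For free Brownian diffusion
#' `F_s(q,t) = exp(-q^2 D t)`.
#'
#' @inheritParams van_hove_self
#' @param q Scattering vector magnitude, nm^-1 (use [q_angstrom_to_nm()] for
#'   values quoted in inverse Angstrom).
#' @param t_grid Lag times (ps) including 0, multiples of the frame interval.
#' @return Object of class `isf_curve`: list with `q`, `t` (ps), `F`,
#'   `n_particles`, `n_time_origins`, `origin_stride`, `selection`.
#' @export
isf_self <- function(trajectory, selection = NULL, q, t_grid,
                     origin_stride = 1L) {
  if (q <= 0) stop("q must be positive")
  coords <- trajectory$coords
  if (!is.null(selection)) coords <- coords[, selection, , drop = FALSE]
  n <- dim(coords)[1]
  lf <- lag_frames(trajectory$times, t_grid)
  Fv <- numeric(length(lf))
  origins_used <- integer(length(lf))
  for (j in seq_along(lf)) {
    l <- lf[j]
    if (l == 0) { Fv[j] <- 1; origins_used[j] <- n; next }
    origins <- time_origins(n, l, origin_stride)
    origins_used[j] <- length(origins)
    acc <- 0
    for (o in origins) {
      d <- sqrt(rowSums((frame_mat(coords, o + l) - frame_mat(coords, o))^2))
      x <- q * d
      s <- ifelse(x < 1e-8, 1 - x^2 / 6, sin(x) / x)
      acc <- acc + mean(s)
    }
    Fv[j] <- acc / length(origins)
  }
  structure(list(q = q, t = t_grid, F = Fv,
                 n_particles = dim(coords)[2],
                 n_time_origins = origins_used,
                 origin_stride = origin_stride,
                 selection = if (is.null(selection)) "all" else "custom"),
            class = "isf_curve")
}

#' Fourier-transform a van Hove curve to the ISF
#'
#' Sinc-kernel quadrature `F_s(q,t) = sum_r G_s(r,t) sinc(q r) 4 pi r^2 dr`
#' over the r grid — an independent route to the ISF used to cross-validate
#' [isf_self()].
#'
#' @param vh A `van_hove` object.
#' @param q Scattering vector, nm^-1.
#' @return data.frame with `t` and `F`.
#' @export
isf_from_van_hove <- function(vh, q) {
  x <- q * vh$r
  kern <- ifelse(x < 1e-8, 1 - x^2 / 6, sin(x) / x)
  Fv <- as.vector(crossprod(vh$G, kern * 4 * pi * vh$r^2 * vh$dr))
  data.frame(t = vh$t, F = Fv)
}

#' Compare two ISF curves
#'
#' Reports, per lag, the sign of (a - b), the fraction of positive lags where
#' a lies below b, and the first lag at which both curves have decayed below a
#' relaxation threshold.  Curves with `max |a - b| < 1e-12` are reported as
#' indistinguishable.
#'
#' @param a,b `isf_curve` objects on the same q and t grid.
#' @param threshold Relaxation threshold (default 0.02).
#' @return List with `indistinguishable`, `sign` (per lag), `fraction_a_below`
#'   (over positive lags), `first_relaxed_lag` (ps or NA).
#' @export
compare_isf <- function(a, b, threshold = 0.02) {
  if (!isTRUE(all.equal(a$t, b$t)) || abs(a$q - b$q) > 1e-12) {
    stop("ISF curves are on different q or t grids")
  }
  d <- a$F - b$F
  if (max(abs(d)) < 1e-12) {
    return(list(indistinguishable = TRUE, sign = rep(0L, length(d)),
                fraction_a_below = NA_real_, first_relaxed_lag = NA_real_))
  }
  pos <- a$t > 0
  relaxed <- which(a$F < threshold & b$F < threshold)
  list(indistinguishable = FALSE,
       sign = sign(d),
       fraction_a_below = mean(d[pos] < 0),
       first_relaxed_lag = if (length(relaxed)) a$t[min(relaxed)] else
         NA_real_)
}

#' Axis-resolved mass density profile
#'
#' Time-averaged mass per slab divided by slab volume, per species, along one
#' box axis.  The bin range covers all observed coordinates so the integral
#' over bins times slab volume equals the total species mass exactly.
#'
#' @param trajectory A [trajectory_set()].
#' @param topology An [assembly_topology()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param species Character vector of species labels.
#' @param n_bins Number of slabs (default 100).
#' @return Object of class `density_profile`: list with `axis`, `centers`
#'   (nm), `density` (bins x species matrix, amu/nm^3), `slab_volume` (nm^3),
#'   `total_mass` (per species).
#' @export
density_profile <- function(trajectory, topology, axis = c("x", "y", "z"),
                            species, n_bins = 100) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  bad <- setdiff(species, ASSEMBLY_SPECIES)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  n_frames <- dim(trajectory$coords)[1]
  box <- colMeans(trajectory$box, na.rm = TRUE)
  cross <- prod(box[-ax])
  if (!is.finite(cross)) cross <- 1   # unit cross-section when box unknown
  u <- trajectory$coords[, , ax, drop = FALSE]
  lo <- min(u); hi <- max(u)
  if (is.finite(box[ax])) { lo <- min(lo, 0); hi <- max(hi, box[ax]) }
  hi <- hi + 1e-9
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  dw <- breaks[2] - breaks[1]
  slab_volume <- dw * cross
  dens <- matrix(0, n_bins, length(species),
                 dimnames = list(NULL, species))
  total_mass <- stats::setNames(numeric(length(species)), species)
  for (sp in species) {
    ids <- topology$atoms$id[topology$atoms$species == sp]
    if (length(ids) == 0) next
    m <- topology$atoms$mass[match(ids, topology$atoms$id)]
    total_mass[sp] <- sum(m)
    acc <- numeric(n_bins)
    for (f in seq_len(n_frames)) {
      pos <- trajectory$coords[f, ids, ax]
      idx <- pmin(pmax(findInterval(pos, breaks, all.inside = TRUE), 1L),
                  n_bins)
      tb <- tapply(m, idx, sum)
      at <- as.integer(names(tb))
      acc[at] <- acc[at] + tb
    }
    dens[, sp] <- acc / (n_frames * slab_volume)
  }
  structure(list(axis = axis, centers = breaks[-1] - dw / 2, density = dens,
                 slab_volume = slab_volume, total_mass = total_mass),
            class = "density_profile")
}
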