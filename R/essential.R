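#' Concatenate superposed subunit trajectories into one ensemble
#'
#' Pools the trajectories of equivalent subunits (heterodimers) into a single
#' ensemble for covariance analysis, after least-squares superposition of
#' every frame onto a common reference.  Concatenation broadens the sampled
#' configuration space compared with a single trajectory of equal length and
#' is the key ergodicity device of the analysis.
#'
#' By default a two-pass fit is used: frames are first fitted to `reference`,
#' then refitted to the resulting mean structure, which removes the bias of an
#' arbitrary reference from the covariance.  Set `refine_reference = FALSE`
#' to fit to `reference` only.
#'
#' @param subunits List of `subunit_trajectory` objects with identical
#'   selections and atom-ordering signatures.
#' @param reference Common reference conformation, (subunit atoms) x 3 (nm).
#' @param weights Per-atom fit weights (e.g. masses).
#' @param fit Superpose frames (default TRUE; FALSE assumes pre-superposed
#'   coordinates).
#' @param refine_reference Two-pass mean-structure refit (default TRUE).
#' @return Object of class `concat_ensemble`: list with `X` (rows x 3M matrix,
#'   row = frame flattened as x1,y1,z1,x2,...), `labels` (data.frame with
#'   system, dimer_id, position_class, pf, frame, time), `reference`,
#'   `selection`.
#' @export
concatenate_subunits <- function(subunits, reference, weights = NULL,
                                 fit = TRUE, refine_reference = TRUE) {
  stopifnot(length(subunits) >= 1)
  sig <- vapply(subunits, function(s) {
    paste(s$selection, dim(s$coords)[2], sep = ":")
  }, "")
  if (length(unique(sig)) != 1) {
    stop("subunits have mismatched selections or atom orderings")
  }
  n_at <- dim(subunits[[1]]$coords)[2]
  if (nrow(reference) != n_at) {
    stop("reference atom count does not match subunits")
  }
  flatten <- function(ref) {
    rows <- lapply(subunits, function(su) {
      nf <- dim(su$coords)[1]
      t(vapply(seq_len(nf), function(f) {
        fr <- su$coords[f, , ]
        if (fit) fr <- kabsch_fit(fr, ref, weights)$fitted
        as.vector(t(fr))
      }, numeric(3 * n_at)))
    })
    do.call(rbind, rows)
  }
  X <- flatten(reference)
  if (fit && refine_reference && nrow(X) > 1) {
    ref2 <- matrix(colMeans(X), n_at, 3, byrow = TRUE)
    X <- flatten(ref2)
    reference <- ref2
  }
  labels <- do.call(rbind, lapply(subunits, function(su) {
    nf <- dim(su$coords)[1]
    data.frame(system = su$provenance, dimer_id = su$dimer_id,
               position_class = su$position_class, pf = su$pf,
               frame = seq_len(nf), time = su$times,
               stringsAsFactors = FALSE)
  }))
  structure(list(X = X, labels = labels, reference = reference,
                 selection = subunits[[1]]$selection),
            class = "concat_ensemble")
}

#' @export
print.concat_ensemble <- function(x, ...) {
  cat(sprintf("concat_ensemble: %d rows x %d coordinates (%d subunits)\n",
              nrow(x$X), ncol(x$X), length(unique(paste(x$labels$system,
                                                        x$labels$dimer_id)))))
  invisible(x)
}

#' Covariance eigenmodes of a concatenated ensemble
#'
#' Principal component analysis of the (optionally mass-weighted) population
#' covariance of the ensemble rows.  Eigenvector signs are fixed
#' deterministically (largest-magnitude component positive) so that overlap
#' matrices and projections are reproducible.
#'
#' @param ensemble A `concat_ensemble` or a plain rows x 3M matrix.
#' @param mass_weighted Multiply coordinates by sqrt(mass) before covariance
#'   (default FALSE).
#' @param masses Per-atom masses, required when `mass_weighted = TRUE`.
#' @return Object of class `mode_set`: list with `mean` (3M), `vectors`
#'   (3M x k orthonormal, columns = modes), `values` (k, descending, nm^2),
#'   `n_frames`, `selection`.
#' @export
covariance_modes <- function(ensemble, mass_weighted = FALSE, masses = NULL) {
  X <- if (inherits(ensemble, "concat_ensemble")) ensemble$X else
    as.matrix(ensemble)
  sel <- if (inherits(ensemble, "concat_ensemble")) ensemble$selection else NA
  N <- nrow(X)
  if (N < 2) stop("at least two rows required for covariance analysis")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (mass_weighted) {
    if (is.null(masses) || 3 * length(masses) != ncol(X)) {
      stop("per-atom masses required for mass weighting")
    }
    Xc <- sweep(Xc, 2, rep(sqrt(masses), each = 3), "*")
  }
  C <- crossprod(Xc) / N                  # population covariance
  ee <- eigen(C, symmetric = TRUE)
  values <- pmax(ee$values, 0)
  vectors <- ee$vectors
  for (j in seq_len(ncol(vectors))) {     # deterministic sign convention
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  structure(list(mean = mu, vectors = vectors, values = values,
                 n_frames = N, selection = sel,
                 mass_weighted = mass_weighted),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  fr <- x$values / sum(x$values)
  cat(sprintf("mode_set: %d modes from %d rows; top fractions %s\n",
              length(x$values), x$n_frames,
              paste(sprintf("%.3f", utils::head(fr, 3)), collapse = ", ")))
  invisible(x)
}

#' Scree data: eigenvalue fractions and accumulated dynamics
#'
#' The accumulated dynamics at mode m is the ratio between the sum of all
#' eigenvalues up to m and the sum of all eigenvalues.
#'
#' @param modes A `mode_set`.
#' @return data.frame with `mode_index`, `eigenvalue`, `fraction`,
#'   `accumulated`.
#' @export
scree <- function(modes) {
  v <- modes$values
  total <- sum(v)
  data.frame(mode_index = seq_along(v), eigenvalue = v,
             fraction = v / total, accumulated = cumsum(v) / total)
}

#' Cattell kink indices of a scree spectrum
#'
#' The Cattell criterion places the essential-subspace boundary at a kink in
#' the scree plot.  Operationalized as local maxima of the discrete second
#' difference of log-eigenvalues; a kink at mode m means modes 1..m lie before
#' the drop.  Kinks are returned ranked by the magnitude of the second
#' difference; an empty result means the spectrum decays smoothly (e.g. exact
#' geometric decay).
#'
#' @param scree_data Output of [scree()] (or a `mode_set`).
#' @param min_eigenvalue Modes with eigenvalues below this are ignored
#'   (numerical zeros from superposition-removed degrees of freedom).
#' @return Integer vector of kink mode indices, ranked; empty when no kink.
#' @export
cattell_kink <- function(scree_data, min_eigenvalue = 1e-12) {
  if (inherits(scree_data, "mode_set")) scree_data <- scree(scree_data)
  v <- scree_data$eigenvalue
  v <- v[v > min_eigenvalue]
  k <- length(v)
  if (k < 3) stop("at least 3 modes required for kink detection")
  lv <- log(v)
  d2 <- lv[seq_len(k - 2)] - 2 * lv[seq_len(k - 2) + 1] + lv[seq_len(k - 2) + 2]
  # d2[i] is the second difference centered at mode i+1
  center <- seq_len(k - 2) + 1
  is_max <- vapply(seq_along(d2), function(i) {
    left <- if (i == 1) -Inf else d2[i - 1]
    right <- if (i == length(d2)) -Inf else d2[i + 1]
    d2[i] > 1e-8 && d2[i] >= left && d2[i] >= right
  }, TRUE)
  kinks <- center[is_max] - 1L           # last mode before the drop
  kinks[order(d2[is_max], decreasing = TRUE)]
}

#' Project an ensemble onto eigenmodes
#'
#' Centered dot products `(row - mean) . eigenvector`, in nm.  The population
#' variance of the projections onto mode i equals eigenvalue i.
#'
#' @param ensemble A `concat_ensemble` or rows x 3M matrix.
#' @param modes A `mode_set` derived from a compatible selection.
#' @param k Number of modes to project onto (default 3).
#' @param subset Optional logical/integer row subset, or a character
#'   position-class label filtering ensemble rows.
#' @return rows x k matrix of projections with the (subset) ensemble labels as
#'   attribute `"labels"`.
#' @export
project_ensemble <- function(ensemble, modes, k = 3, subset = NULL) {
  X <- if (inherits(ensemble, "concat_ensemble")) ensemble$X else
    as.matrix(ensemble)
  labels <- if (inherits(ensemble, "concat_ensemble")) ensemble$labels else NULL
  if (ncol(X) != nrow(modes$vectors)) {
    stop("ensemble and mode set have mismatched dimensions")
  }
  if (!is.null(subset)) {
    idx <- if (is.character(subset)) {
      which(labels$position_class %in% subset)
    } else subset
    X <- X[idx, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[idx, , drop = FALSE]
  }
  P <- sweep(X, 2, modes$mean) %*% modes$vectors[, seq_len(k), drop = FALSE]
  colnames(P) <- sprintf("pc%d", seq_len(k))
  attr(P, "labels") <- labels
  P
}

#' Two-dimensional projection histogram (log10 population)
#'
#' Bins two projection series on a grid with edges symmetric about zero and
#' reports log10 bin populations; empty bins are NA, distinct from
#' log10(1) = 0.  Points beyond the limits are clamped into the edge bins so
#' total counts are conserved.
#'
#' @param px,py Projection vectors (equal length, nm).
#' @param bins Number of bins per axis (default 100).
#' @param limits Half-range of the grid per axis; default 4 standard
#'   deviations of each series.
#' @return List with `x`, `y` (bin centers), `counts` and `log10_counts`
#'   (bins x bins matrices).
#' @export
projection_histogram <- function(px, py, bins = 100, limits = NULL) {
  stopifnot(length(px) == length(py))
  if (is.null(limits)) {
    limits <- c(4 * stats::sd(px), 4 * stats::sd(py))
    limits[limits == 0] <- 1
  }
  if (length(limits) == 1) limits <- rep(limits, 2)
  bx <- seq(-limits[1], limits[1], length.out = bins + 1)
  by <- seq(-limits[2], limits[2], length.out = bins + 1)
  ix <- pmin(pmax(findInterval(px, bx, all.inside = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(py, by, all.inside = TRUE), 1L), bins)
  counts <- matrix(0, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  counts[] <- as.numeric(tab)
  lg <- log10(counts)
  lg[counts == 0] <- NA_real_
  list(x = (bx[-1] + bx[-length(bx)]) / 2,
       y = (by[-1] + by[-length(by)]) / 2,
       counts = counts, log10_counts = lg)
}

#' Inner-product (overlap) matrix between two mode sets
#'
#' Absolute inner products |v_i(a) . v_j(b)| over the first k modes, plus the
#' root mean square inner product (RMSIP) of the k x k block as attribute
#' `"rmsip"`.
#'
#' @param a,b `mode_set` objects over the same coordinate space.
#' @param k Number of modes to compare (default 3).
#' @return k x k matrix of absolute inner products (class `overlap_matrix`).
#' @export
overlap_matrix <- function(a, b, k = 3) {
  if (nrow(a$vectors) != nrow(b$vectors)) {
    stop("mode sets have mismatched dimensions")
  }
  V <- abs(crossprod(a$vectors[, seq_len(k), drop = FALSE],
                     b$vectors[, seq_len(k), drop = FALSE]))
  attr(V, "rmsip") <- sqrt(sum(V^2) / k)
  class(V) <- c("overlap_matrix", class(V))
  V
}

#' Root mean square inner product of two mode subspaces
#'
#' @inheritParams overlap_matrix
#' @return RMSIP over the first k modes, in `[0, 1]`.
#' @export
rmsip <- function(a, b, k = 3) {
  attr(overlap_matrix(a, b, k), "rmsip")
}

#' Mode-overlap convergence with concatenation depth
#'
#' For each N, draws disjoint random subsets of N subunits, builds a mode set
#' from each, and records the absolute first-mode inner product and the RMSIP
#' between the two.  The mean over replicates traces how the precision of the
#' PC-modes improves as more subunit trajectories are concatenated.
#'
#' @param ensemble A `concat_ensemble` whose labels identify the subunits
#'   (system + dimer_id).
#' @param N_list Strictly increasing subset sizes; `2 * max(N_list)` must not
#'   exceed the number of subunits.
#' @param replicates Replicates per N (default 20).
#' @param seed Integer seed.
#' @param k RMSIP subspace size (default 3).
#' @return data.frame with `N`, `mean_overlap`, `se_overlap`, `mean_rmsip`,
#'   `se_rmsip`.
#' @export
convergence_curve <- function(ensemble, N_list, replicates = 20, seed = 1L,
                              k = 3) {
  stopifnot(inherits(ensemble, "concat_ensemble"))
  if (is.unsorted(N_list, strictly = TRUE)) {
    stop("N_list must be strictly increasing")
  }
  key <- paste(ensemble$labels$system, ensemble$labels$dimer_id, sep = "/")
  units <- unique(key)
  if (2 * max(N_list) > length(units)) {
    stop("not enough subunits for disjoint subsets of the largest N")
  }
  rows_of <- split(seq_along(key), key)
  set.seed(seed)
  out <- lapply(N_list, function(N) {
    ov <- numeric(replicates); rp <- numeric(replicates)
    for (r in seq_len(replicates)) {
      pick <- sample(units, 2 * N)
      ia <- unlist(rows_of[pick[seq_len(N)]], use.names = FALSE)
      ib <- unlist(rows_of[pick[N + seq_len(N)]], use.names = FALSE)
      ma <- covariance_modes(ensemble$X[ia, , drop = FALSE])
      mb <- covariance_modes(ensemble$X[ib, , drop = FALSE])
      O <- overlap_matrix(ma, mb, k)
      ov[r] <- O[1, 1]
      rp[r] <- attr(O, "rmsip")
    }
    data.frame(N = N, mean_overlap = mean(ov),
               se_overlap = stats::sd(ov) / sqrt(replicates),
               mean_rmsip = mean(rp),
               se_rmsip = stats::sd(rp) / sqrt(replicates))
  })
  do.call(rbind, out)
}

#' Block-average a series
#'
#' Averages non-overlapping consecutive blocks; a trailing partial block is
#' averaged as-is.  Used to downsample dense projection series for display.
#'
#' @param x Numeric vector or matrix (rows are averaged in blocks).
#' @param block_size Block length (>= 1).
#' @return Downsampled vector or matrix.
#' @export
block_average <- function(x, block_size) {
  if (block_size < 1) stop("block_size must be >= 1")
  block_size <- as.integer(block_size)
  if (is.matrix(x)) {
    idx <- split(seq_len(nrow(x)), (seq_len(nrow(x)) - 1) %/% block_size)
    return(do.call(rbind, lapply(idx, function(i) {
      colMeans(x[i, , drop = FALSE])
    })))
  }
  idx <- split(seq_along(x), (seq_along(x) - 1) %/% block_size)
  vapply(idx, function(i) mean(x[i]), 0, USE.NAMES = FALSE)
}
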