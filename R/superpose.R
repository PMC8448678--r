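#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) RMSD between a mobile and a reference point set.  Reflections are
#' excluded: the returned rotation always has determinant +1.
#'
#' The transform uses the row-vector convention: `fitted = mobile %*% rotation
#' + translation` (rows are atoms).
#'
#' @param mobile,reference Matrices n x 3 (nm), equal atom counts, n >= 3
#'   non-collinear points.
#' @param weights Per-atom weights (e.g. masses); default uniform.
#' @return List of class `rigid_transform` with elements `rotation` (3 x 3),
#'   `translation` (length 3), `fitted` (transformed mobile coordinates) and
#'   `rmsd` (weighted RMSD after fitting, nm).
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  if (!is.matrix(mobile)) mobile <- as.matrix(mobile)
  if (!is.matrix(reference)) reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("atom counts differ")
  if (n < 3) stop("at least 3 atoms required")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  # degeneracy check: collinear point sets leave the fit underdetermined
  for (X in list(P, Q)) {
    sv <- svd(X, nu = 0, nv = 0)$d
    if (sv[2] < 1e-10 * max(sv[1], 1e-300)) {
      stop("degenerate (collinear) point set: superposition is ill-defined")
    }
  }
  H <- crossprod(P, w * Q)                 # 3x3 weighted cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  translation <- cr - as.vector(cm %*% R)
  fitted <- mobile %*% R + matrix(translation, n, 3, byrow = TRUE)
  structure(list(rotation = R, translation = translation, fitted = fitted,
                 rmsd = rmsd(fitted, reference, weights)),
            class = "rigid_transform")
}

#' Apply a rigid transform
#'
#' @param coords n x 3 matrix.
#' @param transform A `rigid_transform`.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords %*% transform$rotation +
    matrix(transform$translation, nrow(coords), 3, byrow = TRUE)
}

#' Root mean square deviation between two conformations
#'
#' @param a,b n x 3 matrices (nm).
#' @param weights Per-atom weights; default uniform.
#' @return RMSD in nm.
#' @export
rmsd <- function(a, b, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(a))
  sqrt(sum(weights * rowSums((a - b)^2)) / sum(weights))
}

#' RMSD time series
#'
#' Per-frame RMSD of a trajectory (or of several subunit trajectories) against
#' a reference conformation, with optional least-squares fitting first.  When
#' several subunits are given, the per-frame mean and standard deviation
#' across subunits are reported, the usual mean +/- sd presentation of
#' heterodimer RMSD in an assembly.
#'
#' @param x A [trajectory_set()], a `subunit_trajectory`, or a list of
#'   `subunit_trajectory` objects sharing frame times.
#' @param reference Reference coordinates: an n x 3 matrix matching the
#'   selection, or a frame index into `x` (default 1, the initial structure).
#' @param selection Atom indices into the coordinate array (default all); for
#'   a `trajectory_set` these are column indices / atom ids.
#' @param fit Superpose each frame on the reference first (default TRUE).
#' @param weights Per-atom weights for fit and RMSD.
#' @return Object of class `rmsd_series`: list with `times` (ps), `values`
#'   (frames x subunits matrix, nm), `mean`, `sd`, `selection`, `reference`.
#' @export
rmsd_series <- function(x, reference = 1L, selection = NULL, fit = TRUE,
                        weights = NULL) {
  subunits <- if (inherits(x, "trajectory_set") ||
                  inherits(x, "subunit_trajectory")) list(x) else x
  times <- subunits[[1]]$times
  one <- function(su) {
    coords <- su$coords
    if (!is.null(selection)) coords <- coords[, selection, , drop = FALSE]
    ref <- if (is.matrix(reference)) reference else coords[reference, , ]
    if (nrow(ref) != dim(coords)[2]) {
      stop("reference atom count does not match selection")
    }
    vapply(seq_len(dim(coords)[1]), function(f) {
      fr <- coords[f, , ]
      if (fit) kabsch_fit(fr, ref, weights)$rmsd else rmsd(fr, ref, weights)
    }, 0)
  }
  values <- vapply(subunits, one, numeric(length(times)))
  values <- matrix(values, nrow = length(times))
  structure(list(
    times = times,
    values = values,
    mean = rowMeans(values),
    sd = if (ncol(values) > 1) apply(values, 1, stats::sd) else rep(0, nrow(values)),
    selection = selection,
    reference = if (is.matrix(reference)) "matrix" else
      sprintf("frame %d", reference)
  ), class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf(
    "rmsd_series: %d frames, %d subunit(s), final mean RMSD %.4f nm\n",
    nrow(x$values), ncol(x$values), x$mean[length(x$mean)]))
  invisible(x)
}

#' @export
as.data.frame.rmsd_series <- function(x, ...) {
  data.frame(time_ps = x$times, mean_nm = x$mean, std_nm = x$sd)
}
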