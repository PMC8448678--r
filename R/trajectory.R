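#' Trajectory container
#'
#' Frames x atoms x 3 coordinates in nm, with per-frame times (ps) and box
#' lengths (nm).  Coordinates are stored unwrapped (no periodic imaging), so
#' displacement-based observables see true displacements.
#'
#' @param coords Numeric array, frames x atoms x 3 (nm).
#' @param times Numeric vector of frame times (ps), strictly increasing.
#' @param box Per-frame box lengths: a length-3 vector (constant box) or a
#'   frames x 3 matrix.
#' @param provenance Character label of the source system/file.
#' @return Object of class `trajectory_set`.
#' @export
trajectory_set <- function(coords, times, box = NULL, provenance = "synthetic") {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be a frames x atoms x 3 array")
  }
  n <- dim(coords)[1]
  if (length(times) != n) stop("times length must equal frame count")
  if (n > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(box)) box <- c(NA_real_, NA_real_, NA_real_)
  if (is.null(dim(box))) box <- matrix(box, n, 3, byrow = TRUE)
  structure(list(coords = coords, times = times, box = box,
                 provenance = provenance),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d frames, %d atoms, t = %g..%g ps [%s]\n",
              dim(x$coords)[1], dim(x$coords)[2],
              x$times[1], x$times[length(x$times)], x$provenance))
  invisible(x)
}

#' Write / read a multi-frame XYZ trajectory
#'
#' Plain-text multi-frame XYZ: per frame an atom count line, a comment line
#' `t= <ps> box= <bx> <by> <bz>`, then one `name x y z` line per atom, in nm.
#' Round trip is lossless to 1e-5 nm.
#'
#' @param trajectory A [trajectory_set()].
#' @param path Output path.
#' @param names Atom names (recycled from the topology or `"X"`).
#' @return `write_xyz_trajectory` returns `path` invisibly;
#'   `read_xyz_trajectory` returns a [trajectory_set()].
#' @export
write_xyz_trajectory <- function(trajectory, path, names = NULL) {
  n_frames <- dim(trajectory$coords)[1]
  n_atoms <- dim(trajectory$coords)[2]
  if (is.null(names)) names <- rep("X", n_atoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    writeLines(as.character(n_atoms), con)
    writeLines(sprintf("t= %.6f box= %.6f %.6f %.6f",
                       trajectory$times[f],
                       trajectory$box[f, 1], trajectory$box[f, 2],
                       trajectory$box[f, 3]), con)
    xyz <- trajectory$coords[f, , ]
    writeLines(sprintf("%s %.6f %.6f %.6f", names, xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz_trajectory
#' @param topology Optional [assembly_topology()]; when given, the atom count
#'   of every frame is checked against it.
#' @export
read_xyz_trajectory <- function(path, topology = NULL) {
  lines <- readLines(path)
  pos <- 1L
  total <- length(lines)
  frames <- list()
  times <- numeric(0)
  boxes <- list()
  f <- 0L
  while (pos <= total) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    f <- f + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop(sprintf("frame %d: bad atom count line", f))
    if (pos + 1L + n > total) {
      stop(sprintf("frame %d is truncated (expected %d atom lines)", f, n))
    }
    if (!is.null(topology) && n != nrow(topology$atoms)) {
      stop(sprintf("frame %d: atom count %d does not match topology (%d)",
                   f, n, nrow(topology$atoms)))
    }
    comment <- lines[pos + 1L]
    tm <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
    times[f] <- if (length(tm) == 2) as.numeric(tm[2]) else f - 1
    bm <- regmatches(comment, regexec(
      "box=\\s*([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)", comment))[[1]]
    boxes[[f]] <- if (length(bm) == 4) as.numeric(bm[2:4]) else rep(NA_real_, 3)
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 0L) < 4L)
    if (length(bad)) {
      stop(sprintf("frame %d: malformed atom line %d", f, bad[1]))
    }
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), n, 3,
                  byrow = TRUE)
    if (any(is.na(xyz))) stop(sprintf("frame %d: non-numeric coordinates", f))
    frames[[f]] <- xyz
    pos <- pos + 2L + n
  }
  if (f == 0L) stop("no frames in ", path)
  n_atoms <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 0L) != n_atoms)) {
    stop("inconsistent atom counts across frames")
  }
  coords <- array(0, dim = c(f, n_atoms, 3))
  for (i in seq_len(f)) coords[i, , ] <- frames[[i]]
  trajectory_set(coords, times, box = do.call(rbind, boxes),
                 provenance = path)
}

#' Convert a scattering vector from inverse Angstrom to inverse nm
#'
#' Internal units are nm and ps; experimental q values are commonly quoted in
#' inverse Angstrom (e.g. 1.26 A^-1 = 12.6 nm^-1).
#'
#' @param q_angstrom q in A^-1.
#' @return q in nm^-1.
#' @export
q_angstrom_to_nm <- function(q_angstrom) q_angstrom * 10

#' Write a JSON manifest
#'
#' Records the generating spec, seed, and package version next to an output so
#' every artifact is regenerable.
#'
#' @param x A list of manifest fields (specs, seeds, parameters).
#' @param path Output path.
#' @export
write_manifest <- function(x, path) {
  x$package <- "assemblyED"
  x$package_version <- as.character(utils::packageVersion("assemblyED"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
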