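#' Specify a toy tubulin lattice
#'
#' Describes a synthetic assembly of alpha/beta-tubulin heterodimers, either a
#' flat protofilament (PF) sheet or a cylindrical microtubule wall.  Layers are
#' counted in monomers, so `n_layers` must be even: each protofilament carries
#' `n_layers / 2` heterodimers stacked along the assembly (z) axis.
#'
#' @param n_protofilaments Number of protofilaments (>= 1).
#' @param n_layers Number of monomer layers along each PF (even, >= 2).
#' @param geometry `"sheet"` (PFs side by side in the xz plane) or
#'   `"cylinder"` (PFs on a circle of radius `radius`).
#' @param monomer_spacing Spacing between consecutive monomer centers along the
#'   PF axis, in nm.  Default 4 nm, the approximate axial extent of a tubulin
#'   monomer.
#' @param atoms_per_monomer Number of pseudo-atoms per monomer (>= 4 so that a
#'   backbone subset and a center of mass are nondegenerate).
#' @param radius Cylinder radius in nm; ignored for sheets.  Defaults to the
#'   radius at which the arc spacing between PFs equals `monomer_spacing`.
#' @param helical_rise_per_pf Axial offset between successive PFs in nm
#'   (cylinder only).  Defaults to the 3-start helix value
#'   `3 * monomer_spacing / n_protofilaments`; 0 for sheets.
#' @param seed Integer seed recorded in the spec (the builder itself is
#'   deterministic; the seed seeds downstream generators that take the spec).
#'
#' @return An object of class `lattice_spec`.
#' @seealso [build_lattice()]
#' @export
lattice_spec <- function(n_protofilaments, n_layers,
                         geometry = c("sheet", "cylinder"),
                         monomer_spacing = 4,
                         atoms_per_monomer = 20,
                         radius = NULL,
                         helical_rise_per_pf = NULL,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  if (n_protofilaments < 1) {
    stop("n_protofilaments must be >= 1")
  }
  if (n_layers < 2 || n_layers %% 2 != 0) {
    stop("n_layers must be an even number of monomer layers (>= 2)")
  }
  if (atoms_per_monomer < 4) {
    stop("atoms_per_monomer must be >= 4")
  }
  if (monomer_spacing <= 0) {
    stop("monomer_spacing must be positive")
  }
  if (geometry == "cylinder") {
    if (is.null(radius)) {
      radius <- n_protofilaments * monomer_spacing / (2 * pi)
    }
    arc <- 2 * pi * radius / n_protofilaments
    if (n_protofilaments > 1 && arc < 0.8 * monomer_spacing) {
      stop(sprintf(paste0(
        "cylinder radius %.3f nm too small: arc spacing between ",
        "protofilaments is %.3f nm but at least %.3f nm is needed to avoid ",
        "overlap of monomers"), radius, arc, 0.8 * monomer_spacing))
    }
    if (is.null(helical_rise_per_pf)) {
      helical_rise_per_pf <- 3 * monomer_spacing / n_protofilaments
    }
  } else {
    radius <- NA_real_
    helical_rise_per_pf <- 0
  }
  structure(list(
    n_protofilaments = as.integer(n_protofilaments),
    n_layers = as.integer(n_layers),
    geometry = geometry,
    monomer_spacing = monomer_spacing,
    atoms_per_monomer = as.integer(atoms_per_monomer),
    radius = radius,
    helical_rise_per_pf = helical_rise_per_pf,
    seed = as.integer(seed)
  ), class = "lattice_spec")
}

# Deterministic pseudo-atom offsets within one monomer: atom 1 at the monomer
# center (the "C-alpha"), the rest on a golden-section spiral over a sphere so
# that any >= 4 atoms are non-collinear and every monomer has the same shape.
monomer_atom_offsets <- function(n_atoms, scale) {
  off <- matrix(0, n_atoms, 3)
  idx <- seq_len(n_atoms - 1)
  golden <- (1 + sqrt(5)) / 2
  z <- if (n_atoms == 2) 0 else 1 - (2 * idx - 1) / (n_atoms - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- 2 * pi * idx / golden
  off[-1, ] <- cbind(r * cos(theta), r * sin(theta), z) * scale
  off
}

#' Build a synthetic tubulin lattice
#'
#' Places heterodimers on the requested sheet or cylinder, each dimer straight
#' (its alpha->beta axis along +z, pointing toward the plus end), and returns
#' the assembly topology together with the reference coordinates and each
#' dimer's local frame (origin at the dimer center, local z along the dimer
#' axis, local x pointing laterally / radially outward).
#'
#' Dimer layers are classified by position: the outermost layer at large z is
#' `plus_end`, the outermost at small z is `minus_end`, interior layers are
#' `central`.  For cylinders the dimer where the helical lattice terminates at
#' each end is additionally marked `plus_corner` / `minus_corner`.
#'
#' @param spec A [lattice_spec()].
#' @return An object of class `assembly_lattice`: a list with elements
#'   `topology` (an [assembly_topology()]), `reference` (atoms x 3 matrix of
#'   reference coordinates, nm) and `spec`.
#' @examples
#' lat <- build_lattice(lattice_spec(3, 6, "sheet", atoms_per_monomer = 5))
#' nrow(lat$topology$dimers)  # 9 heterodimers
#' @export
build_lattice <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  P <- spec$n_protofilaments
  Ld <- spec$n_layers %/% 2L       # dimer layers per PF
  A <- spec$atoms_per_monomer
  s <- spec$monomer_spacing
  n_dimers <- P * Ld
  n_monomers <- 2L * n_dimers
  n_atoms <- n_monomers * A

  offsets <- monomer_atom_offsets(A, 0.25 * s)

  dimers <- data.frame(
    id = seq_len(n_dimers),
    pf = rep(seq_len(P), each = Ld),
    layer = rep(seq_len(Ld), times = P),
    position_class = "central",
    stringsAsFactors = FALSE
  )
  dimers$position_class[dimers$layer == Ld] <- "plus_end"
  dimers$position_class[dimers$layer == 1L] <- "minus_end"
  if (Ld == 1L) dimers$position_class <- "plus_end"  # degenerate single layer
  if (spec$geometry == "cylinder" && P > 1L) {
    dimers$position_class[dimers$pf == P & dimers$layer == Ld] <- "plus_corner"
    dimers$position_class[dimers$pf == 1L & dimers$layer == 1L] <- "minus_corner"
  }

  # dimer local frames: origin at dimer center, columns of rot are the local
  # axes expressed in the global frame (local x lateral/radial, z axial)
  rot_cols <- matrix(0, n_dimers, 9)
  origin <- matrix(0, n_dimers, 3)
  for (d in seq_len(n_dimers)) {
    p <- dimers$pf[d]
    l <- dimers$layer[d]
    zc <- (2 * (l - 1) + 0.5) * s       # dimer center height on its PF
    if (spec$geometry == "sheet") {
      org <- c((p - 1) * s, 0, zc)
      R <- diag(3)
    } else {
      ang <- 2 * pi * (p - 1) / P
      org <- c(spec$radius * cos(ang), spec$radius * sin(ang),
               zc + (p - 1) * spec$helical_rise_per_pf)
      # local x = radial outward, local y = tangential, local z = global z
      R <- cbind(c(cos(ang), sin(ang), 0),
                 c(-sin(ang), cos(ang), 0),
                 c(0, 0, 1))
    }
    origin[d, ] <- org
    rot_cols[d, ] <- as.vector(R)
  }
  colnames(origin) <- c("ox", "oy", "oz")
  colnames(rot_cols) <- paste0("r", rep(1:3, 3), rep(1:3, each = 3))
  dimers <- cbind(dimers, origin, rot_cols)

  monomers <- data.frame(
    id = seq_len(n_monomers),
    dimer = rep(seq_len(n_dimers), each = 2L),
    label = rep(c("alpha", "beta"), times = n_dimers),
    stringsAsFactors = FALSE
  )

  atoms <- data.frame(
    id = seq_len(n_atoms),
    name = rep(sprintf("A%03d", seq_len(A)), times = n_monomers),
    mass = 1,
    species = "protein",
    backbone = rep(seq_len(A) <= ceiling(A / 2), times = n_monomers),
    calpha = rep(seq_len(A) == 1L, times = n_monomers),
    monomer = rep(seq_len(n_monomers), each = A),
    stringsAsFactors = FALSE
  )

  reference <- matrix(0, n_atoms, 3)
  for (m in seq_len(n_monomers)) {
    d <- monomers$dimer[m]
    R <- matrix(unlist(dimers[d, grep("^r[0-9][0-9]$", names(dimers))]), 3, 3)
    half <- if (monomers$label[m] == "alpha") -0.5 else 0.5
    center_local <- c(0, 0, half * s)
    rows <- ((m - 1) * A + 1):(m * A)
    local <- sweep(offsets, 2, center_local, "+")
    reference[rows, ] <- local %*% t(R) +
      matrix(unlist(dimers[d, c("ox", "oy", "oz")]), A, 3, byrow = TRUE)
  }

  topo <- assembly_topology(atoms, monomers, dimers)
  structure(list(topology = topo, reference = reference, spec = spec),
            class = "assembly_lattice")
}

#' Reference coordinates of one dimer in its local frame
#'
#' Returns the (selected) atoms of a dimer expressed in the dimer's local
#' frame, centered at the dimer origin.  This is the common reference structure
#' used when superposing and concatenating subunit trajectories.
#'
#' @param lattice An `assembly_lattice`.
#' @param dimer_id Dimer to use (default 1; all dimers share the same local
#'   reference by construction).
#' @param selection Selector passed to [select_atoms()], or an integer vector
#'   of atom ids.
#' @return Matrix (selected atoms within the dimer) x 3, nm.
#' @export
dimer_reference <- function(lattice, dimer_id = 1L, selection = "backbone") {
  topo <- lattice$topology
  ids <- dimer_atom_ids(topo, dimer_id, selection)
  d <- which(topo$dimers$id == dimer_id)
  R <- dimer_rotation(topo, d)
  org <- unlist(topo$dimers[d, c("ox", "oy", "oz")])
  sweep(lattice$reference[ids, , drop = FALSE], 2, org, "-") %*% R
}

# 3x3 local-frame rotation of dimer at row index d of the dimers table
dimer_rotation <- function(topology, d) {
  matrix(unlist(topology$dimers[d, grep("^r[0-9][0-9]$",
                                        names(topology$dimers))]), 3, 3)
}
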