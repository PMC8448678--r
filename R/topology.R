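ASSEMBLY_SPECIES <- c("protein", "ion_Mg", "ion_Cl", "water",
                      "nucleotide_GTP", "nucleotide_GDP")
POSITION_CLASSES <- c("plus_end", "central", "minus_end",
                      "plus_corner", "minus_corner", "body")

#' Assembly topology
#'
#' The static description of an assembly: an atom table plus the grouping
#' hierarchy atom -> monomer -> heterodimer -> protofilament/layer.  Solvent
#' atoms (ions, water) carry `monomer = 0`, the reserved solvent group.
#'
#' @param atoms data.frame with columns `id`, `name`, `mass` (amu), `species`
#'   (one of protein, ion_Mg, ion_Cl, water, nucleotide_GTP, nucleotide_GDP),
#'   `backbone` (logical), `calpha` (logical), `monomer` (integer, 0 for
#'   solvent).
#' @param monomers data.frame with columns `id`, `dimer`, `label`
#'   ("alpha"/"beta").
#' @param dimers data.frame with columns `id`, `pf`, `layer`, `position_class`
#'   and the local-frame columns `ox,oy,oz` and `r11..r33`.
#' @return Object of class `assembly_topology`.
#' @export
assembly_topology <- function(atoms, monomers, dimers) {
  if (nrow(atoms) == 0) {
    stop("empty atom table")
  }
  if (!all(atoms$species %in% ASSEMBLY_SPECIES)) {
    bad <- setdiff(unique(atoms$species), ASSEMBLY_SPECIES)
    stop("unknown species label(s): ", paste(bad, collapse = ", "))
  }
  if (any(atoms$calpha & !atoms$backbone)) {
    stop("calpha atoms must be a subset of backbone atoms")
  }
  if (any(atoms$backbone & atoms$species != "protein")) {
    stop("backbone atoms must be protein atoms")
  }
  prot <- atoms$monomer[atoms$species == "protein"]
  if (any(prot < 1) || !all(prot %in% monomers$id)) {
    stop("every protein atom must belong to exactly one monomer")
  }
  if (any(atoms$monomer[atoms$species != "protein"] != 0)) {
    stop("solvent atoms must belong to the reserved solvent group (monomer 0)")
  }
  per_dimer <- table(monomers$dimer)
  if (any(per_dimer != 2)) {
    stop("each dimer must consist of exactly two monomers")
  }
  if (!all(monomers$dimer %in% dimers$id)) {
    stop("monomer table references unknown dimers")
  }
  if (!all(dimers$position_class %in% POSITION_CLASSES)) {
    stop("unknown position class")
  }
  structure(list(atoms = atoms, monomers = monomers, dimers = dimers),
            class = "assembly_topology")
}

#' @export
print.assembly_topology <- function(x, ...) {
  cat(sprintf("assembly_topology: %d atoms, %d monomers, %d dimers, %d PFs\n",
              nrow(x$atoms), nrow(x$monomers), nrow(x$dimers),
              length(unique(x$dimers$pf))))
  invisible(x)
}

#' Resolve an atom selection
#'
#' Selections are pure functions of the topology.  Supported selectors:
#' `"backbone"`, `"calpha"`, `"protein"`, `"sidechain"` (protein minus
#' backbone), `"all"`, or `"species=X"` with X a species label.
#'
#' @param topology An [assembly_topology()].
#' @param selector Character selector, or an integer vector of atom ids which
#'   is validated and returned sorted.
#' @return Sorted integer vector of atom ids.
#' @export
select_atoms <- function(topology, selector) {
  a <- topology$atoms
  if (is.numeric(selector)) {
    ids <- sort(as.integer(selector))
    if (!all(ids %in% a$id)) stop("unknown atom ids in selection")
    return(ids)
  }
  ids <- if (selector == "all") {
    a$id
  } else if (selector == "protein") {
    a$id[a$species == "protein"]
  } else if (selector == "backbone") {
    a$id[a$backbone]
  } else if (selector == "calpha") {
    a$id[a$calpha]
  } else if (selector == "sidechain") {
    a$id[a$species == "protein" & !a$backbone]
  } else if (startsWith(selector, "species=")) {
    sp <- sub("^species=", "", selector)
    if (!sp %in% ASSEMBLY_SPECIES) stop("unknown species label: ", sp)
    a$id[a$species == sp]
  } else {
    stop("unknown selector: ", selector)
  }
  sort(ids)
}

# Atom ids of one dimer restricted to a selection, in canonical order:
# alpha-monomer atoms first, then beta, each sorted by id.
dimer_atom_ids <- function(topology, dimer_id, selection = "backbone") {
  sel <- select_atoms(topology, selection)
  mono <- topology$monomers[topology$monomers$dimer == dimer_id, ]
  if (nrow(mono) == 0) stop("unknown dimer id: ", dimer_id)
  mono <- mono[order(match(mono$label, c("alpha", "beta"))), ]
  ids <- unlist(lapply(mono$id, function(m) {
    sort(intersect(topology$atoms$id[topology$atoms$monomer == m], sel))
  }))
  if (length(ids) == 0) {
    stop("selection is empty within dimer ", dimer_id)
  }
  ids
}

#' Extract a per-subunit trajectory
#'
#' Slices the trajectory of a single heterodimer out of an assembly
#' trajectory, with a canonical atom ordering (alpha monomer atoms then beta
#' monomer atoms, each by id) so that subunit trajectories extracted with the
#' same selection can be concatenated.
#'
#' @param trajectory A [trajectory_set()].
#' @param topology An [assembly_topology()].
#' @param dimer_id Dimer to extract.
#' @param selection Selector (see [select_atoms()]).
#' @return Object of class `subunit_trajectory`: list with `dimer_id`,
#'   `coords` (frames x atoms x 3), `atom_ids`, `selection`,
#'   `position_class`, `times`, `superposed`.
#' @export
extract_subunit <- function(trajectory, topology, dimer_id,
                            selection = "backbone") {
  ids <- dimer_atom_ids(topology, dimer_id, selection)
  d <- which(topology$dimers$id == dimer_id)
  structure(list(
    dimer_id = dimer_id,
    coords = trajectory$coords[, ids, , drop = FALSE],
    atom_ids = ids,
    selection = if (is.character(selection)) selection else "custom",
    position_class = topology$dimers$position_class[d],
    pf = topology$dimers$pf[d],
    times = trajectory$times,
    provenance = trajectory$provenance,
    superposed = FALSE
  ), class = "subunit_trajectory")
}

#' Add solvent ions to a synthetic lattice
#'
#' Appends `ion_Mg` and/or `ion_Cl` atoms at uniformly random positions in the
#' given box.  Ions belong to the reserved solvent group (monomer 0).
#'
#' @param lattice An `assembly_lattice`.
#' @param n_mg,n_cl Ion counts.
#' @param box Box lengths, nm (length 3).
#' @param seed Integer seed.
#' @return The lattice with extended topology and reference coordinates.
#' @export
add_ions <- function(lattice, n_mg = 0L, n_cl = 0L, box = c(20, 10, 32),
                     seed = 1L) {
  n <- n_mg + n_cl
  if (n == 0) return(lattice)
  set.seed(seed)
  pos <- cbind(stats::runif(n, 0, box[1]),
               stats::runif(n, 0, box[2]),
               stats::runif(n, 0, box[3]))
  a <- lattice$topology$atoms
  ions <- data.frame(
    id = max(a$id) + seq_len(n),
    name = c(rep("MG", n_mg), rep("CL", n_cl)),
    mass = c(rep(24.305, n_mg), rep(35.45, n_cl)),
    species = c(rep("ion_Mg", n_mg), rep("ion_Cl", n_cl)),
    backbone = FALSE, calpha = FALSE, monomer = 0L,
    stringsAsFactors = FALSE
  )
  lattice$topology$atoms <- rbind(a, ions)
  lattice$reference <- rbind(lattice$reference, pos)
  lattice
}

#' Write / read an assembly topology
#'
#' The canonical exchange form is a JSON assembly map carrying the atom table
#' and the full hierarchy; reference coordinates, when given, are additionally
#' written as a PDB file (via bio3d) with coordinates converted nm -> Angstrom.
#' `read_topology(write_topology(t))` round-trips all fields.
#'
#' @param topology An [assembly_topology()].
#' @param json_path Path of the JSON assembly map.
#' @param reference Optional atoms x 3 reference coordinates (nm).
#' @param pdb_path Optional PDB output path (requires `reference`).
#' @return `write_topology` returns `json_path` invisibly; `read_topology`
#'   returns the topology, with the reference coordinates as attribute
#'   `"reference"` when a PDB is given.
#' @export
write_topology <- function(topology, json_path, reference = NULL,
                           pdb_path = NULL) {
  payload <- list(
    format = "assembly_map",
    version = 1L,
    atoms = topology$atoms,
    monomers = topology$monomers,
    dimers = topology$dimers
  )
  jsonlite::write_json(payload, json_path, digits = NA, dataframe = "columns")
  if (!is.null(pdb_path)) {
    if (is.null(reference)) stop("reference coordinates required to write PDB")
    if (nrow(reference) != nrow(topology$atoms)) {
      stop("atom count mismatch between topology and reference coordinates")
    }
    xyz <- as.vector(t(reference)) * 10  # nm -> Angstrom
    suppressWarnings(bio3d::write.pdb(
      file = pdb_path, xyz = xyz,
      type = rep("ATOM", nrow(topology$atoms)),
      resno = pmax(topology$atoms$monomer, 1L),
      resid = substr(toupper(topology$atoms$species), 1, 3),
      eleno = topology$atoms$id,
      elety = substr(topology$atoms$name, 1, 4)
    ))
  }
  invisible(json_path)
}

#' @rdname write_topology
#' @export
read_topology <- function(json_path, pdb_path = NULL) {
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(payload$format) || payload$format != "assembly_map") {
    stop("not an assembly map: ", json_path)
  }
  atoms <- as.data.frame(payload$atoms, stringsAsFactors = FALSE)
  atoms$id <- as.integer(atoms$id); atoms$monomer <- as.integer(atoms$monomer)
  monomers <- as.data.frame(payload$monomers, stringsAsFactors = FALSE)
  monomers$id <- as.integer(monomers$id)
  monomers$dimer <- as.integer(monomers$dimer)
  dimers <- as.data.frame(payload$dimers, stringsAsFactors = FALSE)
  dimers$id <- as.integer(dimers$id)
  dimers$pf <- as.integer(dimers$pf)
  dimers$layer <- as.integer(dimers$layer)
  topo <- assembly_topology(atoms, monomers, dimers)
  if (!is.null(pdb_path)) {
    pdb <- bio3d::read.pdb(pdb_path)
    ref <- matrix(pdb$xyz, ncol = 3, byrow = TRUE) / 10  # Angstrom -> nm
    if (nrow(ref) != nrow(atoms)) {
      stop("atom count mismatch between PDB and assembly map")
    }
    attr(topo, "reference") <- ref
  }
  topo
}
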