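#' @keywords internal
"_PACKAGE"

# Topology columns shared by every constructor and reader.
TOPOLOGY_COLS <- c("atom_id", "name", "element", "residue_number",
                   "residue_name", "is_hydrogen", "is_ligand")

#' Build an atom topology table
#'
#' A topology is a plain `data.frame` with one row per atom and columns
#' `atom_id` (unique non-negative integer), `name` (PDB atom name, e.g.
#' `"CA"`), `element` (chemical symbol), `residue_number` (author-assigned
#' integer; kinase-domain numbering 697--1019 for EGFR), `residue_name`
#' (3-letter code), `is_hydrogen` and `is_ligand` (logical). Protein atoms
#' must be grouped by residue with strictly increasing residue numbers;
#' numbering gaps (deletion mutants) are permitted. Ligand (HETATM) atoms
#' form a separate partition and are excluded from residue profiles and
#' superposition fits unless explicitly requested.
#'
#' @param atom_id integer vector of unique atom identifiers.
#' @param name character vector of atom names.
#' @param element character vector of element symbols; hydrogen is inferred
#'   from `element %in% c("H", "D")`.
#' @param residue_number integer vector of author residue numbers.
#' @param residue_name character vector of 3-letter residue codes.
#' @param is_ligand logical vector marking ligand (heteroatom) atoms.
#' @return A validated topology `data.frame`.
#' @export
make_topology <- function(atom_id, name, element, residue_number,
                          residue_name, is_ligand = FALSE) {
  topo <- data.frame(
    atom_id = as.integer(atom_id),
    name = as.character(name),
    element = toupper(as.character(element)),
    residue_number = as.integer(residue_number),
    residue_name = as.character(residue_name),
    stringsAsFactors = FALSE
  )
  topo$is_hydrogen <- topo$element %in% c("H", "D")
  topo$is_ligand <- rep_len(as.logical(is_ligand), nrow(topo))
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  stopifnot(is.data.frame(topo), all(TOPOLOGY_COLS %in% names(topo)))
  if (nrow(topo) == 0L) stop("topology has no atoms", call. = FALSE)
  if (anyDuplicated(topo$atom_id)) {
    stop("atom_id values must be unique within a topology", call. = FALSE)
  }
  if (any(topo$atom_id < 0L)) stop("atom_id must be >= 0", call. = FALSE)
  bad_h <- topo$is_hydrogen != (topo$element %in% c("H", "D"))
  if (any(bad_h)) {
    stop("is_hydrogen must be true iff element is H or D", call. = FALSE)
  }
  prot <- topo[!topo$is_ligand, , drop = FALSE]
  if (nrow(prot) > 0L) {
    rn <- prot$residue_number
    # residues must be contiguous blocks in strictly increasing order
    breaks <- rn[-1L] != rn[-length(rn)]
    res_order <- rn[c(TRUE, breaks)]
    if (anyDuplicated(res_order) || is.unsorted(res_order, strictly = TRUE)) {
      stop("protein residue_number must be strictly increasing ",
           "(contiguous atom blocks per residue)", call. = FALSE)
    }
  }
  invisible(topo)
}

#' Residue membership of a topology
#'
#' @param topo a topology `data.frame`.
#' @param ligand if `TRUE`, list ligand pseudo-residues instead of protein
#'   residues.
#' @return A list with `residue_number`, `residue_name`, and `rows` (a list
#'   of atom row indices into `topo`, one entry per residue, in residue
#'   order).
#' @export
topology_residues <- function(topo, ligand = FALSE) {
  part <- which(topo$is_ligand == ligand)
  rn <- topo$residue_number[part]
  if (length(part) == 0L) {
    return(list(residue_number = integer(0), residue_name = character(0),
                rows = list()))
  }
  idx <- split(part, factor(rn, levels = unique(rn)))
  list(
    residue_number = as.integer(names(idx)),
    residue_name = unname(vapply(idx, function(i) topo$residue_name[i[1L]],
                                 "")),
    rows = unname(idx)
  )
}

#' Construct a single structure frame
#'
#' @param topology a topology `data.frame` (see [make_topology()]).
#' @param coords numeric matrix with one row per atom and columns x, y, z in
#'   Angstrom; all coordinates must be finite.
#' @return An object of class `StructureFrame`.
#' @export
structure_frame <- function(topology, coords) {
  validate_topology(topology)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L) {
    stop("coords must be a numeric n x 3 matrix", call. = FALSE)
  }
  if (nrow(coords) != nrow(topology)) {
    stop("coordinate count (", nrow(coords), ") must equal topology atom ",
         "count (", nrow(topology), ")", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(topology = topology, coords = coords),
            class = "StructureFrame")
}

#' Construct a trajectory
#'
#' A trajectory is an ordered set of frames over one fixed topology: a
#' `n_atoms x 3 x n_frames` coordinate array in Angstrom plus the shared
#' topology. The frame interval is metadata only (the stability statistics
#' are order-agnostic).
#'
#' @param topology a topology `data.frame`.
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`.
#' @param frame_interval_ps positive sampling interval in picoseconds.
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(topology, coords, frame_interval_ps = 2) {
  validate_topology(topology)
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array", call. = FALSE)
  }
  if (dim(coords)[1L] != nrow(topology)) {
    stop("coordinate count per frame must equal topology atom count",
         call. = FALSE)
  }
  if (dim(coords)[3L] < 1L) stop("a trajectory needs at least one frame",
                                 call. = FALSE)
  if (!all(is.finite(coords))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  if (!is.numeric(frame_interval_ps) || frame_interval_ps <= 0) {
    stop("frame_interval_ps must be positive", call. = FALSE)
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"), NULL)
  structure(list(topology = topology, coords = coords,
                 frame_interval_ps = as.numeric(frame_interval_ps)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames,", nrow(x$topology), "atoms (",
      sum(!x$topology$is_ligand), "protein /", sum(x$topology$is_ligand),
      "ligand ),", length(topology_residues(x$topology)$residue_number),
      "protein residues\n")
  invisible(x)
}

#' @export
print.StructureFrame <- function(x, ...) {
  cat("StructureFrame:", nrow(x$topology), "atoms,",
      length(topology_residues(x$topology)$residue_number),
      "protein residues\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return Integer frame count J.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Extract one frame from a trajectory
#' @param traj a `Trajectory`.
#' @param j frame index (1-based).
#' @return A `StructureFrame`.
#' @export
get_frame <- function(traj, j) {
  j <- as.integer(j)
  if (j < 1L || j > n_frames(traj)) {
    stop("frame index ", j, " out of range 1..", n_frames(traj),
         call. = FALSE)
  }
  structure_frame(traj$topology, traj$coords[, , j, drop = TRUE])
}

#' Remove hydrogen atoms
#'
#' Drops every hydrogen (and deuterium) atom from the topology and all
#' frames; displacement statistics consider only non-hydrogen atoms, which
#' are too small and light to carry structural signal on their own. A
#' residue left with zero heavy atoms is dropped entirely. The operation is
#' idempotent.
#'
#' @param x a `Trajectory` or `StructureFrame`.
#' @return Object of the same class restricted to heavy atoms.
#' @export
strip_hydrogens <- function(x) UseMethod("strip_hydrogens")

#' @export
strip_hydrogens.Trajectory <- function(x) {
  keep <- !x$topology$is_hydrogen
  if (all(keep)) return(x)
  if (!any(keep)) stop("no heavy atoms left after hydrogen stripping",
                       call. = FALSE)
  trajectory(droplevels_topology(x$topology[keep, , drop = FALSE]),
             x$coords[keep, , , drop = FALSE], x$frame_interval_ps)
}

#' @export
strip_hydrogens.StructureFrame <- function(x) {
  keep <- !x$topology$is_hydrogen
  if (all(keep)) return(x)
  if (!any(keep)) stop("no heavy atoms left after hydrogen stripping",
                       call. = FALSE)
  structure_frame(droplevels_topology(x$topology[keep, , drop = FALSE]),
                  x$coords[keep, , drop = FALSE])
}

droplevels_topology <- function(topo) {
  rownames(topo) <- NULL
  topo
}

#' Heavy-atom counts per protein residue
#' @param topo a topology `data.frame`.
#' @return Named integer vector (names are residue numbers) of non-hydrogen,
#'   non-ligand atom counts K per residue.
#' @export
heavy_atom_counts <- function(topo) {
  res <- topology_residues(topo)
  k <- vapply(res$rows, function(i) sum(!topo$is_hydrogen[i]), 0L)
  names(k) <- res$residue_number
  k
}
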