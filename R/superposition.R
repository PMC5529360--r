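#' Least-squares rigid-body fit (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' the masked atoms of `mobile` onto `reference`, i.e. the rigid transform
#' `x -> R x + t`. The reflection branch of the SVD solution is handled by
#' the standard determinant correction (negate the smallest singular axis),
#' so the rotation is always proper (det = +1).
#'
#' @param mobile,reference `StructureFrame`s sharing the mask atoms.
#' @param atom_mask integer vector of `atom_id`s to fit on; default all
#'   protein heavy atoms of the reference. At least 3 non-collinear atoms
#'   are required.
#' @return A list of class `RigidTransform` with elements `rotation` (3x3,
#'   proper orthogonal) and `translation` (length-3, Angstrom).
#' @export
kabsch_fit <- function(mobile, reference, atom_mask = NULL) {
  if (is.null(atom_mask)) atom_mask <- default_fit_mask(reference$topology)
  P <- masked_coords(mobile, atom_mask)
  Q <- masked_coords(reference, atom_mask)
  if (nrow(P) < 3L) {
    stop("degenerate fit: mask must contain at least 3 atoms", call. = FALSE)
  }
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp)
  Q0 <- sweep(Q, 2L, cq)
  # collinearity: centered mobile coordinates of rank < 2 leave the rotation
  # about the shared axis undetermined
  if (svd(P0, nu = 0, nv = 0)$d[2L] < 1e-8) {
    stop("degenerate fit: mask atoms are collinear", call. = FALSE)
  }
  H <- crossprod(P0, Q0)          # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp)),
            class = "RigidTransform")
}

default_fit_mask <- function(topo) {
  topo$atom_id[!topo$is_hydrogen & !topo$is_ligand]
}

masked_coords <- function(frame, atom_mask) {
  rows <- match(atom_mask, frame$topology$atom_id)
  if (anyNA(rows)) {
    stop("mask atom ids absent from frame: ",
         paste(utils::head(atom_mask[is.na(rows)], 5L), collapse = ", "),
         call. = FALSE)
  }
  frame$coords[rows, , drop = FALSE]
}

#' Apply a rigid transform to coordinates
#' @param transform a `RigidTransform`.
#' @param coords n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  sweep(coords %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' Best-fit every frame of a trajectory onto a reference structure
#'
#' For each frame, the rigid transform is fit on the mask atoms (default:
#' all protein heavy atoms — the fit is not narrowed to backbone or CA) and
#' then applied to all atoms of the frame, removing global translation and
#' rotation while preserving internal motion. This replicates cpptraj-style
#' best-fit of each frame to the original structure prior to averaging.
#'
#' @param traj a [trajectory()].
#' @param reference a `StructureFrame` sharing the trajectory topology;
#'   defaults to the first frame (the "original structure").
#' @param atom_mask atom ids to fit on; default all protein heavy atoms.
#' @return An aligned `Trajectory`, frame order preserved.
#' @export
align_trajectory <- function(traj, reference = NULL, atom_mask = NULL) {
  if (is.null(reference)) reference <- get_frame(traj, 1L)
  if (is.null(atom_mask)) atom_mask <- default_fit_mask(reference$topology)
  out <- traj$coords
  frame <- structure_frame(traj$topology, traj$coords[, , 1L])
  for (j in seq_len(n_frames(traj))) {
    frame$coords[] <- traj$coords[, , j]
    tr <- tryCatch(
      kabsch_fit(frame, reference, atom_mask),
      error = function(e) stop("alignment failed at frame ", j, ": ",
                               conditionMessage(e), call. = FALSE))
    out[, , j] <- apply_transform(tr, frame$coords)
  }
  trajectory(traj$topology, out, traj$frame_interval_ps)
}

#' Average structure of a trajectory
#'
#' Per-atom arithmetic mean of the coordinates over all frames. Meaningful
#' as a displacement reference only after [align_trajectory()]; the caller
#' is responsible for alignment (not checked). The average is used as-is —
#' it is a statistical reference, not an idealised structure.
#'
#' @param traj a [trajectory()] (assumed aligned).
#' @return A `StructureFrame` of mean coordinates.
#' @export
average_structure <- function(traj) {
  n <- dim(traj$coords)[1L]
  m <- rowMeans(matrix(traj$coords, n * 3L, n_frames(traj)), dims = 1L)
  structure_frame(traj$topology, matrix(m, n, 3L))
}

#' Mask RMSD between two frames
#' @param a,b `StructureFrame`s.
#' @param atom_mask atom ids; default all protein heavy atoms of `a`.
#' @return Root-mean-square deviation in Angstrom.
#' @export
frame_rmsd <- function(a, b, atom_mask = NULL) {
  if (is.null(atom_mask)) atom_mask <- default_fit_mask(a$topology)
  pa <- masked_coords(a, atom_mask)
  pb <- masked_coords(b, atom_mask)
  sqrt(mean(rowSums((pa - pb)^2)))
}
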