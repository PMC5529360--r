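#' Euclidean distance between two atoms
#' @param a1,a2 length-3 coordinate vectors (Angstrom).
#' @return The Euclidean distance in Angstrom.
#' @export
atom_distance <- function(a1, a2) {
  sqrt(sum((as.numeric(a1) - as.numeric(a2))^2))
}

#' Displacement of one residue between a frame and a reference
#'
#' The residue displacement is the unweighted average, over the K heavy
#' atoms of the residue, of the Euclidean distances between corresponding
#' atoms (paired by `atom_id`) in the frame and the reference structure.
#'
#' @param frame,reference `StructureFrame`s containing the residue with the
#'   same heavy-atom set.
#' @param residue_number author residue number.
#' @return Mean per-atom displacement in Angstrom.
#' @export
residue_distance <- function(frame, reference, residue_number) {
  rows_f <- residue_heavy_rows(frame$topology, residue_number)
  rows_r <- residue_heavy_rows(reference$topology, residue_number)
  ids_f <- frame$topology$atom_id[rows_f]
  ids_r <- reference$topology$atom_id[rows_r]
  if (!setequal(ids_f, ids_r)) {
    stop("heavy-atom set of residue ", residue_number,
         " differs between frame and reference", call. = FALSE)
  }
  rows_r <- rows_r[match(ids_f, ids_r)]
  d <- sqrt(rowSums((frame$coords[rows_f, , drop = FALSE] -
                     reference$coords[rows_r, , drop = FALSE])^2))
  mean(d)
}

residue_heavy_rows <- function(topo, residue_number) {
  rows <- which(!topo$is_ligand & !topo$is_hydrogen &
                topo$residue_number == residue_number)
  if (length(rows) == 0L) {
    stop("residue ", residue_number, " not found (or has no heavy atoms)",
         call. = FALSE)
  }
  rows
}

#' Per-residue stability profile
#'
#' For each protein residue i, computes the mean over frames of the residue
#' displacement from the reference (stability mean) and the sample standard
#' deviation of those displacements (denominator J-1). Higher values mean
#' lower stability. In the default pipeline the trajectory has been
#' best-fit aligned and the reference is its average structure; this
#' function does not itself align.
#'
#' @param traj an aligned [trajectory()] (heavy atoms; hydrogens, if
#'   present, are ignored).
#' @param reference a `StructureFrame`; defaults to
#'   [average_structure()]`(traj)`.
#' @return A `data.frame` of class `StabilityProfile` with columns
#'   `residue_number`, `residue_name`, `K` (heavy atoms),
#'   `stability_mean` and `stability_std` (Angstrom), plus attribute
#'   `n_frames`. With a single frame `stability_std` is `NA` (undefined).
#' @export
stability_profile <- function(traj, reference = NULL) {
  if (is.null(reference)) reference <- average_structure(traj)
  D <- residue_frame_distances(traj, reference)
  J <- ncol(D)
  res <- attr(D, "residues")
  out <- data.frame(
    residue_number = res$residue_number,
    residue_name = res$residue_name,
    K = res$K,
    stability_mean = rowMeans(D),
    stability_std = if (J >= 2L) apply(D, 1L, stats::sd) else NA_real_,
    row.names = NULL
  )
  attr(out, "n_frames") <- J
  class(out) <- c("StabilityProfile", "data.frame")
  out
}

# R x J matrix of residue displacements (heavy atoms, protein partition),
# residues as attribute. Vectorised over the whole coordinate array.
residue_frame_distances <- function(traj, reference) {
  topo <- traj$topology
  heavy <- which(!topo$is_ligand & !topo$is_hydrogen)
  ref_rows <- match(topo$atom_id[heavy], reference$topology$atom_id)
  if (anyNA(ref_rows)) {
    stop("reference is missing atoms of the trajectory topology",
         call. = FALSE)
  }
  n <- length(heavy)
  J <- n_frames(traj)
  ref <- reference$coords[ref_rows, , drop = FALSE]
  # per-atom distance to reference, all frames at once
  dsq <- matrix(0, n, J)
  for (a in 1:3) {
    dsq <- dsq + (matrix(traj$coords[heavy, a, ], n, J) - ref[, a])^2
  }
  d <- sqrt(dsq)
  rn <- topo$residue_number[heavy]
  grp <- factor(rn, levels = unique(rn))
  D <- rowsum(d, grp, reorder = FALSE) / as.vector(table(grp))
  res_first <- heavy[!duplicated(rn)]
  attr(D, "residues") <- list(
    residue_number = topo$residue_number[res_first],
    residue_name = topo$residue_name[res_first],
    K = as.integer(table(grp))
  )
  D
}

#' Order residues by mean distance to a focal residue
#'
#' Residue centers are unweighted heavy-atom centroids, computed per frame;
#' the distance of residue i to the focal residue is the average over
#' frames of the Euclidean distance between their centers. Residues are
#' then ranked by ascending mean distance: rank 0 is the focal residue
#' itself (distance exactly 0), rank 1 its closest neighbour, and so on.
#' Ties are broken by ascending residue number.
#'
#' @param traj an aligned [trajectory()].
#' @param focal_residue_number author residue number of the focal residue
#'   (EGFR T790 in the motivating analysis).
#' @return A `data.frame` of class `FocalOrdering` with columns
#'   `residue_number`, `dist_to_focal` (Angstrom) and `rank` (0-based),
#'   sorted by rank; attribute `focal_residue_number`.
#' @export
focal_ordering <- function(traj, focal_residue_number = 790L) {
  topo <- traj$topology
  heavy <- which(!topo$is_ligand & !topo$is_hydrogen)
  rn <- topo$residue_number[heavy]
  if (!focal_residue_number %in% rn) {
    avail <- unique(rn)
    stop("focal residue ", focal_residue_number, " not in topology ",
         "(available: ", avail[1L], "..", avail[length(avail)], ")",
         call. = FALSE)
  }
  J <- n_frames(traj)
  grp <- factor(rn, levels = unique(rn))
  K <- as.vector(table(grp))
  R <- nlevels(grp)
  # residue centroids per axis: R x J
  centers <- lapply(1:3, function(a) {
    rowsum(matrix(traj$coords[heavy, a, ], length(heavy), J), grp,
           reorder = FALSE) / K
  })
  focal_i <- match(as.character(focal_residue_number), levels(grp))
  dsq <- matrix(0, R, J)
  for (a in 1:3) {
    dsq <- dsq + sweep(centers[[a]], 2L, centers[[a]][focal_i, ])^2
  }
  dist_to_focal <- rowMeans(sqrt(dsq))
  res_num <- as.integer(levels(grp))
  ord <- order(dist_to_focal, res_num)
  out <- data.frame(
    residue_number = res_num[ord],
    dist_to_focal = dist_to_focal[ord],
    rank = seq_along(ord) - 1L,
    row.names = NULL
  )
  attr(out, "focal_residue_number") <- as.integer(focal_residue_number)
  class(out) <- c("FocalOrdering", "data.frame")
  out
}

#' Restrict a stability profile to a residue-number range
#'
#' The head and tail of the modelled kinase domain carry a degree of
#' arbitrariness, so reporting is restricted to the span between the first
#' and last helix (EGFR residues 716--976 by default). Residues absent from
#' the range (including deletion-mutant gaps) are simply dropped. Trimming
#' is a reporting step: alignment and reference construction use the whole
#' structure.
#'
#' @param profile a [stability_profile()] (or any data frame with a
#'   `residue_number` column, e.g. a [focal_ordering()]).
#' @param lo,hi inclusive residue-number bounds.
#' @return The profile restricted to `lo <= residue_number <= hi`; ranks in
#'   a `FocalOrdering` are recomputed over the survivors.
#' @export
trim_to_range <- function(profile, lo = 716L, hi = 976L) {
  if (lo > hi) stop("lo must be <= hi", call. = FALSE)
  keep <- profile$residue_number >= lo & profile$residue_number <= hi
  if (!any(keep)) {
    stop("no residues in range ", lo, "..", hi, call. = FALSE)
  }
  out <- profile[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(out$rank)) out$rank <- seq_len(nrow(out)) - 1L
  for (a in c("n_frames", "focal_residue_number")) {
    attr(out, a) <- attr(profile, a)
  }
  out
}

#' Cumulative average stability over the focal ordering
#'
#' Value at rank position k is the running mean of the chosen stability
#' statistic over the k+1 residues closest to the focal residue (the focal
#' residue itself included at k = 0). The curve's first value is therefore
#' the focal residue's own stability and its last value is the plain mean
#' over all profiled residues. The first few dozen values summarise
#' stability around the focal residue.
#'
#' @param profile a [stability_profile()], trimmed as desired.
#' @param ordering a [focal_ordering()] covering the same residue set
#'   (apply [trim_to_range()] to both first).
#' @param statistic `"mean"` or `"std"` — which profile column to
#'   accumulate.
#' @return A `data.frame` of class `CumulativeCurve` with columns `k`
#'   (0-based rank position), `residue_number` and `cumulative` (Angstrom);
#'   attribute `statistic`.
#' @export
cumulative_average <- function(profile, ordering,
                               statistic = c("mean", "std")) {
  statistic <- match.arg(statistic)
  mismatch <- c(setdiff(profile$residue_number, ordering$residue_number),
                setdiff(ordering$residue_number, profile$residue_number))
  if (length(mismatch) > 0L) {
    stop("profile and ordering cover different residues: ",
         paste(sort(mismatch), collapse = ", "), call. = FALSE)
  }
  col <- if (statistic == "mean") "stability_mean" else "stability_std"
  s <- profile[[col]][match(ordering$residue_number,
                            profile$residue_number)]
  out <- data.frame(
    k = seq_along(s) - 1L,
    residue_number = ordering$residue_number,
    cumulative = cumsum(s) / seq_along(s),
    row.names = NULL
  )
  attr(out, "statistic") <- statistic
  class(out) <- c("CumulativeCurve", "data.frame")
  out
}

#' Rank mutant complexes by stability around the focal residue
#'
#' Orders labelled cumulative curves by the mean of their first `k_window`
#' values (rank positions 0..k_window-1), descending: a higher cumulative
#' average displacement means lower stability, so the first label is the
#' least stable complex around the focal residue.
#'
#' @param curves named list of [cumulative_average()] curves sharing the
#'   statistic.
#' @param k_window number of leading rank positions to average (default 50,
#'   i.e. the first few dozen residues around the focal residue).
#' @return A `data.frame` with columns `label`, `window_mean` (Angstrom)
#'   and `rank` (1 = least stable), ordered least to most stable; ties are
#'   reported via the `tied_with_next` logical column. Attribute `k_window`
#'   records the window used.
#' @export
compare_mutants <- function(curves, k_window = 50L) {
  if (length(curves) == 0L) stop("no curves to compare", call. = FALSE)
  if (is.null(names(curves)) || any(names(curves) == "")) {
    stop("curves must be a named list", call. = FALSE)
  }
  if (k_window < 1L) stop("k_window must be >= 1", call. = FALSE)
  stats <- unique(vapply(curves, function(cv) attr(cv, "statistic"), ""))
  if (length(stats) > 1L) {
    stop("curves mix statistics: ", paste(stats, collapse = ", "),
         call. = FALSE)
  }
  wm <- vapply(curves, function(cv) {
    kw <- min(k_window, nrow(cv))
    mean(cv$cumulative[seq_len(kw)])
  }, 0)
  ord <- order(-wm, names(curves))
  out <- data.frame(
    label = names(curves)[ord],
    window_mean = unname(wm[ord]),
    rank = seq_along(ord),
    row.names = NULL
  )
  out$tied_with_next <- c(diff(out$window_mean) == 0, FALSE)
  attr(out, "k_window") <- as.integer(min(k_window,
                                          max(vapply(curves, nrow, 0L))))
  out
}
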