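#' Recipe for a synthetic MD-like trajectory
#'
#' Describes the statistical structure of a generated trajectory emulating
#' a production MD run of a kinase domain: a fixed heavy-atom topology,
#' author residue numbering starting at 697 with optional deletion gaps,
#' i.i.d. per-atom Gaussian fluctuation with a per-residue amplitude, and
#' optional per-frame rigid-body jitter (uniform random rotation axis,
#' angle uniform in `[0, max_rotation_deg]`, translation uniform in a cube
#' of half-width `max_translation_A`). Defaults mirror the emulated study
#' conditions: 5000 frames sampled every 2 ps over 10 ns. No force field,
#' solvent or thermostat is emulated — only the displacement statistics the
#' stability analysis consumes.
#'
#' @param n_residues number of residues.
#' @param atoms_per_residue heavy atoms per residue (scalar or per-residue
#'   vector).
#' @param residue_number_start first author residue number (default 697,
#'   the start of the EGFR kinase domain numbering).
#' @param deletion_gaps integer vector of residue numbers to skip
#'   (e.g. `746:750` for the delE746_A750 mutant).
#' @param per_residue_sigma Gaussian fluctuation amplitude per coordinate,
#'   in Angstrom (scalar or per-residue vector). Default 0.4 A, a typical
#'   heavy-atom fluctuation scale for a folded kinase domain at 300 K.
#' @param rigid_jitter list with `max_rotation_deg` and `max_translation_A`
#'   for per-frame rigid-body drift (both 0 = no jitter).
#' @param n_frames number of frames J (default 5000).
#' @param frame_interval_ps sampling interval metadata (default 2 ps).
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @return A list of class `TrajectoryRecipe`.
#' @export
trajectory_recipe <- function(n_residues = 323L,
                              atoms_per_residue = 8L,
                              residue_number_start = 697L,
                              deletion_gaps = integer(0),
                              per_residue_sigma = 0.4,
                              rigid_jitter = list(max_rotation_deg = 0,
                                                  max_translation_A = 0),
                              n_frames = 5000L,
                              frame_interval_ps = 2,
                              seed = 1L) {
  stopifnot(n_residues >= 1L, n_frames >= 1L,
            all(per_residue_sigma >= 0), all(atoms_per_residue >= 1L))
  numbers <- residue_numbers_with_gaps(residue_number_start, n_residues,
                                       deletion_gaps)
  structure(list(
    n_residues = as.integer(n_residues),
    atoms_per_residue = rep_len(as.integer(atoms_per_residue), n_residues),
    residue_numbers = numbers,
    per_residue_sigma = rep_len(as.numeric(per_residue_sigma), n_residues),
    rigid_jitter = list(
      max_rotation_deg = rigid_jitter$max_rotation_deg %||% 0,
      max_translation_A = rigid_jitter$max_translation_A %||% 0),
    n_frames = as.integer(n_frames),
    frame_interval_ps = frame_interval_ps,
    seed = as.integer(seed)
  ), class = "TrajectoryRecipe")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

residue_numbers_with_gaps <- function(start, n, gaps) {
  pool <- setdiff(seq.int(start, start + n + length(gaps) + 64L),
                  as.integer(gaps))
  pool[seq_len(n)]
}

#' Deterministic synthetic reference structure
#'
#' Places residue centroids on a coarse 3D helix-like curve (so that
#' distance-to-focal-residue ordering is spatially nontrivial) and
#' scatters each residue's heavy atoms around its centroid with a fixed
#' 1.5 A spread. Reproducible: the same recipe always yields the same
#' frame.
#'
#' @param recipe a [trajectory_recipe()].
#' @return A `StructureFrame` of heavy atoms.
#' @export
make_reference <- function(recipe) {
  stopifnot(inherits(recipe, "TrajectoryRecipe"))
  withr_seed(recipe$seed, {
    n_res <- recipe$n_residues
    k <- recipe$atoms_per_residue
    t <- seq_len(n_res)
    centers <- cbind(6 * cos(t / 3), 6 * sin(t / 3), 1.5 * t)
    rows <- rep(seq_len(n_res), k)
    coords <- centers[rows, , drop = FALSE] +
      matrix(stats::rnorm(sum(k) * 3L, sd = 1.5), sum(k), 3L)
    topo <- make_topology(
      atom_id = seq_len(sum(k)),
      name = paste0("C", sequence(k)),
      element = "C",
      residue_number = recipe$residue_numbers[rows],
      residue_name = "ALA"
    )
    structure_frame(topo, coords)
  })
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic trajectory around a reference structure
#'
#' Frame j is `G_j(reference + noise_j)`: i.i.d. per-atom Gaussian noise
#' with the residue's sigma per coordinate, optionally followed by a
#' random rigid transform `G_j` (the jitter the alignment step must
#' remove). Frames are independent: the stability statistics are
#' order-agnostic, so temporal autocorrelation is irrelevant to them; an
#' AR(1) mode (`ar1_phi`) exists to demonstrate that invariance. The
#' ground-truth sigmas are recorded in attribute `true_sigma`.
#'
#' @param reference a `StructureFrame` from [make_reference()] (or any
#'   frame whose topology matches the recipe's residue layout).
#' @param recipe a [trajectory_recipe()].
#' @param ar1_phi optional AR(1) coefficient in `[0, 1)` for temporally
#'   correlated noise (default 0 = i.i.d. frames); the marginal sigma is
#'   held at the recipe value.
#' @return A [trajectory()] with attributes `true_sigma` (named by
#'   residue) and `seed`.
#' @export
generate_trajectory <- function(reference, recipe, ar1_phi = 0) {
  stopifnot(inherits(recipe, "TrajectoryRecipe"),
            inherits(reference, "StructureFrame"),
            ar1_phi >= 0, ar1_phi < 1)
  topo <- reference$topology
  rows <- match(topo$residue_number,
                recipe$residue_numbers)
  if (anyNA(rows)) {
    stop("reference topology does not match recipe residue numbering",
         call. = FALSE)
  }
  sig_atom <- recipe$per_residue_sigma[rows]
  n <- nrow(topo)
  J <- recipe$n_frames
  withr_seed(recipe$seed + 1L, {
    coords <- array(NA_real_, c(n, 3L, J))
    innov_sd <- if (ar1_phi > 0) sqrt(1 - ar1_phi^2) else 1
    prev <- matrix(0, n, 3L)
    for (j in seq_len(J)) {
      eps <- matrix(stats::rnorm(n * 3L), n, 3L)
      prev <- if (ar1_phi > 0) ar1_phi * prev + innov_sd * eps else eps
      fr <- reference$coords + prev * sig_atom
      jit <- recipe$rigid_jitter
      if (jit$max_rotation_deg > 0 || jit$max_translation_A > 0) {
        G <- random_rigid_transform(jit$max_rotation_deg,
                                    jit$max_translation_A)
        fr <- apply_transform(G, fr)
      }
      coords[, , j] <- fr
    }
    out <- trajectory(topo, coords, recipe$frame_interval_ps)
    attr(out, "true_sigma") <- stats::setNames(recipe$per_residue_sigma,
                                               recipe$residue_numbers)
    attr(out, "seed") <- recipe$seed
    out
  })
}

# uniform random axis on the sphere, angle uniform in [0, max_deg],
# translation uniform in [-max_A, max_A]^3
random_rigid_transform <- function(max_deg, max_A) {
  ax <- stats::rnorm(3L)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1L, 0, max_deg * pi / 180)
  R <- rotation_about_axis(ax, th)
  structure(list(rotation = R,
                 translation = stats::runif(3L, -max_A, max_A)),
            class = "RigidTransform")
}

rotation_about_axis <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Per-residue sigma profile concentrated around a focal residue
#'
#' Convenience for three-mutant comparison scenarios: assigns
#' `sigma_near` to the `n_near` residues whose reference centroids lie
#' closest to the focal residue's centroid (the focal residue included)
#' and `sigma_far` to the rest, so that generated complexes differ in
#' flexibility specifically around the focal residue.
#'
#' @param reference a `StructureFrame` (e.g. [make_reference()]).
#' @param focal_residue_number focal residue number.
#' @param n_near number of near-focal residues (default 20).
#' @param sigma_near,sigma_far fluctuation amplitudes in Angstrom.
#' @return Numeric sigma vector ordered as the reference's residues.
#' @export
near_focal_sigma <- function(reference, focal_residue_number,
                             n_near = 20L, sigma_near = 0.8,
                             sigma_far = 0.3) {
  res <- topology_residues(reference$topology)
  cen <- t(vapply(res$rows,
                  function(i) colMeans(reference$coords[i, , drop = FALSE]),
                  numeric(3L)))
  fi <- match(focal_residue_number, res$residue_number)
  if (is.na(fi)) stop("focal residue not in reference", call. = FALSE)
  d <- sqrt(rowSums(sweep(cen, 2L, cen[fi, ])^2))
  near <- order(d)[seq_len(min(n_near, length(d)))]
  sig <- rep(sigma_far, length(d))
  sig[near] <- sigma_near
  sig
}
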