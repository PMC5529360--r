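# Independent oracles and small builders shared across the suite.

# Horn's quaternion method for rigid superposition: an independent route
# to the optimal rotation, used to cross-check the SVD-based fit.
quaternion_fit_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  M <- crossprod(P0, Q0)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  fit <- sweep(P0 %*% t(R), 2, cq, "+")
  sqrt(mean(rowSums((fit - Q)^2)))
}

# brute-force per-atom / per-frame loops re-deriving the stability
# statistics directly from their definitions
naive_residue_dist <- function(frame, reference, resnum) {
  topo <- frame$topology
  rows <- which(!topo$is_ligand & !topo$is_hydrogen &
                topo$residue_number == resnum)
  total <- 0
  for (r in rows) {
    rr <- which(reference$topology$atom_id == topo$atom_id[r])
    total <- total + sqrt(sum((frame$coords[r, ] -
                               reference$coords[rr, ])^2))
  }
  total / length(rows)
}

naive_stability_profile <- function(traj, reference) {
  res <- topology_residues(traj$topology)
  J <- n_frames(traj)
  means <- stds <- numeric(length(res$residue_number))
  for (i in seq_along(res$residue_number)) {
    d <- numeric(J)
    for (j in seq_len(J)) {
      d[j] <- naive_residue_dist(get_frame(traj, j), reference,
                                 res$residue_number[i])
    }
    means[i] <- sum(d) / J
    stds[i] <- if (J >= 2) sqrt(sum((d - means[i])^2) / (J - 1)) else NA
  }
  data.frame(residue_number = res$residue_number,
             stability_mean = means, stability_std = stds)
}

naive_focal_distances <- function(traj, focal) {
  res <- topology_residues(traj$topology)
  J <- n_frames(traj)
  centroid <- function(j, rows) {
    colSums(traj$coords[rows, , j, drop = FALSE]) / length(rows)
  }
  fi <- match(focal, res$residue_number)
  out <- numeric(length(res$residue_number))
  for (i in seq_along(res$residue_number)) {
    d <- 0
    for (j in seq_len(J)) {
      d <- d + sqrt(sum((centroid(j, res$rows[[i]]) -
                         centroid(j, res$rows[[fi]]))^2))
    }
    out[i] <- d / J
  }
  names(out) <- res$residue_number
  out
}

naive_cumulative <- function(values) {
  out <- numeric(length(values))
  for (k in seq_along(values)) out[k] <- sum(values[seq_len(k)]) / k
  out
}

# small randomized trajectory over a gappy residue numbering
random_small_trajectory <- function(n_res = 6, k = 3, J = 8, seed = 1,
                                    sigma = 0.6) {
  set.seed(seed)
  rn <- sort(sample(700:760, n_res))
  topo <- make_topology(
    atom_id = seq_len(n_res * k),
    name = paste0("C", rep(seq_len(k), n_res)),
    element = "C",
    residue_number = rep(rn, each = k),
    residue_name = "GLY"
  )
  base <- matrix(rnorm(n_res * k * 3, sd = 4), n_res * k, 3)
  coords <- array(NA_real_, c(n_res * k, 3, J))
  for (j in seq_len(J)) {
    coords[, , j] <- base + matrix(rnorm(n_res * k * 3, sd = sigma),
                                   n_res * k, 3)
  }
  trajectory(topo, coords)
}

# three-atom, two-residue frame used by several hand computations
tiny_frame <- function(coords = rbind(c(0, 0, 0), c(1, 0, 0),
                                      c(0, 0, 7))) {
  topo <- make_topology(atom_id = 1:3, name = c("CA", "CB", "CA"),
                        element = "C", residue_number = c(10L, 10L, 11L),
                        residue_name = c("ALA", "ALA", "GLY"))
  structure_frame(topo, coords)
}

expect_transform_close <- function(tr, rotation, translation,
                                   tol = 1e-8) {
  expect_lt(max(abs(tr$rotation - rotation)), tol)
  expect_lt(max(abs(tr$translation - translation)), tol)
}
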