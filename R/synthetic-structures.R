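# Synthetic two-domain structures related by a known hinge rotation.

rotation_about_axis <- function(axis, angle_deg) {
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("rotation axis must be nonzero")
  u <- axis / nrm
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a synthetic open/closed two-domain structure pair
#'
#' Two pseudo-atomic domains (uniform points in spheres 24 A apart); the
#' "closed" state rotates domain 2 by `angle_deg` about `axis` through
#' the inter-domain interface centroid while domain 1 stays fixed, then
#' optionally adds isotropic Gaussian jitter to the closed coordinates.
#' A synthetic analogue of a PDZ-tandem open/closed conformational pair.
#'
#' @param n_atoms_per_domain atoms per domain (>= 3).
#' @param angle_deg hinge rotation in degrees.
#' @param axis rotation axis 3-vector (nonzero).
#' @param jitter_sd coordinate jitter sd in Angstrom.
#' @param seed integer seed.
#' @return Object of class `two_state_structure`: `open_coords`,
#'   `closed_coords` (N x 3), `domain1_idx`, `domain2_idx`,
#'   `true_angle_deg`, `true_axis` (unit), `pivot`, `seed`.
#' @export
gen_two_state <- function(n_atoms_per_domain, angle_deg = 33,
                          axis = c(0, 0, 1), jitter_sd = 0, seed = 1L) {
  stopifnot(n_atoms_per_domain >= 3, jitter_sd >= 0)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("rotation axis must be nonzero")
  local_seed(seed)
  n <- as.integer(n_atoms_per_domain)
  sphere <- function(center, radius) {
    pts <- matrix(stats::rnorm(3 * n), n, 3)
    pts <- pts / sqrt(rowSums(pts^2)) * radius * stats::runif(n)^(1 / 3)
    sweep(pts, 2, center, `+`)
  }
  d1 <- sphere(c(-12, 0, 0), 10)
  d2 <- sphere(c(12, 0, 0), 10)
  open <- rbind(d1, d2)
  pivot <- (colMeans(d1) + colMeans(d2)) / 2
  R <- rotation_about_axis(axis, angle_deg)
  d2r <- sweep(sweep(d2, 2, pivot, `-`) %*% t(R), 2, pivot, `+`)
  closed <- rbind(d1, d2r)
  if (jitter_sd > 0)
    closed <- closed + matrix(stats::rnorm(length(closed), 0, jitter_sd),
                              nrow(closed), 3)
  structure(list(open_coords = open, closed_coords = closed,
                 domain1_idx = seq_len(n), domain2_idx = n + seq_len(n),
                 true_angle_deg = angle_deg, true_axis = axis / nrm,
                 pivot = pivot, seed = seed),
            class = "two_state_structure")
}

#' Build a CA-only structure model from a coordinate matrix
#'
#' Wraps an N x 3 coordinate matrix as a CA-trace [structure_model] with
#' residue numbers `1..N` on a single chain, so synthetic structures can
#' flow through the same hinge machinery as parsed PDB files.
#'
#' @param xyz N x 3 numeric matrix (Angstrom).
#' @param chain chain identifier (default "A").
#' @param source label stored on the model.
#' @return A `structure_model`.
#' @export
structure_from_coords <- function(xyz, chain = "A", source = "synthetic") {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, all(is.finite(xyz)))
  atoms <- data.frame(chain = chain, resno = seq_len(nrow(xyz)),
                      resid = "ALA", elety = "CA",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  structure(list(atoms = atoms, source = source), class = "structure_model")
}
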