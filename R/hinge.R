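# Open/closed two-domain conformational analysis on CA traces: pair the
# residues common to both models, superpose on domain 1, report the
# domain-2 rmsd in that frame and the effective hinge rotation from the
# best-fit rigid rotation of domain 2, plus anisotropic-network normal
# modes and their overlap with the observed transition.

#' Read a CA-trace structure model from a PDB file
#'
#' Parses a PDB file (via bio3d), drops waters, resolves alternate
#' locations to the highest-occupancy copy, and keeps the CA atoms of one
#' protein chain (the first chain by default). Residues without a CA atom
#' are skipped with a warning.
#'
#' @param path PDB file path.
#' @param chain chain identifier; default: first chain in the file.
#' @return Object of class `structure_model`: `atoms` data.frame
#'   (`chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`) and `source`.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("failed to parse ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$resid != "HOH", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms on chain ", chain)
  ca <- at[at$elety == "CA", , drop = FALSE]
  # alternate locations: keep the highest-occupancy copy per residue
  if (any(!is.na(ca$alt) & nzchar(ca$alt) & ca$alt != " ")) {
    ca <- ca[order(ca$resno, -ca$o), , drop = FALSE]
    ca <- ca[!duplicated(ca$resno), , drop = FALSE]
    ca <- ca[order(ca$resno), , drop = FALSE]
  }
  n_res <- length(unique(at$resno))
  if (nrow(ca) < n_res)
    warning(sprintf("%d residue(s) without CA skipped", n_res - nrow(ca)))
  if (nrow(ca) == 0L) stop("no CA atoms on chain ", chain)
  if (!all(is.finite(c(ca$x, ca$y, ca$z)))) stop("non-finite coordinates")
  structure(list(atoms = data.frame(chain = ca$chain, resno = ca$resno,
                                    resid = ca$resid, elety = ca$elety,
                                    x = ca$x, y = ca$y, z = ca$z),
                 source = path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d CA atoms, chain %s, residues %d-%d (%s)\n",
              nrow(x$atoms), x$atoms$chain[1], min(x$atoms$resno),
              max(x$atoms$resno), x$source))
  invisible(x)
}

#' Download a PDB entry (requires network access)
#'
#' Thin wrapper over `bio3d::get.pdb()` for fetching entries such as the
#' ligand-free and cargo-bound PDZ-tandem structures; intended for
#' interactive use, never called by the test-suite.
#'
#' @param id 4-character PDB identifier.
#' @param path destination directory.
#' @return Path of the downloaded file.
#' @export
fetch_pdb <- function(id, path = ".") {
  bio3d::get.pdb(id, path = path)
}

#' Two-domain residue-range definition
#'
#' Inclusive residue-number intervals for the two domains; defaults match
#' the PDZ-tandem construct boundaries (PDZ1 residues 2-107, PDZ2
#' residues 108-208).
#'
#' @param pdz1_range,pdz2_range length-2 inclusive residue intervals;
#'   must be disjoint.
#' @return Object of class `domain_definition`.
#' @export
domain_definition <- function(pdz1_range = c(2, 107),
                              pdz2_range = c(108, 208)) {
  stopifnot(length(pdz1_range) == 2, length(pdz2_range) == 2,
            pdz1_range[1] <= pdz1_range[2], pdz2_range[1] <= pdz2_range[2])
  if (max(pdz1_range[1], pdz2_range[1]) <= min(pdz1_range[2], pdz2_range[2]))
    stop("domain ranges must be disjoint")
  structure(list(pdz1_range = pdz1_range, pdz2_range = pdz2_range),
            class = "domain_definition")
}

#' Pair the CA atoms common to two models, per domain
#'
#' Restricts each domain to the residue numbers present in both models
#' (crystal structures routinely have unresolved residues) and returns
#' paired coordinate matrices.
#'
#' @param a,b `structure_model` objects.
#' @param dom a [domain_definition].
#' @return list of two elements `pdz1`, `pdz2`, each with matrices `a`,
#'   `b` (n x 3) and `resno`.
#' @export
match_common_ca <- function(a, b, dom = domain_definition()) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"),
            inherits(dom, "domain_definition"))
  one <- function(rng) {
    ra <- a$atoms[a$atoms$resno >= rng[1] & a$atoms$resno <= rng[2], ]
    rb <- b$atoms[b$atoms$resno >= rng[1] & b$atoms$resno <= rng[2], ]
    common <- intersect(ra$resno, rb$resno)
    if (length(common) < 3L)
      stop(sprintf("fewer than 3 common residues in range %d-%d",
                   rng[1], rng[2]))
    common <- sort(common)
    ia <- match(common, ra$resno); ib <- match(common, rb$resno)
    list(a = as.matrix(ra[ia, c("x", "y", "z")]),
         b = as.matrix(rb[ib, c("x", "y", "z")]),
         resno = common)
  }
  list(pdz1 = one(dom$pdz1_range), pdz2 = one(dom$pdz2_range))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `||mobile %*% t(R) + t - reference||` and reports the post-transform
#' rmsd. The SVD determinant correction guarantees `det(R) = +1`.
#'
#' @param mobile,reference N x 3 coordinate matrices (N >= 3,
#'   non-degenerate).
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   and `transform(xyz)`, a function applying the fit to new coordinates.
#' @export
superpose <- function(mobile, reference) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            identical(dim(mobile), dim(reference)), ncol(mobile) == 3,
            nrow(mobile) >= 3)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  H <- t(X) %*% Y
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set: superposition not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.vector(cr - R %*% cm)
  transform <- function(xyz) sweep(xyz %*% t(R), 2, tr, `+`)
  moved <- transform(mobile)
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((moved - reference)^2))),
       transform = transform)
}

rotation_angle_axis <- function(R) {
  ang <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  nv <- sqrt(sum(v^2))
  axis <- if (nv > 1e-12) v / nv else {
    e <- eigen(R)                       # 180-degree case: eigenvector at +1
    ax <- Re(e$vectors[, which.min(abs(Re(e$values) - 1))])
    ax / sqrt(sum(ax^2))
  }
  list(angle_deg = ang, axis = axis)
}

#' Hinge metrics between two conformations of a two-domain model
#'
#' Step 1: superpose the second model onto the first on the domain-1 CA
#' pairs. Step 2: report the domain-2 CA rmsd in that frame, without a
#' second fit. Step 3: report the effective hinge rotation as the angle
#' of the best-fit rigid rotation mapping domain 2 of `a` onto domain 2
#' of `b` in the domain-1 frame, `theta = acos((trace(R) - 1) / 2)`, with
#' the rotation axis from the rotation's fixed eigenvector.
#'
#' @param a,b `structure_model` objects (e.g. open and closed states).
#' @param dom a [domain_definition].
#' @return Object of class `hinge_result`: `rmsd_pdz2_A`, `rotation_deg`,
#'   `rotation_axis` (unit 3-vector), `n_matched_atoms` (per domain),
#'   `pdz1_fit_rmsd_A`.
#' @export
hinge_metrics <- function(a, b, dom = domain_definition()) {
  m <- match_common_ca(a, b, dom)
  fit1 <- superpose(m$pdz1$b, m$pdz1$a)     # bring b into a's PDZ1 frame
  b2 <- fit1$transform(m$pdz2$b)
  rmsd2 <- sqrt(mean(rowSums((b2 - m$pdz2$a)^2)))
  fit2 <- superpose(m$pdz2$a, b2)           # rigid rotation of domain 2
  ra <- rotation_angle_axis(fit2$rotation)
  structure(list(rmsd_pdz2_A = rmsd2, rotation_deg = ra$angle_deg,
                 rotation_axis = ra$axis,
                 n_matched_atoms = c(pdz1 = nrow(m$pdz1$a),
                                     pdz2 = nrow(m$pdz2$a)),
                 pdz1_fit_rmsd_A = fit1$rmsd),
            class = "hinge_result")
}

#' @export
print.hinge_result <- function(x, ...) {
  cat(sprintf(paste0("hinge: rotation = %.2f deg, domain-2 rmsd = %.2f A ",
                     "(domain-1 fit rmsd %.2f A, %d + %d CA pairs)\n"),
              x$rotation_deg, x$rmsd_pdz2_A, x$pdz1_fit_rmsd_A,
              x$n_matched_atoms[1], x$n_matched_atoms[2]))
  invisible(x)
}

#' Anisotropic-network-model normal modes of a CA trace
#'
#' Builds the 3N x 3N anisotropic network Hessian with unit springs
#' between CA pairs within `cutoff_A`, removes the six (or, for
#' degenerate geometries, fewer) near-zero rigid-body modes by an
#' eigenvalue gap, and returns the `n_modes` lowest-frequency internal
#' modes, orthonormal, with their eigenvalues (squared frequencies in
#' arbitrary units).
#'
#' @param coords N x 3 CA coordinates (N >= 4).
#' @param cutoff_A contact cutoff in Angstrom (default 10).
#' @param n_modes number of internal modes to return (default 3).
#' @return list with `modes` (3N x n_modes), `frequency_sq`
#'   (length n_modes), `n_zero_modes`.
#' @export
enm_modes <- function(coords, cutoff_A = 10, n_modes = 3L) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, cutoff_A > 0)
  N <- nrow(coords)
  if (N < 2L) stop("need at least 2 atoms")
  D <- as.matrix(stats::dist(coords))
  adj <- D > 0 & D <= cutoff_A
  # connectivity check by label propagation over the contact graph
  comp <- seq_len(N)
  repeat {
    nxt <- vapply(seq_len(N), function(i) min(comp[c(i, which(adj[i, ]))]),
                  numeric(1))
    if (identical(nxt, comp)) break
    comp <- nxt
  }
  if (length(unique(comp)) > 1L)
    stop("contact graph disconnected at cutoff ", cutoff_A,
         " A; increase the cutoff")
  H <- matrix(0, 3 * N, 3 * N)
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    if (!adj[i, j]) next
    dv <- coords[j, ] - coords[i, ]
    blk <- (dv %o% dv) / sum(dv^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  e <- eigen(H, symmetric = TRUE)
  ev <- rev(e$values); vec <- e$vectors[, rev(seq_len(3 * N))]
  tol <- max(ev) * 1e-9
  n_zero <- sum(ev < tol)
  if (n_zero + n_modes > 3 * N)
    stop("not enough internal modes: asked for ", n_modes)
  sel <- n_zero + seq_len(n_modes)
  list(modes = vec[, sel, drop = FALSE], frequency_sq = ev[sel],
       n_zero_modes = n_zero)
}

#' Overlap of normal modes with a conformational displacement
#'
#' For each mode `m_k`, `overlap_k = |<m_k, dr>| / (||m_k|| * ||dr||)`
#' where `dr` is the flattened displacement between the two matched
#' conformations after domain-1 superposition.
#'
#' @param modes 3N x K mode matrix (e.g. from [enm_modes()]).
#' @param displacement N x 3 displacement matrix (closed minus open).
#' @return data.frame with `mode_rank` and `overlap` in `[0, 1]`.
#' @export
mode_overlap <- function(modes, displacement) {
  stopifnot(is.matrix(modes), is.matrix(displacement),
            ncol(displacement) == 3)
  dr <- as.vector(t(displacement))     # (x1,y1,z1,x2,...) matches Hessian
  if (length(dr) != nrow(modes)) stop("dimension mismatch")
  ndr <- sqrt(sum(dr^2))
  if (ndr == 0) stop("zero displacement")
  ov <- vapply(seq_len(ncol(modes)), function(k) {
    m <- modes[, k]
    abs(sum(m * dr)) / (sqrt(sum(m^2)) * ndr)
  }, numeric(1))
  data.frame(mode_rank = seq_len(ncol(modes)), overlap = ov)
}
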