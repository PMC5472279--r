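# Independent brute-force oracles used to validate the package's image
# primitives and superposition code. Deliberately naive implementations:
# correctness over speed, and no shared code with R/.

naive_median_filter <- function(m, k) {
  h <- (k - 1) / 2
  out <- m
  for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m))) {
    rs <- pmin(pmax(r + (-h:h), 1), nrow(m))
    cs <- pmin(pmax(cc + (-h:h), 1), ncol(m))
    out[r, cc] <- median(m[rs, cs][])
  }
  out
}

brute_otsu <- function(x, n_bins = 256) {
  x <- as.vector(x)
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- pmin(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  best <- -Inf; best_t <- NA
  for (t in 1:(n_bins - 1)) {
    g0 <- bin <= t; g1 <- !g0
    w0 <- mean(g0); w1 <- mean(g1)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(mids[bin[g0]]) / sum(g0)
    mu1 <- sum(mids[bin[g1]]) / sum(g1)
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; best_t <- breaks[t + 1] }
  }
  best_t
}

# queue-based border flood fill of the background (4-connected)
flood_fill_holes <- function(mask) {
  n <- nrow(mask); p <- ncol(mask)
  reach <- matrix(FALSE, n, p)
  q <- which((row(mask) == 1 | row(mask) == n |
              col(mask) == 1 | col(mask) == p) & !mask)
  reach[q] <- TRUE
  while (length(q)) {
    i <- q[1]; q <- q[-1]
    r <- (i - 1) %% n + 1; cc <- (i - 1) %/% n + 1
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      rr <- r + d[1]; c2 <- cc + d[2]
      if (rr < 1 || rr > n || c2 < 1 || c2 > p) next
      j <- (c2 - 1) * n + rr
      if (!mask[j] && !reach[j]) { reach[j] <- TRUE; q <- c(q, j) }
    }
  }
  mask | (!mask & !reach)
}

# BFS connected-component labeling
brute_label <- function(mask, connectivity = 8) {
  n <- nrow(mask); p <- ncol(mask)
  lab <- matrix(0L, n, p)
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    q <- start; lab[start] <- nxt
    while (length(q)) {
      i <- q[1]; q <- q[-1]
      r <- (i - 1) %% n + 1; cc <- (i - 1) %/% n + 1
      for (d in offs) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr < 1 || rr > n || c2 < 1 || c2 > p) next
        j <- (c2 - 1) * n + rr
        if (mask[j] && lab[j] == 0L) { lab[j] <- nxt; q <- c(q, j) }
      }
    }
  }
  lab
}

# Horn quaternion-method rigid superposition rmsd (independent of Kabsch)
quaternion_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  S <- t(X) %*% Y
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lam) / nrow(X)
  sqrt(max(msd, 0))
}

# numeric Hessian of the elastic-network potential at equilibrium
numeric_enm_hessian <- function(coords, cutoff) {
  N <- nrow(coords)
  D0 <- as.matrix(dist(coords))
  contacts <- which(upper.tri(D0) & D0 > 0 & D0 <= cutoff, arr.ind = TRUE)
  energy <- function(v) {
    xyz <- matrix(v, N, 3, byrow = TRUE)
    d <- sqrt(rowSums((xyz[contacts[, 1], , drop = FALSE] -
                       xyz[contacts[, 2], , drop = FALSE])^2))
    0.5 * sum((d - D0[contacts])^2)
  }
  v0 <- as.vector(t(coords))
  h <- 1e-4
  n <- length(v0)
  H <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) {
    ei <- ej <- rep(0, n); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (energy(v0 + ei + ej) - energy(v0 + ei - ej) -
       energy(v0 - ei + ej) + energy(v0 - ei - ej)) / (4 * h^2)
  }
  H
}

# minimal PDB writer for fixtures (CA records, optional altloc/occupancy)
write_pdb_fixture <- function(path, resno, xyz, chain = "A",
                              alt = rep(" ", length(resno)),
                              occ = rep(1, length(resno)),
                              extra_lines = character()) {
  lines <- vapply(seq_along(resno), function(i) {
    sprintf("ATOM  %5d  CA %s%s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, alt[i], "ALA", chain, resno[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3], occ[i], 30)
  }, character(1))
  writeLines(c(lines, extra_lines, "END"), path)
}
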