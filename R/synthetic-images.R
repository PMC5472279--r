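# Seeded generators for ground-truthed synthetic micrographs. Shapes are
# kept analytically simple (elliptical nuclei, quasi-circular Golgi
# fragments built from exact pixel sets) so every recorded area equals a
# brute-force pixel count times pixel_size^2.

local_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
  invisible(NULL)
}

# exact-count quasi-circular pixel set: the n_px pixels nearest to center
disc_mask_exact <- function(shape, center, n_px) {
  r_max <- ceiling(sqrt(n_px / pi)) + 3L
  rs <- max(1L, floor(center[1] - r_max)):min(shape[1], ceiling(center[1] + r_max))
  cs <- max(1L, floor(center[2] - r_max)):min(shape[2], ceiling(center[2] + r_max))
  g <- expand.grid(r = rs, c = cs)
  d2 <- (g$r - center[1])^2 + (g$c - center[2])^2
  if (nrow(g) < n_px) stop("disc does not fit inside the image")
  ord <- order(d2, g$r, g$c)[seq_len(n_px)]
  m <- matrix(FALSE, shape[1], shape[2])
  m[cbind(g$r[ord], g$c[ord])] <- TRUE
  m
}

# soft radial profile confined to the mask: edge pixels sit just above
# half-maximum, interior rises to `amplitude`, background stays exactly 0
soft_intensity <- function(mask, amplitude) {
  depth <- matrix(0L, nrow(mask), ncol(mask))
  cur <- mask
  lev <- 0L
  while (any(cur)) {
    lev <- lev + 1L
    depth[cur] <- lev
    er <- cur &
      shift_mat(cur,  1L, 0L, FALSE) & shift_mat(cur, -1L, 0L, FALSE) &
      shift_mat(cur, 0L,  1L, FALSE) & shift_mat(cur, 0L, -1L, FALSE)
    if (identical(er, cur)) { depth[cur] <- lev + 1L; break }
    cur <- er
  }
  dmax <- max(depth)
  out <- matrix(0, nrow(mask), ncol(mask))
  if (dmax > 0)
    out[mask] <- amplitude * (0.55 + 0.45 * (depth[mask] - 1) / max(dmax - 1, 1))
  out
}

# ring of k slightly overlapping discs; Voronoi partition keeps the
# per-fragment ground-truth masks pairwise disjoint while the union
# encloses a central hole (the substrate of the density statistic)
ring_fragment_masks <- function(shape, center, k, frag_px) {
  if (k == 1L)
    return(list(disc_mask_exact(shape, center, frag_px)))
  r_frag <- sqrt(frag_px / pi)
  ring_r <- 0.95 * r_frag / sin(pi / k)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  centers <- cbind(center[1] + ring_r * cos(ang), center[2] + ring_r * sin(ang))
  rs <- max(1L, floor(center[1] - ring_r - r_frag - 2)):
        min(shape[1], ceiling(center[1] + ring_r + r_frag + 2))
  cs <- max(1L, floor(center[2] - ring_r - r_frag - 2)):
        min(shape[2], ceiling(center[2] + ring_r + r_frag + 2))
  g <- expand.grid(r = rs, c = cs)
  d2 <- vapply(seq_len(k), function(i)
    (g$r - centers[i, 1])^2 + (g$c - centers[i, 2])^2, numeric(nrow(g)))
  inside <- matrixStats_rowMins(d2) <= r_frag^2
  nearest <- max.col(-d2, ties.method = "first")
  lapply(seq_len(k), function(i) {
    m <- matrix(FALSE, shape[1], shape[2])
    sel <- inside & nearest == i
    m[cbind(g$r[sel], g$c[sel])] <- TRUE
    m
  })
}

matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

ellipse_mask <- function(shape, center, a_px, b_px) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / a_px)^2 + ((cc - center[2]) / b_px)^2 <= 1
}

#' Generate a synthetic two-channel cell image with ground truth
#'
#' Emulates cultured-cell micrographs: a DAPI channel with elliptical
#' nuclei and a Golgi channel with, per cell, `fragments_per_cell`
#' quasi-circular fragments clustered next to the nucleus. A single
#' fragment is a solid disc; multiple fragments form a slightly
#' overlapping ring that encloses a central gap, so that planted
#' fragmentation lowers the downstream density statistic. Intensities
#' span the 16-bit range; additive Gaussian noise is clipped at zero.
#'
#' @param n_cells number of cells.
#' @param fragments_per_cell fragments per cell (1 = solid Golgi).
#' @param fragment_area_um2 area of each fragment in um^2.
#' @param pixel_size_um micrometres per pixel.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param seed integer seed; identical arguments give identical output.
#' @param shape optional c(rows, cols); when omitted the image is sized to
#'   hold all cells on a grid. With an explicit too-small shape, placement
#'   fails with an error after bounded retries.
#' @return list with `image` (a [calibrated_image] with channels `dapi`
#'   and `golgi`) and `truth` (nucleus mask, per-fragment masks and areas,
#'   fragment-to-cell map, pixel size, seed).
#' @export
gen_cell_image <- function(n_cells, fragments_per_cell = 1L,
                           fragment_area_um2 = 8, pixel_size_um = 0.1,
                           noise_sd = 0, seed, shape = NULL) {
  stopifnot(n_cells >= 1, fragments_per_cell >= 1, fragment_area_um2 > 0,
            pixel_size_um > 0, noise_sd >= 0)
  local_seed(seed)
  k <- as.integer(fragments_per_cell)
  frag_px <- round(fragment_area_um2 / pixel_size_um^2)
  if (frag_px < 1) stop("fragment area below one pixel at this pixel size")
  r_frag <- sqrt(frag_px / pi)
  ring_r <- if (k == 1L) 0 else 0.95 * r_frag / sin(pi / k)
  a_px <- 4 / pixel_size_um; b_px <- 3 / pixel_size_um   # 8 x 6 um nucleus
  golgi_ext <- ring_r + r_frag + 2
  slot <- ceiling(2 * (max(a_px, b_px) + 2 * golgi_ext + 6))
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  auto_shape <- c(nrow_grid, ncol_grid) * slot
  sh <- if (is.null(shape)) auto_shape else as.integer(shape)

  dapi <- matrix(0, sh[1], sh[2]); golgi <- matrix(0, sh[1], sh[2])
  nucleus_mask <- matrix(FALSE, sh[1], sh[2])
  frag_masks <- list(); frag_cell <- integer(); frag_area <- numeric()
  placed <- NULL   # occupied bounding circles: (r, c, radius)
  cell_ext <- max(a_px, b_px) + 2 * golgi_ext + 4

  for (cell in seq_len(n_cells)) {
    ok <- FALSE
    for (try in 1:100) {
      if (is.null(shape)) {
        gi <- (cell - 1L) %/% ncol_grid; gj <- (cell - 1L) %% ncol_grid
        ctr <- c(gi * slot + slot / 2, gj * slot + slot / 2) +
          stats::runif(2, -2, 2)
      } else {
        if (sh[1] < 2 * cell_ext || sh[2] < 2 * cell_ext)
          stop("image too small to place cells at the requested sizes")
        ctr <- c(stats::runif(1, cell_ext, sh[1] - cell_ext),
                 stats::runif(1, cell_ext, sh[2] - cell_ext))
      }
      clash <- !is.null(placed) &&
        any(sqrt((placed[, 1] - ctr[1])^2 + (placed[, 2] - ctr[2])^2) <
              placed[, 3] + cell_ext)
      inside <- all(ctr - cell_ext >= 1) && ctr[1] + cell_ext <= sh[1] &&
        ctr[2] + cell_ext <= sh[2]
      if (!clash && inside) { ok <- TRUE; break }
    }
    if (!ok) stop(sprintf("failed to place cell %d after bounded retries", cell))
    placed <- rbind(placed, c(ctr, cell_ext))

    nmask <- ellipse_mask(sh, ctr, a_px, b_px)
    nucleus_mask <- nucleus_mask | nmask
    dapi <- dapi + soft_intensity(nmask, 30000)

    theta <- stats::runif(1, 0, 2 * pi)
    gctr <- ctr + (max(a_px, b_px) + golgi_ext + 2) * c(cos(theta), sin(theta))
    fm <- ring_fragment_masks(sh, gctr, k, frag_px)
    for (i in seq_along(fm)) {
      frag_masks[[length(frag_masks) + 1L]] <- fm[[i]]
      frag_cell <- c(frag_cell, cell)
      frag_area <- c(frag_area, sum(fm[[i]]) * pixel_size_um^2)
    }
    golgi_union <- Reduce(`|`, fm)
    golgi <- golgi + soft_intensity(golgi_union, 40000)
  }

  if (noise_sd > 0) {
    dapi <- pmax(dapi + matrix(stats::rnorm(length(dapi), 0, noise_sd), sh[1]), 0)
    golgi <- pmax(golgi + matrix(stats::rnorm(length(golgi), 0, noise_sd), sh[1]), 0)
  }
  img <- calibrated_image(list(dapi = dapi, golgi = golgi), pixel_size_um)
  truth <- structure(list(nucleus_mask = nucleus_mask,
                          golgi_fragment_masks = frag_masks,
                          per_fragment_area_um2 = frag_area,
                          fragment_cell = frag_cell,
                          pixel_size_um = pixel_size_um, seed = seed),
                     class = "image_ground_truth")
  list(image = img, truth = truth)
}

#' Generate a synthetic tissue-section image with planted region areas
#'
#' Emulates Golgi-marker-stained seminiferous tubule sections: each
#' tubule is an annular band containing quasi-circular marker-positive
#' regions of the requested areas (realised to the nearest pixel). Region
#' tubule membership is recorded in the ground truth.
#'
#' @param n_tubules number of tubules.
#' @param areas_um2_per_tubule list of numeric vectors, one per tubule,
#'   giving the planted region areas in um^2.
#' @param pixel_size_um micrometres per pixel.
#' @param seed integer seed.
#' @return list with `image` (channels `golgi`, `dapi`) and `truth`
#'   (region masks, areas, region tubule ids, tubule annulus label matrix,
#'   pixel size, seed).
#' @export
gen_tissue_image <- function(n_tubules, areas_um2_per_tubule,
                             pixel_size_um = 0.1, seed) {
  stopifnot(n_tubules >= 1, length(areas_um2_per_tubule) == n_tubules)
  areas <- lapply(areas_um2_per_tubule, as.numeric)
  if (any(unlist(areas) <= 0)) stop("planted areas must be positive")
  if (any(unlist(areas) < pixel_size_um^2))
    stop("requested area below one pixel at this pixel size")
  local_seed(seed)
  r_px <- lapply(areas, function(a) sqrt(round(a / pixel_size_um^2) / pi))
  r_max <- max(unlist(r_px))
  # tubule diameter grows with the largest requested region but is capped
  # at 100 um (annuli larger than a real tubule are not simulated)
  S <- as.integer(min(round(100 / pixel_size_um),
                      max(80, ceiling((r_max + 3) / 0.115))))
  ncol_grid <- ceiling(sqrt(n_tubules))
  nrow_grid <- ceiling(n_tubules / ncol_grid)
  sh <- c(nrow_grid, ncol_grid) * S

  golgi <- matrix(0, sh[1], sh[2]); dapi <- matrix(0, sh[1], sh[2])
  tubule_labels <- matrix(0L, sh[1], sh[2])
  region_masks <- list(); region_area <- numeric(); region_tub <- integer()

  for (tb in seq_len(n_tubules)) {
    gi <- (tb - 1L) %/% ncol_grid; gj <- (tb - 1L) %% ncol_grid
    ctr <- c(gi * S + S / 2, gj * S + S / 2)
    r_out <- 0.45 * S; r_in <- 0.22 * S
    rr <- matrix(seq_len(sh[1]), sh[1], sh[2])
    cc <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
    d <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
    annulus <- d <= r_out & d >= r_in
    tubule_labels[annulus] <- tb
    dapi <- dapi + annulus * 12000

    placed <- NULL
    for (i in seq_along(areas[[tb]])) {
      n_px <- round(areas[[tb]][i] / pixel_size_um^2)
      ri <- sqrt(n_px / pi)
      if (ri + 2 > (r_out - r_in) / 2)
        stop(sprintf("region of %.3g um^2 too large for tubule band", areas[[tb]][i]))
      ok <- FALSE
      for (try in 1:200) {
        rad <- stats::runif(1, r_in + ri + 1, r_out - ri - 1)
        ang <- stats::runif(1, 0, 2 * pi)
        p <- ctr + rad * c(cos(ang), sin(ang))
        if (!is.null(placed) &&
            any(sqrt((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2) <
                  placed[, 3] + ri + 2)) next
        ok <- TRUE; break
      }
      if (!ok) stop("failed to place region after bounded retries")
      placed <- rbind(placed, c(p, ri))
      m <- disc_mask_exact(sh, p, n_px)
      region_masks[[length(region_masks) + 1L]] <- m
      region_area <- c(region_area, sum(m) * pixel_size_um^2)
      region_tub <- c(region_tub, tb)
      golgi <- golgi + soft_intensity(m, 45000)
    }
  }
  img <- calibrated_image(list(golgi = golgi, dapi = dapi), pixel_size_um)
  truth <- structure(list(region_masks = region_masks,
                          region_area_um2 = region_area,
                          region_tubule = region_tub,
                          tubule_labels = tubule_labels,
                          pixel_size_um = pixel_size_um, seed = seed),
                     class = "image_ground_truth")
  list(image = img, truth = truth)
}
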