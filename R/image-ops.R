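# Low-level image operations shared by the Golgi pipelines. These are
# deliberately implemented here rather than borrowed: the pipelines pin
# down specific semantics (replicated-edge median, strict thresholds,
# 8-connected foreground / 4-connected hole detection) that the tests
# verify against brute-force oracles.

shift_mat <- function(m, dr, dc, fill = 0L) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Median smoothing with replicated edges
#'
#' Sliding-window median filter; pixels outside the image are replaced by
#' the nearest edge pixel (replication padding), so a constant image is
#' returned unchanged and single hot pixels in a flat field are removed.
#'
#' @param channel numeric matrix.
#' @param kernel_px odd positive integer window side length (default 3).
#' @return Matrix of the same dimensions.
#' @export
median_smooth <- function(channel, kernel_px = 3L) {
  stopifnot(is.matrix(channel), is.numeric(channel))
  if (length(kernel_px) != 1L || kernel_px < 1 || kernel_px %% 2 != 1)
    stop("'kernel_px' must be an odd positive integer")
  if (kernel_px == 1L) return(channel)
  n <- nrow(channel); p <- ncol(channel)
  h <- (kernel_px - 1L) / 2L
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  m <- nrow(offs)
  stack <- matrix(0, n * p, m)
  ri <- rep.int(seq_len(n), p)
  ci <- rep(seq_len(p), each = n)
  for (k in seq_len(m)) {
    rr <- pmin(pmax(ri + offs$dr[k], 1L), n)
    cc <- pmin(pmax(ci + offs$dc[k], 1L), p)
    stack[, k] <- channel[cbind(rr, cc)]
  }
  # vectorised bubble sort over the m window columns; median = middle col
  for (i in seq_len(m - 1L)) for (j in seq_len(m - i)) {
    lo <- pmin(stack[, j], stack[, j + 1L])
    hi <- pmax(stack[, j], stack[, j + 1L])
    stack[, j] <- lo; stack[, j + 1L] <- hi
  }
  matrix(stack[, (m + 1L) / 2L], n, p)
}

#' Otsu automatic threshold
#'
#' Exhaustively maximises the between-class variance over the 256-bin
#' intensity histogram and returns the cut value; `binarize_golgi()`
#' applies it with a strict comparison (`intensity > threshold`).
#'
#' @param channel numeric matrix; must not be constant.
#' @param n_bins number of histogram bins (default 256).
#' @return Scalar threshold on the intensity scale of `channel`.
#' @export
otsu_threshold <- function(channel, n_bins = 256L) {
  x <- as.vector(channel)
  if (!all(is.finite(x))) stop("non-finite intensities")
  lo <- min(x); hi <- max(x)
  if (lo == hi) stop("constant channel: automatic threshold undefined")
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w <- counts / length(x)
  cw <- cumsum(w)                    # class-0 weight for cut after bin t
  cmu <- cumsum(w * mids)
  mu_t <- cmu[n_bins]
  t <- seq_len(n_bins - 1L)
  denom <- cw[t] * (1 - cw[t])
  sigma_b <- ifelse(denom > 0, (mu_t * cw[t] - cmu[t])^2 / denom, -Inf)
  breaks[which.max(sigma_b) + 1L]    # upper edge of the best cut bin
}

#' Binarize the Golgi channel by automatic (Otsu) threshold
#'
#' @param channel numeric matrix; must not be constant.
#' @return Logical mask, TRUE where intensity strictly exceeds the Otsu
#'   threshold.
#' @export
binarize_golgi <- function(channel) {
  channel > otsu_threshold(channel)
}

#' Binarize the nucleus channel at the minimum intensity
#'
#' The nucleus mask keeps every pixel strictly above the channel minimum,
#' capturing the full above-floor nucleus signal.
#'
#' @param channel numeric matrix; must not be constant.
#' @return Logical mask.
#' @export
binarize_nucleus <- function(channel) {
  lo <- min(channel)
  if (lo == max(channel)) stop("constant channel: threshold undefined")
  channel > lo
}

#' Fill interior holes of a binary mask
#'
#' Background components not 4-connected to the image border are set TRUE;
#' foreground pixels are never modified. Implemented as an iterative
#' border flood of the background.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same dimensions.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  bg <- !mask
  n <- nrow(mask); p <- ncol(mask)
  reach <- matrix(FALSE, n, p)
  reach[1, ] <- bg[1, ]; reach[n, ] <- bg[n, ]
  reach[, 1] <- bg[, 1]; reach[, p] <- bg[, p]
  # alternating raster sweeps: each pass pushes reachability across full
  # straight runs of background, so convergence takes a handful of passes
  repeat {
    old <- reach
    if (p > 1) {
      for (j in 2:p) reach[, j] <- reach[, j] | (reach[, j - 1] & bg[, j])
      for (j in (p - 1):1) reach[, j] <- reach[, j] | (reach[, j + 1] & bg[, j])
    }
    if (n > 1) {
      for (i in 2:n) reach[i, ] <- reach[i, ] | (reach[i - 1, ] & bg[i, ])
      for (i in (n - 1):1) reach[i, ] <- reach[i, ] | (reach[i + 1, ] & bg[i, ])
    }
    if (identical(reach, old)) break
  }
  mask | (bg & !reach)
}

#' Label connected foreground components
#'
#' 8-connected labeling (the complementary pair to the 4-connected hole
#' detection of [fill_holes()]). Labels are consecutive integers starting
#' at 1 in raster-scan order of the component minima; background is 0.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4L, 8L))
  n <- nrow(mask); p <- ncol(mask)
  lab <- matrix(0L, n, p)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  lab[idx] <- idx
  offs <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  big <- n * p + 1L
  repeat {
    prev <- lab[idx]
    cur <- lab
    cur[!mask] <- big
    for (o in offs) {
      nb <- shift_mat(cur, o[1], o[2], big)
      lab <- pmin(lab, nb) * (lab > 0L) + lab * (lab == 0L)
      mode(lab) <- "integer"
    }
    # path compression: labels are linear pixel indices, so chase them
    for (k in 1:3) lab[idx] <- lab[lab[idx]]
    if (identical(lab[idx], prev)) break
  }
  u <- sort(unique(lab[idx]))
  lab[idx] <- match(lab[idx], u)
  lab
}

#' Per-component pixel counts, areas and centroids
#'
#' @param labels integer label matrix from [label_components()].
#' @param pixel_size_um micrometres per pixel.
#' @return data.frame with columns `label`, `n_px`, `area_um2`,
#'   `centroid_row`, `centroid_col`.
#' @export
component_stats <- function(labels, pixel_size_um = 1) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(), n_px = integer(),
                      area_um2 = numeric(), centroid_row = numeric(),
                      centroid_col = numeric()))
  lab <- labels[idx]
  ri <- ((idx - 1L) %% nrow(labels)) + 1L
  ci <- ((idx - 1L) %/% nrow(labels)) + 1L
  n_px <- tabulate(lab)
  keep <- which(n_px > 0L)
  data.frame(label = keep,
             n_px = n_px[keep],
             area_um2 = n_px[keep] * pixel_size_um^2,
             centroid_row = as.vector(tapply(ri, lab, mean)),
             centroid_col = as.vector(tapply(ci, lab, mean)))
}
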