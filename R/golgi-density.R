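# Per-cell Golgi density pipeline for cultured-cell micrographs:
# split channels -> median smooth -> binarize (Otsu for Golgi, channel
# minimum for nucleus) -> fill holes -> per-Golgi density = stacks area /
# hole-filled total area, with the hole-filled Golgi area additionally
# reported relative to the nucleus area of the owning cell.

#' Assign Golgi components to cells by nearest nucleus
#'
#' Nuclei are labeled as 8-connected components; each (hole-filled) Golgi
#' component is assigned to the nucleus with the nearest centroid.
#'
#' @param golgi_mask logical mask of (hole-filled) Golgi pixels.
#' @param nucleus_mask logical mask of nucleus pixels; must contain at
#'   least one component.
#' @return list with `nucleus_labels`, `golgi_labels` (integer matrices)
#'   and `assignment` (data.frame: `golgi_label`, `nucleus_label`,
#'   `distance_px`).
#' @export
assign_golgi_to_cells <- function(golgi_mask, nucleus_mask) {
  nuc_lab <- label_components(nucleus_mask)
  if (max(nuc_lab) == 0L) stop("no nucleus component found")
  gol_lab <- label_components(golgi_mask)
  nst <- component_stats(nuc_lab)
  gst <- component_stats(gol_lab)
  if (nrow(gst) == 0L)
    return(list(nucleus_labels = nuc_lab, golgi_labels = gol_lab,
                assignment = data.frame(golgi_label = integer(),
                                        nucleus_label = integer(),
                                        distance_px = numeric())))
  d2 <- outer(gst$centroid_row, nst$centroid_row, `-`)^2 +
        outer(gst$centroid_col, nst$centroid_col, `-`)^2
  j <- max.col(-d2, ties.method = "first")
  list(nucleus_labels = nuc_lab, golgi_labels = gol_lab,
       assignment = data.frame(golgi_label = gst$label,
                               nucleus_label = nst$label[j],
                               distance_px = sqrt(d2[cbind(seq_len(nrow(gst)), j)])))
}

#' Golgi density of a single Golgi object
#'
#' Density is the ratio of the pre-fill (stacks) area to the hole-filled
#' total area; the pixel size cancels in the ratio. The hole-filled area
#' is also reported relative to the nucleus area of the owning cell as a
#' per-cell normalisation covariate.
#'
#' @param stack_mask logical mask of the binarized Golgi stacks.
#' @param filled_mask logical hole-filled mask; must contain `stack_mask`.
#' @param nucleus_area_um2 nucleus area of the owning cell (um^2).
#' @param pixel_size_um micrometres per pixel.
#' @return list with `golgi_stack_area_um2`, `golgi_total_area_um2`,
#'   `density`, `golgi_to_nucleus_ratio`, `valid`.
#' @export
compute_density <- function(stack_mask, filled_mask, nucleus_area_um2,
                            pixel_size_um) {
  if (any(stack_mask & !filled_mask))
    stop("filled mask must contain the stack mask")
  n_stack <- sum(stack_mask); n_fill <- sum(filled_mask)
  if (n_fill == 0L)
    return(list(golgi_stack_area_um2 = 0, golgi_total_area_um2 = 0,
                density = NA_real_, golgi_to_nucleus_ratio = NA_real_,
                valid = FALSE))
  list(golgi_stack_area_um2 = n_stack * pixel_size_um^2,
       golgi_total_area_um2 = n_fill * pixel_size_um^2,
       density = n_stack / n_fill,
       golgi_to_nucleus_ratio = n_fill * pixel_size_um^2 / nucleus_area_um2,
       valid = TRUE)
}

#' Per-cell Golgi density pipeline
#'
#' Runs the full workflow on a two-channel [calibrated_image] and returns
#' one record per Golgi object (a cell may carry several). Components
#' below `min_area_um2` are treated as specks and discarded before the
#' density computation.
#'
#' @param img a [calibrated_image].
#' @param nucleus_channel,golgi_channel channel names.
#' @param kernel_px odd median-filter kernel (default 3).
#' @param min_area_um2 Golgi speck-removal threshold (default 0.05 um^2).
#' @param min_nucleus_area_um2 nucleus components smaller than this are
#'   discarded (default 5 um^2). The minimum-intensity nucleus threshold
#'   assumes a flat dark background (background-subtracted micrographs);
#'   on noisy backgrounds, pre-subtract the background first.
#' @return data.frame with columns `cell_id`, `golgi_id`,
#'   `golgi_stack_area_um2`, `golgi_total_area_um2`, `nucleus_area_um2`,
#'   `density`, `golgi_to_nucleus_ratio`, `valid`.
#' @export
golgi_density <- function(img, nucleus_channel = "dapi",
                          golgi_channel = "golgi", kernel_px = 3L,
                          min_area_um2 = 0.05, min_nucleus_area_um2 = 5) {
  ch <- split_channels(img, c(nucleus_channel, golgi_channel))
  px <- img$pixel_size_um
  nuc <- median_smooth(ch[[nucleus_channel]], kernel_px)
  gol <- median_smooth(ch[[golgi_channel]], kernel_px)
  nuc_mask <- fill_holes(binarize_nucleus(nuc))
  nlab0 <- label_components(nuc_mask)
  nst0 <- component_stats(nlab0, px)
  tiny <- nst0$label[nst0$area_um2 < min_nucleus_area_um2]
  if (length(tiny)) nuc_mask[nlab0 %in% tiny] <- FALSE
  stack_mask <- binarize_golgi(gol)

  # speck removal before densities
  slab <- label_components(stack_mask)
  sst <- component_stats(slab, px)
  small <- sst$label[sst$area_um2 < min_area_um2]
  if (length(small)) stack_mask[slab %in% small] <- FALSE

  filled_mask <- fill_holes(stack_mask)
  asg <- assign_golgi_to_cells(filled_mask, nuc_mask)
  nst <- component_stats(asg$nucleus_labels, px)
  gst <- component_stats(asg$golgi_labels, px)
  if (nrow(gst) == 0L)
    return(data.frame(cell_id = integer(), golgi_id = integer(),
                      golgi_stack_area_um2 = numeric(),
                      golgi_total_area_um2 = numeric(),
                      nucleus_area_um2 = numeric(), density = numeric(),
                      golgi_to_nucleus_ratio = numeric(), valid = logical()))
  recs <- lapply(seq_len(nrow(gst)), function(i) {
    gl <- gst$label[i]
    nl <- asg$assignment$nucleus_label[asg$assignment$golgi_label == gl]
    comp <- asg$golgi_labels == gl
    r <- compute_density(stack_mask & comp, comp,
                         nst$area_um2[nst$label == nl], px)
    data.frame(cell_id = nl, golgi_id = gl,
               golgi_stack_area_um2 = r$golgi_stack_area_um2,
               golgi_total_area_um2 = r$golgi_total_area_um2,
               nucleus_area_um2 = nst$area_um2[nst$label == nl],
               density = r$density,
               golgi_to_nucleus_ratio = r$golgi_to_nucleus_ratio,
               valid = r$valid)
  })
  do.call(rbind, recs)
}

#' Two-group comparison by unpaired pooled-variance t-test
#'
#' Classical two-sample Student t-test with pooled variance (equal
#' variances assumed), as used for per-Golgi density and per-tubule
#' percentage comparisons. Degenerate zero-variance inputs are resolved
#' by the limit of the statistic: equal means give `t = 0, p = 1`,
#' separated means give `t = +/-Inf, p = 0`.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  if (!all(is.finite(c(values_a, values_b)))) stop("non-finite values")
  df <- length(values_a) + length(values_b) - 2L
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    d <- mean(values_a) - mean(values_b)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0, df = df,
                mean_a = mean(values_a), mean_b = mean(values_b)))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(values_a), mean_b = mean(values_b))
}
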