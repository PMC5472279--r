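# Tissue-section Golgi-area pipeline: segment marker-positive regions,
# measure areas in um^2, classify against a 5 um^2 threshold, aggregate
# per seminiferous-tubule stage group, and render pseudo-colored maps.

STAGE_GROUPS <- c("II-III", "IV", "VI-VIII", "IX", "X-XII", "unknown")

#' Segment marker-positive regions and measure their areas
#'
#' Otsu binarization (shared with the density pipeline), 8-connected
#' labeling, areas as pixel counts times `pixel_size_um^2`; regions below
#' `min_area_um2` are dropped. An image that is empty after filtering
#' yields an empty table, not an error.
#'
#' @param channel numeric matrix (non-constant).
#' @param pixel_size_um micrometres per pixel.
#' @param min_area_um2 minimum retained region area (default 0.2 um^2).
#' @return list with `labels` (integer matrix; dropped regions zeroed)
#'   and `regions` (data.frame: `region_id`, `area_um2`, `centroid_row`,
#'   `centroid_col`).
#' @export
segment_regions <- function(channel, pixel_size_um, min_area_um2 = 0.2) {
  mask <- binarize_golgi(channel)
  labels <- label_components(mask)
  st <- component_stats(labels, pixel_size_um)
  drop <- st$label[st$area_um2 < min_area_um2]
  if (length(drop)) labels[labels %in% drop] <- 0L
  st <- st[!(st$label %in% drop), , drop = FALSE]
  regions <- data.frame(region_id = st$label, area_um2 = st$area_um2,
                        centroid_row = st$centroid_row,
                        centroid_col = st$centroid_col)
  rownames(regions) <- NULL
  list(labels = labels, regions = regions)
}

#' Classify a Golgi area against the enlargement threshold
#'
#' Strict comparison: an area exactly equal to the threshold is *not*
#' enlarged ("greater than" semantics).
#'
#' @param area_um2 positive area(s) in um^2.
#' @param threshold_um2 threshold (default 5 um^2).
#' @return Logical vector.
#' @export
classify_area <- function(area_um2, threshold_um2 = 5) {
  stopifnot(all(area_um2 > 0), threshold_um2 > 0)
  area_um2 > threshold_um2
}

#' Attach tubule membership and stage annotation to segmented regions
#'
#' Tubule membership is the majority tubule label over the region's
#' pixels (0 maps to `unknown`); stage groups come from a user-supplied
#' annotation, as tubule staging is a manual morphological call.
#'
#' @param seg output of [segment_regions()].
#' @param tubule_labels integer matrix of tubule ids (0 = outside).
#' @param stage_by_tubule named character vector mapping tubule id to one
#'   of "II-III", "IV", "VI-VIII", "IX", "X-XII", "unknown".
#' @param threshold_um2 enlargement threshold (default 5 um^2).
#' @return data.frame of region records: `region_id`, `tubule_id`,
#'   `stage_group`, `area_um2`, `above_threshold`.
#' @export
golgi_area_records <- function(seg, tubule_labels,
                               stage_by_tubule = NULL, threshold_um2 = 5) {
  stopifnot(identical(dim(seg$labels), dim(tubule_labels)))
  regs <- seg$regions
  tub <- vapply(regs$region_id, function(id) {
    tl <- tubule_labels[seg$labels == id]
    tl <- tl[tl > 0L]
    if (length(tl) == 0L) 0L else as.integer(names(which.max(table(tl))))
  }, integer(1))
  stage <- rep("unknown", nrow(regs))
  if (!is.null(stage_by_tubule)) {
    hit <- match(as.character(tub), names(stage_by_tubule))
    stage[!is.na(hit)] <- stage_by_tubule[hit[!is.na(hit)]]
  }
  if (!all(stage %in% STAGE_GROUPS))
    stop("stage annotations must be one of: ",
         paste(STAGE_GROUPS, collapse = ", "))
  data.frame(region_id = regs$region_id, tubule_id = tub,
             stage_group = factor(stage, levels = STAGE_GROUPS),
             area_um2 = regs$area_um2,
             above_threshold = classify_area(regs$area_um2, threshold_um2))
}

#' Summarise enlarged-Golgi percentages by tubule stage
#'
#' Percent-above is computed per tubule first and then summarised across
#' tubules of each stage group (mean and standard error), because tubules
#' are the experimental unit; the pooled region-level percentage is also
#' reported. When records carry a 2-level `condition` column, each stage
#' is additionally compared between conditions by unpaired t-test on the
#' per-tubule percentages.
#'
#' @param records data.frame from [golgi_area_records()], optionally with
#'   a `condition` column.
#' @return list with `per_tubule` (tubule-level percentages), `by_stage`
#'   (stage summaries) and `tests` (per-stage comparisons or NULL).
#' @export
summarize_by_stage <- function(records) {
  stopifnot(all(c("tubule_id", "stage_group", "above_threshold") %in%
                  names(records)))
  has_cond <- "condition" %in% names(records) &&
    length(unique(records$condition)) == 2L
  key <- records[, c("tubule_id", "stage_group")]
  if (has_cond) key$condition <- records$condition
  agg <- stats::aggregate(records$above_threshold, by = key,
                          FUN = function(v) 100 * mean(v))
  names(agg)[ncol(agg)] <- "percent_above"
  cnt <- stats::aggregate(records$above_threshold, by = key, FUN = length)
  agg$n_regions <- cnt$x

  present <- droplevels(agg$stage_group)
  empty <- setdiff(setdiff(STAGE_GROUPS, "unknown"), levels(present))
  if (length(empty))
    warning("stage group(s) with no tubules omitted: ",
            paste(empty, collapse = ", "))
  by_stage <- do.call(rbind, lapply(levels(present), function(sg) {
    sub <- agg[agg$stage_group == sg, ]
    pooled <- records[records$stage_group == sg, ]
    data.frame(stage_group = sg, n_tubules = nrow(sub),
               n_regions = sum(sub$n_regions),
               percent_above_mean = mean(sub$percent_above),
               percent_above_sem = stats::sd(sub$percent_above) /
                 sqrt(nrow(sub)),
               percent_above_pooled = 100 * mean(pooled$above_threshold))
  }))
  tests <- NULL
  if (has_cond) {
    conds <- unique(agg$condition)
    tests <- do.call(rbind, lapply(levels(present), function(sg) {
      a <- agg$percent_above[agg$stage_group == sg & agg$condition == conds[1]]
      b <- agg$percent_above[agg$stage_group == sg & agg$condition == conds[2]]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      ct <- compare_groups(a, b)
      data.frame(stage_group = sg, mean_a = ct$mean_a, mean_b = ct$mean_b,
                 t = ct$t, p = ct$p)
    }))
  }
  list(per_tubule = agg, by_stage = by_stage, tests = tests)
}

#' Pseudo-color segmented regions by area
#'
#' Regions at or below the threshold are colored on a continuous
#' blue-to-yellow ramp by area; regions strictly above the threshold get
#' a distinct color class (red); background is black.
#'
#' @param labels integer label matrix from [segment_regions()].
#' @param areas data.frame with `region_id` and `area_um2` (the `regions`
#'   element of [segment_regions()]).
#' @param threshold_um2 enlargement threshold (default 5 um^2).
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
pseudocolor <- function(labels, areas, threshold_um2 = 5) {
  out <- array(0, dim = c(dim(labels), 3))
  if (nrow(areas) == 0L) return(out)
  ramp <- grDevices::colorRamp(c("#1030A0", "#20B0B0", "#F0E020"))
  for (i in seq_len(nrow(areas))) {
    id <- areas$region_id[i]; a <- areas$area_um2[i]
    col <- if (a > threshold_um2) c(1, 0, 0)
           else ramp(min(a / threshold_um2, 1))[1, ] / 255
    sel <- labels == id
    for (k in 1:3) out[, , k][sel] <- col[k]
  }
  out
}
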