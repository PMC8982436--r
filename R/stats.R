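#' Exclude low-expression cells
#'
#' Removes cells with fewer than `min_count` counted mRNAs — the filter
#' applied before genotype comparisons to drop cells dominated by leaky
#' transcription or false-positive detections. "Fewer than" is strict, so a
#' cell with exactly `min_count` survives.
#'
#' @param cells a cell table with `mrna_count`.
#' @param min_count minimum retained count (default 10).
#' @return The filtered cell table; the number of removed rows is logged.
#' @examples
#' df <- data.frame(label = 1:4, mrna_count = c(0, 9, 10, 11))
#' filter_low_expression(df)$mrna_count
#' @export
filter_low_expression <- function(cells, min_count = 10L) {
  stopifnot(min_count >= 0)
  keep <- cells$mrna_count >= min_count
  eq_log("filter_low_expression: removed %d of %d cells (< %d mRNAs)",
         sum(!keep), length(keep), min_count)
  if (!any(keep)) warning("all cells removed by the low-expression filter")
  cells[keep, , drop = FALSE]
}

#' Subgroup cells by transcription-site class
#'
#' Partitions a cell table into the three TS classes used to stratify count
#' distributions: cells with no TS, one TS, and two or more TSs.
#'
#' @param cells a cell table with `ts_count` (non-negative).
#' @return list `(ts0, ts1, ts2plus)` of sub-tables, with an attribute
#'   `sizes` giving the three class sizes.
#' @export
group_by_ts <- function(cells) {
  if (any(cells$ts_count < 0)) stop("negative ts_count")
  out <- list(ts0 = cells[cells$ts_count == 0L, , drop = FALSE],
              ts1 = cells[cells$ts_count == 1L, , drop = FALSE],
              ts2plus = cells[cells$ts_count >= 2L, , drop = FALSE])
  attr(out, "sizes") <- vapply(out, nrow, integer(1))
  out
}

#' Rank-based genotype comparison
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing a per-cell
#' statistic between genotypes: exact enumeration when both samples have at
#' most 8 untied observations, normal approximation with continuity and tie
#' correction otherwise. The effect summary reports both medians and the
#' Hodges-Lehmann shift estimate.
#'
#' @param values_wt,values_ko numeric samples (non-empty; `NA` dropped).
#' @param statistic label describing what is being compared (carried into
#'   the output, e.g. `"counts"` or `"fano"`).
#' @return list `(statistic, p.value, method, exact, median_wt, median_ko,
#'   hl_shift, n_wt, n_ko, what)`; `hl_shift` is the KO minus WT location
#'   shift.
#' @export
compare_genotypes <- function(values_wt, values_ko,
                              statistic = c("counts", "fano")) {
  what <- match.arg(statistic)
  x <- values_wt[!is.na(values_wt)]
  y <- values_ko[!is.na(values_ko)]
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(y, x, alternative = "two.sided", exact = exact,
                correct = TRUE, conf.int = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = wt$method, exact = exact,
       median_wt = median(x), median_ko = median(y),
       hl_shift = unname(wt$estimate), n_wt = length(x), n_ko = length(y),
       what = what)
}

#' Sample measurement ROIs across embryo regions
#'
#' Draws `n_per_region` non-overlapping square regions of interest,
#' uniformly at random, inside each of `regions` equal slices of the tissue
#' along its long axis (anterior / central / posterior for the default 3) —
#' 15 ROIs per embryo by default.
#'
#' @param tissue_mask logical matrix, `TRUE` = tissue.
#' @param n_per_region ROIs per region (default 5).
#' @param regions number of slices along the long axis (default 3).
#' @param box_px ROI side length in pixels.
#' @param seed RNG seed for reproducible sampling.
#' @return data.frame `(region, x0, y0, box_px)`; `x0`, `y0` are top-left
#'   corners. Errors when a region cannot host the requested disjoint ROIs.
#' @export
sample_measurement_areas <- function(tissue_mask, n_per_region = 5L,
                                     regions = 3L, box_px = 10L, seed = 1L) {
  stopifnot(is.matrix(tissue_mask), n_per_region >= 1, regions >= 1,
            box_px >= 1)
  H <- nrow(tissue_mask); W <- ncol(tissue_mask)
  long_is_x <- W >= H
  region_names <- if (regions == 3L) c("anterior", "central", "posterior")
                  else paste0("region", seq_len(regions))
  ext <- if (long_is_x) W else H
  breaks <- floor(seq(0, ext, length.out = regions + 1))
  with_seed(seed, {
    rois <- NULL
    for (r in seq_len(regions)) {
      lo <- breaks[r] + 1L; hi <- breaks[r + 1]
      got <- 0L; tries <- 0L
      while (got < n_per_region) {
        tries <- tries + 1L
        if (tries > 2000L)
          stop("region too small for ", n_per_region,
               " non-overlapping ", box_px, "px boxes")
        if (long_is_x) {
          x0 <- sample(lo:(max(lo, hi - box_px + 1L)), 1L)
          y0 <- sample(seq_len(max(1L, H - box_px + 1L)), 1L)
        } else {
          y0 <- sample(lo:(max(lo, hi - box_px + 1L)), 1L)
          x0 <- sample(seq_len(max(1L, W - box_px + 1L)), 1L)
        }
        if (x0 + box_px - 1L > W || y0 + box_px - 1L > H) next
        if (long_is_x && (x0 + box_px - 1L) > hi) next
        if (!long_is_x && (y0 + box_px - 1L) > hi) next
        if (!all(tissue_mask[y0:(y0 + box_px - 1L), x0:(x0 + box_px - 1L)]))
          next
        if (!is.null(rois)) {
          ovl <- rois$x0 < x0 + box_px & x0 < rois$x0 + box_px &
                 rois$y0 < y0 + box_px & y0 < rois$y0 + box_px
          if (any(ovl)) next
        }
        rois <- rbind(rois, data.frame(region = region_names[r],
                                       x0 = x0, y0 = y0, box_px = box_px))
        got <- got + 1L
      }
    }
    rois
  })
}

#' Background-adjusted fluorescence
#'
#' The standard background correction for region-of-interest fluorescence:
#' `integrated_density - area * background_mean`. Negative results are legal
#' (they indicate an overestimated background) and are flagged, never
#' clamped.
#'
#' @param integrated_density summed pixel intensity over the ROI (a.u.).
#' @param area ROI area in pixels (`>= 0`).
#' @param background_mean mean background intensity per pixel (a.u./px).
#' @return numeric vector of adjusted values, with attribute `flagged`
#'   marking negative entries.
#' @examples
#' adjusted_fluorescence(1000, 50, 4)  # 800
#' @export
adjusted_fluorescence <- function(integrated_density, area, background_mean) {
  if (any(!is.finite(integrated_density)) || any(!is.finite(area)) ||
      any(!is.finite(background_mean)))
    stop("non-finite inputs")
  if (any(area < 0)) stop("area must be >= 0")
  adj <- integrated_density - area * background_mean
  neg <- adj < 0
  if (any(neg))
    eq_log("adjusted_fluorescence: %d negative value(s) (background overestimate)",
           sum(neg))
  attr(adj, "flagged") <- neg
  adj
}

#' Measure integrated density of ROIs on an image
#'
#' @param image numeric matrix.
#' @param rois data.frame from [sample_measurement_areas()].
#' @return data.frame `(region, x0, y0, box_px, integrated_density, area)`.
#' @export
measure_rois <- function(image, rois) {
  rois$integrated_density <- vapply(seq_len(nrow(rois)), function(k) {
    sum(image[rois$y0[k]:(rois$y0[k] + rois$box_px[k] - 1L),
              rois$x0[k]:(rois$x0[k] + rois$box_px[k] - 1L)])
  }, numeric(1))
  rois$area <- rois$box_px^2
  rois
}
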