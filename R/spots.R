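#' Detect diffraction-limited spots by Laplacian-of-Gaussian filtering
#'
#' Standard single-molecule spot detection: the image is convolved with a
#' scale-normalized Laplacian-of-Gaussian (LoG) kernel at the PSF scale
#' (bright blobs give positive response), local maxima of the response are
#' kept when they exceed `threshold_factor` times a robust noise estimate
#' (the median absolute deviation of the response), and positions are
#' refined to sub-pixel precision by a 3x3 response-weighted centroid.
#' The reported intensity is an integrated-Gaussian proxy: the amplitude
#' recovered from the response via a matched-filter calibration constant,
#' times `2 * pi * sigma^2`.
#'
#' A constant background offset does not affect detection (the LoG of a
#' constant is zero). Raising `threshold_factor` can only remove detections,
#' never add them.
#'
#' @param img numeric image matrix (rows = y, cols = x).
#' @param psf_sigma_px PSF sigma in pixels (`> 0`).
#' @param threshold_factor multiple of the robust noise level a maximum must
#'   exceed.
#' @param min_response absolute response floor, guarding the noise-free case
#'   where the MAD estimate collapses to numerical ripple.
#' @return A spot table: data.frame
#'   `(x, y, intensity, response, channel, cell_label)`; empty when nothing
#'   is detected.
#' @export
detect_spots <- function(img, psf_sigma_px, threshold_factor = 5,
                         min_response = 1e-3) {
  if (!is.matrix(img)) stop("img must be a matrix")
  if (!is.finite(psf_sigma_px) || psf_sigma_px <= 0)
    stop("psf_sigma_px must be positive")
  empty <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0),
                      response = numeric(0), channel = NA_character_[0],
                      cell_label = integer(0))
  if (length(img) == 0 || all(img == img[1])) return(empty)
  H <- nrow(img); W <- ncol(img)
  kern <- log_kernel(psf_sigma_px)
  if (nrow(kern) > H || ncol(kern) > W) return(empty)
  resp <- -psf_sigma_px^2 *
    EBImage::filter2(img, kern, boundary = "replicate")
  resp <- matrix(as.numeric(resp), H, W)

  sig <- mad(resp)
  thr <- max(threshold_factor * sig, min_response)

  mx <- local_maxima(resp)
  keep <- which(mx & resp > thr, arr.ind = TRUE)
  if (nrow(keep) == 0) return(empty)

  # sub-pixel 3x3 centroid on the (positive part of the) response
  cal <- log_response_calibration(psf_sigma_px)
  out <- data.frame(x = numeric(nrow(keep)), y = numeric(nrow(keep)),
                    intensity = numeric(nrow(keep)),
                    response = resp[keep])
  for (k in seq_len(nrow(keep))) {
    i <- keep[k, 1]; j <- keep[k, 2]
    if (i > 1 && i < H && j > 1 && j < W) {
      wdw <- resp[(i - 1):(i + 1), (j - 1):(j + 1)]
      wdw <- pmax(wdw, 0)
      s <- sum(wdw)
      out$y[k] <- if (s > 0) sum(wdw * ((i - 1):(i + 1))) / s else i
      out$x[k] <- if (s > 0) sum(t(wdw) * ((j - 1):(j + 1))) / s else j
    } else {
      out$y[k] <- i; out$x[k] <- j
    }
  }
  amp <- out$response / cal
  out$intensity <- amp * 2 * pi * psf_sigma_px^2
  out$channel <- NA_character_
  out$cell_label <- 0L
  out[order(out$y, out$x), , drop = FALSE]
}

# internal: scale-normalized LoG kernel (sign flipped so the detector can
# negate once); zero-sum so flat regions give exactly zero response
log_kernel <- function(sigma) {
  w <- ceiling(4 * sigma)
  xs <- -w:w
  g <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma^2))
  r2 <- outer(xs^2, xs^2, "+")
  k <- (r2 - 2 * sigma^2) / sigma^4 * g
  k - mean(k)
}

# internal: peak LoG response of a unit-amplitude Gaussian at matched scale
log_response_calibration <- function(sigma) {
  w <- ceiling(6 * sigma)
  xs <- -w:w
  patch <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma^2))
  resp <- -sigma^2 * EBImage::filter2(patch, log_kernel(sigma),
                                      boundary = "replicate")
  max(resp)
}

# internal: strict local maxima over the 8-neighbourhood (half strict /
# half non-strict so plateaus yield a single maximum)
local_maxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  sh <- function(di, dj) pad[(2:(H + 1)) + di, (2:(W + 1)) + dj]
  (m > sh(0, 1)) & (m > sh(1, 0)) & (m > sh(1, 1)) & (m > sh(-1, 1)) &
    (m >= sh(0, -1)) & (m >= sh(-1, 0)) & (m >= sh(-1, -1)) & (m >= sh(1, -1))
}

#' Assign spots to segmented cells
#'
#' Sets each spot's `cell_label` to the label-image value at its nearest
#' pixel (rounded coordinates); label 0 means unassigned (outside any cell).
#'
#' @param spots a spot table with `x`, `y` columns.
#' @param label_image integer label matrix.
#' @return The spot table with `cell_label` filled in.
#' @export
assign_spots_to_cells <- function(spots, label_image) {
  if (nrow(spots) == 0) { spots$cell_label <- integer(0); return(spots) }
  i <- round(spots$y); j <- round(spots$x)
  if (any(i < 1 | i > nrow(label_image) | j < 1 | j > ncol(label_image)))
    stop("spot coordinates outside the label image")
  spots$cell_label <- label_image[cbind(i, j)]
  spots
}

#' Call transcription sites from intron-channel spots
#'
#' The intron probe only labels nascent transcripts, so an intron-channel
#' spot lying inside the nuclei mask is a transcription site (TS). Each TS
#' is matched (greedy nearest-neighbour) to an exon-channel spot within
#' `coloc_radius_px`; the matched exon spot is flagged `is_ts` and excluded
#' from the mature-mRNA count downstream. Unmatched in-mask intron spots
#' still count as TSs for their cell. Intron spots outside every nucleus are
#' discarded (logged). Per-cell TS counts are capped at 4 (two alleles, four
#' after replication); excess is logged.
#'
#' @param exon_spots,intron_spots spot tables from [detect_spots()], already
#'   carrying `cell_label` (see [assign_spots_to_cells()]).
#' @param nuclei_mask logical matrix of nucleus regions.
#' @param coloc_radius_px colocalization radius (`> 0`); defaults elsewhere
#'   to `2 * psf_sigma_px`.
#' @return list with
#'   \describe{
#'     \item{exon_spots}{input table plus logical `is_ts`.}
#'     \item{ts_counts}{data.frame `(cell_label, ts_count)` for cells with
#'       at least one TS.}
#'     \item{n_intron_rejected}{intron spots outside the nuclei mask.}
#'   }
#' @export
call_transcription_sites <- function(exon_spots, intron_spots, nuclei_mask,
                                     coloc_radius_px) {
  if (!is.finite(coloc_radius_px) || coloc_radius_px <= 0)
    stop("coloc_radius_px must be positive")
  exon_spots$is_ts <- rep(FALSE, nrow(exon_spots))
  in_mask <- if (nrow(intron_spots)) {
    i <- pmin(pmax(round(intron_spots$y), 1), nrow(nuclei_mask))
    j <- pmin(pmax(round(intron_spots$x), 1), ncol(nuclei_mask))
    nuclei_mask[cbind(i, j)]
  } else logical(0)
  n_rej <- sum(!in_mask)
  if (n_rej > 0)
    eq_log("call_transcription_sites: %d intron spot(s) outside nuclei mask discarded", n_rej)
  ts_spots <- intron_spots[in_mask, , drop = FALSE]

  matched_exon <- integer(0)
  ts_cells <- integer(0)
  if (nrow(ts_spots) > 0) {
    if (nrow(exon_spots) > 0) {
      d <- outer(ts_spots$x, exon_spots$x, "-")^2 +
           outer(ts_spots$y, exon_spots$y, "-")^2
      pairs <- which(d <= coloc_radius_px^2, arr.ind = TRUE)
      if (nrow(pairs) > 0) {
        pairs <- pairs[order(d[pairs]), , drop = FALSE]
        used_ts <- logical(nrow(ts_spots)); used_ex <- logical(nrow(exon_spots))
        for (k in seq_len(nrow(pairs))) {
          ti <- pairs[k, 1]; ei <- pairs[k, 2]
          if (!used_ts[ti] && !used_ex[ei]) {
            used_ts[ti] <- TRUE; used_ex[ei] <- TRUE
            matched_exon <- c(matched_exon, ei)
            ts_cells <- c(ts_cells, exon_spots$cell_label[ei])
          }
        }
        ts_cells <- c(ts_cells, ts_spots$cell_label[!used_ts])
      } else ts_cells <- ts_spots$cell_label
    } else ts_cells <- ts_spots$cell_label
  }
  exon_spots$is_ts[matched_exon] <- TRUE

  ts_cells <- ts_cells[ts_cells > 0]
  ts_counts <- if (length(ts_cells)) {
    tab <- table(ts_cells)
    df <- data.frame(cell_label = as.integer(names(tab)),
                     ts_count = as.integer(tab))
    over <- df$ts_count > 4L
    if (any(over)) {
      eq_log("call_transcription_sites: %d cell(s) with >4 TS capped", sum(over))
      df$ts_count[over] <- 4L
    }
    df
  } else data.frame(cell_label = integer(0), ts_count = integer(0))
  list(exon_spots = exon_spots, ts_counts = ts_counts,
       n_intron_rejected = n_rej)
}

#' Aggregate per-cell counts into a cell table
#'
#' One row per segmented cell: centroid and area from the label image, mature
#' mRNA count (exon spots assigned to the cell and not flagged as TS), TS
#' count, and a border flag (cell touches the image edge). Count
#' conservation holds by construction: summed `mrna_count` plus TS-flagged
#' exon spots plus unassigned exon spots equals the number of exon spots.
#'
#' @param exon_spots exon spot table with `cell_label` and `is_ts`.
#' @param ts_counts data.frame `(cell_label, ts_count)`.
#' @param label_image integer label matrix.
#' @param genotype,embryo_id metadata carried into the table.
#' @return data.frame `(label, cx, cy, area_px, mrna_count, ts_count,
#'   genotype, embryo_id, border)`.
#' @export
build_cell_table <- function(exon_spots, ts_counts, label_image,
                             genotype = NA_character_, embryo_id = NA_character_) {
  labs <- sort(unique(as.vector(label_image)))
  labs <- labs[labs > 0]
  H <- nrow(label_image)
  ii <- seq_along(label_image)
  lv <- as.vector(label_image)
  sel <- lv > 0
  ys <- (ii[sel] - 1L) %% H + 1L
  xs <- (ii[sel] - 1L) %/% H + 1L
  cy <- tapply(ys, lv[sel], mean)
  cx <- tapply(xs, lv[sel], mean)
  area <- tapply(ys, lv[sel], length)
  edge_labs <- unique(c(label_image[1, ], label_image[nrow(label_image), ],
                        label_image[, 1], label_image[, ncol(label_image)]))
  counted <- exon_spots$cell_label[!exon_spots$is_ts & exon_spots$cell_label > 0]
  mtab <- table(factor(counted, levels = labs))
  out <- data.frame(label = labs,
                    cx = as.numeric(cx[as.character(labs)]),
                    cy = as.numeric(cy[as.character(labs)]),
                    area_px = as.integer(area[as.character(labs)]),
                    mrna_count = as.integer(mtab),
                    ts_count = 0L,
                    genotype = genotype, embryo_id = embryo_id,
                    border = labs %in% edge_labs)
  m <- match(ts_counts$cell_label, out$label)
  out$ts_count[m[!is.na(m)]] <- ts_counts$ts_count[!is.na(m)]
  out
}

#' Score detections against ground truth
#'
#' Greedy nearest-neighbour matching within `radius` pixels; each truth spot
#' matches at most one detection.
#'
#' @param detected,truth tables with `x`, `y` columns.
#' @param radius matching radius in pixels.
#' @return list `(tp, fp, fn, precision, recall, f1)`.
#' @export
score_detection <- function(detected, truth, radius) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(tp = 0L, fp = nd, fn = nt,
                precision = if (nd) 0 else NA_real_,
                recall = if (nt) 0 else NA_real_, f1 = 0))
  d <- outer(detected$x, truth$x, "-")^2 + outer(detected$y, truth$y, "-")^2
  pairs <- which(d <= radius^2, arr.ind = TRUE)
  tp <- 0L
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(d[pairs]), , drop = FALSE]
    ud <- logical(nd); ut <- logical(nt)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!ud[i] && !ut[j]) { ud[i] <- TRUE; ut[j] <- TRUE; tp <- tp + 1L }
    }
  }
  fp <- nd - tp; fn <- nt - tp
  prec <- tp / nd; rec <- tp / nt
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}

#' Quantify one embryo image end to end
#'
#' Segmentation (or ground-truth label bypass), LoG spot detection in the
#' exon and intron channels, spot-to-cell assignment, transcription-site
#' calling, and per-cell aggregation.
#'
#' @param images named list with `exon`, `intron`, `membrane`, `nuclei`
#'   matrices (as from [render_channels()] or [read_embryo_tiff()]).
#' @param psf_sigma_px PSF sigma for detection.
#' @param threshold_factor detection threshold (see [detect_spots()]).
#' @param coloc_radius_px TS colocalization radius; default `2 * psf_sigma_px`.
#' @param labels optional ground-truth label image (bypasses segmentation).
#' @param nuclei_mask optional ground-truth nuclei mask; by default the
#'   nuclei channel is thresholded.
#' @param genotype,embryo_id metadata for the cell table.
#' @return list `(cells, spots, labels)`.
#' @export
quantify_embryo <- function(images, psf_sigma_px, threshold_factor = 5,
                            coloc_radius_px = 2 * psf_sigma_px,
                            labels = NULL, nuclei_mask = NULL,
                            genotype = NA_character_,
                            embryo_id = NA_character_) {
  labels <- segment_cells(images$membrane, images$nuclei, labels)
  if (is.null(nuclei_mask)) {
    nsm <- EBImage::gblur(images$nuclei, sigma = 2)
    bg <- as.numeric(quantile(nsm, 0.05))
    top <- as.numeric(quantile(nsm, 0.995))
    nuclei_mask <- nsm > (bg + 0.5 * (top - bg))
  }
  ex <- detect_spots(images$exon, psf_sigma_px, threshold_factor)
  ex$channel <- rep("exon", nrow(ex))
  it <- detect_spots(images$intron, psf_sigma_px, threshold_factor)
  it$channel <- rep("intron", nrow(it))
  ex <- assign_spots_to_cells(ex, labels)
  it <- assign_spots_to_cells(it, labels)
  ts <- call_transcription_sites(ex, it, nuclei_mask, coloc_radius_px)
  cells <- build_cell_table(ts$exon_spots, ts$ts_counts, labels,
                            genotype = genotype, embryo_id = embryo_id)
  list(cells = cells, spots = rbind(ts$exon_spots,
                                    cbind(it, is_ts = NA)),
       labels = labels)
}
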