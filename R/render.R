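#' Render multi-channel smFISH images from ground truth
#'
#' Produces the four channels of a synthetic smFISH acquisition:
#' \describe{
#'   \item{exon}{one Gaussian spot (sigma `psf_sigma_px`, peak `spot_amp`)
#'     per mature mRNA at a uniform-random position inside its cell, plus one
#'     spot per active transcription site (TS) with peak
#'     `spot_amp * ts_amp_scale * nascent load` — nascent transcripts carry
#'     exonic sequence, so TSs appear in the exon channel too.}
#'   \item{intron}{TS spots only, inside the nucleus disk: introns are
#'     excised from mature mRNA, so only nascent transcripts are visible.}
#'   \item{membrane}{rasterized cell boundaries.}
#'   \item{nuclei}{filled disks at cell centers.}
#' }
#' Constant camera background (`background_mean`) and Gaussian read noise
#' (`noise_sd`) are added to every channel.
#'
#' mRNA positions keep `margin_px` away from the cell boundary; if
#' `min_sep_px > 0`, positions within a cell (mRNA and TS) are rejection-
#' sampled to be at least that far apart — the "well-separated" regime used
#' to validate exact count recovery. A warning is recorded when the expected
#' spot spacing falls below `2 * psf_sigma_px` (counting becomes unreliable).
#'
#' @param cellmap a `cell_map`.
#' @param ground_truth a `ground_truth` from [simulate_transcription()].
#' @param config a [sim_config()].
#' @param seed RNG stream seed (default `config$seed`).
#' @return list with
#'   \describe{
#'     \item{images}{named list of matrices `exon`, `intron`, `membrane`,
#'       `nuclei` (rows = y, cols = x).}
#'     \item{spots}{ground-truth spot table
#'       `(x, y, channel, amplitude, cell_label, type)`.}
#'     \item{nuclei_mask}{logical matrix of the nucleus disks.}
#'   }
#' @export
render_channels <- function(cellmap, ground_truth, config, seed = config$seed) {
  validate_sim_config(config)
  H <- cellmap$height; W <- cellmap$width
  gt <- ground_truth$cells
  sigma <- config$psf_sigma_px
  nuc_r <- config$nucleus_radius_frac * cellmap$pitch

  interior <- interior_pixels(cellmap, config$margin_px)
  spots <- with_seed(derive_seed(seed, 33L), {
    rows <- vector("list", nrow(gt))
    for (i in seq_len(nrow(gt))) {
      lab <- gt$label[i]
      cell <- cellmap$cells[cellmap$cells$label == lab, ]
      al <- ground_truth$alleles
      al <- al[al$label == lab & al$active == 1L, , drop = FALSE]
      n_ts <- nrow(al)
      pts <- sample_cell_positions(
        n_mrna = gt$true_mrna[i], n_ts = n_ts,
        pix = interior[[as.character(lab)]], fallback = cellmap$idx_by_label[[as.character(lab)]],
        H = H, cx = cell$cx, cy = cell$cy, nuc_r = nuc_r,
        min_sep = config$min_sep_px)
      out <- NULL
      if (gt$true_mrna[i] > 0) {
        out <- data.frame(x = pts$mrna[, 1], y = pts$mrna[, 2],
                          channel = "exon", amplitude = config$spot_amp,
                          cell_label = lab, type = "mrna")
      }
      if (n_ts > 0) {
        amp_ts <- config$spot_amp * config$ts_amp_scale * al$nascent
        out <- rbind(out,
          data.frame(x = pts$ts[, 1], y = pts$ts[, 2], channel = "exon",
                     amplitude = amp_ts, cell_label = lab, type = "ts"),
          data.frame(x = pts$ts[, 1], y = pts$ts[, 2], channel = "intron",
                     amplitude = amp_ts, cell_label = lab, type = "ts"))
      }
      rows[[i]] <- out
    }
    do.call(rbind, rows)
  })
  if (is.null(spots))
    spots <- data.frame(x = numeric(0), y = numeric(0), channel = character(0),
                        amplitude = numeric(0), cell_label = integer(0),
                        type = character(0))

  n_exon <- sum(spots$channel == "exon")
  if (n_exon > 1) {
    spacing <- sqrt(H * W / n_exon)
    if (spacing < 2 * sigma)
      warning(sprintf(
        "expected spot spacing %.2f px < 2*psf_sigma (%.2f px): counting unreliable",
        spacing, 2 * sigma))
  }

  exon <- add_gaussian_spots(matrix(0, H, W),
                             spots[spots$channel == "exon", ], sigma)
  intron <- add_gaussian_spots(matrix(0, H, W),
                               spots[spots$channel == "intron", ], sigma)
  membrane <- boundary_mask(cellmap$label_image) * config$membrane_amp
  nd <- nucleus_disks(cellmap, nuc_r)
  nuclei <- nd * config$nuclei_amp

  images <- list(exon = exon, intron = intron,
                 membrane = membrane, nuclei = nuclei)
  images <- with_seed(derive_seed(seed, 34L), lapply(images, function(im)
    im + config$background_mean +
      if (config$noise_sd > 0) matrix(rnorm(H * W, 0, config$noise_sd), H, W) else 0))

  list(images = images, spots = spots, nuclei_mask = nd > 0)
}

# internal: per-cell pixel indices at least margin_px inside the cell
interior_pixels <- function(cellmap, margin_px) {
  if (margin_px <= 0) return(cellmap$idx_by_label)
  bnd <- boundary_mask(cellmap$label_image)
  d <- EBImage::distmap(1 - bnd)   # distance to nearest boundary pixel
  keep <- as.vector(d) > margin_px
  lapply(cellmap$idx_by_label, function(ii) ii[keep[ii]])
}

# internal: draw spot positions inside one cell honouring min separation
sample_cell_positions <- function(n_mrna, n_ts, pix, fallback, H,
                                  cx, cy, nuc_r, min_sep) {
  if (length(pix) == 0) pix <- fallback
  acc <- matrix(numeric(0), 0, 2)
  draw_mrna <- function() {
    ii <- pix[sample.int(length(pix), 1L)]
    c((ii - 1L) %/% H + 1L + runif(1, -0.5, 0.5),
      (ii - 1L) %% H + 1L + runif(1, -0.5, 0.5))
  }
  draw_ts <- function() {
    th <- runif(1, 0, 2 * pi); r <- 0.8 * nuc_r * sqrt(runif(1))
    c(cx + r * cos(th), cy + r * sin(th))
  }
  place <- function(n, drawer) {
    out <- matrix(NA_real_, n, 2)
    for (k in seq_len(n)) {
      for (try in seq_len(200L)) {
        pt <- drawer()
        if (min_sep <= 0 || nrow(acc) == 0 ||
            min((acc[, 1] - pt[1])^2 + (acc[, 2] - pt[2])^2) >= min_sep^2) break
      }
      out[k, ] <- pt
      acc <<- rbind(acc, pt)
    }
    out
  }
  ts <- place(n_ts, draw_ts)       # TSs first: they are few and constrained
  mrna <- place(n_mrna, draw_mrna)
  list(mrna = mrna, ts = ts)
}

# internal: additively render Gaussian spots into an image matrix
add_gaussian_spots <- function(img, spots, sigma) {
  if (nrow(spots) == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  w <- ceiling(4 * sigma)
  for (k in seq_len(nrow(spots))) {
    x <- spots$x[k]; y <- spots$y[k]; a <- spots$amplitude[k]
    xs <- max(1L, floor(x - w)):min(W, ceiling(x + w))
    ys <- max(1L, floor(y - w)):min(H, ceiling(y + w))
    if (!length(xs) || !length(ys)) next
    gx <- exp(-(xs - x)^2 / (2 * sigma^2))
    gy <- exp(-(ys - y)^2 / (2 * sigma^2))
    img[ys, xs] <- img[ys, xs] + a * outer(gy, gx)
  }
  img
}

# internal: pixels whose 4-neighbour has a different label
boundary_mask <- function(label_image) {
  H <- nrow(label_image); W <- ncol(label_image)
  b <- matrix(FALSE, H, W)
  b[-H, ] <- b[-H, ] | (label_image[-H, ] != label_image[-1, ])
  b[-1, ] <- b[-1, ] | (label_image[-1, ] != label_image[-H, ])
  b[, -W] <- b[, -W] | (label_image[, -W] != label_image[, -1])
  b[, -1] <- b[, -1] | (label_image[, -1] != label_image[, -W])
  b * 1
}

# internal: filled nucleus disks at cell centers
nucleus_disks <- function(cellmap, nuc_r) {
  H <- cellmap$height; W <- cellmap$width
  img <- matrix(0, H, W)
  for (i in seq_len(nrow(cellmap$cells))) {
    cx <- cellmap$cells$cx[i]; cy <- cellmap$cells$cy[i]
    xs <- max(1L, floor(cx - nuc_r)):min(W, ceiling(cx + nuc_r))
    ys <- max(1L, floor(cy - nuc_r)):min(H, ceiling(cy + nuc_r))
    if (!length(xs) || !length(ys)) next
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    img[ys, xs][d2 <= nuc_r^2] <- 1
  }
  img
}

#' Render a protein immunofluorescence image
#'
#' Draws per-cell uniform protein intensity on a canvas with an empty margin
#' of pure background around the tissue (so background regions exist for the
#' background-mean measurement), then adds camera background and read noise.
#'
#' @param cellmap a `cell_map`.
#' @param protein data.frame `(label, protein)` from [simulate_protein()].
#' @param config a [sim_config()].
#' @param margin_px width of the background margin around the tissue.
#' @param seed RNG stream seed.
#' @return list `(image, tissue_mask, offset)`; `offset` is the (x, y) shift
#'   of tissue coordinates on the canvas.
#' @export
render_protein_image <- function(cellmap, protein, config, margin_px = 24,
                                 seed = config$seed) {
  H <- cellmap$height; W <- cellmap$width
  lev <- protein$protein[match(as.vector(cellmap$label_image), protein$label)]
  lev[is.na(lev)] <- 0
  tissue <- matrix(lev, H, W)
  Hc <- H + 2 * margin_px; Wc <- W + 2 * margin_px
  img <- matrix(0, Hc, Wc)
  img[margin_px + seq_len(H), margin_px + seq_len(W)] <- tissue
  mask <- matrix(FALSE, Hc, Wc)
  mask[margin_px + seq_len(H), margin_px + seq_len(W)] <-
    cellmap$label_image > 0
  img <- with_seed(derive_seed(seed, 55L),
    img + config$background_mean +
      if (config$noise_sd > 0) matrix(rnorm(Hc * Wc, 0, config$noise_sd), Hc, Wc) else 0)
  list(image = img, tissue_mask = mask, offset = c(margin_px, margin_px))
}

#' Write / read a multi-channel embryo image as multi-page TIFF
#'
#' One 16-bit page per channel, in the order exon, intron, membrane, nuclei.
#' Intensities are clamped to `[0, 65535]` on write.
#'
#' @param images named list of equal-sized matrices.
#' @param path TIFF file path.
#' @return `write_embryo_tiff` returns `path` invisibly; `read_embryo_tiff`
#'   returns a named list of matrices.
#' @export
write_embryo_tiff <- function(images, path) {
  stopifnot(is.list(images), length(images) >= 1)
  pages <- lapply(images, function(im) pmin(pmax(im, 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_embryo_tiff
#' @export
read_embryo_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) p * 65535)
  if (length(pages) == 4)
    names(pages) <- c("exon", "intron", "membrane", "nuclei")
  pages
}
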