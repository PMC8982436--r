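#' Build the synthetic cell lattice
#'
#' Generates a planar epithelium as the Voronoi tessellation of jittered
#' staggered-hexagonal lattice centers, clipped to a rectangular strip. The
#' strip models the surface cell layer of the pre-gastrulation blastoderm:
#' columns run along the anteroposterior axis, rows along the dorsoventral
#' (DV) axis, and each cell carries a normalized DV coordinate used by the
#' expression-domain logic.
#'
#' The tessellation is computed on the pixel raster (each pixel is assigned
#' to its nearest center), which is exactly the label image downstream
#' segmentation and spot assignment operate on. Voronoi cells are convex, so
#' each cell's polygon is recovered as the convex hull of its pixel centers.
#'
#' @param config a [sim_config()]; uses `n_cols`, `n_rows`, `jitter`,
#'   `cell_pitch_px` and `seed`.
#' @return An object of class `cell_map`: list with
#'   \describe{
#'     \item{cells}{data.frame `(label, cx, cy, dv, area_px, row, col, border)`;
#'       labels are contiguous from 1 in row-major order.}
#'     \item{label_image}{integer matrix (rows = image y, cols = image x);
#'       pixel value = owning cell label.}
#'     \item{polygons}{list of two-column vertex matrices, one per cell.}
#'     \item{width, height, pitch}{strip geometry in pixels.}
#'   }
#' @examples
#' cm <- build_cell_lattice(sim_config(n_cols = 3, n_rows = 3, cell_pitch_px = 20))
#' nrow(cm$cells)
#' @export
build_cell_lattice <- function(config) {
  validate_sim_config(config)
  p <- config$cell_pitch_px
  s <- p * sqrt(3) / 2                      # hex row spacing
  W <- max(1L, as.integer(round(config$n_cols * p)))
  H <- max(1L, as.integer(round(config$n_rows * s)))
  nr <- config$n_rows; nc <- config$n_cols

  grid <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  # alternate rows staggered by +/- pitch/4 to keep edge margins symmetric
  x0 <- (grid$col - 0.5) * p + ifelse(grid$row %% 2L == 1L, -p / 4, p / 4)
  y0 <- (grid$row - 0.5) * s
  n <- nrow(grid)
  if (config$jitter > 0) {
    jit <- with_seed(derive_seed(config$seed, 101L), {
      theta <- runif(n, 0, 2 * pi)
      rad <- config$jitter * p * sqrt(runif(n))
      cbind(rad * cos(theta), rad * sin(theta))
    })
    x0 <- x0 + jit[, 1]; y0 <- y0 + jit[, 2]
  }

  # nearest-center assignment; candidates restricted to a 5x5 lattice
  # neighborhood of each pixel (valid because displacement < pitch/2)
  px <- rep(seq_len(W), each = H)   # x = column coordinate of pixel center
  py <- rep(seq_len(H), times = W)  # y = row coordinate
  c0 <- pmin(pmax(round(px / p + 0.5), 1L), nc)
  r0 <- pmin(pmax(round(py / s + 0.5), 1L), nr)
  best_d <- rep(Inf, W * H)
  best_lab <- integer(W * H)
  for (dr in -2:2) for (dc in -2:2) {
    rr <- r0 + dr; cc <- c0 + dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (!any(ok)) next
    idx <- (rr - 1L) * nc + cc       # row-major label
    d <- rep(Inf, W * H)
    d[ok] <- (px[ok] - x0[idx[ok]])^2 + (py[ok] - y0[idx[ok]])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_lab[upd] <- idx[upd]
  }
  label_image <- matrix(0L, nrow = H, ncol = W)
  label_image[cbind(py, px)] <- best_lab
  storage.mode(label_image) <- "integer"

  # expand.grid(col, row) varies col fastest, so element i has row-major
  # label i: centers are already in label order
  labels <- seq_len(n)
  cells <- data.frame(
    label = labels, cx = x0, cy = y0,
    dv = (grid$row - 0.5) / nr,
    area_px = tabulate(best_lab, nbins = n),
    row = grid$row, col = grid$col
  )
  # border cells: touch the image edge
  edge_labs <- unique(c(label_image[1, ], label_image[H, ],
                        label_image[, 1], label_image[, W]))
  cells$border <- cells$label %in% edge_labs

  idx_by_label <- split(seq_along(label_image), as.vector(label_image))
  polygons <- lapply(as.character(labels), function(l) {
    ii <- idx_by_label[[l]]
    yy <- (ii - 1L) %% H + 1L
    xx <- (ii - 1L) %/% H + 1L
    pts <- cbind(x = xx, y = yy)
    pts[grDevices::chull(pts), , drop = FALSE]
  })

  structure(list(cells = cells, label_image = label_image,
                 polygons = polygons, idx_by_label = idx_by_label,
                 width = W, height = H, pitch = p),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat("cell_map:", nrow(x$cells), "cells,", x$width, "x", x$height, "px\n")
  invisible(x)
}

#' Flag gene activity per cell from DV expression domains
#'
#' A cell is active for a gene iff its DV coordinate falls inside that gene's
#' half-open interval `[lo, hi)` from `config$domain_spec`. Because the `rho`
#' interval is required to nest inside the `mir9a` interval, the set of
#' rho-active cells is contained in the set of mir9a-active cells; when the
#' intervals differ a band of mir9a-only cells appears at the ventral edge.
#'
#' @param cellmap a `cell_map`.
#' @param config a [sim_config()].
#' @return data.frame `(label, rho, mir9a, ...)` with one logical column per
#'   gene in `domain_spec`.
#' @export
assign_domains <- function(cellmap, config) {
  validate_sim_config(config)
  dv <- cellmap$cells$dv
  out <- data.frame(label = cellmap$cells$label)
  for (g in names(config$domain_spec)) {
    iv <- config$domain_spec[[g]]
    out[[g]] <- dv >= iv[1] & dv < iv[2]
  }
  if (any(out$rho & !out$mir9a))
    stop("domain assignment violated rho ⊆ mir9a containment")
  out
}
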