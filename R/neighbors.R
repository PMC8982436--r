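#' Build the immediate-neighbor graph of segmented cells
#'
#' Primary definition: two cells are neighbors iff their labels touch across
#' a pixel edge in the label image (4-connectivity across the shared
#' boundary). Fallback, when only centroids are available: adjacency of the
#' discrete Voronoi tessellation of the centroids (equivalent to Delaunay
#' adjacency up to raster resolution), with edges longer than twice the
#' median edge length pruned to suppress spurious long-range links along the
#' convex hull.
#'
#' @param label_image integer label matrix (primary definition).
#' @param centroids two-column matrix or data.frame of cell centers with
#'   optional `label` column (fallback definition); used only when
#'   `label_image` is `NULL`.
#' @param resolution raster pixel size for the centroid fallback, as a
#'   fraction of the median nearest-neighbor distance.
#' @return An object of class `neighbor_graph`: list with `nodes` (integer
#'   labels), `adj` (named list of neighbor vectors), `edges` (two-column
#'   matrix, each unordered pair once), and `border` (named logical: cell
#'   touches the image edge).
#' @export
build_neighbor_graph <- function(label_image = NULL, centroids = NULL,
                                 resolution = 0.15) {
  if (is.null(label_image)) {
    if (is.null(centroids)) stop("need a label image or centroids")
    label_image <- voronoi_raster(centroids, resolution)
  }
  H <- nrow(label_image); W <- ncol(label_image)
  a <- as.vector(label_image[-H, ]); b <- as.vector(label_image[-1, ])
  cc <- as.vector(label_image[, -W]); d <- as.vector(label_image[, -1])
  pairs <- rbind(cbind(a, b), cbind(cc, d))
  pairs <- pairs[pairs[, 1] != pairs[, 2] & pairs[, 1] > 0 & pairs[, 2] > 0,
                 , drop = FALSE]
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- unique(pairs)
  nodes <- sort(unique(as.vector(label_image)))
  nodes <- nodes[nodes > 0]

  if (!is.null(centroids) && nrow(pairs) > 0) {
    # prune long edges (centroid fallback only)
    cdf <- as.data.frame(centroids)
    lab <- if ("label" %in% names(cdf)) cdf$label else seq_len(nrow(cdf))
    cen <- as.matrix(cdf[, setdiff(names(cdf), "label")][, 1:2])
    i1 <- match(pairs[, 1], lab); i2 <- match(pairs[, 2], lab)
    len <- sqrt(rowSums((cen[i1, , drop = FALSE] - cen[i2, , drop = FALSE])^2))
    pairs <- pairs[len <= 2 * median(len), , drop = FALSE]
  }

  adj <- lapply(nodes, function(nd)
    sort(unique(c(pairs[pairs[, 1] == nd, 2], pairs[pairs[, 2] == nd, 1]))))
  names(adj) <- as.character(nodes)
  edge_labs <- unique(c(label_image[1, ], label_image[H, ],
                        label_image[, 1], label_image[, W]))
  border <- nodes %in% edge_labs
  names(border) <- as.character(nodes)
  structure(list(nodes = nodes, adj = adj, edges = pairs, border = border),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("neighbor_graph:", length(x$nodes), "cells,", nrow(x$edges), "edges\n")
  invisible(x)
}

# internal: discrete Voronoi label raster of a centroid set
voronoi_raster <- function(centroids, resolution = 0.15) {
  cdf <- as.data.frame(centroids)
  lab <- if ("label" %in% names(cdf)) cdf$label else seq_len(nrow(cdf))
  cen <- as.matrix(cdf[, setdiff(names(cdf), "label")][, 1:2])
  n <- nrow(cen)
  if (n == 1) return(matrix(lab[1], 8, 8))
  dd <- as.matrix(stats::dist(cen)); diag(dd) <- Inf
  nn <- median(apply(dd, 1, min))
  px <- max(nn * resolution, 1e-6)
  xr <- range(cen[, 1]); yr <- range(cen[, 2])
  xs <- seq(xr[1] - nn / 2, xr[2] + nn / 2, by = px)
  ys <- seq(yr[1] - nn / 2, yr[2] + nn / 2, by = px)
  G <- expand.grid(y = ys, x = xs)
  best <- rep(Inf, nrow(G)); bl <- integer(nrow(G))
  for (k in seq_len(n)) {
    d <- (G$x - cen[k, 1])^2 + (G$y - cen[k, 2])^2
    upd <- d < best
    best[upd] <- d[upd]; bl[upd] <- lab[k]
  }
  matrix(bl, length(ys), length(xs))
}

#' Local dispersion of counts over neighbor clusters
#'
#' For each non-border focal cell, the cluster is the focal cell together
#' with its immediate neighbors (focal inclusion switchable). The cluster's
#' mRNA counts give the cluster mean, sample variance (denominator `n - 1`
#' by default), Fano factor (variance/mean) and coefficient of variation
#' (sd/mean). Clusters with fewer than 3 members, or with zero mean, are
#' recorded as missing — a 0/0 Fano factor is not evidence of low
#' variability. Border cells are excluded as focal cells but still
#' contribute as neighbors.
#'
#' @param cells a cell table with `label` and `mrna_count` (and optionally
#'   `border`).
#' @param graph a `neighbor_graph`.
#' @param include_focal include the focal cell in its own cluster
#'   (default `TRUE`).
#' @param denom variance denominator, `"n-1"` (sample, default) or `"n"`.
#' @return data.frame `(label, cluster_size, cluster_mean, cluster_var,
#'   fano, cv)`, one row per non-border focal cell; undefined statistics are
#'   `NA`.
#' @export
local_dispersion <- function(cells, graph, include_focal = TRUE,
                             denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  if (!all(as.character(graph$nodes) %in% as.character(cells$label)))
    stop("every graph node must be present in the cell table")
  counts <- cells$mrna_count[match(graph$nodes, cells$label)]
  names(counts) <- as.character(graph$nodes)
  focal <- graph$nodes[!graph$border[as.character(graph$nodes)]]
  rows <- lapply(focal, function(f) {
    members <- graph$adj[[as.character(f)]]
    if (include_focal) members <- c(f, members)
    v <- counts[as.character(members)]
    n <- length(v)
    if (n < 3) return(data.frame(label = f, cluster_size = n,
                                 cluster_mean = NA_real_, cluster_var = NA_real_,
                                 fano = NA_real_, cv = NA_real_))
    m <- mean(v)
    s2 <- if (denom == "n-1") var(v) else var(v) * (n - 1) / n
    if (m == 0)
      data.frame(label = f, cluster_size = n, cluster_mean = m,
                 cluster_var = s2, fano = NA_real_, cv = NA_real_)
    else
      data.frame(label = f, cluster_size = n, cluster_mean = m,
                 cluster_var = s2, fano = s2 / m, cv = sqrt(s2) / m)
  })
  if (!length(rows))
    return(data.frame(label = integer(0), cluster_size = integer(0),
                      cluster_mean = numeric(0), cluster_var = numeric(0),
                      fano = numeric(0), cv = numeric(0)))
  do.call(rbind, rows)
}
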