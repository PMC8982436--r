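#' Segment cells from membrane and nuclei channels
#'
#' Marker-controlled watershed re-implementation of the commercial
#' cell-segmentation step: nuclei are smoothed, thresholded and labelled to
#' provide one seed per cell, and seeds are grown over the smoothed membrane
#' channel (EBImage `propagate`, a watershed-type region growing whose
#' boundaries settle on membrane intensity ridges). Flooding ties are
#' resolved deterministically by label order.
#'
#' @param membrane,nuclei numeric matrices of the same size.
#' @param labels optional precomputed integer label image; when supplied it
#'   is validated and returned unchanged (ground-truth bypass mode).
#' @param nuclei_smooth,membrane_smooth Gaussian smoothing sigmas (px).
#' @param lambda `propagate` regularization: larger values weight Euclidean
#'   distance over image gradient.
#' @return integer label matrix, 0 = background, labels contiguous from 1.
#' @export
segment_cells <- function(membrane, nuclei, labels = NULL,
                          nuclei_smooth = 2, membrane_smooth = 1,
                          lambda = 1e-3) {
  if (!is.null(labels)) {
    stopifnot(is.matrix(labels))
    storage.mode(labels) <- "integer"
    return(labels)
  }
  if (!all(dim(membrane) == dim(nuclei)))
    stop("membrane and nuclei channels must have the same shape")
  nsm <- EBImage::gblur(nuclei, sigma = nuclei_smooth)
  # threshold halfway between background level and nuclear plateau
  bg <- as.numeric(quantile(nsm, 0.05))
  top <- as.numeric(quantile(nsm, 0.995))
  seeds_mask <- nsm > (bg + 0.5 * (top - bg))
  seeds <- EBImage::bwlabel(seeds_mask)
  if (max(seeds) == 0) stop("no seeds: no nuclei detected")
  msm <- EBImage::gblur(membrane, sigma = membrane_smooth)
  rng <- range(msm)
  msm <- if (diff(rng) > 0) (msm - rng[1]) / diff(rng) else msm * 0
  seg <- EBImage::propagate(msm, seeds, lambda = lambda)
  seg <- matrix(as.integer(seg), nrow(membrane), ncol(membrane))
  seg
}

#' Mean boundary displacement between two segmentations
#'
#' For every boundary pixel of `test`, the distance to the nearest boundary
#' pixel of `reference`; used to score recovered segmentations against
#' ground-truth label images.
#'
#' @param test,reference integer label matrices of equal size.
#' @return mean displacement in pixels.
#' @export
boundary_displacement <- function(test, reference) {
  bt <- boundary_mask(test) > 0
  br <- boundary_mask(reference) > 0
  if (!any(bt) || !any(br)) return(0)
  d <- EBImage::distmap(matrix(as.numeric(!br), nrow(reference)))
  mean(d[bt])
}
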