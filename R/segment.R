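## Nuclear segmentation from the DAPI channel.

.asEBImage <- function(mat) EBImage::Image(mat / 65535)

#' Segment nuclei from a DAPI image
#'
#' Thresholds the DAPI channel (Otsu by default), fills holes, splits
#' touching nuclei by a watershed on the distance transform, then filters
#' the resulting components by area and removes objects touching the image
#' border (their features would be truncated).
#'
#' @param dapi numeric matrix, 16-bit intensities in [0, 65535].
#' @param minArea,maxArea area gates in pixels.
#' @param threshold \code{"otsu"} or a numeric intensity cutoff in camera
#'   units.
#' @param pixelSize micrometres per pixel, stored as an attribute on the
#'   returned mask (default 0.32).
#' @return integer label matrix (background 0, one positive label per
#'   connected nucleus) with attribute \code{pixelSize}. A blank or fully
#'   saturated image yields an empty mask with a warning.
#' @examples
#' syn <- renderNucleusImage(4, fociPerNucleus = 0, noiseSd = 20, seed = 3,
#'                           width = 256, height = 256)
#' mask <- segmentNuclei(syn$image)
#' max(mask)
#' @export
segmentNuclei <- function(dapi, minArea = 200, maxArea = 5000,
                          threshold = "otsu", pixelSize = 0.32) {
  stopifnot(is.matrix(dapi))
  empty <- matrix(0L, nrow = nrow(dapi), ncol = ncol(dapi))
  attr(empty, "pixelSize") <- pixelSize
  rng <- range(dapi)
  if (diff(rng) == 0) {
    warning("image is constant (blank or saturated); returning empty mask")
    return(empty)
  }
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(.asEBImage(dapi), range = c(0, 1)) * 65535
  } else {
    stopifnot(is.numeric(threshold))
    threshold
  }
  bin <- EBImage::Image(dapi > thr)
  if (sum(bin) == 0) {
    warning("no foreground pixels above threshold; returning empty mask")
    return(empty)
  }
  bin <- EBImage::fillHull(bin)
  ## split touching nuclei on the distance transform
  lab <- EBImage::watershed(EBImage::distmap(bin), tolerance = 2)
  labMat <- matrix(as.integer(EBImage::imageData(lab)),
                   nrow = nrow(dapi))
  ## area gate + border removal, then relabel compactly
  keep <- integer(0)
  tab <- tabulate(labMat)
  border <- unique(c(labMat[1, ], labMat[nrow(labMat), ],
                     labMat[, 1], labMat[, ncol(labMat)]))
  for (l in seq_along(tab)) {
    if (tab[l] >= minArea && tab[l] <= maxArea && !(l %in% border))
      keep <- c(keep, l)
  }
  out <- matrix(0L, nrow = nrow(dapi), ncol = ncol(dapi))
  for (j in seq_along(keep))
    out[labMat == keep[j]] <- j
  attr(out, "pixelSize") <- pixelSize
  out
}

## internal: per-label centroids (0-based row/col) of a label matrix
.maskCentroids <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs))
    return(data.frame(label = integer(), row = numeric(), col = numeric()))
  idx <- which(mask > 0, arr.ind = TRUE)
  l <- mask[mask > 0]
  data.frame(
    label = labs,
    row = tapply(idx[, 1], l, mean)[as.character(labs)] - 1,
    col = tapply(idx[, 2], l, mean)[as.character(labs)] - 1,
    row.names = NULL)
}
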