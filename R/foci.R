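## Focus detection: white top-hat filtering followed by per-nucleus
## adaptive thresholding and connected-component segmentation.

#' Detect nuclear foci in a marker channel
#'
#' Applies a morphological white top-hat with a disk structuring element
#' (isolating bright objects smaller than the disk), thresholds the
#' response inside each nucleus at \code{median + thresholdFactor * robust
#' sd} (MAD) of that nucleus' response, and keeps connected components of
#' at least \code{minFocusArea} pixels. Components whose centroid falls
#' outside every nucleus are discarded; each focus is assigned to the
#' nucleus containing its centroid.
#'
#' @param channel numeric matrix aligned with \code{mask}.
#' @param mask integer label matrix from \code{\link{segmentNuclei}} (or a
#'   ground-truth label map).
#' @param tophatRadius disk radius in pixels (default 5, about 1.6 um at
#'   0.32 um/px, sized to pass typical 53BP1 foci).
#' @param thresholdFactor robust-sd multiplier (default 3).
#' @param minFocusArea minimum focus size in pixels (default 4).
#' @param minResponse absolute floor on the top-hat response in camera
#'   units (default 2000); guards against the shallow dome and rim
#'   response a smooth nucleus produces even without noise.
#' @param splitTolerance watershed tolerance in camera units (default
#'   3000) used to split touching foci at the saddle of the top-hat
#'   response; raise it to merge more aggressively.
#' @return data.frame, one row per focus: label (parent nucleus), row/col
#'   centroid (0-based), area, integrated/average/min/max intensity of the
#'   original channel over the focus pixels.
#' @examples
#' syn <- renderNucleusImage(2, fociPerNucleus = 3, noiseSd = 0, seed = 5,
#'                           width = 192, height = 192)
#' detectFoci(syn$image, syn$labelMap)
#' @export
detectFoci <- function(channel, mask, tophatRadius = 5,
                       thresholdFactor = 3, minFocusArea = 4,
                       minResponse = 2000, splitTolerance = 3000) {
  stopifnot(is.matrix(channel), all(dim(channel) == dim(mask)))
  if (tophatRadius < 1)
    stop("tophatRadius must be >= 1", call. = FALSE)
  emptyFoci <- data.frame(label = integer(), row = numeric(),
                          col = numeric(), area = numeric(),
                          integrated_intensity = numeric(),
                          average_intensity = numeric(),
                          min_intensity = numeric(),
                          max_intensity = numeric())
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) return(emptyFoci)

  brush <- EBImage::makeBrush(2L * as.integer(tophatRadius) + 1L, "disc")
  th <- EBImage::imageData(EBImage::whiteTopHat(.asEBImage(channel), brush))
  ## the top-hat of an integer image is integer-valued; rounding removes
  ## float knife-edges so thresholding is exactly offset/translation
  ## invariant
  th <- round(matrix(th, nrow = nrow(channel)) * 65535, 6)

  ## per-nucleus adaptive threshold on the top-hat response
  sel <- matrix(FALSE, nrow = nrow(channel), ncol = ncol(channel))
  for (l in labs) {
    inl <- mask == l
    v <- th[inl]
    cut <- max(stats::median(v) + thresholdFactor * stats::mad(v),
               minResponse)
    sel[inl] <- th[inl] > cut
  }
  if (!any(sel)) return(emptyFoci)

  ## label components, splitting touching foci at response saddles
  comp <- EBImage::watershed(EBImage::Image((th * sel) / 65535),
                             tolerance = splitTolerance / 65535)
  compMat <- matrix(as.integer(EBImage::imageData(comp)),
                    nrow = nrow(channel))
  ncomp <- max(compMat)
  out <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    idx <- which(compMat == k, arr.ind = TRUE)
    if (nrow(idx) < minFocusArea) next
    cr <- mean(idx[, 1]); cc <- mean(idx[, 2])
    parent <- mask[round(cr), round(cc)]
    if (parent == 0) next
    vals <- channel[idx]
    out[[k]] <- data.frame(
      label = as.integer(parent), row = cr - 1, col = cc - 1,
      area = nrow(idx),
      integrated_intensity = sum(vals),
      average_intensity = mean(vals),
      min_intensity = min(vals),
      max_intensity = max(vals))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(emptyFoci)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$label, res$row, res$col), , drop = FALSE]
}
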