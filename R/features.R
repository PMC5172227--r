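## Per-nucleus feature computation: the per-readout feature sets measured
## on segmented nuclei, matching the synthetic feature-table schema.

## boundary-pixel contour length: label pixels with at least one
## 4-neighbour outside the label (image edge counts as outside)
.perimeterLength <- function(inLabel) {
  p <- inLabel
  up <- rbind(inLabel[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, inLabel[-nrow(inLabel), , drop = FALSE])
  lf <- cbind(inLabel[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, inLabel[, -ncol(inLabel), drop = FALSE])
  sum(inLabel & !(up & dn & lf & rt))
}

## intensity-weighted second-moment ellipse axes (full lengths)
.momentAxes <- function(idx, w) {
  w <- w / sum(w)
  mr <- sum(idx[, 1] * w); mc <- sum(idx[, 2] * w)
  crr <- sum((idx[, 1] - mr)^2 * w)
  ccc <- sum((idx[, 2] - mc)^2 * w)
  crc <- sum((idx[, 1] - mr) * (idx[, 2] - mc) * w)
  ev <- eigen(matrix(c(crr, crc, crc, ccc), 2), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  c(length = 4 * sqrt(ev[1]), breadth = 4 * sqrt(ev[2]))
}

## 3x3 mean filter (used for the per-nucleus min/max average intensities)
.meanFilter3 <- function(mat) {
  k <- matrix(1 / 9, 3, 3)
  out <- EBImage::filter2(EBImage::Image(mat), k)
  matrix(as.numeric(EBImage::imageData(out)), nrow = nrow(mat))
}

#' Compute per-nucleus readout features
#'
#' Measures, for every labelled nucleus, the feature set of each readout
#' supplied in \code{channels}: seven morphology features from the DAPI /
#' morphology channel (integrated and average intensity, area, perimeter
#' by boundary-pixel contour length, cell length and breadth as the major
#' and minor axes of the intensity-weighted second-moment ellipse, and the
#' elliptical form factor length/breadth), focus summaries for the 53BP1
#' and gamma-H2AX channels, and average/integrated nuclear intensities for
#' p53 and EdU. Nuclei without detected foci get zero for all focus
#' features. Integrated intensity equals average intensity times area
#' exactly.
#'
#' @param mask integer label matrix.
#' @param channels named list of image matrices; names from
#'   \code{\link{screenReadouts}}. Every requested readout must be present.
#' @param foci optional named list of focus tables from
#'   \code{\link{detectFoci}} for the focal readouts; computed with default
#'   parameters when missing.
#' @return data.frame, one row per label, columns \code{label} plus
#'   \code{<readout>.<feature>} per \code{\link{readoutFeatures}}.
#' @export
computeNucleusFeatures <- function(mask, channels, foci = list()) {
  stopifnot(is.matrix(mask), is.list(channels), length(channels) > 0)
  bad <- setdiff(names(channels), screenReadouts())
  if (length(bad))
    stop("unknown readout(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (r in names(channels))
    if (!all(dim(channels[[r]]) == dim(mask)))
      stop("channel '", r, "' does not match the mask dimensions",
           call. = FALSE)
  labs <- sort(unique(mask[mask > 0]))
  for (r in intersect(c("b53bp1", "gh2ax"), names(channels)))
    if (is.null(foci[[r]]))
      foci[[r]] <- detectFoci(channels[[r]], mask)

  rows <- vector("list", length(labs))
  gh2axSmooth <- if ("gh2ax" %in% names(channels))
    .meanFilter3(channels$gh2ax) else NULL
  for (j in seq_along(labs)) {
    l <- labs[j]
    inl <- mask == l
    idx <- which(inl, arr.ind = TRUE)
    rec <- list(label = as.integer(l))
    if ("morphology" %in% names(channels)) {
      v <- channels$morphology[inl]
      area <- length(v)
      axes <- .momentAxes(idx, v)
      rec[["morphology.integrated_intensity"]] <- sum(v)
      rec[["morphology.average_intensity"]] <- sum(v) / area
      rec[["morphology.area"]] <- area
      rec[["morphology.perimeter"]] <- .perimeterLength(inl)
      rec[["morphology.length"]] <- axes[["length"]]
      rec[["morphology.breadth"]] <- axes[["breadth"]]
      rec[["morphology.form_factor"]] <-
        axes[["length"]] / max(axes[["breadth"]], .Machine$double.eps)
    }
    if ("b53bp1" %in% names(channels)) {
      f <- foci$b53bp1[foci$b53bp1$label == l, , drop = FALSE]
      rec[["b53bp1.foci_count"]] <- nrow(f)
      rec[["b53bp1.foci_area"]] <- sum(f$area)
      rec[["b53bp1.foci_intensity"]] <- sum(f$integrated_intensity)
    }
    if ("gh2ax" %in% names(channels)) {
      v <- channels$gh2ax[inl]
      f <- foci$gh2ax[foci$gh2ax$label == l, , drop = FALSE]
      rec[["gh2ax.nuc_integrated"]] <- sum(v)
      rec[["gh2ax.nuc_average"]] <- mean(v)
      rec[["gh2ax.min_average"]] <- min(gh2axSmooth[inl])
      rec[["gh2ax.max_average"]] <- max(gh2axSmooth[inl])
      rec[["gh2ax.foci_count"]] <- nrow(f)
      rec[["gh2ax.foci_area"]] <- sum(f$area)
      rec[["gh2ax.foci_intensity"]] <- sum(f$integrated_intensity)
      rec[["gh2ax.foci_average"]] <-
        if (nrow(f)) mean(f$average_intensity) else 0
      rec[["gh2ax.foci_min"]] <- if (nrow(f)) min(f$min_intensity) else 0
      rec[["gh2ax.foci_max"]] <- if (nrow(f)) max(f$max_intensity) else 0
    }
    for (r in intersect(c("p53", "edu"), names(channels))) {
      v <- channels[[r]][inl]
      rec[[paste0(r, ".average_intensity")]] <- mean(v)
      rec[[paste0(r, ".integrated_intensity")]] <- sum(v)
    }
    rows[[j]] <- as.data.frame(rec)
  }
  if (!length(rows)) {
    return(data.frame(label = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average summed focus intensity per mitotic cell
#'
#' Identifies mitotic cells as DAPI objects whose average intensity
#' exceeds \code{mitoticIntensityThreshold} (condensed mitotic chromatin
#' is markedly brighter than interphase chromatin), sums the integrated
#' intensities of the gamma-H2AX foci detected inside each mitotic cell,
#' and returns the mean of these per-cell sums over all mitotic cells.
#'
#' @param dapi,gh2ax aligned image matrices.
#' @param mitoticIntensityThreshold average-DAPI-intensity cutoff in
#'   camera units.
#' @param ... passed to \code{\link{detectFoci}}.
#' @return mean summed focus intensity per mitotic cell; 0 with a warning
#'   when no object exceeds the threshold.
#' @export
mitoticGammaH2AXScore <- function(dapi, gh2ax, mitoticIntensityThreshold,
                                  ...) {
  stopifnot(all(dim(dapi) == dim(gh2ax)))
  thr <- EBImage::otsu(.asEBImage(dapi), range = c(0, 1)) * 65535
  lab <- EBImage::bwlabel(EBImage::Image(dapi > thr))
  labMat <- matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(dapi))
  labs <- seq_len(max(labMat))
  mitotic <- labs[vapply(labs, function(l)
    mean(dapi[labMat == l]) > mitoticIntensityThreshold, logical(1))]
  if (!length(mitotic)) {
    warning("no mitotic cells above the intensity threshold; returning 0")
    return(0)
  }
  mitoMask <- matrix(0L, nrow = nrow(dapi), ncol = ncol(dapi))
  for (j in seq_along(mitotic))
    mitoMask[labMat == mitotic[j]] <- j
  f <- detectFoci(gh2ax, mitoMask, ...)
  sums <- vapply(seq_along(mitotic), function(j)
    sum(f$integrated_intensity[f$label == j]), numeric(1))
  mean(sums)
}
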