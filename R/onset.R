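## Temporal ordering of mitotic errors versus DNA-damage onset, and the
## onset-sorted heat-map layout.

#' Classify phenotype onset order for one condition
#'
#' Finds the first time the morphology fold change reaches
#' \code{mitoThreshold} (threefold over control by default) and the first
#' time the DNA-damage fold change reaches \code{ddrThreshold} (1.5-fold
#' by default). Conditions are split by which event occurs first in the
#' time series; conditions with milder increases in both readouts form
#' the "mild" group. A tie (both thresholds crossed at the same frame)
#' counts as mitosis-first. The sort key for heat-map ordering is the
#' first time point with increased DNA damage (the 1.5-fold crossing),
#' with conditions that never cross sorting last.
#'
#' @param morph morphology \code{\linkS4class{TimeCourse}}.
#' @param ddr DNA-damage \code{\linkS4class{TimeCourse}} on the same grid.
#' @param mitoThreshold morphology fold threshold (default 3.0).
#' @param ddrThreshold DNA-damage fold threshold (default 1.5).
#' @return one-row data.frame: condition, group ("mitosis-first",
#'   "ddr-first" or "mild"), t_mito, t_ddr (hours, NA when never
#'   crossed), sort_key.
#' @export
classifyOnset <- function(morph, ddr, mitoThreshold = 3.0,
                          ddrThreshold = 1.5) {
  stopifnot(is(morph, "TimeCourse"), is(ddr, "TimeCourse"))
  .checkSameGrid(morph@times, ddr@times)
  firstCross <- function(tc, thr) {
    i <- which(tc@folds >= thr)
    if (length(i)) tc@times[i[1]] else NA_real_
  }
  tMito <- firstCross(morph, mitoThreshold)
  tDdr <- firstCross(ddr, ddrThreshold)
  group <- if (is.na(tMito) && is.na(tDdr)) {
    "mild"
  } else if (!is.na(tMito) && (is.na(tDdr) || tMito <= tDdr)) {
    "mitosis-first"
  } else {
    "ddr-first"
  }
  data.frame(condition = morph@condition, group = group,
             t_mito = tMito, t_ddr = tDdr,
             sort_key = if (is.na(tDdr)) Inf else tDdr,
             stringsAsFactors = FALSE)
}

#' Build the onset-ordered heat-map matrix
#'
#' Stacks the conditions' fold-change series into a matrix ordered the
#' way the screen's heat map is read: the mild group at the top, then the
#' mitosis-first and ddr-first groups, each sorted ascending by the first
#' time point with increased DNA damage (never-crossing conditions last,
#' ties by condition name). The color convention anchors white at each
#' series' own mean, blue below (the control level 1 is on the blue
#' side), red above; see \code{\link{heatmapColors}}.
#'
#' @param timecourses named list of \code{\linkS4class{TimeCourse}}, one
#'   per condition, all on one frame grid.
#' @param classifications data.frame of \code{\link{classifyOnset}} rows
#'   covering the same conditions.
#' @return list with \code{matrix} (conditions x frames, ordered),
#'   \code{classifications} (rows in heat-map order), \code{times} and
#'   \code{anchors} (per-row color anchor = series mean).
#' @export
buildHeatmap <- function(timecourses, classifications) {
  if (!length(timecourses))
    stop("no time courses supplied", call. = FALSE)
  conds <- vapply(timecourses, slot, character(1), "condition")
  names(timecourses) <- conds
  if (!setequal(conds, classifications$condition))
    stop("classifications must cover exactly the supplied conditions",
         call. = FALSE)
  groupRank <- c("mild" = 1L, "mitosis-first" = 2L, "ddr-first" = 3L)
  cl <- classifications
  ord <- order(groupRank[cl$group], cl$sort_key, cl$condition)
  cl <- cl[ord, , drop = FALSE]
  rownames(cl) <- NULL
  times <- timecourses[[1]]@times
  for (tc in timecourses) .checkSameGrid(times, tc@times)
  m <- t(vapply(cl$condition,
                function(cn) timecourses[[cn]]@folds,
                numeric(length(times))))
  rownames(m) <- cl$condition
  list(matrix = m, classifications = cl, times = times,
       anchors = rowMeans(m))
}

#' Map fold changes to the blue-white-red heat-map colors
#'
#' Monotone value-to-color mapping with white exactly at the anchor (by
#' default the series mean), shades of blue below it and shades of red
#' above it. A constant series maps entirely to white.
#'
#' @param values numeric fold changes of one series.
#' @param anchor value mapped to white (default \code{mean(values)}).
#' @return character vector of colors, one per value.
#' @export
heatmapColors <- function(values, anchor = mean(values)) {
  lo <- anchor - min(values)
  hi <- max(values) - anchor
  cols <- character(length(values))
  blue <- grDevices::colorRamp(c("white", "#2166AC"))
  red <- grDevices::colorRamp(c("white", "#B2182B"))
  for (i in seq_along(values)) {
    d <- values[i] - anchor
    cols[i] <- if (d < 0 && lo > 0) {
      grDevices::rgb(blue(min(-d / lo, 1)), maxColorValue = 255)
    } else if (d > 0 && hi > 0) {
      grDevices::rgb(red(min(d / hi, 1)), maxColorValue = 255)
    } else {
      "#FFFFFF"
    }
  }
  cols
}
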