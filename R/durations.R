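## Duration estimators on per-frame trajectory tables. Both estimators
## median-smooth the per-frame state indicator (removing isolated
## misclassified frames) and use the longest contiguous run, which is
## exact on noiseless trajectories and robust to spurious single-frame
## flips after smoothing.

.medianSmooth <- function(ind, window) {
  if (window <= 1L || length(ind) < window) return(ind)
  if (window %% 2L == 0L) window <- window + 1L
  stats::runmed(as.numeric(ind), k = window, endrule = "keep") > 0.5
}

.longestRun <- function(ind) {
  if (!any(ind)) return(0L)
  r <- rle(ind)
  max(r$lengths[r$values])
}

.frameInterval <- function(time_h) {
  dt <- unique(round(diff(sort(unique(time_h))), 8))
  if (length(dt) != 1L)
    stop("trajectory frames are not uniformly spaced", call. = FALSE)
  dt
}

#' Mean mitotic duration from trajectories
#'
#' Per cell, the longest contiguous run of the (median-smoothed) mitotic
#' state times the frame interval; the mean is taken over all cells that
#' show a mitotic run. Results from fewer than \code{minCells}
#' contributing cells are returned with a warning, mirroring the
#' convention of averaging at least 25 manually tracked cells.
#'
#' @param traj trajectory data.frame (long format).
#' @param minCells minimum contributing cells before warning (default 25).
#' @param smoothWindow median-filter window in frames (default 3; 1
#'   disables smoothing).
#' @return mean mitotic duration in hours.
#' @export
mitoticDuration <- function(traj, minCells = 25L, smoothWindow = 3L) {
  stopifnot(all(c("cell_id", "time_h", "state") %in% names(traj)))
  dt <- .frameInterval(traj$time_h)
  runs <- vapply(split(traj, traj$cell_id), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    .longestRun(.medianSmooth(d$state == "mitotic", smoothWindow))
  }, integer(1))
  runs <- runs[runs > 0]
  if (!length(runs))
    stop("no mitotic cells in the trajectories", call. = FALSE)
  if (length(runs) < minCells)
    warning("only ", length(runs), " cells contribute (minimum ",
            minCells, " recommended)")
  mean(runs) * dt
}

#' Mean S-phase duration from trajectories
#'
#' Per cell, the S-pattern indicator is median-filtered (window
#' \code{smoothWindow} frames) and the duration is the longest contiguous
#' S run times the frame interval; the mean is over all cells with an S
#' run.
#'
#' @param traj trajectory data.frame with a replication_pattern column.
#' @param smoothWindow median-filter window in frames (default 3).
#' @return mean S-phase duration in hours.
#' @export
estimateSPhaseDuration <- function(traj, smoothWindow = 3L) {
  stopifnot(all(c("cell_id", "time_h", "replication_pattern") %in%
                names(traj)))
  dt <- .frameInterval(traj$time_h)
  runs <- vapply(split(traj, traj$cell_id), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    .longestRun(.medianSmooth(d$replication_pattern == "S-pattern",
                              smoothWindow))
  }, integer(1))
  runs <- runs[runs > 0]
  if (!length(runs))
    stop("no S-phase cells in the trajectories", call. = FALSE)
  mean(runs) * dt
}

#' Replication asymmetry between the two nuclei of binucleated cells
#'
#' For cells carrying two nuclei in a common cytoplasm (after cytokinesis
#' failure), replication of the two nuclei need not be synchronized. The
#' per-cell shift is the absolute difference between the S-phase start
#' times of nucleus A and nucleus B in hours; cells in which one nucleus
#' never replicates are excluded and counted.
#'
#' @param traj long-format data.frame with columns cell_id, time_h,
#'   nucleus (two levels per cell) and replication_pattern.
#' @return list with \code{perCell} (cell_id, shift_h), \code{mean},
#'   \code{max} and \code{nExcluded}.
#' @export
replicationAsymmetry <- function(traj) {
  stopifnot(all(c("cell_id", "time_h", "nucleus",
                  "replication_pattern") %in% names(traj)))
  excluded <- 0L
  rows <- list()
  for (d in split(traj, traj$cell_id)) {
    nuc <- unique(d$nucleus)
    if (length(nuc) != 2L)
      stop("cell ", d$cell_id[1], " does not have exactly two nuclei",
           call. = FALSE)
    starts <- vapply(nuc, function(nn) {
      dd <- d[d$nucleus == nn, , drop = FALSE]
      dd <- dd[order(dd$time_h), , drop = FALSE]
      i <- which(dd$replication_pattern == "S-pattern")
      if (length(i)) dd$time_h[i[1]] else NA_real_
    }, numeric(1))
    if (anyNA(starts)) {
      excluded <- excluded + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = d$cell_id[1], shift_h = abs(starts[1] - starts[2]))
  }
  perCell <- if (length(rows)) do.call(rbind, rows)
             else data.frame(cell_id = integer(), shift_h = numeric())
  rownames(perCell) <- NULL
  list(perCell = perCell,
       mean = if (nrow(perCell)) mean(perCell$shift_h) else NA_real_,
       max = if (nrow(perCell)) max(perCell$shift_h) else NA_real_,
       nExcluded = excluded)
}
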