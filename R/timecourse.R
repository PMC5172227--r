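## Control-normalized time courses from per-frame trajectory tables.

#' Per-frame population fractions and focus counts
#'
#' Summarizes a long-format trajectory table per frame: the fractions of
#' cells with aberrant nuclear morphology, in mitosis and dead (over all
#' cells), and the mean 53BP1 focus count per interphase cell.
#'
#' @param traj trajectory data.frame from
#'   \code{\link{generateTrajectories}} (columns cell_id, frame, time_h,
#'   state, foci_count, replication_pattern, aberrant_flag).
#' @return data.frame per frame: frame, time_h, frac_aberrant,
#'   frac_mitotic, frac_dead, mean_foci_interphase, n_interphase, n_cells.
#' @export
frameFractions <- function(traj) {
  need <- c("cell_id", "frame", "time_h", "state", "foci_count",
            "aberrant_flag")
  miss <- setdiff(need, names(traj))
  if (length(miss))
    stop("trajectory table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sp <- split(traj, traj$frame)
  rows <- lapply(sp, function(d) {
    inter <- d$state == "interphase"
    data.frame(
      frame = d$frame[1], time_h = d$time_h[1],
      frac_aberrant = mean(d$aberrant_flag),
      frac_mitotic = mean(d$state == "mitotic"),
      frac_dead = mean(d$state == "dead"),
      mean_foci_interphase = if (any(inter)) mean(d$foci_count[inter])
                             else NA_real_,
      n_interphase = sum(inter),
      n_cells = nrow(d))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.checkSameGrid <- function(t1, t2) {
  if (length(t1) != length(t2) || max(abs(t1 - t2)) > 1e-8)
    stop("condition and control are on different frame grids",
         call. = FALSE)
  invisible(TRUE)
}

#' Composite morphology-aberration time course
#'
#' The composite morphology value per frame is the sum of the fractions
#' of aberrant, mitotic and dead cells; it is normalized to the control
#' wells at each time point over the entire recording. The control
#' composite is floored at \code{epsilon} to keep early-time folds finite
#' when almost no control cell shows any phenotype.
#'
#' @param fractions per-frame fractions for the condition (from
#'   \code{\link{frameFractions}}).
#' @param controlFractions same for the control condition, same grid.
#' @param condition condition key stored in the result.
#' @param epsilon control floor (default 1e-3).
#' @return a \code{\linkS4class{TimeCourse}}.
#' @export
compositeMorphology <- function(fractions, controlFractions,
                                condition = "condition",
                                epsilon = 1e-3) {
  .checkSameGrid(fractions$time_h, controlFractions$time_h)
  comp <- fractions$frac_aberrant + fractions$frac_mitotic +
    fractions$frac_dead
  ctl <- controlFractions$frac_aberrant + controlFractions$frac_mitotic +
    controlFractions$frac_dead
  folds <- pmax(comp, epsilon) / pmax(ctl, epsilon)
  new("TimeCourse", condition = condition, times = fractions$time_h,
      values = comp, folds = folds)
}

#' DNA-damage (53BP1 foci per interphase cell) time course
#'
#' Mean focus count per interphase cell per frame, normalized to the
#' control wells frame by frame. Frames with zero interphase cells carry
#' the previous frame's value forward with a warning.
#'
#' @inheritParams compositeMorphology
#' @return a \code{\linkS4class{TimeCourse}}.
#' @export
ddrTimecourse <- function(fractions, controlFractions,
                          condition = "condition", epsilon = 1e-3) {
  .checkSameGrid(fractions$time_h, controlFractions$time_h)
  fill <- function(v, who) {
    if (anyNA(v)) {
      warning("frames with zero interphase cells in ", who,
              "; carrying previous value forward")
      for (i in seq_along(v)) {
        if (is.na(v[i])) v[i] <- if (i > 1) v[i - 1] else 0
      }
    }
    v
  }
  val <- fill(fractions$mean_foci_interphase, "condition")
  ctl <- fill(controlFractions$mean_foci_interphase, "control")
  folds <- pmax(val, epsilon) / pmax(ctl, epsilon)
  new("TimeCourse", condition = condition, times = fractions$time_h,
      values = val, folds = folds)
}

setMethod("frameTimes", "TimeCourse", function(x) x@times)
setMethod("foldChanges", "TimeCourse", function(x) x@folds)

setMethod("show", "TimeCourse", function(object) {
  cat("TimeCourse [", object@condition, "]:", length(object@times),
      "frames,", object@times[1], "-", object@times[length(object@times)],
      "h\n")
  cat("  fold range:", round(min(object@folds), 3), "-",
      round(max(object@folds), 3), "\n")
})
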