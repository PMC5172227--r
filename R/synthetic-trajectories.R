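## Synthetic single-cell time-lapse trajectories.
##
## Each trajectory follows one cell through one cell cycle on the frame
## grid: G1, S (PCNA-like replication pattern), G2, a single mitosis whose
## duration carries the planted mitotic delay, then interphase (or
## binucleation after cytokinesis failure), with optional death and a
## planted DDR-onset time after which 53BP1 focus counts jump to the
## elevated rate. Cells that already went through one or two aberrant
## mitoses before the recording carry escalating S-phase extensions:
## base + ext after the first, base + 3*ext after the second aberrant
## mitosis (KIF23-like: 16 h -> 18 h -> 22 h for ext = 2 h).

.TRAJ_BASELINE <- list(
  g1_mean = 3, g1_sd = 1,          # hours until S entry
  s_mean = 16, s_sd = 1,           # control S-phase duration (hours)
  g2_mean = 4, g2_sd = 0.5,
  mito_mean = 1, mito_sd = 0.15,   # unperturbed mitosis (hours)
  foci_rate = 0.8,                 # 53BP1 foci per interphase cell
  base_aberrant = 0.02             # always-on aberrant-morphology rate
)

.conditionTrajParams <- function(config, condition) {
  if (condition == config@controlLabel) {
    return(list(mito_delay = 0, death_prob = 0.02, ddr_onset = NA_real_,
                s_ext = 0, aberrant_frac = 0.05, cytokinesis_failure = 0,
                ddr_mult = 1))
  }
  et <- config@effectTable
  i <- match(condition, et$target)
  if (is.na(i))
    stop("condition '", condition, "' not present in the effect table",
         call. = FALSE)
  list(mito_delay = et$mito_delay_h[i],
       death_prob = et$death_prob[i],
       ddr_onset = et$ddr_onset_h[i],
       s_ext = et$s_extension_h[i],
       aberrant_frac = et$aberrant_frac[i],
       cytokinesis_failure = et$cytokinesis_failure[i],
       ## time-lapse focus-rate elevation after DDR onset
       ddr_mult = exp(0.8 * et$shift_b53bp1[i]))
}

#' Generate synthetic single-cell time-lapse trajectories
#'
#' Simulates per-frame cell states, 53BP1 focus counts, replication
#' pattern and the aberrant-morphology flag for one condition of a screen
#' configuration, together with the per-cell planted event times. All
#' planted durations are rounded to the frame grid, so on noiseless
#' trajectories every event is exactly recoverable. Per-frame
#' misclassification noise (rate \code{noiseRate}) randomly corrupts the
#' observed state, replication pattern and aberrant flag of non-dead
#' frames; the death state is absorbing and never corrupted.
#'
#' @param config a \code{\linkS4class{ScreenConfig}}; supplies the frame
#'   grid and the effect table.
#' @param condition the control label or a target present in the effect
#'   table.
#' @param nCells number of cells.
#' @param seed RNG seed.
#' @param noiseRate per-frame misclassification rate; defaults to
#'   \code{config@noiseRate}.
#' @return list with \code{trajectories}, a long-format data.frame
#'   (cell_id, frame, time_h, state, foci_count, replication_pattern,
#'   aberrant_flag), and \code{truth}, one row per cell with planted
#'   s_start/s_end, mitosis_entry/mitosis_exit, death_time, ddr_onset,
#'   prior_aberrant count and flags.
#' @examples
#' cfg <- screenConfig(nTargets = 4, duration = 24)
#' tr <- generateTrajectories(cfg, "NEG", nCells = 3, seed = 1,
#'                            noiseRate = 0)
#' head(tr$trajectories)
#' @export
generateTrajectories <- function(config, condition, nCells,
                                 seed = config@seed,
                                 noiseRate = config@noiseRate) {
  validObject(config)
  stopifnot(nCells >= 1, noiseRate >= 0, noiseRate < 1)
  p <- .conditionTrajParams(config, condition)
  b <- .TRAJ_BASELINE
  dt <- config@frameInterval
  nf <- nFrames(config)
  times <- (seq_len(nf) - 1L) * dt
  snap <- function(x) round(x / dt) * dt   # snap to the frame grid

  withr::with_seed(seed, {
    truth <- data.frame(cell_id = seq_len(nCells))
    isCtl <- condition == config@controlLabel
    ## aberrant mitoses completed before the recording started
    truth$prior_aberrant <- if (isCtl) 0L
      else rbinom(nCells, 2L, p$aberrant_frac)
    sDur <- rnorm(nCells, b$s_mean, b$s_sd) +
      p$s_ext * (2^truth$prior_aberrant - 1)
    g1 <- pmax(rnorm(nCells, b$g1_mean, b$g1_sd), dt)
    g2 <- pmax(rnorm(nCells, b$g2_mean, b$g2_sd), dt)
    mDur <- pmax(rnorm(nCells, b$mito_mean, b$mito_sd) + p$mito_delay, dt)

    truth$s_start <- snap(g1)
    truth$s_end <- snap(truth$s_start + pmax(sDur, dt))
    truth$mitosis_entry <- snap(truth$s_end + g2)
    truth$mitosis_exit <- pmin(snap(truth$mitosis_entry + mDur),
                               config@duration)
    truth$aberrant_after <- runif(nCells) < p$aberrant_frac
    truth$base_aberrant <- runif(nCells) < b$base_aberrant
    truth$binucleated <- runif(nCells) < p$cytokinesis_failure
    dies <- runif(nCells) < p$death_prob
    truth$death_time <- ifelse(
      dies, snap(truth$mitosis_exit +
                 runif(nCells) *
                   pmax(config@duration - truth$mitosis_exit, 0)),
      NA_real_)
    truth$ddr_onset <- if (is.na(p$ddr_onset)) NA_real_
                       else rep(snap(p$ddr_onset), nCells)

    rows <- vector("list", nCells)
    for (i in seq_len(nCells)) {
      state <- rep("interphase", nf)
      inMito <- times >= truth$mitosis_entry[i] &
                times < truth$mitosis_exit[i]
      state[inMito] <- "mitotic"
      if (truth$binucleated[i])
        state[times >= truth$mitosis_exit[i]] <- "binucleated"
      sPat <- times >= truth$s_start[i] & times < truth$s_end[i]
      aber <- rep(truth$base_aberrant[i], nf)
      if (truth$aberrant_after[i])
        aber[times >= truth$mitosis_exit[i]] <- TRUE
      rate <- rep(b$foci_rate, nf)
      if (!is.na(truth$ddr_onset[i]))
        rate[times >= truth$ddr_onset[i]] <- b$foci_rate * p$ddr_mult
      foci <- rpois(nf, rate)
      if (!is.na(truth$death_time[i])) {
        deadFrom <- times >= truth$death_time[i]
        state[deadFrom] <- "dead"
        sPat[deadFrom] <- FALSE
        aber[deadFrom] <- FALSE
        foci[deadFrom] <- 0L
      }
      if (noiseRate > 0) {
        alive <- state != "dead"
        flip <- alive & runif(nf) < noiseRate
        if (any(flip)) {
          others <- c("interphase", "mitotic", "binucleated")
          state[flip] <- vapply(state[flip], function(s)
            sample(setdiff(others, s), 1L), character(1))
        }
        flipS <- alive & runif(nf) < noiseRate
        sPat[flipS] <- !sPat[flipS]
        flipA <- alive & runif(nf) < noiseRate
        aber[flipA] <- !aber[flipA]
      }
      rows[[i]] <- data.frame(
        cell_id = i, frame = seq_len(nf) - 1L, time_h = times,
        state = state, foci_count = foci,
        replication_pattern = ifelse(sPat, "S-pattern", "none"),
        aberrant_flag = aber, stringsAsFactors = FALSE)
    }
  })
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  list(trajectories = traj, truth = truth)
}

#' Write / read a trajectory table as CSV
#'
#' @param traj long-format trajectory data.frame.
#' @param path file path.
#' @return \code{readTrajectories} returns the data.frame.
#' @export
writeTrajectories <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectories
#' @export
readTrajectories <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
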