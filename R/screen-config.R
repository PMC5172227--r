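#' Default planted effect table
#'
#' Builds the per-target effect table the synthetic screen plants. Targets
#' are assigned round-robin to four phenotype archetypes mirroring the four
#' phenotypic clusters a mitotic-perturbation screen resolves: (1) mild
#' responses, (2) mitotic-error-dominant with little DNA damage, (3) mitotic
#' errors with a strong DNA-damage response, (4) strong combined phenotypes.
#' Within an archetype, per-target strengths are varied by a deterministic
#' jitter so effect magnitudes are graded rather than tied, which lets
#' rank-recovery checks compare planted order against recovered scores.
#'
#' Columns: per-readout standardized mean shifts (`shift_<readout>`),
#' focus-rate multipliers for the two DSB markers (`foci_mult_*`, equal to
#' `exp(0.4 * shift)`), and the temporal parameters used by the trajectory
#' generator: mitotic delay (h), per-cell death probability, DDR onset time
#' (h, NA for none), S-phase extension per aberrant mitosis (h), fraction of
#' cells with aberrant morphology after mitosis, and the probability of
#' cytokinesis failure (binucleation).
#'
#' @param nTargets number of targets.
#' @return data.frame with one row per target.
#' @export
defaultEffectTable <- function(nTargets = 47L) {
  i <- seq_len(nTargets)
  cluster <- ((i - 1L) %% 4L) + 1L
  ## deterministic per-target jitter in [0.75, 1.25]
  jitter <- 0.75 + 0.5 * ((i * 7L) %% 11L) / 10
  base <- c(0.3, 1.0, 1.6, 2.4)[cluster]
  strength <- base * jitter
  w <- rbind(
    c(0.30, 0.30, 0.30, 0.30, 0.30),  # mild
    c(1.00, 0.35, 0.35, 0.90, 0.50),  # mitotic-dominant
    c(0.80, 1.00, 1.00, 0.70, 0.80),  # mitotic + strong DDR
    c(1.10, 1.10, 1.10, 1.00, 1.00)   # strong combined
  )
  colnames(w) <- screenReadouts()
  shifts <- w[cluster, , drop = FALSE] * strength
  out <- data.frame(
    target = sprintf("T%02d", i),
    cluster = cluster,
    strength = strength,
    stringsAsFactors = FALSE
  )
  for (r in screenReadouts())
    out[[paste0("shift_", r)]] <- shifts[, r]
  out$foci_mult_b53bp1 <- exp(0.4 * out$shift_b53bp1)
  out$foci_mult_gh2ax <- exp(0.4 * out$shift_gh2ax)
  out$mito_delay_h <- c(0.5, 6, 2, 8)[cluster] * jitter
  out$death_prob <- c(0.02, 0.15, 0.10, 0.30)[cluster]
  ## cluster 3 is the DDR-first archetype: damage rises well before the
  ## bulk of (mildly delayed) mitoses; cluster 4 damages right after its
  ## strongly aberrant mitoses; cluster 2 is mitosis-first with sub-1.5x
  ## damage; cluster 1 stays mild on both axes
  out$ddr_onset_h <- c(NA, 40, 12, 26)[cluster]
  out$s_extension_h <- c(0, 2, 4, 6)[cluster]
  out$aberrant_frac <- c(0.05, 0.50, 0.25, 0.70)[cluster]
  out$cytokinesis_failure <- c(0.00, 0.30, 0.20, 0.40)[cluster]
  out
}

#' Null effect table (no planted effects)
#'
#' All shifts zero, all multipliers one, and temporal parameters equal to
#' the control baseline; conditions generated from it are statistically
#' identical to control.
#'
#' @param nTargets number of targets.
#' @return data.frame with one row per target.
#' @export
nullEffectTable <- function(nTargets = 47L) {
  et <- defaultEffectTable(nTargets)
  et$cluster <- 1L
  et$strength <- 0
  for (r in screenReadouts()) et[[paste0("shift_", r)]] <- 0
  et$foci_mult_b53bp1 <- 1
  et$foci_mult_gh2ax <- 1
  et$mito_delay_h <- 0
  et$death_prob <- 0.02
  et$ddr_onset_h <- NA_real_
  et$s_extension_h <- 0
  et$aberrant_frac <- 0.05
  et$cytokinesis_failure <- 0
  et
}

#' Construct a screen configuration
#'
#' @param nTargets number of target genes (default 47).
#' @param sirnasPerTarget independent siRNAs per target (default 2).
#' @param nReplicates biological replicates (default 3).
#' @param meanCellsPerSirna screen-wide mean cells per siRNA well
#'   (default 700).
#' @param frameInterval time-lapse frame interval in hours (default 0.5).
#' @param duration time-lapse duration in hours (default 72).
#' @param controlLabel label of the negative-control condition
#'   (default "NEG").
#' @param noiseRate per-frame misclassification rate for trajectories
#'   (default 0.05).
#' @param effectTable planted effects; defaults to
#'   \code{\link{defaultEffectTable}(nTargets)}.
#' @param seed integer RNG seed (default 42).
#' @return a validated \code{\linkS4class{ScreenConfig}}.
#' @examples
#' cfg <- screenConfig(nTargets = 4, meanCellsPerSirna = 50)
#' cfg
#' @export
screenConfig <- function(nTargets = 47L, sirnasPerTarget = 2L,
                         nReplicates = 3L, meanCellsPerSirna = 700,
                         frameInterval = 0.5, duration = 72,
                         controlLabel = "NEG", noiseRate = 0.05,
                         effectTable = defaultEffectTable(nTargets),
                         seed = 42L) {
  new("ScreenConfig",
      nTargets = as.integer(nTargets),
      sirnasPerTarget = as.integer(sirnasPerTarget),
      nReplicates = as.integer(nReplicates),
      meanCellsPerSirna = as.numeric(meanCellsPerSirna),
      frameInterval = as.numeric(frameInterval),
      duration = as.numeric(duration),
      controlLabel = as.character(controlLabel),
      noiseRate = as.numeric(noiseRate),
      effectTable = effectTable,
      seed = as.integer(seed))
}

#' @describeIn screenConfig number of frames per trajectory
#'   (duration / frameInterval + 1).
#' @param config a \code{ScreenConfig}.
#' @export
nFrames <- function(config) {
  as.integer(round(config@duration / config@frameInterval)) + 1L
}

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig:", object@nTargets, "targets x",
      object@sirnasPerTarget, "siRNAs x", object@nReplicates,
      "replicates\n")
  cat("  mean cells/siRNA:", object@meanCellsPerSirna,
      "| control:", object@controlLabel, "\n")
  cat("  time-lapse:", object@duration, "h at",
      object@frameInterval * 60, "min intervals (",
      nFrames(object), "frames ), frame noise", object@noiseRate, "\n")
  cat("  seed:", object@seed, "\n")
})
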