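## Shared small screens, generated once per test run.

.fixtures <- new.env(parent = emptyenv())

## 6 targets x 2 siRNAs x 3 replicates, ~60 cells per well: big enough
## for stable LR fits, small enough to keep the suite fast
smallScreen <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- screenConfig(nTargets = 6, meanCellsPerSirna = 60, seed = 5)
    .fixtures$small <- c(generateFeatureTable(cfg), list(config = cfg))
  }
  .fixtures$small
}

## the full default screen (47 x 2 x 3, ~700 cells/siRNA); generated once
defaultScreen <- function() {
  if (is.null(.fixtures$default)) {
    cfg <- screenConfig()
    .fixtures$default <- c(generateFeatureTable(cfg), list(config = cfg))
  }
  .fixtures$default
}

nullScreen <- function() {
  if (is.null(.fixtures$null)) {
    cfg <- screenConfig(nTargets = 8, meanCellsPerSirna = 120,
                        effectTable = nullEffectTable(8), seed = 9)
    .fixtures$null <- c(generateFeatureTable(cfg), list(config = cfg))
  }
  .fixtures$null
}

## single-readout feature table with hand-planted per-siRNA shifts on the
## 53BP1 feature set; returns the table plus the planted shift per siRNA
plantedSirnaTable <- function(shifts, nPerSirna = 150, nControl = 400,
                              nReplicates = 3, seed = 101) {
  cols <- featureColumns("b53bp1")
  withr::with_seed(seed, {
    mk <- function(sirna, target, rep_i, n, d) {
      X <- data.frame(
        rpois(n, 2 * exp(0.4 * d)),
        rlnorm(n, log(12) + 0.4 * d, 0.4),
        rlnorm(n, log(8000) + 0.5 * d, 0.5))
      names(X) <- cols
      cbind(data.frame(target = target, sirna_id = sirna,
                       replicate = rep_i, well = sirna,
                       cell_id = seq_len(n), stringsAsFactors = FALSE),
            X)
    }
    pieces <- list()
    for (rep_i in seq_len(nReplicates)) {
      pieces[[length(pieces) + 1L]] <-
        mk("CTRL", "CTRL", rep_i, nControl, 0)
      for (i in seq_along(shifts))
        pieces[[length(pieces) + 1L]] <-
          mk(sprintf("S%02d", i), sprintf("G%02d", i), rep_i,
             nPerSirna, shifts[i])
    }
  })
  tab <- do.call(rbind, pieces)
  rownames(tab) <- NULL
  list(cells = tab, shifts = structure(shifts,
                                       names = sprintf("S%02d",
                                                       seq_along(shifts))))
}
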