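## Synthetic single-cell feature tables with planted ground truth.
##
## Control cells are drawn from fixed baseline distributions: log-normal
## for intensity-type features, Normal for shape features, Poisson for
## focus counts. A treated condition shifts each readout's features by a
## standardized mean shift (on the log scale for log-normal features) and
## multiplies focus-count rates by the planted rate factor.

## second siRNA against the same target is modelled as a slightly weaker
## knockdown; concordance between the two stays below 1 as in real screens
.SIRNA_ATTENUATION <- c(1.0, 0.8)

.featureBaselines <- function() {
  ln <- function(m, s) list(dist = "lnorm", meanlog = log(m), sdlog = s)
  no <- function(m, s) list(dist = "norm", mean = m, sd = s)
  po <- function(l) list(dist = "pois", lambda = l)
  list(
    morphology = list(
      integrated_intensity = ln(5e5, 0.30),
      average_intensity = ln(250, 0.25),
      area = no(2000, 300),
      perimeter = no(170, 20),
      length = no(58, 7),
      breadth = no(44, 5),
      form_factor = no(1.32, 0.15)
    ),
    b53bp1 = list(
      foci_count = po(2),
      foci_area = ln(12, 0.4),
      foci_intensity = ln(8000, 0.5)
    ),
    gh2ax = list(
      nuc_integrated = ln(3e5, 0.35),
      nuc_average = ln(150, 0.30),
      min_average = ln(60, 0.30),
      max_average = ln(400, 0.35),
      foci_count = po(1.5),
      foci_area = ln(10, 0.4),
      foci_intensity = ln(6000, 0.5),
      foci_average = ln(600, 0.30),
      foci_min = ln(200, 0.30),
      foci_max = ln(900, 0.35)
    ),
    p53 = list(
      average_intensity = ln(120, 0.35),
      integrated_intensity = ln(2.4e5, 0.40)
    ),
    edu = list(
      average_intensity = ln(180, 0.45),
      integrated_intensity = ln(3.6e5, 0.50)
    )
  )
}

## draw n cells' features for one condition; shifts is a named numeric of
## per-readout standardized shifts, fociMults a named numeric of count-rate
## multipliers for the DSB-marker readouts
.drawConditionFeatures <- function(n, shifts, fociMults) {
  base <- .featureBaselines()
  out <- vector("list", sum(lengths(base)))
  nms <- character(length(out))
  j <- 0L
  for (r in names(base)) {
    d <- shifts[[r]]
    for (f in names(base[[r]])) {
      p <- base[[r]][[f]]
      x <- switch(p$dist,
        lnorm = rlnorm(n, p$meanlog + d * p$sdlog, p$sdlog),
        norm = rnorm(n, p$mean + d * p$sd, p$sd),
        pois = rpois(n, p$lambda * (fociMults[[r]] %||% 1))
      )
      if (f == "form_factor") x <- pmax(x, 1)
      j <- j + 1L
      out[[j]] <- x
      nms[j] <- paste(r, f, sep = ".")
    }
  }
  names(out) <- nms
  as.data.frame(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## proliferation penalty: relative cell count exp(-coef * mitotic-error
## strength), coupling planted mitotic errors to reduced proliferation
.PROLIF_COEF <- 0.3

.conditionPlan <- function(config) {
  et <- config@effectTable
  S <- config@sirnasPerTarget
  plan <- expand.grid(sirna_no = seq_len(S), row = seq_len(nrow(et)),
                      KEEP.OUT.ATTRS = FALSE)
  atten <- .SIRNA_ATTENUATION[pmin(plan$sirna_no, length(.SIRNA_ATTENUATION))]
  cond <- data.frame(
    target = et$target[plan$row],
    sirna_id = paste0(et$target[plan$row], "_s", plan$sirna_no),
    cluster = et$cluster[plan$row],
    stringsAsFactors = FALSE
  )
  for (r in screenReadouts())
    cond[[paste0("shift_", r)]] <- et[[paste0("shift_", r)]][plan$row] * atten
  cond$foci_mult_b53bp1 <- exp(0.4 * cond$shift_b53bp1)
  cond$foci_mult_gh2ax <- exp(0.4 * cond$shift_gh2ax)
  cond$prolif_mult <- exp(-.PROLIF_COEF * cond$shift_morphology)
  cond
}

#' Generate a synthetic per-cell feature table with ground truth
#'
#' Simulates the fixed-cell arm of a high-content screen: one row per
#' segmented cell carrying all five readouts' features, keyed by target,
#' siRNA, replicate, well and cell id, plus the control condition in every
#' replicate. Cell counts per well are Poisson; anti-proliferative
#' conditions get proportionally fewer cells via the planted proliferation
#' multiplier, while the Poisson baseline is calibrated so the screen-wide
#' mean matches \code{meanCellsPerSirna}. Deterministic given
#' \code{config@seed}.
#'
#' @param config a \code{\linkS4class{ScreenConfig}}.
#' @return list with elements \code{cells} (the feature table) and
#'   \code{truth} (planted effects per condition, cluster labels,
#'   per-well cell counts and proliferation multipliers).
#' @examples
#' scr <- generateFeatureTable(screenConfig(nTargets = 2,
#'                                          meanCellsPerSirna = 30))
#' head(scr$cells[, 1:7])
#' @export
generateFeatureTable <- function(config) {
  validObject(config)
  cond <- .conditionPlan(config)
  R <- config@nReplicates
  ## calibrate the Poisson baseline so the screen-wide mean cell count per
  ## well equals the configured mean despite proliferation penalties
  mults <- c(cond$prolif_mult, 1)            # siRNA conditions + control
  baseLambda <- config@meanCellsPerSirna / mean(mults)
  zeroShift <- structure(as.list(rep(0, 5)), names = screenReadouts())

  withr::with_seed(config@seed, {
    pieces <- list()
    counts <- list()
    wellNo <- 0L
    for (rep_i in seq_len(R)) {
      ## control well for this replicate
      wellNo <- wellNo + 1L
      n0 <- rpois(1L, baseLambda)
      ctl <- .drawConditionFeatures(n0, zeroShift,
                                    list(b53bp1 = 1, gh2ax = 1))
      pieces[[length(pieces) + 1L]] <- cbind(
        data.frame(target = config@controlLabel,
                   sirna_id = config@controlLabel,
                   replicate = rep_i,
                   well = sprintf("W%03d", wellNo),
                   cell_id = seq_len(n0),
                   stringsAsFactors = FALSE),
        ctl)
      counts[[length(counts) + 1L]] <- data.frame(
        target = config@controlLabel, sirna_id = config@controlLabel,
        replicate = rep_i, n_cells = n0, prolif_mult = 1)
      for (ci in seq_len(nrow(cond))) {
        wellNo <- wellNo + 1L
        n <- rpois(1L, baseLambda * cond$prolif_mult[ci])
        shifts <- as.list(cond[ci, paste0("shift_", screenReadouts())])
        names(shifts) <- screenReadouts()
        fm <- list(b53bp1 = cond$foci_mult_b53bp1[ci],
                   gh2ax = cond$foci_mult_gh2ax[ci])
        feats <- .drawConditionFeatures(n, shifts, fm)
        pieces[[length(pieces) + 1L]] <- cbind(
          data.frame(target = cond$target[ci],
                     sirna_id = cond$sirna_id[ci],
                     replicate = rep_i,
                     well = sprintf("W%03d", wellNo),
                     cell_id = seq_len(n),
                     stringsAsFactors = FALSE),
          feats)
        counts[[length(counts) + 1L]] <- data.frame(
          target = cond$target[ci], sirna_id = cond$sirna_id[ci],
          replicate = rep_i, n_cells = n,
          prolif_mult = cond$prolif_mult[ci])
      }
    }
    cells <- do.call(rbind, pieces)
    rownames(cells) <- NULL
    cellCounts <- do.call(rbind, counts)
    rownames(cellCounts) <- NULL
  })

  effLong <- do.call(rbind, lapply(screenReadouts(), function(r) {
    data.frame(target = cond$target, sirna_id = cond$sirna_id,
               readout = r, shift = cond[[paste0("shift_", r)]],
               foci_mult = if (r %in% c("b53bp1", "gh2ax"))
                 cond[[paste0("foci_mult_", r)]] else 1,
               stringsAsFactors = FALSE)
  }))
  rownames(effLong) <- NULL
  truth <- list(
    effects = effLong,
    clusters = unique(data.frame(target = cond$target,
                                 cluster = cond$cluster,
                                 stringsAsFactors = FALSE)),
    counts = cellCounts,
    baseLambda = baseLambda
  )
  list(cells = cells, truth = truth)
}

#' Write / read a feature table as CSV
#'
#' @param cells feature table as returned by
#'   \code{\link{generateFeatureTable}}.
#' @param path file path.
#' @return \code{readFeatureTable} returns the table; \code{writeFeatureTable}
#'   returns \code{path} invisibly.
#' @export
writeFeatureTable <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
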