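## Ensemble selection, per-cell scoring and leave-one-replicate-out
## validation.

#' Select the ROC-ranked model ensemble for a readout
#'
#' Fits one logistic-regression model per non-control siRNA (that siRNA's
#' training-replicate cells versus the control cells of the same
#' replicates), ranks the models by training AUC and keeps the ten best
#' (all of them when fewer than ten candidates exist). The ten best models
#' correspond to the ten siRNAs with phenotypes maximally different from
#' control, removing the need for pre-designed positive controls. Ties in
#' AUC are broken by larger training sample, then lexicographic siRNA id.
#'
#' @param cells per-cell feature table (see \code{\link{keyColumns}}).
#' @param controlLabel the control \code{sirna_id}.
#' @param readout readout whose feature set is used.
#' @param trainingReplicates replicates to train on (default: all present).
#' @param maxModels ensemble size cap (default 10).
#' @param ridge passed to \code{\link{fitLR}}.
#' @return a \code{\linkS4class{RankedEnsemble}}.
#' @export
selectEnsemble <- function(cells, controlLabel, readout,
                           trainingReplicates = NULL, maxModels = 10L,
                           ridge = 1e-6) {
  .checkFeatureTable(cells, readout)
  if (is.null(trainingReplicates))
    trainingReplicates <- sort(unique(cells$replicate))
  train <- cells[cells$replicate %in% trainingReplicates, , drop = FALSE]
  ctl <- train[train$sirna_id == controlLabel, , drop = FALSE]
  if (nrow(ctl) == 0)
    stop("no control cells in the training replicates", call. = FALSE)
  sirnas <- setdiff(unique(train$sirna_id), controlLabel)
  if (!length(sirnas))
    stop("need at least one non-control siRNA", call. = FALSE)

  cols <- featureColumns(readout)
  ctlX <- as.matrix(ctl[, cols, drop = FALSE])
  models <- lapply(sort(sirnas), function(s) {
    pos <- train[train$sirna_id == s, , drop = FALSE]
    X <- rbind(as.matrix(pos[, cols, drop = FALSE]), ctlX)
    y <- c(rep(1, nrow(pos)), rep(0, nrow(ctlX)))
    fitLR(X, y, ridge = ridge, sirna = s, readout = readout)
  })
  auc <- vapply(models, trainingAUC, numeric(1))
  n <- vapply(models, slot, integer(1), "trainingN")
  ids <- vapply(models, slot, character(1), "sirna")
  ord <- order(-auc, -n, ids)
  keep <- ord[seq_len(min(maxModels, length(ord)))]
  new("RankedEnsemble", models = models[keep], readout = readout)
}

#' Score cells with an ensemble
#'
#' The per-cell probability score is the arithmetic mean of the ensemble
#' members' predicted probabilities; it lies in [0, 1] and reflects both
#' the magnitude and the frequency of phenotypic deviation from control.
#'
#' @param ensemble a \code{\linkS4class{RankedEnsemble}}.
#' @param cells feature table.
#' @return numeric vector, one score per row of \code{cells}.
#' @export
scoreCells <- function(ensemble, cells) {
  stopifnot(is(ensemble, "RankedEnsemble"))
  validObject(ensemble)
  .checkFeatureTable(cells, ensemble@readout)
  X <- as.matrix(cells[, featureColumns(ensemble@readout), drop = FALSE])
  probs <- vapply(ensemble@models, function(m) predictProb(m, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

#' Leave-one-replicate-out cross-validated scoring
#'
#' For each replicate, the ensemble is trained on the remaining
#' replicates (with three replicates each fold trains on about 66% of the
#' cells) and scores are computed only for the held-out replicate's cells
#' — held-out cells never enter fitting or standardization. Folds whose
#' training replicates lack control cells are skipped with a warning.
#'
#' @param cells feature table with at least two replicates.
#' @param controlLabel control \code{sirna_id}.
#' @param readout readout to score.
#' @param maxModels,ridge passed to \code{\link{selectEnsemble}}.
#' @return data.frame of held-out cells (key columns, \code{fold} = the
#'   held-out replicate, \code{score}); attribute \code{"folds"} holds a
#'   per-fold summary (fold, n_train, n_test, train_fraction) and
#'   attribute \code{"ensembles"} the per-fold ensembles.
#' @export
crossvalidate <- function(cells, controlLabel, readout, maxModels = 10L,
                          ridge = 1e-6) {
  .checkFeatureTable(cells, readout)
  reps <- sort(unique(cells$replicate))
  if (length(reps) < 2L)
    stop("need at least two replicates for leave-one-out validation",
         call. = FALSE)
  out <- list(); foldInfo <- list(); ensembles <- list()
  for (r in reps) {
    trainReps <- setdiff(reps, r)
    hasCtl <- any(cells$replicate %in% trainReps &
                  cells$sirna_id == controlLabel)
    if (!hasCtl) {
      warning("training replicates for fold ", r,
              " have no control cells; fold skipped")
      next
    }
    ens <- selectEnsemble(cells, controlLabel, readout,
                          trainingReplicates = trainReps,
                          maxModels = maxModels, ridge = ridge)
    test <- cells[cells$replicate == r, , drop = FALSE]
    sc <- scoreCells(ens, test)
    piece <- test[, keyColumns(), drop = FALSE]
    piece$fold <- r
    piece$score <- sc
    out[[length(out) + 1L]] <- piece
    nTrain <- sum(cells$replicate %in% trainReps)
    foldInfo[[length(foldInfo) + 1L]] <- data.frame(
      fold = r, n_train = nTrain, n_test = nrow(test),
      train_fraction = nTrain / nrow(cells))
    ensembles[[as.character(r)]] <- ens
  }
  if (!length(out))
    stop("no usable folds", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "folds") <- do.call(rbind, foldInfo)
  attr(res, "ensembles") <- ensembles
  res
}

setMethod("ensembleModels", "RankedEnsemble", function(x) x@models)

setMethod("trainingAUC", "RankedEnsemble", function(x)
  vapply(x@models, slot, numeric(1), "trainingAUC"))

setMethod("show", "RankedEnsemble", function(object) {
  cat("RankedEnsemble [", object@readout, "] with",
      length(object@models), "models\n")
  for (m in object@models)
    cat("  ", m@sirna, ": AUC", round(m@trainingAUC, 4), "\n")
})
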