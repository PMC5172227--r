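#' @import methods
NULL

#' Screen configuration
#'
#' Parameters of a (synthetic) high-content RNAi screen: plate layout,
#' cell numbers, time-lapse sampling and the planted per-target effect
#' table. The defaults emulate a 47-target, two-siRNAs-per-target,
#' three-replicate U-2-OS screen with on average 700 cells per siRNA and
#' 30-min-interval 72-h time-lapse recordings.
#'
#' @slot nTargets number of target genes.
#' @slot sirnasPerTarget independent siRNAs per target.
#' @slot nReplicates biological replicates.
#' @slot meanCellsPerSirna screen-wide mean cell count per siRNA condition
#'   (per replicate well).
#' @slot frameInterval time-lapse frame interval in hours.
#' @slot duration time-lapse duration in hours; must be a positive multiple
#'   of \code{frameInterval}.
#' @slot controlLabel condition key of the negative control.
#' @slot noiseRate per-frame state misclassification rate applied to
#'   simulated trajectories.
#' @slot effectTable data.frame of planted per-target effects (see
#'   \code{\link{defaultEffectTable}}).
#' @slot seed integer seed governing all generator randomness.
#'
#' @seealso \code{\link{screenConfig}}
#' @exportClass ScreenConfig
setClass("ScreenConfig",
  representation(
    nTargets = "integer",
    sirnasPerTarget = "integer",
    nReplicates = "integer",
    meanCellsPerSirna = "numeric",
    frameInterval = "numeric",
    duration = "numeric",
    controlLabel = "character",
    noiseRate = "numeric",
    effectTable = "data.frame",
    seed = "integer"
  )
)

setValidity("ScreenConfig", function(object) {
  msg <- character()
  counts <- c(nTargets = object@nTargets,
              sirnasPerTarget = object@sirnasPerTarget,
              nReplicates = object@nReplicates,
              meanCellsPerSirna = object@meanCellsPerSirna)
  bad <- counts < 1 | !is.finite(counts)
  if (any(bad))
    msg <- c(msg, paste0("counts must be >= 1: ",
                         paste(names(counts)[bad], collapse = ", ")))
  if (!is.finite(object@frameInterval) || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be > 0")
  if (!is.finite(object@duration) || object@duration <= 0)
    msg <- c(msg, "duration must be > 0")
  else {
    k <- object@duration / object@frameInterval
    if (abs(k - round(k)) > 1e-8)
      msg <- c(msg, "duration must be a positive multiple of frameInterval")
  }
  if (length(object@controlLabel) != 1L || !nzchar(object@controlLabel))
    msg <- c(msg, "controlLabel must be a single non-empty string")
  if (length(object@noiseRate) != 1L || object@noiseRate < 0 ||
      object@noiseRate >= 1)
    msg <- c(msg, "noiseRate must be in [0, 1)")
  et <- object@effectTable
  ## ddr_onset_h is allowed to be NA (= no DDR onset); all effect sizes
  ## and multipliers must be finite
  eff <- grep("^(shift_|foci_mult_)", names(et), value = TRUE)
  if (length(eff) && !all(is.finite(as.matrix(et[eff]))))
    msg <- c(msg, "effect sizes must be finite")
  if (nrow(et) != object@nTargets)
    msg <- c(msg, "effectTable must have one row per target")
  if (length(msg)) msg else TRUE
})

#' Fitted logistic-regression model for one siRNA versus control
#'
#' A linear logistic model on one readout's standardized feature set. The
#' probability that a cell belongs to the siRNA-treated (positive) class is
#' \eqn{\pi(x) = 1/(1 + \exp(-(w_0 + \sum_j w_j \tilde x_j)))}, where
#' \eqn{\tilde x} is the feature vector standardized by the training mean
#' and standard deviation stored in the model.
#'
#' @slot intercept intercept \eqn{w_0}.
#' @slot weights named feature weights \eqn{w_1 \ldots w_k}.
#' @slot center,scale per-feature training mean and sd used to standardize.
#' @slot sirna identity of the training siRNA (positive class).
#' @slot readout readout whose feature set the model uses.
#' @slot trainingAUC area under the ROC curve on the training sample.
#' @slot trainingN training sample size.
#' @slot converged whether IRLS converged.
#' @exportClass LRModel
setClass("LRModel",
  representation(
    intercept = "numeric",
    weights = "numeric",
    center = "numeric",
    scale = "numeric",
    sirna = "character",
    readout = "character",
    trainingAUC = "numeric",
    trainingN = "integer",
    converged = "logical"
  )
)

setValidity("LRModel", function(object) {
  msg <- character()
  if (!all(is.finite(c(object@intercept, object@weights))))
    msg <- c(msg, "weights must be finite")
  if (length(object@weights) != length(object@center) ||
      length(object@weights) != length(object@scale))
    msg <- c(msg, "weights, center and scale must have equal length")
  if (any(object@scale <= 0))
    msg <- c(msg, "standardization sds must be > 0")
  if (length(object@trainingAUC) == 1L &&
      (object@trainingAUC < 0 || object@trainingAUC > 1))
    msg <- c(msg, "trainingAUC must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ROC-ranked ensemble of logistic-regression models
#'
#' The models trained on the siRNAs whose cell populations are maximally
#' different from control, ordered by descending training AUC. At most the
#' ten best models are retained at selection time; the ensemble score of a
#' cell is the arithmetic mean of the member probabilities.
#'
#' @slot models list of \code{\linkS4class{LRModel}}, descending training AUC.
#' @slot readout the readout the ensemble scores.
#' @exportClass RankedEnsemble
setClass("RankedEnsemble",
  representation(models = "list", readout = "character"))

setValidity("RankedEnsemble", function(object) {
  msg <- character()
  if (length(object@models) == 0L)
    msg <- c(msg, "ensemble must contain at least one model")
  if (!all(vapply(object@models, is, logical(1), "LRModel")))
    msg <- c(msg, "all members must be LRModel objects")
  else {
    aucs <- vapply(object@models, slot, numeric(1), "trainingAUC")
    if (is.unsorted(rev(aucs), strictly = FALSE))
      msg <- c(msg, "training AUCs must be non-increasing")
    rd <- unique(vapply(object@models, slot, character(1), "readout"))
    if (length(rd) > 1L)
      msg <- c(msg, "all members must share one readout")
  }
  if (length(msg)) msg else TRUE
})

#' Control-normalized time course
#'
#' A per-frame summary value for one condition together with its fold
#' change over the control condition at the same frame (control == 1 by
#' construction).
#'
#' @slot condition condition key.
#' @slot times frame times in hours (uniform spacing).
#' @slot values per-frame raw summary values.
#' @slot folds per-frame control-normalized fold changes (> 0).
#' @exportClass TimeCourse
setClass("TimeCourse",
  representation(condition = "character", times = "numeric",
                 values = "numeric", folds = "numeric"))

setValidity("TimeCourse", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@values) != n || length(object@folds) != n)
    msg <- c(msg, "times, values and folds must have equal length")
  if (any(object@folds <= 0, na.rm = TRUE))
    msg <- c(msg, "folds must be > 0")
  if (n > 2) {
    d <- diff(object@times)
    if (max(abs(d - d[1])) > 1e-6)
      msg <- c(msg, "frame spacing must be uniform")
  }
  if (length(msg)) msg else TRUE
})

#' k-means clustering result on phenotype profiles
#'
#' @slot k number of clusters.
#' @slot labels named integer cluster label per target, in 1..k.
#' @slot centroids k x p centroid matrix.
#' @slot wcss total within-cluster sum of squares of the best restart.
#' @slot nRestarts number of k-means++ restarts searched.
#' @slot seed RNG seed used.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(k = "integer", labels = "integer", centroids = "matrix",
                 wcss = "numeric", nRestarts = "integer", seed = "integer"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (any(object@labels < 1L | object@labels > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(unique(object@labels)) != object@k)
    msg <- c(msg, "every cluster must be nonempty")
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "centroids must have k rows")
  if (length(msg)) msg else TRUE
})
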