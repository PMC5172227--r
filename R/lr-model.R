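## Logistic-regression core: ridge-stabilized maximum-likelihood fitting
## by iteratively reweighted least squares on standardized features. The
## model is linear in the standardized features; the probability that a
## cell belongs to the siRNA-treated class is the logistic function of
## the linear predictor.

#' Fit a logistic-regression model for one siRNA versus control
#'
#' Features are standardized by the training mean and sd (stored in the
#' model so prediction applies the same transform), then weights are found
#' by maximizing the Bernoulli log-likelihood with a small ridge penalty
#' on the feature weights (not the intercept) via iteratively reweighted
#' least squares. The ridge stabilizer keeps weights finite under complete
#' class separation; at its default of 1e-6 the fit is classical maximum
#' likelihood for all practical purposes.
#'
#' @param X numeric matrix (cells x features) or data.frame.
#' @param y binary labels (0 = control, 1 = siRNA-treated).
#' @param ridge ridge penalty on the standardized-feature weights
#'   (default 1e-6).
#' @param sirna,readout identity metadata stored in the model.
#' @param maxIter,tol IRLS iteration cap (100) and convergence tolerance
#'   on the max weight change (1e-8); non-convergence warns and returns
#'   the best iterate.
#' @return an \code{\linkS4class{LRModel}}.
#' @examples
#' x <- matrix(rnorm(200), ncol = 2)
#' y <- rbinom(100, 1, plogis(x[, 1]))
#' fitLR(x, y)
#' @export
fitLR <- function(X, y, ridge = 1e-6, sirna = NA_character_,
                  readout = NA_character_, maxIter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit", call. = FALSE)
  if (nrow(X) <= ncol(X))
    stop("need more cells than features", call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1   # constant feature: weight stays 0
  Z <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  k <- ncol(Z)
  pen <- diag(c(0, rep(ridge, k - 1L)))  # no penalty on the intercept

  w <- numeric(k)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- drop(Z %*% w)
    mu <- plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    ## IRLS step for the penalized Bernoulli log-likelihood
    H <- crossprod(Z, Z * wt) + pen
    g <- crossprod(Z, y - mu) - pen %*% w
    step <- solve(H, g)
    w <- w + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("IRLS did not converge in ", maxIter,
            " iterations; returning last iterate")

  scores <- plogis(drop(Z %*% w))
  new("LRModel",
      intercept = unname(w[1]),
      weights = structure(unname(w[-1]), names = colnames(X)),
      center = structure(ctr, names = colnames(X)),
      scale = structure(scl, names = colnames(X)),
      sirna = sirna, readout = readout,
      trainingAUC = rocAUC(scores, y),
      trainingN = nrow(X),
      converged = converged)
}

#' Predicted probability of the siRNA-treated class
#'
#' \eqn{\pi(x) = 1/(1+\exp(-(w_0 + \sum_j w_j \tilde x_j)))} on features
#' standardized by the model's training mean/sd; strictly increasing in
#' the linear predictor.
#'
#' @param model an \code{\linkS4class{LRModel}}.
#' @param x numeric matrix/data.frame of cells, or a single feature
#'   vector; columns must match the model's feature schema.
#' @return numeric vector of probabilities in (0, 1).
#' @rdname predictProb
#' @export
setMethod("predictProb", "LRModel", function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (ncol(x) != length(model@weights))
    stop("feature schema mismatch: model expects ",
         length(model@weights), " features", call. = FALSE)
  if (!is.null(colnames(x)) && !all(is.na(names(model@weights)))) {
    if (!setequal(colnames(x), names(model@weights)))
      stop("feature schema mismatch: feature names differ", call. = FALSE)
    x <- x[, names(model@weights), drop = FALSE]
  }
  z <- sweep(sweep(x, 2, model@center), 2, model@scale, "/")
  plogis(model@intercept + drop(z %*% model@weights))
})

#' Area under the ROC curve by rank statistics
#'
#' \eqn{AUC = P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)} over all
#' positive/negative score pairs, computed from the Mann-Whitney rank-sum
#' with midranks for ties; identical to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels (0/1 or logical).
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC is undefined with a single class", call. = FALSE)
  r <- rank(scores)           # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## DeLong placement values: for each positive, the fraction of negatives
## it beats (ties count half), and vice versa
.placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  v10 <- vapply(pos, function(s)
    (sum(s > neg) + 0.5 * sum(s == neg)) / length(neg), numeric(1))
  v01 <- vapply(neg, function(s)
    (sum(pos > s) + 0.5 * sum(pos == s)) / length(pos), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong test comparing two correlated ROC curves
#'
#' Compares the AUCs of two classifiers scored on the same cells using
#' the DeLong covariance of the paired AUC estimates computed from
#' placement values, with a two-sided z-test on the AUC difference. Used
#' to check whether adding models to the ensemble buys discrimination.
#'
#' @param scoresM,scoresN the two classifiers' scores on the same cells.
#' @param labels shared binary labels.
#' @return list with aucM, aucN, delta (aucM - aucN), se, z and p (the
#'   two-sided p-value; 1 when the scores are identical).
#' @export
delongCompare <- function(scoresM, scoresN, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scoresM) == length(labels),
            length(scoresN) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("DeLong test undefined with a single class", call. = FALSE)
  pm <- .placements(scoresM, labels)
  pn <- .placements(scoresN, labels)
  aucM <- mean(pm$v10); aucN <- mean(pn$v10)
  ## 2x2 covariance of (aucM, aucN)
  s10 <- stats::cov(cbind(pm$v10, pn$v10))
  s01 <- stats::cov(cbind(pm$v01, pn$v01))
  S <- s10 / n1 + s01 / n0
  varDelta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- aucM - aucN
  if (varDelta <= .Machine$double.eps) {
    p <- if (abs(delta) < .Machine$double.eps^0.5) 1 else 0
    return(list(aucM = aucM, aucN = aucN, delta = delta, se = 0,
                z = if (p == 1) 0 else Inf, p = p))
  }
  z <- delta / sqrt(varDelta)
  list(aucM = aucM, aucN = aucN, delta = delta, se = sqrt(varDelta),
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

setMethod("modelWeights", "LRModel", function(x)
  c("(intercept)" = x@intercept, x@weights))

setMethod("trainingAUC", "LRModel", function(x) x@trainingAUC)

setMethod("show", "LRModel", function(object) {
  cat("LRModel [", object@readout, "] siRNA:", object@sirna,
      "| training AUC:", round(object@trainingAUC, 4),
      "| n:", object@trainingN, "\n")
  print(round(modelWeights(object), 4))
})
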