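## Phenotypic clustering of per-target probability profiles.

## k-means++ seeding: spread the initial centroids by sampling points
## with probability proportional to squared distance from the nearest
## centroid chosen so far
.kmeansppInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (k > 1) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j, ] <- X[sample.int(n, 1L), ]
      } else {
        centers[j, ] <- X[sample.int(n, 1L, prob = d2), ]
      }
      dj <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
      d2 <- pmin(d2, dj)
    }
  }
  centers
}

#' k-means clustering of phenotype profiles
#'
#' Lloyd's algorithm with k-means++ initialization on the Euclidean
#' distance over the profile columns, taking the best of \code{nRestarts}
#' restarts by total within-cluster sum of squares. Profiles are
#' probability scores on [0, 1] and are clustered unscaled. Empty
#' clusters are re-seeded from the point farthest from its centroid.
#' Cluster labels are renumbered in descending order of centroid norm, so
#' the highest label is the strongest combined phenotype; this ordering
#' is a presentation convention.
#'
#' @param profiles data.frame with a \code{target} column plus numeric
#'   profile columns, or a plain numeric matrix with rownames.
#' @param k number of clusters (2 to nrow).
#' @param nRestarts restarts (default 50); WCSS ties break first-found.
#' @param seed RNG seed (default 42).
#' @return a \code{\linkS4class{ClusterResult}}.
#' @examples
#' pr <- data.frame(target = paste0("T", 1:6),
#'                  a = c(0.1, 0.12, 0.11, 0.8, 0.82, 0.79),
#'                  b = c(0.2, 0.18, 0.22, 0.9, 0.88, 0.91))
#' clusterLabels(kmeansCluster(pr, k = 2))
#' @export
kmeansCluster <- function(profiles, k, nRestarts = 50L, seed = 42L) {
  X <- .profileMatrix(profiles)
  n <- nrow(X)
  if (k > n)
    stop("k must not exceed the number of profiles", call. = FALSE)
  if (!all(is.finite(X)))
    stop("profiles must be finite", call. = FALSE)
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(nRestarts)) {
      centers <- .kmeansppInit(X, k)
      km <- suppressWarnings(
        stats::kmeans(X, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd"))
      ## re-seed empty clusters from the farthest point
      guard <- 0L
      while (length(unique(km$cluster)) < k && guard < 10L) {
        guard <- guard + 1L
        d <- rowSums((X - km$centers[km$cluster, , drop = FALSE])^2)
        missing <- setdiff(seq_len(k), unique(km$cluster))
        cen <- km$centers
        for (mj in missing) {
          far <- which.max(d)
          cen[mj, ] <- X[far, ]
          d[far] <- 0
        }
        km <- suppressWarnings(
          stats::kmeans(X, centers = cen, iter.max = 100L,
                        algorithm = "Lloyd"))
      }
      if (is.null(best) || km$tot.withinss < best$tot.withinss)
        best <- km
    }
  })
  ## relabel in descending centroid norm
  ord <- order(-sqrt(rowSums(best$centers^2)))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[best$cluster]
  names(labels) <- rownames(X)
  new("ClusterResult",
      k = as.integer(k),
      labels = structure(as.integer(labels), names = rownames(X)),
      centroids = best$centers[ord, , drop = FALSE],
      wcss = best$tot.withinss,
      nRestarts = as.integer(nRestarts),
      seed = as.integer(seed))
}

.profileMatrix <- function(profiles) {
  if (is.data.frame(profiles)) {
    stopifnot("target" %in% names(profiles))
    num <- vapply(profiles, is.numeric, logical(1))
    X <- as.matrix(profiles[, num, drop = FALSE])
    rownames(X) <- profiles$target
  } else {
    X <- as.matrix(profiles)
    if (is.null(rownames(X))) rownames(X) <- seq_len(nrow(X))
  }
  X
}

#' Choose k by mean silhouette width
#'
#' Runs \code{\link{kmeansCluster}} for each k in \code{kRange} and
#' returns the k maximizing the mean silhouette width (how much closer
#' each profile is to its own cluster than to the nearest other cluster).
#'
#' @param profiles as in \code{\link{kmeansCluster}}.
#' @param kRange candidate k values, within [2, n - 1].
#' @param nRestarts,seed passed to \code{\link{kmeansCluster}}.
#' @return list with \code{k} (the argmax), \code{silhouettes} (named
#'   mean silhouette per candidate k) and \code{results} (the
#'   ClusterResult per k).
#' @export
chooseK <- function(profiles, kRange = 2:6, nRestarts = 50L, seed = 42L) {
  X <- .profileMatrix(profiles)
  n <- nrow(X)
  if (any(kRange < 2) || any(kRange > n - 1))
    stop("kRange must lie within [2, n - 1]", call. = FALSE)
  if (nrow(unique(X)) < max(kRange) + 1)
    stop("profiles are degenerate (too few distinct points)",
         call. = FALSE)
  d <- stats::dist(X)
  sil <- numeric(length(kRange))
  results <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    res <- kmeansCluster(X, kRange[i], nRestarts = nRestarts, seed = seed)
    results[[i]] <- res
    sil[i] <- mean(cluster::silhouette(as.integer(res@labels), d)[, 3])
  }
  names(sil) <- kRange
  names(results) <- kRange
  list(k = kRange[which.max(sil)], silhouettes = sil, results = results)
}

setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: k =", object@k, "| WCSS =",
      signif(object@wcss, 5), "| restarts =", object@nRestarts, "\n")
  print(table(cluster = object@labels))
})

#' Concordance between the two siRNAs per target
#'
#' Pearson product-moment correlation between paired per-target scores of
#' siRNA #1 and siRNA #2, with the Fisher-z 95% confidence interval and
#' the t-test p-value for the hypothesis of no correlation.
#'
#' @param scoresSirna1,scoresSirna2 paired per-target score vectors
#'   (n >= 3).
#' @param conf confidence level (default 0.95).
#' @return list with r, ci (length 2), p and n.
#' @export
replicateCorrelation <- function(scoresSirna1, scoresSirna2,
                                 conf = 0.95) {
  n <- length(scoresSirna1)
  stopifnot(n == length(scoresSirna2), n >= 3)
  if (stats::sd(scoresSirna1) == 0 || stats::sd(scoresSirna2) == 0)
    stop("zero variance; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(scoresSirna1, scoresSirna2, method = "pearson",
                        conf.level = conf)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = n)
}
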