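## Independent oracles used to pin expected values. These deliberately
## use brute force / enumeration, never the package's own code paths.

## AUC by exhaustive pairwise comparison over all (positive, negative)
## score pairs; ties count one half
aucPairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos)
    for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## maximize the 1-feature logistic log-likelihood over a (w0, w1) grid;
## feature is assumed already standardized by (center, scale)
gridSearchLR1 <- function(x, y, center, scale, grid = seq(-6, 6, by = 0.001)) {
  z <- (x - center) / scale
  best <- c(NA, NA); bestLL <- -Inf
  coarse <- seq(-6, 6, by = 0.05)
  ll <- function(w0, w1) {
    eta <- w0 + w1 * z
    sum(y * eta - log1p(exp(eta)))
  }
  for (w0 in coarse) for (w1 in coarse) {
    v <- ll(w0, w1)
    if (v > bestLL) { bestLL <- v; best <- c(w0, w1) }
  }
  ## refine around the coarse optimum
  for (pass in 1:3) {
    step <- 0.05 / 10^pass
    g0 <- seq(best[1] - 10 * step * 10, best[1] + 10 * step * 10,
              by = step)
    g1 <- seq(best[2] - 10 * step * 10, best[2] + 10 * step * 10,
              by = step)
    for (w0 in g0) for (w1 in g1) {
      v <- ll(w0, w1)
      if (v > bestLL) { bestLL <- v; best <- c(w0, w1) }
    }
  }
  best
}

## exact two-sided Mann-Whitney p by enumerating all group assignments
mwuExactP <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  uStat <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  obs <- uStat(seq_len(na))
  mu <- na * (n - na) / 2
  combs <- utils::combn(n, na)
  cnt <- 0
  for (j in seq_len(ncol(combs))) {
    u <- sum(r[combs[, j]]) - na * (na + 1) / 2
    if (abs(u - mu) >= abs(obs - mu) - 1e-12) cnt <- cnt + 1
  }
  cnt / ncol(combs)
}

## minimum WCSS over all 2-partitions of a small point set
wcssExhaustive2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    if (all(grp == grp[1])) next
    w <- 0
    for (g in 0:1) {
      pts <- X[grp == g, , drop = FALSE]
      if (nrow(pts) == 0) { w <- Inf; break }
      cen <- colMeans(pts)
      w <- w + sum(sweep(pts, 2, cen)^2)
    }
    best <- min(best, w)
  }
  best
}

## well-separated planted profile groups in [0,1]^5 for cluster recovery
plantedProfiles <- function(nPerGroup = 10, noiseSd = 0.04, seed = 1) {
  centers <- rbind(c(0.10, 0.10, 0.10, 0.10, 0.10),
                   c(0.80, 0.20, 0.20, 0.70, 0.30),
                   c(0.50, 0.80, 0.80, 0.50, 0.60),
                   c(0.90, 0.90, 0.90, 0.90, 0.90))
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(1:4, function(g)
      sweep(matrix(rnorm(nPerGroup * 5, 0, noiseSd), nPerGroup, 5),
            2, centers[g, ], "+")))
  })
  X <- pmin(pmax(X, 0), 1)
  list(profiles = data.frame(target = sprintf("P%02d", seq_len(4 * nPerGroup)),
                             X),
       truth = rep(1:4, each = nPerGroup))
}
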