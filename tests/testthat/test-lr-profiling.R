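test_that("a null relation yields near-zero weights and the prevalence", {
  withr::with_seed(1, {
    X <- matrix(rnorm(4000 * 3), ncol = 3)
    y <- rep(c(1, 0), c(1000, 3000))   # 25% prevalence, x independent
  })
  m <- fitLR(X, y)
  expect_true(all(abs(m@weights) < 0.1))
  expect_equal(plogis(m@intercept), 0.25, tolerance = 0.05)
})

test_that("IRLS matches a brute-force likelihood grid on 8 points", {
  x <- c(0.2, 0.5, 1.1, 1.9, 2.3, 2.9, 3.6, 4.0)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  m <- fitLR(matrix(x, ncol = 1), y, ridge = 0)
  oracle <- gridSearchLR1(x, y, center = m@center, scale = m@scale)
  expect_equal(unname(m@intercept), oracle[1], tolerance = 1e-3)
  expect_equal(unname(m@weights[1]), oracle[2], tolerance = 1e-3)
  ## and agrees with glm's maximum-likelihood fit on standardized x
  z <- (x - m@center) / m@scale
  g <- glm(y ~ z, family = binomial())
  expect_equal(unname(m@intercept), unname(coef(g)[1]), tolerance = 1e-5)
  expect_equal(unname(m@weights[1]), unname(coef(g)[2]), tolerance = 1e-5)
})

test_that("the ridge stabilizer bounds complete separation", {
  X <- matrix(c(1:5, 11:15), ncol = 1)
  y <- rep(c(0, 1), each = 5)
  m <- fitLR(X, y, ridge = 1e-6)
  expect_true(all(is.finite(modelWeights(m))))
  expect_equal(trainingAUC(m), 1)
  expect_error(fitLR(X, rep(1, 10)), "both classes")
})

test_that("predicted probabilities follow the logistic closed form", {
  m <- new("LRModel", intercept = 0, weights = c(x1 = 0),
           center = c(x1 = 0), scale = c(x1 = 1),
           sirna = "s", readout = "b53bp1", trainingAUC = 0.5,
           trainingN = 10L, converged = TRUE)
  expect_equal(predictProb(m, c(x1 = 3.7)), 0.5)   # all weights zero
  m@weights <- c(x1 = 1)
  expect_equal(predictProb(m, c(x1 = 0)), 0.5)
  expect_gt(predictProb(m, c(x1 = 50)), 0.999)     # sigmoid limit
  ## hand-set: w0 = -1, w1 = 2, standardized x = 0.5 -> 1/(1+e^0)
  m@intercept <- -1; m@weights <- c(x1 = 2)
  expect_equal(predictProb(m, c(x1 = 0.5)), 0.5)
  ## strictly increasing in the linear predictor
  p <- predictProb(m, matrix(seq(-2, 2, 0.5), ncol = 1,
                             dimnames = list(NULL, "x1")))
  expect_true(all(diff(p) > 0))
  expect_error(predictProb(m, c(a = 1, b = 2)), "schema")
})

test_that("rank-based AUC equals the exhaustive pairwise oracle", {
  ## toy set with a tie
  s <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  l <- c(1, 1, 0, 1, 0, 0)
  expect_identical(rocAUC(s, l), aucPairwise(s, l))
  ## property: exact agreement on random inputs up to n = 50
  withr::with_seed(7, {
    for (trial in 1:25) {
      n <- sample(4:50, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- sample(seq_len(ceiling(n / 2)), n, replace = TRUE) / 10
      expect_equal(rocAUC(scores, labels), aucPairwise(scores, labels))
    }
  })
  expect_error(rocAUC(1:4, c(1, 1, 1, 1)), "single class")
})

test_that("AUC calibration matches the chance and separation regimes", {
  withr::with_seed(42, {
    scores <- runif(4000)
    labels <- rep(0:1, each = 2000)
  })
  expect_equal(rocAUC(scores, labels), 0.5, tolerance = 0.05)
  expect_equal(rocAUC(c(runif(50), runif(50) + 2),
                      rep(0:1, each = 50)), 1)
})

test_that("AUC agrees with pROC on a shared example", {
  withr::with_seed(3, {
    scores <- rnorm(300)
    labels <- rbinom(300, 1, plogis(scores))
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(rocAUC(scores, labels), ref)
})

test_that("DeLong comparison behaves at the reference points", {
  withr::with_seed(11, {
    labels <- rep(0:1, each = 150)
    informative <- labels + rnorm(300, sd = 0.7)
    junk <- rnorm(300)
  })
  same <- delongCompare(informative, informative, labels)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  diff <- delongCompare(informative, junk, labels)
  expect_lt(diff$p, 0.05)
  expect_gt(diff$delta, 0)
})

test_that("DeLong variance agrees with a bootstrap oracle", {
  withr::with_seed(19, {
    labels <- rep(0:1, each = 100)
    s1 <- labels + rnorm(200, sd = 1.2)
    s2 <- 0.6 * labels + rnorm(200, sd = 1.2)
    dl <- delongCompare(s1, s2, labels)
    boot <- replicate(600, {
      i <- c(sample(which(labels == 0), replace = TRUE),
             sample(which(labels == 1), replace = TRUE))
      rocAUC(s1[i], labels[i]) - rocAUC(s2[i], labels[i])
    })
  })
  expect_equal(dl$se^2, var(boot), tolerance = 0.2)
})

test_that("DeLong p-value matches pROC's implementation", {
  withr::with_seed(23, {
    labels <- rep(0:1, each = 120)
    s1 <- labels + rnorm(240)
    s2 <- 0.4 * labels + rnorm(240)
  })
  ours <- delongCompare(s1, s2, labels)
  ref <- pROC::roc.test(pROC::roc(labels, s1, quiet = TRUE),
                        pROC::roc(labels, s2, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
})
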