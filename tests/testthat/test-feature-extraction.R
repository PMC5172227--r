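test_that("well-separated nuclei are segmented with accurate centroids", {
  syn <- renderNucleusImage(5, fociPerNucleus = 0, noiseSd = 0, seed = 11,
                            width = 384, height = 384)
  mask <- segmentNuclei(syn$image)
  expect_equal(max(mask), 5)
  got <- mitoprofiler:::.maskCentroids(mask)
  ## match each true nucleus to the nearest segmented centroid
  for (i in seq_len(nrow(syn$nuclei))) {
    d <- sqrt((got$row - syn$nuclei$row[i])^2 +
              (got$col - syn$nuclei$col[i])^2)
    expect_lt(min(d), 2)
  }
  ## area recovery: rendered area within 5% of the segmented area
  trueAreas <- tabulate(syn$labelMap[syn$labelMap > 0])
  for (i in seq_len(nrow(syn$nuclei))) {
    j <- which.min(sqrt((got$row - syn$nuclei$row[i])^2 +
                        (got$col - syn$nuclei$col[i])^2))
    segArea <- sum(mask == got$label[j])
    expect_equal(segArea / trueAreas[i], 1, tolerance = 0.05)
  }
})

test_that("degenerate images give empty masks with a warning", {
  blank <- matrix(0, 64, 64)
  expect_warning(m <- segmentNuclei(blank), "constant")
  expect_equal(max(m), 0)
  saturated <- matrix(65535, 64, 64)
  expect_warning(m2 <- segmentNuclei(saturated), "constant")
  expect_equal(max(m2), 0)
})

test_that("the area gate removes small objects", {
  syn <- renderNucleusImage(1, fociPerNucleus = 0, noiseSd = 0, seed = 3,
                            width = 128, height = 128)
  trueArea <- sum(syn$labelMap > 0)   # direct pixel count oracle
  keep <- segmentNuclei(syn$image, minArea = 0.9 * trueArea)
  expect_equal(max(keep), 1)
  drop <- segmentNuclei(syn$image, minArea = 1.1 * trueArea)
  expect_equal(max(drop), 0)
})

test_that("planted foci are detected with accurate centroids", {
  syn <- renderNucleusImage(5, fociPerNucleus = 3, noiseSd = 0, seed = 11,
                            width = 384, height = 384)
  f <- detectFoci(syn$image, syn$labelMap)
  expect_equal(nrow(f), 15)
  for (i in seq_len(nrow(syn$foci))) {
    same <- f[f$label == syn$foci$label[i], ]
    d <- sqrt((same$row - syn$foci$row[i])^2 +
              (same$col - syn$foci$col[i])^2)
    expect_lt(min(d), 2)
  }
  expect_error(detectFoci(syn$image, syn$labelMap, tophatRadius = 0),
               "tophatRadius")
})

test_that("a uniform nucleus contains no foci", {
  img <- matrix(300, 128, 128)
  mask <- matrix(0L, 128, 128)
  for (i in 1:128) for (j in 1:128)
    if ((i - 64)^2 + (j - 64)^2 <= 20^2) mask[i, j] <- 1L
  img[mask == 1] <- 9000
  expect_equal(nrow(detectFoci(img, mask)), 0)
})

test_that("per-nucleus counts match ground truth on a noisy field", {
  ## 100 nuclei with Poisson(4) planted foci under moderate camera noise
  ok <- 0L; total <- 0L
  for (s in 1:4) {
    syn <- renderNucleusImage(25, fociPerNucleus = 4, noiseSd = 200,
                              seed = s, fociDistribution = "poisson",
                              width = 768, height = 768)
    f <- detectFoci(syn$image, syn$labelMap)
    tt <- table(factor(syn$foci$label, levels = 1:25))
    dd <- table(factor(f$label, levels = 1:25))
    ok <- ok + sum(tt == dd)
    total <- total + 25L
  }
  expect_gte(ok / total, 0.9)
})

test_that("focus detection ignores translation and constant background", {
  syn <- renderNucleusImage(2, fociPerNucleus = 3, noiseSd = 0, seed = 6,
                            width = 256, height = 256)
  base <- detectFoci(syn$image, syn$labelMap)
  ## add a constant offset: the top-hat removes it entirely
  lifted <- detectFoci(syn$image + 4000, syn$labelMap)
  expect_equal(nrow(lifted), nrow(base))
  expect_equal(lifted$area, base$area)
  ## translate image and mask together by 10 pixels
  sh <- function(m) rbind(m[-(1:10), ], m[1:10, ])
  shifted <- detectFoci(sh(syn$image), sh(syn$labelMap))
  expect_equal(nrow(shifted), nrow(base))
  expect_equal(sort(shifted$area), sort(base$area))
})

test_that("disk geometry features match the analytic values", {
  img <- matrix(0, 64, 64)
  mask <- matrix(0L, 64, 64)
  cy <- 32; cx <- 32; r <- 10
  for (i in 1:64) for (j in 1:64)
    if ((i - cy)^2 + (j - cx)^2 <= r^2) mask[i, j] <- 1L
  img[mask == 1] <- 100
  ft <- computeNucleusFeatures(mask, list(morphology = img))
  expect_equal(ft$morphology.area, pi * r^2, tolerance = 0.03)
  expect_equal(ft$morphology.average_intensity, 100)
  expect_equal(ft$morphology.integrated_intensity,
               ft$morphology.average_intensity * ft$morphology.area)
  expect_equal(ft$morphology.form_factor, 1, tolerance = 0.02)
  ## second-moment axis of a uniform disk is its diameter
  expect_equal(ft$morphology.length, 2 * r, tolerance = 0.05)
  ## boundary-pixel contour length tracks the circumference
  expect_gt(ft$morphology.perimeter, 0.8 * 2 * pi * r)
  expect_lt(ft$morphology.perimeter, 1.2 * 2 * pi * r)
})

test_that("feature linearity and zero-focus conventions hold", {
  syn <- renderNucleusImage(3, fociPerNucleus = 0, noiseSd = 50, seed = 13,
                            width = 256, height = 256)
  chans <- list(morphology = syn$image, b53bp1 = syn$image,
                gh2ax = syn$image, p53 = syn$image, edu = syn$image)
  ft <- computeNucleusFeatures(syn$labelMap, chans)
  ## no planted foci -> all focus features zero
  expect_true(all(ft$b53bp1.foci_count == 0))
  expect_true(all(ft$gh2ax.foci_intensity == 0))
  expect_true(all(ft$gh2ax.foci_average == 0))
  ## doubling intensities doubles intensity features, fixes geometry
  chans2 <- lapply(chans, function(m) m * 2)
  ft2 <- computeNucleusFeatures(syn$labelMap, chans2)
  expect_equal(ft2$morphology.integrated_intensity,
               2 * ft$morphology.integrated_intensity)
  expect_equal(ft2$p53.average_intensity, 2 * ft$p53.average_intensity)
  expect_equal(ft2$morphology.area, ft$morphology.area)
  expect_equal(ft2$morphology.perimeter, ft$morphology.perimeter)
  expect_equal(ft2$morphology.form_factor, ft$morphology.form_factor)
  ## integrated = average x area exactly, for every readout
  expect_equal(ft$gh2ax.nuc_integrated,
               ft$gh2ax.nuc_average * ft$morphology.area)
  expect_error(computeNucleusFeatures(syn$labelMap, list(bogus = syn$image)),
               "unknown readout")
})

test_that("mitotic gamma-H2AX score averages per-cell focus sums", {
  ## two condensed (bright) mitotic cells with flat square foci of known
  ## integrated intensity, one dim interphase cell
  dapi <- matrix(200, 160, 160)
  gh2ax <- matrix(0, 160, 160)
  put <- function(m, r, c, h, v) { m[r:(r + h), c:(c + h)] <- v; m }
  dapi <- put(dapi, 20, 20, 30, 30000)   # mitotic cell 1
  dapi <- put(dapi, 100, 100, 30, 30000) # mitotic cell 2
  dapi <- put(dapi, 30, 110, 30, 6000)   # interphase cell
  gh2ax <- put(gh2ax, 30, 30, 4, 4000)   # 25 px x 4000
  gh2ax <- put(gh2ax, 110, 110, 4, 4000)
  gh2ax <- put(gh2ax, 120, 120, 4, 8000) # second focus in cell 2
  gh2ax <- put(gh2ax, 40, 120, 4, 8000)  # focus in the interphase cell
  s1 <- 25 * 4000
  s2 <- 25 * 4000 + 25 * 8000
  score <- mitoticGammaH2AXScore(dapi, gh2ax,
                                 mitoticIntensityThreshold = 20000)
  expect_equal(score, (s1 + s2) / 2)
  expect_warning(
    z <- mitoticGammaH2AXScore(dapi, gh2ax,
                               mitoticIntensityThreshold = 60000),
    "no mitotic")
  expect_equal(z, 0)
})
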