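## small helper: a TimeCourse straight from fold values
tcOf <- function(folds, cond = "c", dt = 0.5) {
  new("TimeCourse", condition = cond,
      times = (seq_along(folds) - 1) * dt,
      values = folds, folds = folds)
}

test_that("self-normalization gives fold 1 at every frame", {
  cfg <- screenConfig(nTargets = 4, seed = 2)
  fr <- frameFractions(
    generateTrajectories(cfg, "T02", 60, seed = 4)$trajectories)
  m <- compositeMorphology(fr, fr, condition = "T02")
  expect_true(all(foldChanges(m) == 1))
  d <- ddrTimecourse(fr, fr, condition = "T02")
  expect_true(all(foldChanges(d) == 1))
})

test_that("fold changes follow the stated arithmetic", {
  mk <- function(ab, mi, de) data.frame(
    frame = 0:2, time_h = c(0, 0.5, 1), frac_aberrant = ab,
    frac_mitotic = mi, frac_dead = de,
    mean_foci_interphase = c(3, 3, 3), n_interphase = 10, n_cells = 10)
  cond <- mk(0.2, 0.1, 0.1)
  ctl <- mk(0.1, 0.05, 0.05)
  expect_equal(foldChanges(compositeMorphology(cond, ctl)),
               rep(2, 3))
  ctl$mean_foci_interphase <- c(2, 2, 2)
  expect_equal(foldChanges(ddrTimecourse(cond, ctl)), rep(1.5, 3))
  ctl$time_h <- c(0, 1, 2)
  expect_error(compositeMorphology(cond, ctl), "grids")
})

test_that("planted aberration excess is recovered by the composite fold", {
  ## condition with 4x the control post-mitotic aberration rate and
  ## otherwise control-like parameters
  et <- defaultEffectTable(1)
  et[, grep("^shift_", names(et))] <- 0
  et$mito_delay_h <- 0; et$death_prob <- 0.02
  et$ddr_onset_h <- NA; et$s_extension_h <- 0
  et$aberrant_frac <- 0.20; et$cytokinesis_failure <- 0
  cfg <- screenConfig(nTargets = 1, effectTable = et, seed = 6)
  tr <- generateTrajectories(cfg, "T01", 400, seed = 6, noiseRate = 0)
  ct <- generateTrajectories(cfg, "NEG", 400, seed = 7, noiseRate = 0)
  m <- compositeMorphology(frameFractions(tr$trajectories),
                           frameFractions(ct$trajectories))
  ## late in the movie every cell has exited mitosis: the composite is
  ## dominated by the aberrant fraction; oracle from the planted truth
  lastFold <- tail(foldChanges(m), 1)
  oracle <- (mean(tr$truth$aberrant_after | tr$truth$base_aberrant) +
             mean(!is.na(tr$truth$death_time))) /
            (mean(ct$truth$aberrant_after | ct$truth$base_aberrant) +
             mean(!is.na(ct$truth$death_time)))
  expect_equal(lastFold, oracle, tolerance = 0.15)
})

test_that("DDR fold crosses 1.5 at the planted onset", {
  et <- defaultEffectTable(3)   # T03: DDR-first archetype, onset 12 h
  cfg <- screenConfig(nTargets = 3, effectTable = et, seed = 10)
  tr <- generateTrajectories(cfg, "T03", 250, seed = 10, noiseRate = 0)
  ct <- generateTrajectories(cfg, "NEG", 250, seed = 11, noiseRate = 0)
  d <- ddrTimecourse(frameFractions(tr$trajectories),
                     frameFractions(ct$trajectories))
  crossing <- frameTimes(d)[which(foldChanges(d) >= 1.5)[1]]
  expect_lte(abs(crossing - et$ddr_onset_h[3]), 2 * cfg@frameInterval)
})

test_that("onset classification follows the first-crossing rule", {
  up <- function(at, to, n = 80, dt = 0.5) {
    f <- rep(1, n); f[(seq_len(n) - 1) * dt >= at] <- to; f
  }
  ## morphology crosses 3 at 20 h, DDR crosses 1.5 at 30 h
  cl <- classifyOnset(tcOf(up(20, 4), "a"), tcOf(up(30, 2), "a"))
  expect_equal(cl$group, "mitosis-first")
  expect_equal(cl$t_mito, 20)
  expect_equal(cl$t_ddr, 30)
  ## DDR crosses at 10 h, morphology never reaches 3
  cl2 <- classifyOnset(tcOf(up(99, 4), "b"), tcOf(up(10, 2), "b"))
  expect_equal(cl2$group, "ddr-first")
  expect_true(is.na(cl2$t_mito))
  ## both flat at 1 -> mild
  cl3 <- classifyOnset(tcOf(rep(1, 80), "c"), tcOf(rep(1, 80), "c"))
  expect_equal(cl3$group, "mild")
  expect_equal(cl3$sort_key, Inf)
  ## tie -> mitosis-first
  cl4 <- classifyOnset(tcOf(up(15, 4), "d"), tcOf(up(15, 2), "d"))
  expect_equal(cl4$group, "mitosis-first")
})

test_that("raising the morphology threshold only empties mitosis-first", {
  up <- function(at, to, n = 80, dt = 0.5) {
    f <- rep(1, n); f[(seq_len(n) - 1) * dt >= at] <- to; f
  }
  morph <- tcOf(up(12, 3.5), "m")
  ddr <- tcOf(up(25, 2), "m")
  lo <- classifyOnset(morph, ddr, mitoThreshold = 3)
  hi <- classifyOnset(morph, ddr, mitoThreshold = 4)
  expect_equal(lo$group, "mitosis-first")
  expect_false(hi$group == "mitosis-first")
})

test_that("the heat map orders mild, then groups by DDR onset", {
  up <- function(at, to, n = 40, dt = 0.5) {
    f <- rep(1, n); f[(seq_len(n) - 1) * dt >= at] <- to; f
  }
  tcs <- list(
    tcOf(up(15, 2), "lateDDR"), tcOf(up(10, 2), "earlyDDR"),
    tcOf(rep(1, 40), "quiet"), tcOf(up(5, 2), "ddrOnly"))
  morphs <- list(
    tcOf(up(5, 4, 40), "lateDDR"), tcOf(up(5, 4, 40), "earlyDDR"),
    tcOf(rep(1, 40), "quiet"), tcOf(rep(1, 40), "ddrOnly"))
  cls <- do.call(rbind, Map(classifyOnset, morphs, tcs))
  hm <- buildHeatmap(tcs, cls)
  expect_equal(rownames(hm$matrix),
               c("quiet", "earlyDDR", "lateDDR", "ddrOnly"))
  expect_equal(hm$classifications$group,
               c("mild", "mitosis-first", "mitosis-first", "ddr-first"))
  ## within-group ascending by DDR onset
  expect_equal(hm$classifications$sort_key[2:3], c(10, 15))
  expect_error(buildHeatmap(list(), cls), "no time courses")
})

test_that("heat-map colors anchor white at the series mean", {
  v <- c(1, 1.5, 2, 2.5, 3)
  cols <- heatmapColors(v)            # mean = 2 -> white
  expect_equal(cols[3], "#FFFFFF")
  expect_equal(heatmapColors(rep(1.3, 5)), rep("#FFFFFF", 5))
  ## monotone: below-anchor values are blue-ish, above red-ish
  rgbv <- grDevices::col2rgb(cols)
  expect_true(all(rgbv["blue", 1:2] >= rgbv["red", 1:2]))
  expect_true(all(rgbv["red", 4:5] >= rgbv["blue", 4:5]))
})
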