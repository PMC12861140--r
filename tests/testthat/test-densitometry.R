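test_that("region intensity stats match hand-computed values", {
  img <- matrix(0, 64, 64)
  img[1, 1:4] <- c(40, 50, 50, 60)
  f <- ScheimpflugFrame(img)
  mask <- matrix(FALSE, 64, 64); mask[1, 1:4] <- TRUE
  st <- regionIntensityStats(f, mask)
  expect_equal(unname(st["mean"]), 50)
  expect_equal(unname(st["sd"]), sqrt(sum(c(-10, 0, 0, 10)^2) / 3),
               tolerance = 1e-12)                      # 8.16497 (n-1 form)

  const <- matrix(FALSE, 64, 64); const[2, 1:5] <- TRUE
  img2 <- img; img2[2, 1:5] <- 50
  st2 <- regionIntensityStats(ScheimpflugFrame(img2), const)
  expect_equal(unname(st2), c(50, 0))

  one <- matrix(FALSE, 64, 64); one[3, 3] <- TRUE
  expect_equal(unname(regionIntensityStats(f, one)["sd"]), 0)

  expect_error(regionIntensityStats(f, matrix(FALSE, 64, 64)),
               class = "DegenerateRegion")
})

test_that("full-frame stats equal a brute-force loop oracle", {
  ph <- makePhantom(phantomSpec(seed = 21))
  px <- framePixels(ph$frame)
  acc <- 0; n <- 0
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    acc <- acc + px[i, j]; n <- n + 1
  }
  bruteMean <- acc / n
  ss <- 0
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    ss <- ss + (px[i, j] - bruteMean)^2
  }
  st <- regionIntensityStats(ph$frame, matrix(TRUE, nrow(px), ncol(px)))
  expect_equal(unname(st["mean"]), bruteMean, tolerance = 1e-12)
  expect_equal(unname(st["sd"]), sqrt(ss / (n - 1)), tolerance = 1e-12)
})

test_that("the adaptive threshold is MPI plus three SDs, unclamped", {
  expect_equal(artefactThreshold(50, 10), 80)
  expect_equal(artefactThreshold(47.2, 0), 47.2)
  expect_equal(artefactThreshold(50, sqrt(200 / 3)), 50 + 3 * sqrt(200 / 3))
  expect_gt(artefactThreshold(250, 30), 255)   # no clamping at 8-bit ceiling
})

test_that("artefact percentage counts strictly super-threshold pixels", {
  img <- matrix(0, 64, 64)
  img[1, 1:8] <- c(10, 10, 10, 80, 80, 50, 50, 50)   # 2 of 8 above T = 60
  f <- ScheimpflugFrame(img)
  mask <- matrix(FALSE, 64, 64); mask[1, 1:8] <- TRUE
  expect_equal(artefactPercentage(f, mask, 60), 25)
  expect_equal(artefactPercentage(f, mask, 100), 0)
  expect_equal(artefactPercentage(f, mask, 80), 0)    # ties are not artefacts
  expect_error(artefactPercentage(f, matrix(FALSE, 64, 64), 60),
               class = "DegenerateRegion")
})

test_that("planted artefact fractions are recovered to the pixel quantum", {
  for (s in 1:5) {
    fIris <- c(0, 0.02, 0.1, 0.25, 0.4)[s]
    ph <- makePhantom(phantomSpec(artefactFractionIris = fIris,
                                  artefactFractionLateral = 0.05, seed = s))
    fd <- analyzeFrame(ph$frame, ph$masks)
    expect_equal(fd$pctIris, 100 * ph$truth$plantedIris / ph$truth$nIris,
                 tolerance = 1e-12)
    expect_lte(abs(fd$pctIris - 100 * fIris), 100 / ph$truth$nIris)
    expect_equal(fd$pctLateral,
                 100 * ph$truth$plantedLateral / ph$truth$nLateral,
                 tolerance = 1e-12)
  }
})

test_that("percentages are shift-invariant and cd shifts by the constant", {
  ph <- makePhantom(phantomSpec(artefactFractionIris = 0.1, seed = 31))
  fd <- analyzeFrame(ph$frame, ph$masks)
  shifted <- ScheimpflugFrame(framePixels(ph$frame) + 20,
                              eyeId = eyeId(ph$frame))
  fs <- analyzeFrame(shifted, ph$masks)
  expect_equal(fs$mpiCornea, fd$mpiCornea + 20, tolerance = 1e-12)
  expect_equal(fs$pctIris, fd$pctIris)
  expect_equal(fs$pctLateral, fd$pctLateral)
  expect_equal(fs$pctOverall, fd$pctOverall)
})

test_that("raising an iris pixel above threshold never decreases pctIris", {
  ph <- makePhantom(phantomSpec(artefactFractionIris = 0.05, seed = 41))
  fd <- analyzeFrame(ph$frame, ph$masks)
  px <- framePixels(ph$frame)
  below <- which(irisMask(ph$masks) & px <= fd$threshold)
  px[below[1]] <- 255
  bumped <- analyzeFrame(ScheimpflugFrame(px), ph$masks)
  expect_gte(bumped$pctIris, fd$pctIris)
})

test_that("overall percentage is the pixel-weighted union of the regions", {
  ph <- makePhantom(phantomSpec(artefactFractionIris = 0.2,
                                artefactFractionLateral = 0.05, seed = 51))
  fd <- analyzeFrame(ph$frame, ph$masks)
  nI <- ph$truth$nIris; nL <- ph$truth$nLateral
  expect_equal(fd$pctOverall,
               (fd$pctIris * nI + fd$pctLateral * nL) / (nI + nL),
               tolerance = 1e-12)
  expect_true(all(c(fd$pctIris, fd$pctLateral, fd$pctOverall) >= 0))
  expect_true(all(c(fd$pctIris, fd$pctLateral, fd$pctOverall) <= 100))
  expect_gte(fd$threshold, fd$mpiCornea)
})

test_that("per-eye aggregation is the unweighted mean over frames", {
  ph <- makePhantom(phantomSpec(artefactFractionIris = 0.1, seed = 61))
  fd <- analyzeFrame(ph$frame, ph$masks)
  same <- do.call(rbind, replicate(25, fd, simplify = FALSE))
  agg <- aggregateEye(same)
  expect_equal(agg$nFrames, 25)
  expect_equal(agg$cd, fd$mpiCornea)
  expect_equal(agg$pctIris, fd$pctIris)

  two <- fd[c(1, 1), ]; two$mpiCornea <- c(40, 60)
  expect_equal(aggregateEye(two)$cd, 50)

  expect_error(aggregateEye(fd[0, ]), class = "EmptyInput")
})

test_that("a seeded multi-frame eye aggregates to the per-field loop mean", {
  rows <- lapply(1:6, function(i) {
    ph <- makePhantom(phantomSpec(artefactFractionIris = 0.02 * i, seed = i))
    fr <- ScheimpflugFrame(framePixels(ph$frame), eyeId = "E1",
                           meridianIndex = i)
    analyzeFrame(fr, ph$masks)
  })
  tab <- do.call(rbind, rows)
  agg <- aggregateEye(tab)
  for (col in c("pctIris", "pctLateral", "pctOverall")) {
    acc <- 0
    for (i in 1:6) acc <- acc + tab[[col]][i]
    expect_equal(agg[[col]], acc / 6, tolerance = 1e-12)
    expect_gte(agg[[col]], min(tab[[col]]))
    expect_lte(agg[[col]], max(tab[[col]]))
  }
})
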