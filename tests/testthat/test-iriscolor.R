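# Frozen oracle for mid-gray (119,119,119): standard sRGB linearization,
# sRGB -> XYZ (D65) matrix, XYZ -> Lab closed form, evaluated by hand:
#   v = ((119/255 + 0.055)/1.055)^2.4 = 0.184475
#   Y = v (achromatic), L = 116 * f(Y) - 16 = 50.03444, a = b = 0
midGrayL <- 50.0344387925

test_that("sRGB white, black and mid-gray map to the CIELAB references", {
  white <- rgbToCielab(array(255, c(1, 1, 3)))[1, 1, ]
  expect_equal(unname(white), c(100, 0, 0), tolerance = 1e-6)
  black <- rgbToCielab(array(0, c(1, 1, 3)))[1, 1, ]
  expect_equal(unname(black), c(0, 0, 0), tolerance = 1e-6)
  gray <- rgbToCielab(array(119, c(1, 1, 3)))[1, 1, ]
  expect_equal(unname(gray[1]), midGrayL, tolerance = 1e-4)
  expect_equal(unname(gray[2:3]), c(0, 0), tolerance = 1e-6)
  expect_error(rgbToCielab(matrix(1, 4, 4)), class = "NotColorImage")
})

test_that("ROI summaries reduce Lab pixels as requested", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(255, 255, 255)
  lab <- rgbToCielab(img)
  roi1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  s <- summarizeIrisRoi(lab, roi1, eyeId = "E")
  expect_equal(s$L, 100, tolerance = 1e-6)
  expect_equal(s$eyeId, "E")

  roiAll <- matrix(TRUE, 2, 2)
  s2 <- summarizeIrisRoi(lab, roiAll)
  expect_equal(s2$L, mean(lab[, , "L"]), tolerance = 1e-12)
  s3 <- summarizeIrisRoi(lab, roiAll, stat = "median")
  expect_equal(s3$L, median(lab[, , "L"]), tolerance = 1e-12)

  expect_error(summarizeIrisRoi(lab, matrix(FALSE, 2, 2)),
               class = "DegenerateRegion")
})

test_that("synthetic iris patches summarize to the planted Lab truth", {
  for (p in c(0, 0.4, 1)) {
    im <- makeIrisImage(p, seed = 5, noiseSd = 2)
    s <- summarizeIrisRoi(rgbToCielab(im$image), im$roi)
    expect_lt(max(abs(c(s$L, s$a, s$b) - im$truth$lab)), 0.5)
  }
})

test_that("cohort normalization uses median and interpolated-quantile IQR", {
  vals <- data.frame(eyeId = paste0("E", 1:5),
                     L = c(1, 2, 3, 4, 5), a = c(2, 4, 6, 8, 10),
                     b = c(0, 1, 2, 3, 10))
  nrm <- fitCohortNormalization(vals)
  expect_equal(unname(cohortMedians(nrm)), c(3, 6, 2))
  expect_equal(unname(cohortIqrs(nrm)), c(2, 4, 2))   # type-7 quantiles
  expect_equal(cohortSize(nrm), 5L)

  # independent sort-based oracle on a seeded cohort
  set.seed(9)
  co <- data.frame(eyeId = paste0("E", 1:40), L = rnorm(40, 60, 8),
                   a = rnorm(40, 5, 4), b = rnorm(40, 8, 6))
  nrm2 <- fitCohortNormalization(co)
  for (cmp in c("L", "a", "b")) {
    x <- sort(co[[cmp]])
    q <- function(p) {                 # linear interpolation between order stats
      hpos <- (length(x) - 1) * p + 1
      lo <- floor(hpos)
      x[lo] + (hpos - lo) * (x[min(lo + 1, length(x))] - x[lo])
    }
    expect_equal(unname(cohortMedians(nrm2)[cmp]), q(0.5), tolerance = 1e-12)
    expect_equal(unname(cohortIqrs(nrm2)[cmp]), q(0.75) - q(0.25),
                 tolerance = 1e-12)
  }

  expect_error(fitCohortNormalization(vals[1:3, ]), class = "CohortTooSmall")
  same <- vals; same$a <- 7
  expect_error(fitCohortNormalization(same), class = "ZeroIQR")
})

test_that("component normalization and the composite index are exact", {
  expect_equal(normalizeComponent(3, 3, 2), 0)
  expect_equal(normalizeComponent(5, 3, 2), 1)
  expect_error(normalizeComponent(1, 0, 0), class = "ZeroIQR")

  expect_equal(irisColorIndex(0, 0, 0), 0)
  expect_equal(irisColorIndex(1, 0, 0), -1)
  expect_equal(irisColorIndex(-1, 1, 1), 3)
})

test_that("pigmentation classification follows the sign rule", {
  expect_identical(classifyPigmentation(c(-0.5, 2, 0)),
                   c("light", "dark", "indeterminate"))
})

test_that("scored cohorts are self-centred with unit IQR per component", {
  set.seed(13)
  co <- data.frame(eyeId = paste0("E", 1:30), L = rnorm(30, 55, 10),
                   a = rnorm(30, 4, 5), b = rnorm(30, 6, 8))
  sc <- scoreIrisCohort(co)
  for (cmp in c("Ln", "an", "bn")) {
    expect_equal(median(sc[[cmp]]), 0, tolerance = 1e-10)
    expect_equal(unname(diff(quantile(sc[[cmp]], c(0.25, 0.75)))), 1,
                 tolerance = 1e-10)
  }
  expect_equal(sc$irisColor, -sc$Ln + sc$an + sc$bn, tolerance = 1e-12)
})

test_that("the index responds in the right direction per component", {
  set.seed(17)
  co <- data.frame(eyeId = paste0("E", 1:20), L = rnorm(20, 55, 10),
                   a = rnorm(20, 4, 5), b = rnorm(20, 6, 8))
  nrm <- fitCohortNormalization(co)
  med <- cohortMedians(nrm); iqr <- cohortIqrs(nrm)
  score <- function(L, a, b) {
    irisColorIndex(normalizeComponent(L, med["L"], iqr["L"]),
                   normalizeComponent(a, med["a"], iqr["a"]),
                   normalizeComponent(b, med["b"], iqr["b"]))
  }
  base <- score(55, 4, 6)
  expect_lt(score(60, 4, 6), base)   # brighter iris scores lighter
  expect_gt(score(55, 9, 6), base)
  expect_gt(score(55, 4, 11), base)
})

test_that("rank order along a noise-free pigmentation gradient is exact", {
  levels <- seq(0, 1, length.out = 11)
  summaries <- do.call(rbind, lapply(seq_along(levels), function(i) {
    im <- makeIrisImage(levels[i], seed = i, noiseSd = 0)
    summarizeIrisRoi(rgbToCielab(im$image), im$roi,
                     eyeId = sprintf("E%02d", i))
  }))
  sc <- scoreIrisCohort(summaries)
  expect_identical(order(sc$irisColor), seq_along(levels))
  expect_equal(cor(sc$irisColor, levels, method = "spearman"), 1)
  # level-0 eye scores below the level-1 eye in the same cohort
  expect_lt(sc$irisColor[1], sc$irisColor[11])
})

test_that("the metric is cohort-relative: adding an eye changes all scores", {
  set.seed(19)
  co <- data.frame(eyeId = paste0("E", 1:12), L = rnorm(12, 55, 8),
                   a = rnorm(12, 4, 3), b = rnorm(12, 6, 4))
  sc1 <- scoreIrisCohort(co)
  extreme <- data.frame(eyeId = "X", L = 95, a = -10, b = -25)
  sc2 <- scoreIrisCohort(rbind(co, extreme))
  expect_false(isTRUE(all.equal(sc1$irisColor,
                                sc2$irisColor[seq_len(12)])))
})

test_that("polygon masks rasterize convex ROIs", {
  sq <- polygonMask(cbind(c(2, 2, 8, 8), c(2, 8, 8, 2)), 10, 10)
  expect_true(sq[5, 5])
  expect_false(sq[1, 1])
  expect_false(sq[10, 10])
})
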