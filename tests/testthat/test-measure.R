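sinImage <- function(period = 20, n = 128, px = 1, noise = 0, seed = 1) {
  set.seed(seed)
  prof <- sin(2 * pi * (seq_len(n) - 0.5) * px / period)
  m <- matrix(rep(prof, 20), n, 20) +
    matrix(rnorm(n * 20, sd = noise), n, 20)
  new("ProjectionImage", pixels = m - min(m), pixelSize = px,
      projectionAxis = "y", modality = "mass-thickness")
}

test_that("period estimator is exact on a sinusoid and fails on noise", {
  est <- estimateDPeriod(sinImage(period = 20), periodRange = c(10, Inf))
  expect_equal(est$value_nm, 20, tolerance = 0.01)
  set.seed(4)
  wn <- new("ProjectionImage",
            pixels = matrix(abs(rnorm(128 * 20)), 128, 20),
            pixelSize = 1, projectionAxis = "y",
            modality = "mass-thickness")
  expect_error(estimateDPeriod(wn), "no periodicity")
})

test_that("D-period of the synthetic longitudinal view is the configured 67 nm", {
  est <- estimateDPeriod(longImage())
  expect_equal(est$value_nm, 67, tolerance = 1 / 67)
  expect_gte(est$n, 3)
})

test_that("period estimators are unbiased within 2% across 40-100 nm", {
  # gap/overlap-like asymmetric square waves (60% duty cycle) plus noise
  for (period in c(40, 55, 67, 82, 100)) {
    x <- (seq_len(512) - 0.5) %% period
    prof <- ifelse(x < 0.6 * period, 1, 0.35)
    set.seed(period)
    m <- matrix(rep(prof, 16), 512, 16) +
      matrix(rnorm(512 * 16, sd = 0.1), 512, 16)
    img <- new("ProjectionImage", pixels = m - min(m), pixelSize = 1,
               projectionAxis = "y", modality = "mass-thickness")
    est <- estimateDPeriod(img)
    expect_lt(abs(est$value_nm - period) / period, 0.02)
  }
})

test_that("lane spacing recovers the lattice pitch", {
  expect_equal(measureLaneSpacing(longImage())$value_nm, 77,
               tolerance = 2 / 77)
  # a different pitch, via a narrower fibril + stack
  g60 <- UnitCellGeometry(fibrilWidth = 40, stackWidth = 20)
  s60 <- buildScene(SceneConfig(geometry = g60, nFibrils = 3L,
                                nPeriods = 2L))
  expect_equal(measureLaneSpacing(projectScene(s60, "y"))$value_nm, 60,
               tolerance = 2 / 60)
  # a single fibril offers no repeat to measure
  s1 <- buildScene(SceneConfig(nFibrils = 1L, nPeriods = 2L))
  expect_error(measureLaneSpacing(projectScene(s1, "y")))
})

test_that("FWHM of a rectangular pulse equals its width", {
  prof <- rep(0, 60)
  prof[20:29] <- 8
  m <- matrix(rep(prof, 5), 60, 5)
  img <- new("ProjectionImage", pixels = m, pixelSize = 1,
             projectionAxis = "x", modality = "mass-thickness")
  est <- measurePlateThickness(img, list(from = c(1, 2.5),
                                         to = c(60, 2.5)))
  expect_equal(est$value_nm, 10, tolerance = 0.1)
  expect_error(measurePlateThickness(
    new("ProjectionImage", pixels = m * 0, pixelSize = 1,
        projectionAxis = "x", modality = "mass-thickness"),
    list(from = c(1, 2.5), to = c(60, 2.5))),
    "no feature")
})

test_that("plate thickness is recovered from cross-section transects", {
  # default scene: 4 plates of 5 nm across the central lane
  est5 <- measurePlateThickness(crossImage(),
                                list(from = c(115.5, 139),
                                     to = c(115.5, 180)))
  expect_equal(est5$value_nm, 5, tolerance = 1 / 5)
  expect_equal(est5$n, 4)
  # rebuilt scene with 10 nm plates in single-plate stacks
  g10 <- UnitCellGeometry(plateThickness = 10, stackWidth = 20)
  s10 <- buildScene(SceneConfig(geometry = g10, nFibrils = 2L,
                                nPeriods = 2L, plateStackDepth = 1L))
  est10 <- measurePlateThickness(projectScene(s10, "x"),
                                 list(from = c(30, 30), to = c(30, 100)))
  expect_equal(est10$value_nm, 10, tolerance = 1 / 10)
})

test_that("ellipse fitting recovers analytic discs and oblique sections", {
  mkimg <- function(mask) new("ProjectionImage",
                              pixels = 1 - mask, pixelSize = 1,
                              projectionAxis = "x",
                              modality = "mass-thickness")
  n <- 101
  ctr <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n) - ctr
  xx <- t(yy)
  # disc of radius 20 px
  disc <- (xx^2 + yy^2) < 20^2
  h <- fitHoleEllipses(mkimg(disc), intensityThreshold = 0.5)
  expect_equal(nrow(h), 1L)
  expect_equal(h$major_nm, 40, tolerance = 1 / 40)
  expect_equal(h$minor_nm, 40, tolerance = 1 / 40)
  expect_equal(h$eccentricity, 1, tolerance = 0.02)
  # cylinder radius r cut at angle theta to its normal plane:
  # ellipse with semi-axes r / cos(theta) and r
  for (thetaDeg in c(20, 40)) {
    a <- 18 / cos(thetaDeg * pi / 180)
    ell <- ((xx / a)^2 + (yy / 18)^2) < 1
    h <- fitHoleEllipses(mkimg(ell), intensityThreshold = 0.5)
    expect_equal(h$eccentricity, 1 / cos(thetaDeg * pi / 180),
                 tolerance = 0.05)
  }
})

test_that("hole fits of the default cross-section match the lattice", {
  holes <- fitHoleEllipses(crossImage())
  holes <- holes[holes$area_nm2 > 1000, ]   # the fibril loci
  cfg <- defaultConfig()
  expect_equal(nrow(holes), cfg@nFibrils^2)
  expect_true(all(holes$eccentricity >= 1))
  # the hole footprint is the square cell bounded by the plate stacks;
  # its moment-equivalent axes are side * 2 / sqrt(3)
  side <- cfg@geometry@fibrilWidth
  expect_equal(mean(holes$minor_nm), side * 2 / sqrt(3),
               tolerance = 0.03)
  expect_equal(holeAxesMean(54.6, 36.3), 45.45)
  expect_equal(holeAxesMean(10, 20), 15)
})

test_that("band contrast is ordered lane > gap > overlap", {
  img <- longImage()
  mk <- regionMasks(defaultConfig(), dim(pixels(img)), pixelSize(img))
  bc <- bandContrastProfile(img, mk)
  expect_gt(bc$lane_mean, bc$gap_mean)
  expect_gt(bc$gap_mean, bc$overlap_mean)
  # the overlap mean is far from zero: the plate slabs cast counts
  # everywhere ("dark cast")
  expect_gt(bc$overlap_mean, 0.25 * bc$gap_mean)
  # without plates only the gap zones carry signal
  s0 <- buildScene(smallConfig(plateStackDepth = 0L, voxelSize = 2))
  img0 <- projectScene(s0, "y")
  mk0 <- regionMasks(sceneConfigOf(s0), dim(pixels(img0)),
                     pixelSize(img0))
  bc0 <- bandContrastProfile(img0, mk0)
  expect_equal(bc0$lane_mean, 0)
  expect_equal(bc0$overlap_mean, 0)
  expect_gt(bc0$gap_mean, 0)
  # uniform field: all equal
  u <- new("ProjectionImage", pixels = matrix(2, 201, 231),
           pixelSize = 1, projectionAxis = "y",
           modality = "mass-thickness")
  mku <- regionMasks(defaultConfig(), c(201, 231), 1)
  bcu <- bandContrastProfile(u, mku)
  expect_equal(bcu$gap_mean, bcu$overlap_mean)
  expect_equal(bcu$gap_mean, bcu$lane_mean)
})

test_that("measurements are invariant to global intensity scaling", {
  img <- longImage()
  scaled <- new("ProjectionImage", pixels = pixels(img) * 37.5,
                pixelSize = pixelSize(img), projectionAxis = "y",
                modality = "mass-thickness")
  expect_equal(estimateDPeriod(scaled)$value_nm,
               estimateDPeriod(img)$value_nm)
  expect_equal(measureLaneSpacing(scaled)$value_nm,
               measureLaneSpacing(img)$value_nm)
  xs <- crossImage()
  xsScaled <- new("ProjectionImage", pixels = pixels(xs) * 37.5,
                  pixelSize = pixelSize(xs), projectionAxis = "x",
                  modality = "mass-thickness")
  tr <- list(from = c(115.5, 139), to = c(115.5, 180))
  expect_equal(measurePlateThickness(xsScaled, tr)$value_nm,
               measurePlateThickness(xs, tr)$value_nm)
  h1 <- fitHoleEllipses(xs)
  h2 <- fitHoleEllipses(xsScaled)
  expect_equal(h2$major_nm, h1$major_nm)
})
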