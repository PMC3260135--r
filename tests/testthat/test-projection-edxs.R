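# a uniform unit-density cube built directly, bypassing buildScene
uniformScene <- function(n = 40, v = 1) {
  dens <- array(1, dim = c(n, n, n))
  labs <- array(3L, dim = c(n, n, n))
  new("VoxelScene", caDensity = dens, labels = labs, voxelSize = v,
      config = smallConfig(), plates = data.frame(),
      groundTruth = extrafib:::computeGroundTruth(dens, labs))
}

test_that("projection of a uniform cube is the path length, any axis", {
  sc <- uniformScene(n = 40, v = 1)
  for (ax in c("x", "y", "z")) {
    img <- projectScene(sc, ax)
    expect_true(all(pixels(img) == 40))
  }
  # numeric principal-axis vectors are accepted; oblique axes are not
  expect_equal(pixels(projectScene(sc, c(0, 1, 0))),
               pixels(projectScene(sc, "y")))
  expect_error(projectScene(sc, c(1, 1, 0)), "principal axes")
})

test_that("projection conserves mass for structured scenes", {
  sc <- defaultScene()
  tot <- sum(caDensity(sc)) * voxelSize(sc)
  for (ax in c("x", "y", "z"))
    expect_equal(sum(pixels(projectScene(sc, ax))), tot)
})

test_that("longitudinal projection has the D-period autocorrelation peak", {
  img <- longImage()
  prof <- rowMeans(pixels(img))
  prof <- prof - mean(prof)
  # brute-force lag search, independent of the estimator code
  lags <- 30:100
  ac <- sapply(lags, function(L) {
    n <- length(prof)
    sum(prof[1:(n - L)] * prof[(L + 1):n])
  })
  expect_equal(lags[which.max(ac)], 67, tolerance = 1)
})

test_that("cross-section has high mineral signal around low fibril discs", {
  img <- crossImage()
  lb <- sceneLabels(defaultScene())
  # label masks in the (y, z) plane: a pixel is plate/fibril if any voxel
  # along the beam carries that label
  plateMask <- apply(lb == 3L, c(2, 3), any)
  fibrilMask <- apply(lb == 1L | lb == 2L, c(2, 3), any)
  expect_gt(mean(pixels(img)[plateMask & !fibrilMask]),
            mean(pixels(img)[fibrilMask]))
})

test_that("EDXS counts follow Poisson statistics per probe position", {
  # 16 x 16 image in four uniform 8 x 8 quadrants; 2 x 2 nm probe tiles
  # never straddle a quadrant boundary
  vals <- c(0, 20, 50, 120)
  m <- rbind(cbind(matrix(vals[1], 8, 8), matrix(vals[2], 8, 8)),
             cbind(matrix(vals[3], 8, 8), matrix(vals[4], 8, 8)))
  img <- new("ProjectionImage", pixels = m, pixelSize = 1,
             projectionAxis = "y", modality = "mass-thickness")
  reps <- sapply(1:1200, function(s)
    as.vector(pixels(simulateEdxs(img, probeArea = 4, doseScale = 0.5,
                                  seed = s))))
  expected <- 0.5 * as.vector(extrafib:::integrateTiles(img, 4)$mat)
  mu <- rowMeans(reps)
  v <- apply(reps, 1, var)
  # zero-density probes never count; means track dose x integral
  expect_true(all(reps[expected == 0, ] == 0))
  expect_equal(mu[expected > 0], expected[expected > 0], tolerance = 0.05)
  # variance ~ mean (Fano factor ~ 1) over >= 1000 replicates
  fano <- v[expected > 0] / mu[expected > 0]
  expect_lt(abs(mean(fano) - 1), 0.05)
})

test_that("counts divided by dose converge to the integrated density", {
  sc <- buildScene(smallConfig(voxelSize = 2))
  img <- projectScene(sc, "y")
  tiles <- extrafib:::integrateTiles(img, 100)
  cm <- simulateEdxs(img, probeArea = 100, doseScale = 1e4, seed = 9)
  expect_equal(pixels(cm) / 1e4, tiles$mat, tolerance = 2e-3)
})

test_that("region rates on a uniform image are identical", {
  cfg <- defaultConfig()
  img <- new("ProjectionImage", pixels = matrix(5, 201, 231),
             pixelSize = 1, projectionAxis = "y",
             modality = "mass-thickness")
  mk <- regionMasks(cfg, dim(pixels(img)), 1)
  r <- regionRates(img, mk)
  expect_equal(r$C_O, r$C_G)
  expect_equal(r$C_G, r$C_V)
})

test_that("overlap-zone rate comes from the plate slabs alone", {
  slab <- defaultSlab()
  img <- longImage()
  mk <- regionMasks(defaultConfig(), dim(pixels(img)), pixelSize(img))
  lb <- sceneLabels(slab)
  dn <- caDensity(slab)
  w <- which(mk$O, arr.ind = TRUE)
  set.seed(5)
  w <- w[sample(nrow(w), 300), ]
  for (i in seq_len(nrow(w))) {
    beamLabels <- lb[w[i, 1], , w[i, 2]]
    beamDens <- dn[w[i, 1], , w[i, 2]]
    # nothing but plates contributes along an overlap-zone beam path
    expect_equal(sum(beamDens[beamLabels != 3L]), 0)
    expect_equal(sum(beamDens) * voxelSize(slab),
                 pixels(img)[w[i, 1], w[i, 2]])
  }
})

test_that("noise-free region rates are ordered V > G > O as observed", {
  img <- longImage()
  mk <- regionMasks(defaultConfig(), dim(pixels(img)), pixelSize(img))
  r <- regionRates(img, mk)
  expect_gt(r$C_V, r$C_G)
  expect_gt(r$C_G, r$C_O)
  expect_error(sampleRegionCounts(img, list(O = matrix(FALSE, 201, 231),
                                            G = mk$G, V = mk$V), "O"),
               "empty region mask")
})
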