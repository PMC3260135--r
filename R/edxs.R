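#' Simulate an EDXS count map from a projection image
#'
#' Tiles the image into square probe positions of area \code{probeArea}
#' and draws, per tile, a Poisson count with mean
#' \code{doseScale x integrated density over the tile} (pixel value x
#' pixel area summed over the tile). This models thin-section EDXS where
#' the count rate over an area is proportional to the total mineral below
#' it. Zero-density tiles always yield zero counts.
#'
#' @param image a mass-thickness [ProjectionImage-class]
#' @param probeArea probe tile area, nm^2 (default 100, i.e. 10 x 10 nm)
#' @param doseScale expected counts per unit of integrated density
#'   (relative density x nm^3)
#' @param seed integer seed, or NULL to use the current RNG state
#' @return a [ProjectionImage-class] of modality \code{"ca-counts"} whose
#'   pixels are counts per probe tile and whose pixel size is the probe
#'   edge
#' @examples
#' sc <- buildScene(SceneConfig(nFibrils = 2, nPeriods = 2, voxelSize = 2))
#' cm <- simulateEdxs(projectScene(sc, "y"), doseScale = 0.01, seed = 1)
#' @rdname simulateEdxs
#' @export
setMethod("simulateEdxs", "ProjectionImage",
          function(image, probeArea = 100, doseScale = 1, seed = NULL) {
  stopifnot(image@modality == "mass-thickness", doseScale > 0,
            probeArea > 0)
  tiles <- integrateTiles(image, probeArea)
  expected <- doseScale * tiles$mat
  counts <- withSeed(seed,
    matrix(stats::rpois(length(expected), expected),
           nrow(expected), ncol(expected)))
  new("ProjectionImage", pixels = counts, pixelSize = tiles$tileNm,
      projectionAxis = image@projectionAxis, modality = "ca-counts")
})

# block-sum the image into square tiles of ~sqrt(probeArea) edge;
# returns integrated density (value x nm^2) per tile
integrateTiles <- function(image, probeArea) {
  px <- image@pixelSize
  s <- max(1L, round(sqrt(probeArea) / px))
  d <- dim(image@pixels)
  n1 <- d[1] %/% s; n2 <- d[2] %/% s
  if (n1 < 1L || n2 < 1L) stop("probe tile larger than the image")
  m <- image@pixels[seq_len(n1 * s), seq_len(n2 * s), drop = FALSE]
  dim(m) <- c(s, n1, s * n2)
  m <- colSums(m)                       # (n1, s * n2)
  dim(m) <- c(n1, s, n2)
  m <- aperm(m, c(2, 1, 3))
  dim(m) <- c(s, n1 * n2)
  m <- colSums(m)
  dim(m) <- c(n1, n2)
  list(mat = m * px^2, tileNm = s * px)
}

#' Region masks for the O / G / V analysis areas of a longitudinal view
#'
#' Builds logical masks on the pixel grid of a longitudinal projection
#' (beam along y): \code{O} overlap-zone bands over the fibril columns,
#' \code{G} gap-zone bands over the fibril columns, \code{V} the lanes of
#' vertical mineral-structure stacks between the columns. Each mask spans
#' the full footprint of its compartment so that region-mean count rates
#' multiplied by the compartment areas recover compartment totals.
#'
#' @param config the [SceneConfig-class] the image was generated from
#' @param dims image dimensions in pixels (rows along x, cols along z)
#' @param pixelSize image pixel size, nm
#' @return list of logical matrices \code{O}, \code{G}, \code{V}
#' @export
regionMasks <- function(config, dims, pixelSize) {
  g <- config@geometry
  p <- config@pitch
  D <- dPeriod(g)
  xs <- (seq_len(dims[1]) - 0.5) * pixelSize
  zs <- (seq_len(dims[2]) - 0.5) * pixelSize
  colBand <- abs(wrapCentered(zs - p / 2, p)) < g@fibrilWidth / 2
  laneBand <- !colBand
  gapBand <- (xs %% D) < g@gapLength
  list(O = outer(!gapBand, colBand, "&"),
       G = outer(gapBand, colBand, "&"),
       V = outer(rep(TRUE, dims[1]), laneBand, "&"))
}

#' Mean count rate over a region mask
#'
#' Averages an image over a region: counts/nm^2 for count maps
#' (\code{sum(counts) / mask area}); for mass-thickness images the region
#' mean of the density path, which is proportional to the count rate and
#' serves as the noise-free expected rate (the partition estimator is
#' scale invariant).
#'
#' @param image a [ProjectionImage-class]
#' @param masks list of logical masks from [regionMasks()]
#' @param region which region to sample, \code{"O"}, \code{"G"} or
#'   \code{"V"}
#' @return the region rate (scalar)
#' @export
sampleRegionCounts <- function(image, masks, region = c("O", "G", "V")) {
  region <- match.arg(region)
  m <- masks[[region]]
  stopifnot(identical(dim(m), dim(image@pixels)))
  if (!any(m)) stop("empty region mask for ", region)
  vals <- image@pixels[m]
  if (image@modality == "ca-counts")
    sum(vals) / (length(vals) * image@pixelSize^2)
  else mean(vals)
}

#' Count rates from single probe areas centred on each analysis region
#'
#' Emulates the reference measurement protocol: one square probe area per
#' region, centred on a representative feature (a gap band at a fibril
#' column centre, the adjacent overlap band, the middle of a lane of
#' mineral structures), with the recorded counts drawn from a Poisson law
#' with mean \code{doseScale x integrated density over the probe}. With
#' \code{doseScale = NULL} the noise-free expected rate is returned.
#' Probe-level Poisson scatter at realistic doses (a few hundred counts
#' per probe) dominates the sample-to-sample variability of the resulting
#' partition estimates.
#'
#' @param image a longitudinal mass-thickness [ProjectionImage-class]
#' @param config the [SceneConfig-class] the image derives from
#' @param probeArea probe area, nm^2 (default 100)
#' @param doseScale expected counts per unit integrated density, or NULL
#'   for noise-free rates
#' @param seed integer seed for the Poisson draws
#' @param label sample identifier
#' @return a one-row count-rate data.frame (counts/nm^2 per region)
#' @export
probeRegionRates <- function(image, config, probeArea = 100,
                             doseScale = NULL, seed = NULL,
                             label = "probe") {
  stopifnot(image@modality == "mass-thickness")
  g <- config@geometry
  p <- config@pitch
  D <- dPeriod(g)
  n <- config@nFibrils
  midPeriod <- floor(config@nPeriods / 2) * D
  colC <- (ceiling(n / 2) - 0.5) * p      # a central fibril column
  chanC <- if (n > 1) ceiling(n / 2) * p else p / 2
  centres <- list(
    G = c(midPeriod + g@gapLength / 2, colC),
    O = c(midPeriod + g@gapLength + g@overlapLength / 2, colC),
    V = c(midPeriod + D / 2, chanC))
  s <- sqrt(probeArea)
  px <- image@pixelSize
  d <- dim(image@pixels)
  xs <- (seq_len(d[1]) - 0.5) * px
  zs <- (seq_len(d[2]) - 0.5) * px
  rate1 <- function(ctr) {
    ix <- which(xs >= ctr[1] - s / 2 & xs < ctr[1] + s / 2)
    iz <- which(zs >= ctr[2] - s / 2 & zs < ctr[2] + s / 2)
    if (!length(ix) || !length(iz)) stop("probe area outside the image")
    area <- length(ix) * length(iz) * px^2
    integral <- sum(image@pixels[ix, iz]) * px^2
    if (is.null(doseScale)) integral / area
    else stats::rpois(1L, doseScale * integral) / area
  }
  withSeed(seed, {
    countRateTriple(C_O = rate1(centres$O), C_G = rate1(centres$G),
                    C_V = rate1(centres$V), label = label)
  })
}

#' Count-rate triple for all three analysis regions
#'
#' Convenience wrapper over [sampleRegionCounts()] returning a one-row
#' count table ready for [correctCounts()] / [externalFraction()].
#'
#' @inheritParams sampleRegionCounts
#' @param label sample identifier
#' @return a one-row count-rate data.frame
#' @export
regionRates <- function(image, masks, label = "scene") {
  countRateTriple(C_O = sampleRegionCounts(image, masks, "O"),
                  C_G = sampleRegionCounts(image, masks, "G"),
                  C_V = sampleRegionCounts(image, masks, "V"),
                  label = label)
}
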