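#' Project a scene along a principal axis
#'
#' Line integral of the Ca density along the beam direction, the
#' mass-thickness contrast proxy for a thin section (no diffraction
#' contrast; collagen itself contributes no Ca signal). Pixel values carry
#' nm units (density x path length) and the image conserves mass: the
#' pixel sum equals the voxel density sum times the voxel size.
#'
#' Axis \code{"y"} (or \code{"z"}) gives a longitudinal view showing the
#' D-banding and the lanes of mineral structures; axis \code{"x"}
#' (the fibril axis) gives the cross-section view with its open, lacy
#' pattern of mineral surrounding low-density fibril discs. With
#' \code{vacancy = TRUE} and a cross-section view, the configured fraction
#' of fibril discs is rendered vacant (interior zeroed), emulating
#' preferential erosion of collagen during ion milling; the scene ground
#' truth is never affected.
#'
#' @param scene a [VoxelScene-class]
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}, or a principal-axis
#'   unit vector
#' @param vacancy apply the vacancy mask (cross-section view only)
#' @return a [ProjectionImage-class]
#' @examples
#' sc <- buildScene(SceneConfig(nFibrils = 2, nPeriods = 2, voxelSize = 2))
#' img <- projectScene(sc, "y")
#' sum(pixels(img)) == sum(caDensity(sc)) * voxelSize(sc)
#' @rdname projectScene
#' @export
setMethod("projectScene", "VoxelScene",
          function(scene, axis = "y", vacancy = FALSE) {
  axis <- normalizeAxis(axis)
  A <- scene@caDensity
  v <- scene@voxelSize
  px <- switch(axis,
    x = colSums(A, dims = 1),                      # (y, z)
    y = rowSums(aperm(A, c(1, 3, 2)), dims = 2),   # (x, z)
    z = rowSums(A, dims = 2)) * v                  # (x, y)
  img <- new("ProjectionImage", pixels = px, pixelSize = v,
             projectionAxis = axis, modality = "mass-thickness")
  if (vacancy && scene@config@vacancyFraction > 0) {
    if (axis != "x")
      warning("vacancy mask applies to cross-section views only; ignored")
    else img <- applyVacancyMask(img, scene@config)
  }
  img
})

normalizeAxis <- function(axis) {
  if (is.character(axis)) {
    axis <- match.arg(axis, c("x", "y", "z"))
    return(axis)
  }
  stopifnot(is.numeric(axis), length(axis) == 3)
  a <- abs(axis / sqrt(sum(axis^2)))
  i <- which(a > 1 - 1e-9)
  if (length(i) != 1L)
    stop("projection supports principal axes only; cut an oblique slab ",
         "with cutSection() and project along a principal axis")
  c("x", "y", "z")[i]
}

# zero the interior of a seeded subset of fibril discs in a cross-section
# image (display realism only; ground truth untouched)
applyVacancyMask <- function(img, config) {
  p <- config@pitch
  n <- config@nFibrils
  fw <- config@geometry@fibrilWidth
  nVacant <- floor(config@vacancyFraction * n * n)
  if (nVacant == 0L) return(img)
  centres <- expand.grid(cy = (seq_len(n) - 0.5) * p,
                         cz = (seq_len(n) - 0.5) * p)
  pick <- withSeed(config@seed + 1L,
                   sample.int(nrow(centres), nVacant))
  px <- img@pixels
  d <- dim(px)
  ys <- (seq_len(d[1]) - 0.5) * img@pixelSize
  zs <- (seq_len(d[2]) - 0.5) * img@pixelSize
  for (i in pick) {
    r2 <- outer((ys - centres$cy[i])^2, (zs - centres$cz[i])^2, "+")
    px[r2 < (fw / 2)^2] <- 0
  }
  new("ProjectionImage", pixels = px, pixelSize = img@pixelSize,
      projectionAxis = img@projectionAxis, modality = img@modality)
}

#' @rdname accessors
setMethod("pixels", "ProjectionImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixelSize", "ProjectionImage", function(x) x@pixelSize)

setMethod("show", "ProjectionImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ProjectionImage (%s): %d x %d px @ %g nm, axis %s\n",
              object@modality, d[1], d[2], object@pixelSize,
              object@projectionAxis))
  invisible(NULL)
})

#' Write / read a projection image as 32-bit TIFF with a metadata sidecar
#'
#' Pixel values are stored normalized to [0, 1]; the scale factor, pixel
#' size (nm), projection axis and modality go into a YAML sidecar
#' (\code{<path>.meta.yaml}) so the round trip restores physical units.
#'
#' @param img a [ProjectionImage-class]
#' @param path TIFF file path
#' @return \code{readProjectionTIFF} returns a [ProjectionImage-class];
#'   \code{writeProjectionTIFF} returns \code{path} invisibly
#' @export
writeProjectionTIFF <- function(img, path) {
  stopifnot(is(img, "ProjectionImage"))
  scale <- max(img@pixels, 1e-12)
  tiff::writeTIFF(img@pixels / scale, path, bits.per.sample = 32L,
                  compression = "none")
  yaml::write_yaml(list(scale = scale, pixel_size_nm = img@pixelSize,
                        projection_axis = img@projectionAxis,
                        modality = img@modality),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname writeProjectionTIFF
#' @export
readProjectionTIFF <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  px <- tiff::readTIFF(path)
  new("ProjectionImage", pixels = px * meta$scale,
      pixelSize = meta$pixel_size_nm,
      projectionAxis = meta$projection_axis, modality = meta$modality)
}
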