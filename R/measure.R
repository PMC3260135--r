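# Measurement operators on projection images. All results are in nm
# (pixel-size metadata is authoritative) and invariant to global
# intensity scaling.

measurementRecord <- function(kind, value, n, spread = NA_real_) {
  data.frame(kind = kind, value_nm = value, sd_nm = spread, n = n)
}

# dominant period of a 1D profile: autocorrelation peak with sub-pixel
# parabolic refinement. minPeak is the minimum normalized autocorrelation
# at the peak for a period to be accepted (white noise stays well below
# it for any realistic profile length).
periodFromProfile <- function(profile, pixelSize, minPeak = 0.2,
                              periodRange = c(30, Inf)) {
  n <- length(profile)
  lagMax <- floor(n / 2)
  minLagPx <- max(3L, ceiling(periodRange[1] / pixelSize))
  maxLagPx <- min(lagMax - 1L, floor(periodRange[2] / pixelSize))
  if (maxLagPx <= minLagPx)
    stop("profile too short to estimate a period in the given range")
  r <- as.numeric(stats::acf(profile, lag.max = lagMax, plot = FALSE,
                             demean = TRUE)$acf)   # r[k + 1] = lag k
  lags <- minLagPx:maxLagPx
  isMax <- vapply(lags, function(k)
    r[k + 1] > r[k] && r[k + 1] >= r[k + 2], logical(1))
  cand <- lags[isMax]
  if (!length(cand) || max(r[cand + 1]) < minPeak)
    stop("no periodicity above the noise floor")
  k <- cand[which.max(r[cand + 1])]
  # parabolic interpolation through the peak and its neighbours
  y0 <- r[k]; y1 <- r[k + 1]; y2 <- r[k + 2]
  denom <- y0 - 2 * y1 + y2
  delta <- if (denom != 0) 0.5 * (y0 - y2) / denom else 0
  list(period = (k + delta) * pixelSize, peak = y1)
}

#' Estimate the collagen D-period from a longitudinal projection
#'
#' Averages the image into a 1D profile along the band normal (the fibril
#' axis) and returns the dominant period of that profile from its
#' autocorrelation peak, refined to sub-pixel precision by parabolic
#' interpolation. Autocorrelation is used rather than a raw spectral peak
#' because the gap/overlap banding is strongly non-sinusoidal (sharp or
#' diffuse band edges).
#'
#' @param image a longitudinal [ProjectionImage-class] (rows along the
#'   fibril axis)
#' @param bandNormal in-plane direction across the bands: \code{c(1, 0)}
#'   (image rows, the default) or \code{c(0, 1)} (image columns)
#' @param minPeak minimum normalized autocorrelation at the peak
#' @param periodRange physical search window for the period, nm. The
#'   default lower bound of 30 nm keeps the estimator on the banding /
#'   lane scale and below-resolution features such as the intra-stack
#'   plate repeat out of the search
#' @return a one-row measurement data.frame (kind, value_nm, sd_nm, n)
#' @examples
#' sc <- buildScene(SceneConfig(nFibrils = 2, nPeriods = 3))
#' estimateDPeriod(projectScene(sc, "y"))
#' @export
estimateDPeriod <- function(image, bandNormal = c(1, 0), minPeak = 0.2,
                            periodRange = c(30, Inf)) {
  stopifnot(is(image, "ProjectionImage"))
  prof <- profileAlong(image, bandNormal)
  est <- periodFromProfile(prof, image@pixelSize, minPeak = minPeak,
                           periodRange = periodRange)
  nRepeats <- round(length(prof) * image@pixelSize / est$period)
  measurementRecord("d_period", est$period, nRepeats)
}

profileAlong <- function(image, direction) {
  stopifnot(length(direction) == 2)
  if (abs(direction[1]) >= abs(direction[2])) rowMeans(image@pixels)
  else colMeans(image@pixels)
}

#' Lane spacing of mineral-structure bundles
#'
#' Period of the profile perpendicular to the fibril axis in a
#' longitudinal view: the spacing of the lanes of vertical mineral-plate
#' stacks, equal to the fibril lattice pitch. Uses the same
#' autocorrelation estimator as [estimateDPeriod()].
#'
#' @inheritParams estimateDPeriod
#' @return a one-row measurement data.frame
#' @export
measureLaneSpacing <- function(image, minPeak = 0.2,
                               periodRange = c(30, Inf)) {
  stopifnot(is(image, "ProjectionImage"))
  prof <- profileAlong(image, c(0, 1))
  est <- periodFromProfile(prof, image@pixelSize, minPeak = minPeak,
                           periodRange = periodRange)
  nRepeats <- round(length(prof) * image@pixelSize / est$period)
  measurementRecord("lane_spacing", est$period, nRepeats)
}

#' Plate thickness by full width at half maximum along a transect
#'
#' Samples the image along a line segment crossing one or more mineral
#' plates perpendicular to their long axes, and measures each feature as
#' the full width at half maximum of its peak (half level midway between
#' the profile baseline and maximum; crossings located by linear
#' interpolation). \code{polarity = "dark"} inverts the profile for
#' bright-field style images where mineral is dark.
#'
#' @param image a [ProjectionImage-class]
#' @param transect list with \code{from} and \code{to}, each an (row, col)
#'   position in nm
#' @param polarity \code{"bright"} if plates are high intensity (Ca maps,
#'   mass thickness), \code{"dark"} for inverted contrast
#' @param minRelHeight minimum peak height relative to the profile range
#'   for a feature to count
#' @return a one-row measurement data.frame (mean width, SD, n features)
#' @export
measurePlateThickness <- function(image, transect,
                                  polarity = c("bright", "dark"),
                                  minRelHeight = 0.25) {
  stopifnot(is(image, "ProjectionImage"))
  polarity <- match.arg(polarity)
  px <- image@pixelSize
  from <- transect$from / px
  to <- transect$to / px
  len <- sqrt(sum((to - from)^2))
  nStep <- max(2L, ceiling(len * 2))   # ~half-pixel sampling
  tt <- seq(0, 1, length.out = nStep)
  rr <- pmin(pmax(round(from[1] + tt * (to[1] - from[1]) + 0.5), 1),
             nrow(image@pixels))
  cc <- pmin(pmax(round(from[2] + tt * (to[2] - from[2]) + 0.5), 1),
             ncol(image@pixels))
  prof <- image@pixels[cbind(rr, cc)]
  if (polarity == "dark") prof <- max(prof) - prof
  stepNm <- len * px / (nStep - 1)
  widths <- fwhmWidths(prof, stepNm, minRelHeight)
  if (!length(widths)) stop("no feature above threshold along transect")
  measurementRecord("plate_thickness", mean(widths), length(widths),
                    if (length(widths) > 1) stats::sd(widths) else NA_real_)
}

# widths of all contiguous features above the global half level
fwhmWidths <- function(prof, stepNm, minRelHeight = 0.25) {
  lo <- min(prof); hi <- max(prof)
  if (hi - lo <= 0) return(numeric())
  half <- lo + (hi - lo) / 2
  above <- prof >= half
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1); ends <- which(d == -1) - 1L
  widths <- numeric()
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    if (max(prof[s:e]) - lo < minRelHeight * (hi - lo)) next
    # interpolate the half crossings just outside the run
    left <- if (s > 1)
      (s - 1) + (half - prof[s - 1]) / (prof[s] - prof[s - 1]) else s - 0.5
    right <- if (e < length(prof))
      e + (prof[e] - half) / (prof[e] - prof[e + 1]) else e + 0.5
    widths <- c(widths, (right - left) * stepNm)
  }
  widths
}

#' Fit equivalent ellipses to the low-intensity holes of a cross-section
#'
#' Segments the connected components below an intensity threshold (Otsu's
#' threshold by default, since no segmentation rule is implied by the
#' imaging itself), discards components touching the image border (their
#' axes are not measurable), and reports per component the
#' moment-equivalent ellipse: major/minor axes from the eigenvalues of
#' the pixel-coordinate covariance (full axis = 4 sqrt(lambda)) and
#' eccentricity = major/minor. In cross-section views of bone the holes
#' are the low-mineral fibril loci surrounded by mineral structures.
#'
#' @param image a cross-section [ProjectionImage-class]
#' @param intensityThreshold fraction of the maximum intensity to
#'   threshold at, or NULL for Otsu
#' @param minAreaPx discard components smaller than this (speckle guard)
#' @return data.frame with one row per hole: kind, major_nm, minor_nm,
#'   eccentricity, area_nm2
#' @export
fitHoleEllipses <- function(image, intensityThreshold = NULL,
                            minAreaPx = 9L) {
  stopifnot(is(image, "ProjectionImage"))
  pxv <- image@pixels
  thr <- if (is.null(intensityThreshold)) {
    rng <- range(pxv)
    if (diff(rng) == 0) return(emptyHoleTable())
    EBImage::otsu(EBImage::Image((pxv - rng[1]) / diff(rng)),
                  range = c(0, 1)) * diff(rng) + rng[1]
  } else {
    stopifnot(intensityThreshold > 0, intensityThreshold < 1)
    intensityThreshold * max(pxv)
  }
  holes <- pxv < thr
  if (!any(holes)) return(emptyHoleTable())
  lab <- EBImage::bwlabel(EBImage::Image(holes * 1))
  labm <- EBImage::imageData(lab)
  border <- unique(c(labm[1, ], labm[nrow(labm), ], labm[, 1],
                     labm[, ncol(labm)]))
  ids <- setdiff(seq_len(max(labm)), border)
  out <- lapply(ids, function(id) {
    idx <- which(labm == id, arr.ind = TRUE)
    if (nrow(idx) < minAreaPx) return(NULL)
    co <- stats::cov(idx * image@pixelSize)
    # + voxel variance so a 1-px-wide region has nonzero extent
    ev <- sort(eigen(co, symmetric = TRUE, only.values = TRUE)$values +
                 image@pixelSize^2 / 12, decreasing = TRUE)
    major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
    data.frame(kind = "hole_ellipse", major_nm = major, minor_nm = minor,
               eccentricity = major / minor,
               area_nm2 = nrow(idx) * image@pixelSize^2)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) emptyHoleTable() else out
}

emptyHoleTable <- function() {
  data.frame(kind = character(), major_nm = numeric(),
             minor_nm = numeric(), eccentricity = numeric(),
             area_nm2 = numeric())
}

#' Mean of the major and minor hole axes
#'
#' Arithmetic mean of the average major and minor axes, the conventional
#' single-number hole size.
#'
#' @param majorMean,minorMean mean axes in nm
#' @return their arithmetic mean, nm
#' @examples
#' holeAxesMean(54.6, 36.3)  # 45.45
#' @export
holeAxesMean <- function(majorMean, minorMean) {
  stopifnot(majorMean > 0, minorMean > 0)
  (majorMean + minorMean) / 2
}

#' Mean projected density per analysis region
#'
#' Region means of a longitudinal image over the gap, overlap and lane
#' masks. In the default scene the ordering is
#' lane > gap > overlap, and the overlap mean is nonzero because the beam
#' always traverses the over/underlying mineral plates - the "dark cast"
#' over the whole section.
#'
#' @param image a longitudinal [ProjectionImage-class]
#' @param masks region masks from [regionMasks()]
#' @return list with \code{gap_mean}, \code{overlap_mean},
#'   \code{lane_mean}
#' @export
bandContrastProfile <- function(image, masks) {
  for (r in c("O", "G", "V"))
    if (!any(masks[[r]])) stop("empty region mask for ", r)
  list(gap_mean = mean(image@pixels[masks$G]),
       overlap_mean = mean(image@pixels[masks$O]),
       lane_mean = mean(image@pixels[masks$V]))
}
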