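# Orientation statistics of the mineral c-axes. The 00l lattice planes of
# hydroxyapatite stack along the crystal c-axis, which in bone runs along
# the long axis of the mineral plates; the angular scatter of plate long
# axes about the fibril axis therefore sets the azimuthal extent of the
# 00l diffraction arcs, and their visibility in a given view is a purely
# geometric question of how many c-axes lie close to the plane normal to
# the beam.

checkAngles <- function(angles) {
  if (!length(angles)) stop("empty orientation distribution")
  if (any(!is.finite(angles)) || any(abs(angles) > 90))
    stop("axis angles must be finite and within [-90, 90] degrees")
  angles
}

#' Angular extent of the 00l diffraction arcs
#'
#' The arc subtended by the 00l reflections equals the angular span of the
#' c-axis population about the fibril axis: the symmetric interval
#' containing the central \code{coverage} fraction of axis angles, doubled.
#' A population uniform within +/- 18 degrees subtends 36 degrees at full
#' coverage.
#'
#' @param angles c-axis (plate long-axis) angles vs the fibril axis,
#'   degrees; see \code{plateAngles()} for scene-derived values
#' @param coverage central fraction of axes the arc must contain
#' @return arc extent in degrees
#' @examples
#' arcExtent(seq(-18, 18, by = 0.5))   # 36
#' arcExtent(rep(0, 10))               # 0
#' @export
arcExtent <- function(angles, coverage = 1.0) {
  angles <- checkAngles(angles)
  stopifnot(coverage > 0, coverage <= 1)
  a <- if (coverage >= 1) max(abs(angles))
       else unname(stats::quantile(abs(angles), coverage, type = 7))
  2 * a
}

#' Visibility of 00l reflections in a given view
#'
#' Fraction of c-axes that satisfy the in-plane Bragg condition for the
#' given view, i.e. lie within \code{tol} degrees of the plane normal to
#' the beam. Axis angles are polar angles about the fibril axis; the
#' azimuth is drawn uniformly (Monte Carlo) since nothing orients the
#' plates azimuthally. For a beam along the fibril axis and a tight axial
#' texture the visibility is ~0 (c-axes point down the beam), which is why
#' cross-section diffraction patterns show almost no 00l reflections; for
#' a perpendicular beam it approaches 1.
#'
#' @param angles c-axis angles vs the fibril axis, degrees
#' @param viewAxis \code{"parallel"} / \code{"perpendicular"} (to the
#'   fibril axis), or a length-3 vector with the fibril axis along x
#' @param tol in-plane Bragg tolerance, degrees
#' @param nDraws Monte-Carlo draws
#' @param seed integer seed, or NULL
#' @return visibility fraction in [0, 1]
#' @examples
#' visibility00l(rep(0, 100), "perpendicular")  # 1
#' visibility00l(rep(0, 100), "parallel")       # 0
#' @export
visibility00l <- function(angles, viewAxis = "parallel", tol = 5,
                          nDraws = 1e5, seed = NULL) {
  angles <- checkAngles(angles)
  v <- if (is.character(viewAxis)) {
    switch(match.arg(viewAxis, c("parallel", "perpendicular")),
           parallel = c(1, 0, 0), perpendicular = c(0, 1, 0))
  } else {
    stopifnot(length(viewAxis) == 3)
    viewAxis / sqrt(sum(viewAxis^2))
  }
  withSeed(seed, {
    th <- sample(angles, nDraws, replace = TRUE) * pi / 180
    ph <- stats::runif(nDraws, 0, 2 * pi)
    dotv <- abs(cos(th) * v[1] + sin(th) * cos(ph) * v[2] +
                  sin(th) * sin(ph) * v[3])
    angToBeam <- acos(pmin(1, dotv)) * 180 / pi
    mean(angToBeam >= 90 - tol)
  })
}

#' Orientation samples from CSV and texture report
#'
#' \code{readOrientationCSV} reads a single-column CSV of axis angles
#' (column \code{angle_deg}); \code{textureReport} bundles the arc extent
#' and per-view visibilities and optionally writes them as JSON.
#'
#' @param path CSV path
#' @return numeric vector of angles, degrees
#' @export
readOrientationCSV <- function(path) {
  x <- utils::read.csv(path)
  if (!"angle_deg" %in% names(x))
    stop("orientation CSV must have a column 'angle_deg'")
  checkAngles(x$angle_deg)
}

#' @rdname readOrientationCSV
#' @inheritParams visibility00l
#' @param out optional JSON output path (requires jsonlite)
#' @export
textureReport <- function(angles, tol = 5, nDraws = 1e5, seed = NULL,
                          out = NULL) {
  rep <- list(
    arc_deg = arcExtent(angles),
    visibility_parallel = visibility00l(angles, "parallel", tol, nDraws,
                                        seed),
    visibility_perpendicular = visibility00l(angles, "perpendicular", tol,
                                             nDraws, seed))
  if (!is.null(out)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("writing the report requires the jsonlite package")
    jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA)
  }
  rep
}
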