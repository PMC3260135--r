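#' @rdname projectedAreas
#' @export
setGeneric("projectedAreas", function(geom, roundTo = NULL)
  standardGeneric("projectedAreas"))

#' @rdname dPeriod
#' @export
setGeneric("dPeriod", function(x) standardGeneric("dPeriod"))

#' @rdname buildScene
#' @export
setGeneric("buildScene", function(config) standardGeneric("buildScene"))

#' @rdname cutSection
#' @export
setGeneric("cutSection", function(scene, normal, thickness, offset = 0)
  standardGeneric("cutSection"))

#' @rdname projectScene
#' @export
setGeneric("projectScene", function(scene, axis = "y", vacancy = FALSE)
  standardGeneric("projectScene"))

#' @rdname simulateEdxs
#' @export
setGeneric("simulateEdxs", function(image, probeArea = 100, doseScale = 1,
                                    seed = NULL)
  standardGeneric("simulateEdxs"))

#' Accessors for scene and image objects
#'
#' \code{geometry} returns the [UnitCellGeometry-class] of a config or
#' scene; \code{sceneConfigOf} the [SceneConfig-class] of a scene;
#' \code{groundTruth} the exact voxel-summation mineral partition;
#' \code{caDensity} and \code{sceneLabels} the 3D fields; \code{pixels} and
#' \code{pixelSize} the image data; \code{plateAngles} the plate long-axis
#' angles (degrees, relative to the fibril axis).
#'
#' @param x an object of the documented classes
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("sceneConfigOf", function(x) standardGeneric("sceneConfigOf"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("caDensity", function(x) standardGeneric("caDensity"))

#' @rdname accessors
#' @export
setGeneric("sceneLabels", function(x) standardGeneric("sceneLabels"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("plateAngles", function(x) standardGeneric("plateAngles"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
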