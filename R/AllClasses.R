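#' @import methods
NULL

#' Unit-cell geometry of the mineralized collagen ultrastructure
#'
#' An S4 class holding the dimensions of the rectangular unit volume used to
#' interpret EDXS count rates from longitudinal sections of cortical bone.
#' The unit cell contains one fibril segment spanning one D-period
#' (gap + overlap zone), the vertical stack of plate-like mineral structures
#' separating it from the neighbouring fibril, and the over/underlying
#' mineral plates above and below the fibril layer.
#'
#' All lengths are in nanometres. The defaults describe human femoral
#' cortical bone: 50 nm fibrils with a 40 nm gap / 27 nm overlap D-period,
#' 27 nm wide inter-fibril stacks of 5 x 65 x 200 nm mineral plates, and a
#' 100 nm section thickness.
#'
#' @slot fibrilWidth fibril diameter (nm)
#' @slot gapLength axial length of the gap zone (nm)
#' @slot overlapLength axial length of the overlap zone (nm)
#' @slot stackWidth width of the inter-fibril mineral-structure stack (nm)
#' @slot plateThickness mineral plate thickness (nm)
#' @slot plateWidth mineral plate width (nm)
#' @slot plateLength mineral plate length (nm)
#' @slot sectionThickness TEM section thickness (nm)
#'
#' @seealso [UnitCellGeometry()] for the user-facing constructor,
#'   [projectedAreas()] for the compartment areas derived from it.
#' @export
setClass("UnitCellGeometry",
  representation(
    fibrilWidth = "numeric",
    gapLength = "numeric",
    overlapLength = "numeric",
    stackWidth = "numeric",
    plateThickness = "numeric",
    plateWidth = "numeric",
    plateLength = "numeric",
    sectionThickness = "numeric"
  )
)

setValidity("UnitCellGeometry", function(object) {
  slots <- c("fibrilWidth", "gapLength", "overlapLength", "stackWidth",
             "plateThickness", "plateWidth", "plateLength",
             "sectionThickness")
  for (s in slots) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      return(sprintf("'%s' must be a single finite number", s))
    # stackWidth 0 is a permitted degenerate case (no inter-fibril stack)
    if (s == "stackWidth") {
      if (v < 0) return("'stackWidth' must be >= 0")
    } else if (v <= 0) {
      return(sprintf("'%s' must be > 0", s))
    }
  }
  TRUE
})

#' Projected compartment areas of the unit cell
#'
#' Areas (nm^2) of the four compartments of the unit-cell model as seen in
#' projection along the beam: G (gap zone), O (overlap zone), V (vertical
#' inter-fibril mineral stack) and H (over/underlying mineral plates, which
#' span the whole cell).
#'
#' @slot A_G gap-zone area, fibrilWidth x gapLength (nm^2)
#' @slot A_O overlap-zone area, fibrilWidth x overlapLength (nm^2)
#' @slot A_V vertical-stack area, stackWidth x dPeriod (nm^2)
#' @slot A_H over/underlying-plate area, (fibrilWidth + stackWidth) x
#'   dPeriod (nm^2)
#' @export
setClass("ProjectedAreas",
  representation(A_G = "numeric", A_O = "numeric",
                 A_V = "numeric", A_H = "numeric")
)

setValidity("ProjectedAreas", function(object) {
  v <- c(object@A_G, object@A_O, object@A_V, object@A_H)
  if (any(!is.finite(v)) || any(v < 0))
    return("all areas must be finite and >= 0")
  TRUE
})

#' Configuration of a synthetic bone-ultrastructure scene
#'
#' Describes a periodic 3D voxel scene of mineralized collagen: cylindrical
#' fibrils on a square lattice with D-periodic gap/overlap banding in
#' registry, wrapped by stacks of plate-like mineral structures whose long
#' axes scatter about the fibril axis.
#'
#' @slot geometry a [UnitCellGeometry-class] object
#' @slot lattice fibril packing, currently \code{"square"}
#' @slot pitch lattice pitch (nm); default fibrilWidth + stackWidth
#' @slot nFibrils fibrils per side of the lattice
#' @slot nPeriods number of D-periods along the fibril axis
#' @slot plateStackDepth plates per inter-fibril stack
#' @slot plateAxisDispersion half-angle (degrees) of the uniform scatter of
#'   plate long axes about the fibril axis
#' @slot gapMineralDensity relative Ca density in gap zones, in [0, 1]
#' @slot overlapMineralDensity relative Ca density in overlap zones
#' @slot voxelSize voxel edge (nm); must resolve the plates
#'   (<= plateThickness / 2)
#' @slot vacancyFraction fraction of fibril cross-sections eroded to vacancy
#'   in cross-section renders (display only; never affects ground truth)
#' @slot seed integer seed controlling plate placement
#' @export
setClass("SceneConfig",
  representation(
    geometry = "UnitCellGeometry",
    lattice = "character",
    pitch = "numeric",
    nFibrils = "integer",
    nPeriods = "integer",
    plateStackDepth = "integer",
    plateAxisDispersion = "numeric",
    gapMineralDensity = "numeric",
    overlapMineralDensity = "numeric",
    voxelSize = "numeric",
    vacancyFraction = "numeric",
    seed = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  g <- object@geometry
  ok <- validObject(g, test = TRUE)
  if (!isTRUE(ok)) return(ok)
  if (!identical(object@lattice, "square"))
    return("only 'square' fibril packing is implemented")
  if (object@pitch < g@fibrilWidth)
    return("pitch must be at least fibrilWidth (fibrils must not overlap)")
  if (object@nFibrils < 1L) return("nFibrils must be >= 1")
  if (object@nPeriods < 1L) return("nPeriods must be >= 1")
  if (object@plateStackDepth < 0L) return("plateStackDepth must be >= 0")
  if (object@plateAxisDispersion < 0 || object@plateAxisDispersion > 90)
    return("plateAxisDispersion must be in [0, 90] degrees")
  for (s in c("gapMineralDensity", "overlapMineralDensity",
              "vacancyFraction")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) return(sprintf("'%s' must be in [0, 1]", s))
  }
  if (object@voxelSize <= 0) return("voxelSize must be > 0")
  if (object@voxelSize > g@plateThickness / 2)
    return("voxelSize must be <= plateThickness / 2 to resolve the plates")
  if (object@plateStackDepth > 0L) {
    channel <- object@pitch - g@fibrilWidth
    if (object@plateStackDepth * g@plateThickness > channel)
      return(paste0("plateStackDepth x plateThickness exceeds the ",
                    "inter-fibril channel width; plates would overlap ",
                    "fibril interiors"))
  }
  TRUE
})

#' Voxelized synthetic ultrastructure scene
#'
#' A periodic 3D scalar field of relative Ca density together with a
#' categorical compartment labelling and the exact ground-truth mineral
#' partition obtained by voxel summation. Dimension 1 of the arrays runs
#' along the fibril axis.
#'
#' @slot caDensity 3D numeric array of relative Ca density per voxel
#' @slot labels 3D integer array; 0 background, 1 gap, 2 overlap, 3 plate
#' @slot voxelSize voxel edge (nm)
#' @slot config the [SceneConfig-class] the scene was built from
#' @slot plates data.frame of plate parameters (centres, orientation angles)
#' @slot groundTruth list with elements \code{external} (summed plate
#'   density), \code{internal} (summed gap density) and \code{X_ext_true}
#' @export
setClass("VoxelScene",
  representation(
    caDensity = "array",
    labels = "array",
    voxelSize = "numeric",
    config = "SceneConfig",
    plates = "data.frame",
    groundTruth = "list"
  )
)

setValidity("VoxelScene", function(object) {
  if (length(dim(object@caDensity)) != 3L)
    return("caDensity must be a 3D array")
  if (!identical(dim(object@caDensity), dim(object@labels)))
    return("caDensity and labels must have identical dimensions")
  if (any(object@caDensity < 0)) return("caDensity must be >= 0")
  gt <- object@groundTruth
  need <- c("external", "internal", "X_ext_true")
  if (!all(need %in% names(gt)))
    return("groundTruth must contain external, internal and X_ext_true")
  TRUE
})

#' 2D projection of a voxel scene
#'
#' Mass-thickness style line-integral image, or a simulated EDXS count map,
#' with a physical pixel size. Pixel values are the integral of relative Ca
#' density along the projection axis (nm units) for \code{"mass-thickness"},
#' or Poisson counts per probe tile for \code{"ca-counts"}.
#'
#' @slot pixels numeric matrix of pixel values
#' @slot pixelSize pixel edge (nm)
#' @slot projectionAxis one of "x" (fibril axis), "y", "z"
#' @slot modality "mass-thickness" or "ca-counts"
#' @export
setClass("ProjectionImage",
  representation(
    pixels = "matrix",
    pixelSize = "numeric",
    projectionAxis = "character",
    modality = "character"
  )
)

setValidity("ProjectionImage", function(object) {
  if (any(object@pixels < 0)) return("pixel values must be >= 0")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (!object@projectionAxis %in% c("x", "y", "z"))
    return("projectionAxis must be one of 'x', 'y', 'z'")
  if (!object@modality %in% c("mass-thickness", "ca-counts"))
    return("modality must be 'mass-thickness' or 'ca-counts'")
  TRUE
})
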