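# Scene construction: periodic voxel model of mineralized collagen.
# Conventions: array dim 1 = x (fibril axis), dims 2/3 = y/z (lattice
# plane); voxel centres at (i - 0.5) * voxelSize; everything is periodic
# in all three directions, so one scene is a representative tile of an
# infinite lattice and projections have no edge effects.

# centred periodic wrap of a displacement into (-L/2, L/2]
wrapCentered <- function(d, L) {
  ((d + L / 2) %% L) - L / 2
}

# run expr with a local RNG state seeded by `seed`
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Construct a synthetic-scene configuration
#'
#' Defaults describe the reference scene used throughout: a 3 x 3 square
#' lattice of 50 nm fibrils at 77 nm pitch (fibril width + stack width),
#' three D-periods (201 nm) along the fibril axis, stacks of four 5 nm
#' plates in every inter-fibril channel, plate long axes scattered
#' uniformly within +/- 18 degrees of the fibril axis, gap zones at 0.75
#' relative Ca density (plates are 1), mineral-free overlap zones, and
#' 1 nm voxels.
#'
#' @param geometry a [UnitCellGeometry-class]
#' @param lattice fibril packing; only \code{"square"} is implemented
#' @param pitch lattice pitch in nm; default fibrilWidth + stackWidth
#' @param nFibrils fibrils per lattice side
#' @param nPeriods D-periods along the fibril axis
#' @param plateStackDepth plates per inter-fibril stack
#' @param plateAxisDispersion half-angle of plate long-axis scatter, degrees
#' @param gapMineralDensity,overlapMineralDensity relative Ca densities
#' @param voxelSize voxel edge, nm
#' @param vacancyFraction fraction of fibril cross-sections rendered vacant
#'   in cross-section images (display only)
#' @param seed integer seed for plate placement
#' @return a validated [SceneConfig-class]
#' @examples
#' cfg <- SceneConfig(nFibrils = 2, nPeriods = 2)
#' @export
SceneConfig <- function(geometry = UnitCellGeometry(),
                        lattice = "square",
                        pitch = geometry@fibrilWidth + geometry@stackWidth,
                        nFibrils = 3L, nPeriods = 3L,
                        plateStackDepth = 4L,
                        plateAxisDispersion = 18,
                        gapMineralDensity = 0.75,
                        overlapMineralDensity = 0,
                        voxelSize = 1,
                        vacancyFraction = 0,
                        seed = 1L) {
  new("SceneConfig", geometry = geometry, lattice = lattice,
      pitch = as.numeric(pitch), nFibrils = as.integer(nFibrils),
      nPeriods = as.integer(nPeriods),
      plateStackDepth = as.integer(plateStackDepth),
      plateAxisDispersion = as.numeric(plateAxisDispersion),
      gapMineralDensity = as.numeric(gapMineralDensity),
      overlapMineralDensity = as.numeric(overlapMineralDensity),
      voxelSize = as.numeric(voxelSize),
      vacancyFraction = as.numeric(vacancyFraction),
      seed = as.integer(seed))
}

#' Read / write a scene configuration
#'
#' Scene configurations are stored as YAML with the geometry nested under
#' a \code{geometry} key.
#'
#' @param path file path
#' @param config a [SceneConfig-class]
#' @return \code{readSceneConfig} returns a [SceneConfig-class]
#' @export
readSceneConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$geometry <- do.call(UnitCellGeometry, vals$geometry)
  do.call(SceneConfig, vals)
}

#' @rdname readSceneConfig
#' @export
writeSceneConfig <- function(config, path) {
  stopifnot(is(config, "SceneConfig"))
  g <- config@geometry
  gv <- lapply(slotNames(g), function(s) slot(g, s))
  names(gv) <- slotNames(g)
  vals <- lapply(setdiff(slotNames(config), "geometry"),
                 function(s) slot(config, s))
  names(vals) <- setdiff(slotNames(config), "geometry")
  vals <- c(list(geometry = gv), vals)
  yaml::write_yaml(vals, path)
  invisible(path)
}

setMethod("show", "SceneConfig", function(object) {
  g <- object@geometry
  cat(sprintf(
    "SceneConfig: %d x %d fibrils (square lattice, pitch %g nm), %d D-periods\n",
    object@nFibrils, object@nFibrils, object@pitch, object@nPeriods))
  cat(sprintf(
    "  stacks %d-deep, dispersion +/-%g deg, gap density %g, voxel %g nm, seed %d\n",
    object@plateStackDepth, object@plateAxisDispersion,
    object@gapMineralDensity, object@voxelSize, object@seed))
  invisible(NULL)
})

#' @rdname accessors
setMethod("geometry", "SceneConfig", function(x) x@geometry)
#' @rdname accessors
setMethod("geometry", "VoxelScene", function(x) x@config@geometry)
#' @rdname accessors
setMethod("sceneConfigOf", "VoxelScene", function(x) x@config)
#' @rdname accessors
setMethod("groundTruth", "VoxelScene", function(x) x@groundTruth)
#' @rdname accessors
setMethod("caDensity", "VoxelScene", function(x) x@caDensity)
#' @rdname accessors
setMethod("sceneLabels", "VoxelScene", function(x) x@labels)
#' @rdname accessors
setMethod("voxelSize", "VoxelScene", function(x) x@voxelSize)
#' @rdname accessors
setMethod("plateAngles", "VoxelScene", function(x) x@plates$theta)

# label codes
.LBL <- c(background = 0L, gap = 1L, overlap = 2L, plate = 3L)

# exact partition by voxel summation; intrafibrillar = gap (+ any
# configured overlap-zone mineral)
computeGroundTruth <- function(density, labels) {
  external <- sum(density[labels == .LBL["plate"]])
  internal <- sum(density[labels == .LBL["gap"]]) +
    sum(density[labels == .LBL["overlap"]])
  tot <- external + internal
  list(external = external, internal = internal,
       X_ext_true = if (tot > 0) external / tot else NA_real_)
}

# table of plate parameters for a square-lattice scene. Channels run
# between adjacent rows (family "y") and columns (family "z"); each
# channel x column/row crossing hosts `depth` plates at symmetric offsets
# across the channel; long-axis angle theta ~ U(-disp, disp); axial
# centre cx ~ U(0, Lx) so plates are not in axial registry.
platePlan <- function(config) {
  g <- config@geometry
  p <- config@pitch
  n <- config@nFibrils
  depth <- config@plateStackDepth
  Lx <- config@nPeriods * dPeriod(g)
  if (depth == 0L)
    return(data.frame(family = character(), channel = integer(),
                      host = integer(), slot = integer(), cx = numeric(),
                      cAcross = numeric(), cAlong = numeric(),
                      theta = numeric()))
  # plates are tangential to the fibril surfaces: the innermost and
  # outermost plates sit flush against the two fibrils bounding the
  # channel, with the residual spacing shared between adjacent plates
  channelWidth <- p - g@fibrilWidth
  offsets <- if (depth == 1L) 0 else {
    gapBetween <- (channelWidth - depth * g@plateThickness) / (depth - 1)
    -channelWidth / 2 + g@plateThickness / 2 +
      (seq_len(depth) - 1) * (g@plateThickness + gapBetween)
  }
  grid <- expand.grid(slot = seq_len(depth), host = seq_len(n),
                      channel = seq_len(n), family = c("y", "z"),
                      stringsAsFactors = FALSE)
  nP <- nrow(grid)
  withSeed(config@seed, {
    theta <- stats::runif(nP, -config@plateAxisDispersion,
                          config@plateAxisDispersion)
    cx <- stats::runif(nP, 0, Lx)
  })
  data.frame(
    family = grid$family,
    channel = grid$channel,
    host = grid$host,
    slot = grid$slot,
    cx = cx,
    # centre along the channel normal (y for family "y", z for "z")
    cAcross = grid$channel * p + offsets[grid$slot],
    # centre along the plate width direction: the host fibril centre
    cAlong = (grid$host - 0.5) * p,
    theta = theta)
}

#' Build a voxelized synthetic ultrastructure scene
#'
#' Constructs the periodic 3D Ca-density field of the configured scene:
#' axis-aligned cylindrical fibrils with D-periodic gap/overlap banding in
#' registry across the lattice, and plate-like mineral structures stacked
#' in the inter-fibril channels, tangential to the fibril surfaces, with
#' long axes drawn uniformly within the configured dispersion of the
#' fibril axis. The exact ground-truth mineral partition is computed by
#' voxel summation. Construction is bit-reproducible from (config, seed).
#'
#' @param config a [SceneConfig-class]
#' @return a [VoxelScene-class]
#' @examples
#' scene <- buildScene(SceneConfig(nFibrils = 2, nPeriods = 2,
#'                                 voxelSize = 2))
#' groundTruth(scene)$X_ext_true
#' @rdname buildScene
#' @export
setMethod("buildScene", "SceneConfig", function(config) {
  validObject(config)
  g <- config@geometry
  v <- config@voxelSize
  p <- config@pitch
  D <- dPeriod(g)
  Lx <- config@nPeriods * D
  Lyz <- config@nFibrils * p
  nx <- round(Lx / v); nyz <- round(Lyz / v)
  if (abs(nx * v - Lx) > 1e-9 || abs(nyz * v - Lyz) > 1e-9)
    stop("voxelSize must divide both the D-period x nPeriods and the ",
         "lattice extent for a periodic scene")
  xs <- (seq_len(nx) - 0.5) * v
  ys <- (seq_len(nyz) - 0.5) * v
  zs <- ys

  # fibril cross-section mask on the (y, z) grid, periodic in the lattice
  dy <- wrapCentered(ys - p / 2, p)   # distance to nearest column centre
  r2 <- outer(dy^2, dy^2, "+")
  fibril2d <- r2 < (g@fibrilWidth / 2)^2
  gapBand <- (xs %% D) < g@gapLength

  dens <- array(0, dim = c(nx, nyz, nyz))
  labs <- array(.LBL[["background"]], dim = c(nx, nyz, nyz))
  # fibril banding: loop over x (cheap; one 2D assignment per slice)
  gapSlice <- ifelse(fibril2d, config@gapMineralDensity, 0)
  ovlSlice <- ifelse(fibril2d, config@overlapMineralDensity, 0)
  gapLab <- ifelse(fibril2d, .LBL[["gap"]], .LBL[["background"]])
  ovlLab <- ifelse(fibril2d, .LBL[["overlap"]], .LBL[["background"]])
  for (i in seq_len(nx)) {
    if (gapBand[i]) {
      dens[i, , ] <- gapSlice
      labs[i, , ] <- gapLab
    } else {
      dens[i, , ] <- ovlSlice
      labs[i, , ] <- ovlLab
    }
  }

  plates <- platePlan(config)
  plates$nVoxels <- integer(nrow(plates))
  halfL <- g@plateLength / 2
  halfW <- g@plateWidth / 2
  halfT <- g@plateThickness / 2
  for (k in seq_len(nrow(plates))) {
    pl <- plates[k, ]
    th <- pl$theta * pi / 180
    # thickness band along the channel normal
    wAcross <- wrapCentered(ys - pl$cAcross, Lyz)
    bandIdx <- which(wAcross >= -halfT & wAcross < halfT)
    # in-plane rotated rectangle: u along the long axis, w across the
    # plate width; all displacements wrapped into the periodic tile
    dxw <- wrapCentered(xs - pl$cx, Lx)
    dzw <- wrapCentered(zs - pl$cAlong, Lyz)
    u <- outer(dxw * cos(th), dzw * sin(th), "+")
    w <- outer(-dxw * sin(th), dzw * cos(th), "+")
    inPlane <- (u >= -halfL & u < halfL) & (w >= -halfW & w < halfW)
    if (!any(inPlane)) next
    nvox <- 0L
    for (b in bandIdx) {
      if (pl$family == "y") {
        labSlab <- labs[, b, ][inPlane]
        if (any(labSlab == .LBL[["gap"]] | labSlab == .LBL[["overlap"]]))
          stop("plate overlaps a fibril interior; invalid configuration")
        sl <- dens[, b, ]; sl[inPlane] <- 1; dens[, b, ] <- sl
        sl <- labs[, b, ]; sl[inPlane] <- .LBL[["plate"]]; labs[, b, ] <- sl
      } else {
        labSlab <- labs[, , b][inPlane]
        if (any(labSlab == .LBL[["gap"]] | labSlab == .LBL[["overlap"]]))
          stop("plate overlaps a fibril interior; invalid configuration")
        sl <- dens[, , b]; sl[inPlane] <- 1; dens[, , b] <- sl
        sl <- labs[, , b]; sl[inPlane] <- .LBL[["plate"]]; labs[, , b] <- sl
      }
      nvox <- nvox + sum(inPlane)
    }
    plates$nVoxels[k] <- nvox
  }

  new("VoxelScene", caDensity = dens, labels = labs, voxelSize = v,
      config = config, plates = plates,
      groundTruth = computeGroundTruth(dens, labs))
})

setMethod("show", "VoxelScene", function(object) {
  d <- dim(object@caDensity)
  gt <- object@groundTruth
  cat(sprintf("VoxelScene: %d x %d x %d voxels (%g nm), %d plates\n",
              d[1], d[2], d[3], object@voxelSize, nrow(object@plates)))
  cat(sprintf("  ground truth: X_ext = %.4f (external %.3g, internal %.3g)\n",
              gt$X_ext_true, gt$external, gt$internal))
  invisible(NULL)
})

#' Cut a slab section out of a scene
#'
#' Keeps the voxels between two parallel planes with the given unit normal
#' (voxel centres with \code{offset <= <r, normal> < offset + thickness})
#' and recomputes the ground-truth partition for the slab; everything
#' outside is zeroed. Emulates preparing a thin TEM section, at any
#' orientation, from the bulk.
#'
#' @param scene a [VoxelScene-class]
#' @param normal length-3 vector, the slab normal (normalized internally)
#' @param thickness slab thickness, nm
#' @param offset signed distance of the lower face from the origin, nm
#' @return a [VoxelScene-class] restricted to the slab
#' @examples
#' sc <- buildScene(SceneConfig(nFibrils = 2, nPeriods = 2, voxelSize = 2))
#' slab <- cutSection(sc, c(0, 1, 0), thickness = 50, offset = 25)
#' @rdname cutSection
#' @export
setMethod("cutSection", "VoxelScene",
          function(scene, normal, thickness, offset = 0) {
  stopifnot(length(normal) == 3, thickness > 0)
  nrm <- normal / sqrt(sum(normal^2))
  d <- dim(scene@caDensity)
  v <- scene@voxelSize
  xs <- (seq_len(d[1]) - 0.5) * v
  ys <- (seq_len(d[2]) - 0.5) * v
  zs <- (seq_len(d[3]) - 0.5) * v
  t12 <- outer(nrm[1] * xs, nrm[2] * ys, "+")
  dens <- scene@caDensity
  labs <- scene@labels
  kept <- FALSE
  for (k in seq_len(d[3])) {
    tk <- t12 + nrm[3] * zs[k]
    inSlab <- tk >= offset & tk < offset + thickness
    if (any(inSlab)) kept <- TRUE
    dens[, , k][!inSlab] <- 0
    labs[, , k][!inSlab] <- .LBL[["background"]]
  }
  if (!kept) stop("empty slab: no voxel centres between the two planes")
  new("VoxelScene", caDensity = dens, labels = labs, voxelSize = v,
      config = scene@config, plates = scene@plates,
      groundTruth = computeGroundTruth(dens, labs))
})
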