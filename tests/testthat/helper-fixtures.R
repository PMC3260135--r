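# Shared fixtures. The default scene (3 x 3 fibrils, 3 D-periods, 1 nm
# voxels) is expensive enough to build once and reuse across test files.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, build(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

defaultConfig <- function() SceneConfig()

defaultScene <- function() {
  fixture("defaultScene", function() buildScene(defaultConfig()))
}

# 100 nm section centred on the middle fibril row, beam along y
defaultSlab <- function() {
  fixture("defaultSlab", function() {
    cfg <- defaultConfig()
    midRow <- (ceiling(cfg@nFibrils / 2) - 0.5) * cfg@pitch
    cutSection(defaultScene(), c(0, 1, 0), thickness = 100,
               offset = midRow - 50)
  })
}

longImage <- function() {
  fixture("longImage", function() projectScene(defaultSlab(), "y"))
}

crossImage <- function() {
  fixture("crossImage", function() projectScene(defaultScene(), "x"))
}

smallConfig <- function(...) {
  SceneConfig(nFibrils = 2L, nPeriods = 2L, ...)
}
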