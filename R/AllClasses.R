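#' @useDynLib neuropilMorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' LabelVolume: an integer-label serial-section raster
#'
#' A 3D raster of non-negative integer object labels (0 = background)
#' with anisotropic voxel geometry: square pixels of \code{pixelNM} nm
#' in x/y and a section thickness of \code{thicknessNM} nm in z. The
#' third array index is the section index.
#'
#' @slot voxels integer 3D array of labels.
#' @slot pixelNM numeric(1), xy pixel size in nm.
#' @slot thicknessNM numeric(1), section thickness in nm.
#' @slot channel character(1), one of "bouton", "mitochondrion",
#'   "synapse".
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(voxels = "array", pixelNM = "numeric",
                 thicknessNM = "numeric", channel = "character"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  d <- dim(object@voxels)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "voxels must be a 3D array with positive dims")
  if (!is.integer(object@voxels))
    msg <- c(msg, "voxels must be an integer array")
  else if (min(object@voxels) < 0L)
    msg <- c(msg, "labels must be non-negative (0 = background)")
  if (length(object@pixelNM) != 1L || object@pixelNM <= 0)
    msg <- c(msg, "pixelNM must be a single positive number")
  if (length(object@thicknessNM) != 1L || object@thicknessNM <= 0)
    msg <- c(msg, "thicknessNM must be a single positive number")
  if (!object@channel %in% c("bouton", "mitochondrion", "synapse"))
    msg <- c(msg, "channel must be bouton|mitochondrion|synapse")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelVolume
#'
#' @param voxels integer 3D array (0 = background).
#' @param pixelNM xy pixel size (nm).
#' @param thicknessNM section thickness (nm).
#' @param channel "bouton", "mitochondrion" or "synapse".
#' @return A \linkS4class{LabelVolume}.
#' @examples
#' v <- array(0L, c(4, 4, 2)); v[2:3, 2:3, ] <- 1L
#' LabelVolume(v, pixelNM = 8, thicknessNM = 60, channel = "bouton")
#' @export
LabelVolume <- function(voxels, pixelNM, thicknessNM, channel) {
  storage.mode(voxels) <- "integer"
  new("LabelVolume", voxels = voxels, pixelNM = as.numeric(pixelNM),
      thicknessNM = as.numeric(thicknessNM), channel = channel)
}

#' SurfaceMesh: a triangulated object surface in nm coordinates
#'
#' @slot vertices numeric matrix (n x 3), nm coordinates.
#' @slot faces integer matrix (m x 3), 1-based vertex indices with
#'   consistent outward orientation.
#' @slot closed logical(1), TRUE when the mesh is watertight.
#' @slot truncated logical(1), TRUE when the source object touched the
#'   raster boundary (the mesh is capped at the stack face).
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
                 closed = "logical", truncated = "logical"))

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
  if (nrow(object@faces) > 0 &&
      (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices)))
    msg <- c(msg, "face indices out of range")
  if (length(msg)) msg else TRUE
})

#' @rdname SurfaceMesh-class
#' @param vertices,faces mesh geometry.
#' @param closed,truncated mesh state flags.
#' @export
SurfaceMesh <- function(vertices, faces, closed = TRUE, truncated = FALSE) {
  storage.mode(faces) <- "integer"
  new("SurfaceMesh", vertices = vertices, faces = faces,
      closed = closed, truncated = truncated)
}

#' CountingFrame: a rectangular sampling frame on the reference section
#'
#' A frame has two inclusion and two exclusion edges; objects fully
#' inside the frame or crossing only inclusion edges are counted, so a
#' tiling of frames counts every profile at most once.
#'
#' @slot originNM numeric(2), x/y of the frame's top-left corner (nm).
#' @slot widthNM,heightNM numeric(1), frame size (nm).
#' @slot inclusionEdges character, two of "top","left","bottom","right".
#' @slot exclusionEdges character, the other two edges.
#' @slot roiId character(1).
#' @exportClass CountingFrame
setClass("CountingFrame",
  representation(originNM = "numeric", widthNM = "numeric",
                 heightNM = "numeric", inclusionEdges = "character",
                 exclusionEdges = "character", roiId = "character"))

setValidity("CountingFrame", function(object) {
  msg <- character()
  edges <- c("top", "left", "bottom", "right")
  if (length(object@originNM) != 2L) msg <- c(msg, "originNM must be length 2")
  if (object@widthNM <= 0 || object@heightNM <= 0)
    msg <- c(msg, "frame must have positive area")
  all4 <- sort(c(object@inclusionEdges, object@exclusionEdges))
  if (length(object@inclusionEdges) != 2L ||
      length(object@exclusionEdges) != 2L || !identical(all4, sort(edges)))
    msg <- c(msg, "inclusion/exclusion edges must partition the 4 edges")
  if (length(msg)) msg else TRUE
})

#' @rdname CountingFrame-class
#' @param originNM,widthNM,heightNM frame geometry (nm).
#' @param inclusionEdges,exclusionEdges edge assignment.
#' @param roiId frame label.
#' @export
CountingFrame <- function(originNM, widthNM, heightNM,
                          inclusionEdges = c("top", "left"),
                          exclusionEdges = c("bottom", "right"),
                          roiId = "roi1") {
  new("CountingFrame", originNM = as.numeric(originNM),
      widthNM = as.numeric(widthNM), heightNM = as.numeric(heightNM),
      inclusionEdges = inclusionEdges, exclusionEdges = exclusionEdges,
      roiId = roiId)
}

#' SamplingPlan: counting frames tiling the central analysis region
#'
#' @slot referenceSection integer(1), 1-based index of the middle
#'   section on which profiles are sampled.
#' @slot regionOriginNM numeric(2), top-left of the analysis region (nm).
#' @slot regionDimsNM numeric(2), width/height of the region (nm).
#' @slot frames list of \linkS4class{CountingFrame}.
#' @slot nSections integer(1) and \code{thicknessNM}: depth of sampled
#'   neuropil = nSections * thicknessNM.
#' @slot thicknessNM numeric(1).
#' @exportClass SamplingPlan
setClass("SamplingPlan",
  representation(referenceSection = "integer", regionOriginNM = "numeric",
                 regionDimsNM = "numeric", frames = "list",
                 nSections = "integer", thicknessNM = "numeric"))

setValidity("SamplingPlan", function(object) {
  msg <- character()
  if (!all(vapply(object@frames, is, TRUE, "CountingFrame")))
    msg <- c(msg, "frames must all be CountingFrame objects")
  if (object@nSections < 1L) msg <- c(msg, "nSections must be >= 1")
  if (length(msg)) msg else TRUE
})

#' RegimeConfig: parameters of one synthetic-neuropil regime
#'
#' Encodes the joint size model of a synthetic subject: lognormal
#' bouton surface areas, conditionally lognormal summed synapse and
#' mitochondrion areas tied to the bouton through a Gaussian copula on
#' log sizes (calibrated so the *raw-scale* Pearson correlations equal
#' \code{rhoSB}/\code{rhoMB}), mitochondrial occupancy and morphology
#' mix, and the raster geometry.
#'
#' @slot name regime label ("YA", "AU", "AI" or custom).
#' @slot nBoutons integer(1), boutons per subject.
#' @slot boutonLogMean,boutonLogSd lognormal parameters of bouton
#'   surface area (nm2).
#' @slot synapseLogMean,synapseLogSd lognormal parameters of summed
#'   synapse contact area per bouton (nm2).
#' @slot mitoLogMean,mitoLogSd lognormal parameters of summed
#'   mitochondrion surface area per occupied bouton (nm2).
#' @slot rhoSB,rhoMB target raw-scale Pearson correlations of
#'   (bouton, synapse) and (bouton, mitochondrion) sizes.
#' @slot mitoOccupancy probability a bouton contains >= 1 mitochondrion.
#' @slot occupancySlope logistic slope (per log-sd of bouton size) of
#'   the occupancy probability; > 0 makes mitochondria-bearing boutons
#'   larger on average.
#' @slot morphMix named numeric(3), probabilities of straight/curved/
#'   toroidal mitochondria.
#' @slot densityScale bouton density relative to the young-adult regime
#'   (realized by scaling stack depth at fixed bouton count).
#' @slot sectionThicknessNM,pixelNM raster geometry (nm).
#' @slot volumeDims integer(3), raster dims (x, y, sections).
#' @slot subthresholdFrac fraction of profiles given < 3 vesicles to
#'   exercise the bouton inclusion rule.
#' @slot extraSynapseRate,extraMitoRate Poisson rates of synapses and
#'   mitochondria beyond the first (synapses truncated at 3 extras,
#'   mitochondria at 2).
#' @slot seed integer(1) RNG seed.
#' @exportClass RegimeConfig
setClass("RegimeConfig",
  representation(name = "character", nBoutons = "integer",
                 boutonLogMean = "numeric", boutonLogSd = "numeric",
                 synapseLogMean = "numeric", synapseLogSd = "numeric",
                 mitoLogMean = "numeric", mitoLogSd = "numeric",
                 rhoSB = "numeric", rhoMB = "numeric",
                 mitoOccupancy = "numeric", occupancySlope = "numeric",
                 morphMix = "numeric", densityScale = "numeric",
                 sectionThicknessNM = "numeric", pixelNM = "numeric",
                 volumeDims = "integer", subthresholdFrac = "numeric",
                 extraSynapseRate = "numeric", extraMitoRate = "numeric",
                 seed = "integer"))

setValidity("RegimeConfig", function(object) {
  msg <- character()
  if (object@nBoutons < 4L) msg <- c(msg, "nBoutons must be >= 4")
  if (abs(sum(object@morphMix) - 1) > 1e-8 || any(object@morphMix < 0) ||
      any(object@morphMix > 1))
    msg <- c(msg, "morphMix must be probabilities summing to 1")
  if (!identical(sort(names(object@morphMix)),
                 sort(c("straight", "curved", "toroidal"))))
    msg <- c(msg, "morphMix must be named straight/curved/toroidal")
  if (abs(object@rhoSB) > 1 || abs(object@rhoMB) > 1)
    msg <- c(msg, "rhoSB and rhoMB must be in [-1, 1]")
  if (object@mitoOccupancy < 0 || object@mitoOccupancy > 1)
    msg <- c(msg, "mitoOccupancy must be in [0, 1]")
  if (object@densityScale <= 0) msg <- c(msg, "densityScale must be > 0")
  if (object@sectionThicknessNM < 10 || object@sectionThicknessNM > 200)
    msg <- c(msg, "sectionThicknessNM must be in [10, 200] nm")
  if (object@pixelNM <= 0) msg <- c(msg, "pixelNM must be > 0")
  if (length(object@volumeDims) != 3L || any(object@volumeDims < 1L))
    msg <- c(msg, "volumeDims must be 3 positive integers")
  if (object@subthresholdFrac < 0 || object@subthresholdFrac > 1)
    msg <- c(msg, "subthresholdFrac must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
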