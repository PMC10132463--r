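#' @rdname LabelVolume-class
#' @aliases pixelSize,LabelVolume-method
setMethod("pixelSize", "LabelVolume", function(x) x@pixelNM)

#' @rdname LabelVolume-class
setMethod("sectionThickness", "LabelVolume", function(x) x@thicknessNM)

#' @rdname LabelVolume-class
setMethod("channelName", "LabelVolume", function(x) x@channel)

#' @rdname LabelVolume-class
setMethod("voxelData", "LabelVolume", function(x) x@voxels)

#' @rdname LabelVolume-class
setMethod("objectIds", "LabelVolume", function(x) {
  ids <- sort(unique(as.vector(x@voxels)))
  ids[ids > 0L]
})

#' @rdname LabelVolume-class
setMethod("dim", "LabelVolume", function(x) dim(x@voxels))

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "LabelVolume [%s]: %d x %d px x %d sections (%.0f nm px, %.0f nm z)\n",
    object@channel, d[1], d[2], d[3], object@pixelNM, object@thicknessNM))
  cat(sprintf("  %d labelled objects\n", length(objectIds(object))))
})

#' @rdname SurfaceMesh-class
#' @param object,x a \linkS4class{SurfaceMesh}.
#' @aliases meshArea,SurfaceMesh-method
setMethod("meshArea", "SurfaceMesh", function(x) {
  V <- x@vertices; F <- x@faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
})

#' @rdname SurfaceMesh-class
setMethod("meshVolume", "SurfaceMesh", function(x) {
  V <- x@vertices; F <- x@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det3)) / 6
})

#' @rdname SurfaceMesh-class
setMethod("eulerCharacteristic", "SurfaceMesh", function(x) {
  nV <- nrow(x@vertices)
  nF <- nrow(x@faces)
  e <- rbind(x@faces[, c(1, 2)], x@faces[, c(2, 3)], x@faces[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nV + 1) + pmax(e[, 1], e[, 2])
  nE <- length(unique(key))
  nV - nE + nF
})

#' @rdname SurfaceMesh-class
setMethod("isWatertight", "SurfaceMesh", function(x) {
  nV <- nrow(x@vertices)
  e <- rbind(x@faces[, c(1, 2)], x@faces[, c(2, 3)], x@faces[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nV + 1) + pmax(e[, 1], e[, 2])
  all(tabulate(match(key, unique(key))) == 2L)
})

#' @rdname SurfaceMesh-class
setMethod("isTruncated", "SurfaceMesh", function(x) x@truncated)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces%s%s\n",
              nrow(object@vertices), nrow(object@faces),
              if (object@closed) ", watertight" else ", open",
              if (object@truncated) ", truncated by stack" else ""))
})

#' @rdname CountingFrame-class
#' @param object,x a \linkS4class{CountingFrame}.
#' @aliases frameArea,CountingFrame-method
setMethod("frameArea", "CountingFrame", function(x) x@widthNM * x@heightNM)

setMethod("show", "CountingFrame", function(object) {
  cat(sprintf(
    "CountingFrame %s: %.2f x %.2f um at (%.2f, %.2f) um; inclusion: %s\n",
    object@roiId, object@widthNM / 1e3, object@heightNM / 1e3,
    object@originNM[1] / 1e3, object@originNM[2] / 1e3,
    paste(object@inclusionEdges, collapse = "+")))
})

#' @rdname SamplingPlan-class
#' @param object,x a \linkS4class{SamplingPlan}.
#' @aliases planArea,SamplingPlan-method
setMethod("planArea", "SamplingPlan", function(x)
  sum(vapply(x@frames, frameArea, numeric(1))))

#' @rdname SamplingPlan-class
setMethod("sampledVolume", "SamplingPlan", function(x)
  planArea(x) * x@nSections * x@thicknessNM)

#' @rdname SamplingPlan-class
setMethod("frames", "SamplingPlan", function(x) x@frames)

#' @rdname SamplingPlan-class
setMethod("referenceSection", "SamplingPlan", function(x)
  x@referenceSection)

setMethod("show", "SamplingPlan", function(object) {
  cat(sprintf(
    "SamplingPlan: %d frames tiling %.1f um2 on section %d; depth %.2f um\n",
    length(object@frames), planArea(object) / 1e6,
    object@referenceSection,
    object@nSections * object@thicknessNM / 1e3))
})

setMethod("show", "RegimeConfig", function(object) {
  cat(sprintf("RegimeConfig '%s': %d boutons, rhoSB=%.2f, rhoMB=%.2f\n",
              object@name, object@nBoutons, object@rhoSB, object@rhoMB))
  cat(sprintf("  occupancy %.2f, density scale %.2f, %d x %d px x %d sections (%g nm px, %g nm z)\n",
              object@mitoOccupancy, object@densityScale,
              object@volumeDims[1], object@volumeDims[2],
              object@volumeDims[3], object@pixelNM,
              object@sectionThicknessNM))
})
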