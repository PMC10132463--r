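#' @rdname LabelVolume-class
#' @param object,x a \linkS4class{LabelVolume}.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname LabelVolume-class
#' @export
setGeneric("sectionThickness",
           function(x) standardGeneric("sectionThickness"))

#' @rdname LabelVolume-class
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname LabelVolume-class
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname LabelVolume-class
#' @export
setGeneric("objectIds", function(x) standardGeneric("objectIds"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("meshArea", function(x) standardGeneric("meshArea"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("meshVolume", function(x) standardGeneric("meshVolume"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("eulerCharacteristic",
           function(x) standardGeneric("eulerCharacteristic"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("isWatertight", function(x) standardGeneric("isWatertight"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("isTruncated", function(x) standardGeneric("isTruncated"))

#' @rdname CountingFrame-class
#' @export
setGeneric("frameArea", function(x) standardGeneric("frameArea"))

#' @rdname SamplingPlan-class
#' @export
setGeneric("planArea", function(x) standardGeneric("planArea"))

#' @rdname SamplingPlan-class
#' @export
setGeneric("sampledVolume", function(x) standardGeneric("sampledVolume"))

#' @rdname SamplingPlan-class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname SamplingPlan-class
#' @export
setGeneric("referenceSection",
           function(x) standardGeneric("referenceSection"))
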