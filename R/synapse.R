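#' Per-section contact lengths of a synaptic apposition
#'
#' For every section on which the synapse appears, the contact trace is
#' reduced to its longest geodesic path through the pixel graph
#' (8-connectivity, Euclidean step lengths) and the reported length is
#' the path arc length plus one pixel (half-pixel caps at both ends),
#' so a straight 1-pixel trace of n pixels measures n * pixel_nm.
#'
#' @param volume a synapse-channel \linkS4class{LabelVolume}.
#' @param synapseId object label.
#' @return Named numeric vector of lengths (nm); names are 1-based
#'   section indices.
#' @examples
#' v <- array(0L, c(60, 5, 2)); v[6:55, 3, 1] <- 1L
#' lv <- LabelVolume(v, 2, 60, "synapse")
#' contactLengths(lv, 1L)  # 100 nm on section 1
#' @export
contactLengths <- function(volume, synapseId) {
  stopifnot(is(volume, "LabelVolume"))
  vox <- voxelData(volume)
  hits <- which(vox == synapseId)
  if (!length(hits)) stop("synapse ", synapseId, " is empty / absent")
  co <- arrayInd(hits, dim(vox))
  contactLengthsCore(co, pixelSize(volume))
}

# co: voxel coordinates (1-based, columns x,y,z) of the synapse
contactLengthsCore <- function(co, pixelNM) {
  out <- c()
  for (z in sort(unique(co[, 3]))) {
    pts <- co[co[, 3] == z, 1:2, drop = FALSE]
    out[as.character(z)] <- traceLength2D(pts, pixelNM)
  }
  out
}

# Longest-geodesic-path length of a 2D pixel set (largest connected
# component), plus the one-pixel end-cap term.
traceLength2D <- function(pts, pixelNM) {
  if (nrow(pts) == 1) return(pixelNM)
  o <- c(min(pts[, 1]), min(pts[, 2]))
  d <- c(max(pts[, 1]) - o[1] + 1L, max(pts[, 2]) - o[2] + 1L, 1L)
  m <- array(FALSE, d)
  m[cbind(pts[, 1] - o[1] + 1L, pts[, 2] - o[2] + 1L, 1L)] <- TRUE
  lab <- cpp_label_components(as.vector(m), d, 26L)
  if (attr(lab, "n") > 1L) {
    big <- which.max(tabulate(lab[lab > 0L]))
    m <- array(lab == big, d)
  }
  gp <- cpp_geodesic_path(as.vector(m), d, c(pixelNM, pixelNM, 1),
                          numeric(0), FALSE)
  # smooth the pixel path (endpoints fixed) to remove digital zigzag
  # before taking the arc length; a collinear trace stays exact
  poly <- gp$path[, 1:2, drop = FALSE] * pixelNM
  n <- nrow(poly)
  if (n > 4) {
    sm <- poly
    for (i in 2:(n - 1)) {
      lo <- max(1, i - 2); hi <- min(n, i + 2)
      sm[i, ] <- colMeans(poly[lo:hi, , drop = FALSE])
    }
    poly <- sm
  }
  sum(sqrt(rowSums(diff(poly)^2))) + pixelNM
}

#' Synapse surface area from per-section lengths
#'
#' The apposition area is the sum of per-section contact lengths
#' multiplied by the section thickness.
#'
#' @param lengths numeric vector of per-section lengths (nm), all > 0.
#' @param thicknessNM section thickness (nm), > 0.
#' @return area in nm2.
#' @examples
#' synapseArea(c(200, 250, 300), 60)  # 45000 nm2
#' @export
synapseArea <- function(lengths, thicknessNM) {
  if (!length(lengths)) stop("no contact lengths supplied")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("contact lengths must be positive and finite")
  if (length(thicknessNM) != 1L || thicknessNM <= 0)
    stop("section thickness must be a single positive number")
  sum(lengths) * thicknessNM
}
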