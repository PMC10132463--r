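#' Build the reference-section sampling plan
#'
#' Tiles the central analysis region (default 18 x 9 um) of the
#' reference (middle) section into non-overlapping counting frames
#' (default 4 frames of 9 x 4.5 um = 40.5 um2 each, i.e. a 162 um2
#' plan). Each frame has top+left inclusion and bottom+right exclusion
#' edges, the standard unbiased-counting-frame convention.
#'
#' @param stackDims integer(3): raster dims (x px, y px, sections).
#' @param pixelNM,thicknessNM raster geometry (nm).
#' @param nFrames number of frames tiling the region.
#' @param regionDimsNM analysis-region width/height (nm).
#' @param regionOriginNM optional region origin (nm); default centred.
#' @return A \linkS4class{SamplingPlan}.
#' @examples
#' plan <- makeSamplingPlan(c(2500L, 1375L, 41L), 8, 60)
#' planArea(plan) / 1e6   # 162 um2
#' @export
makeSamplingPlan <- function(stackDims, pixelNM, thicknessNM,
                             nFrames = 4L, regionDimsNM = c(18e3, 9e3),
                             regionOriginNM = NULL) {
  stackDims <- as.integer(stackDims)
  volXY <- stackDims[1:2] * pixelNM
  if (any(volXY < regionDimsNM))
    stop("stack too small for the analysis region: need at least ",
         ceiling(regionDimsNM[1] / pixelNM), " x ",
         ceiling(regionDimsNM[2] / pixelNM), " px at ", pixelNM,
         " nm/px")
  if (is.null(regionOriginNM)) regionOriginNM <- (volXY - regionDimsNM) / 2
  split <- frameGrid(nFrames, regionDimsNM)
  fw <- regionDimsNM[1] / split[1]
  fh <- regionDimsNM[2] / split[2]
  frames <- list()
  k <- 0L
  for (iy in seq_len(split[2]) - 1L) {
    for (ix in seq_len(split[1]) - 1L) {
      k <- k + 1L
      frames[[k]] <- CountingFrame(
        originNM = regionOriginNM + c(ix * fw, iy * fh),
        widthNM = fw, heightNM = fh,
        roiId = sprintf("roi%d", k))
    }
  }
  new("SamplingPlan",
      referenceSection = as.integer(floor(stackDims[3] / 2) + 1L),
      regionOriginNM = regionOriginNM, regionDimsNM = regionDimsNM,
      frames = frames, nSections = stackDims[3],
      thicknessNM = as.numeric(thicknessNM))
}

# factor nFrames into columns x rows with frame aspect closest to 2:1
frameGrid <- function(nFrames, regionDimsNM) {
  best <- NULL; bestScore <- Inf
  for (cx in seq_len(nFrames)) {
    if (nFrames %% cx != 0) next
    cy <- nFrames / cx
    aspect <- (regionDimsNM[1] / cx) / (regionDimsNM[2] / cy)
    score <- abs(log(aspect / 2))
    if (score < bestScore) { bestScore <- score; best <- c(cx, cy) }
  }
  best
}

#' Bouton inclusion rule: three or more presynaptic vesicles
#'
#' @param vesicleCount non-negative integer vector.
#' @return logical vector.
#' @examples
#' qualifiesAsBouton(c(0, 2, 3, 10))
#' @export
qualifiesAsBouton <- function(vesicleCount) {
  if (any(vesicleCount < 0)) stop("vesicle counts must be non-negative")
  vesicleCount >= 3
}

#' Counting-frame inclusion decision for one profile
#'
#' A profile (set of pixels on the reference section) is included if it
#' lies fully inside the frame, or intersects an inclusion edge without
#' intersecting any exclusion edge; it is excluded if it intersects any
#' exclusion edge or lies wholly outside. Pixel squares are treated as
#' closed, so corner touches count as intersections and exclusion
#' dominates ties.
#'
#' @param profile logical matrix (x by y section mask) or a 2-column
#'   matrix of 0-based pixel indices (x, y).
#' @param frame a \linkS4class{CountingFrame}.
#' @param pixelNM pixel size (nm).
#' @return TRUE/FALSE.
#' @export
includeProfile <- function(profile, frame, pixelNM) {
  pts <- profilePixels(profile)
  if (!nrow(pts)) stop("profile is empty on the reference section")
  x0 <- frame@originNM[1]; y0 <- frame@originNM[2]
  x1 <- x0 + frame@widthNM; y1 <- y0 + frame@heightNM
  px0 <- pts[, 1] * pixelNM; px1 <- px0 + pixelNM
  py0 <- pts[, 2] * pixelNM; py1 <- py0 + pixelNM
  hitEdge <- function(edge) {
    switch(edge,
      left   = any(px0 <= x0 & px1 >= x0 & py0 <= y1 & py1 >= y0),
      right  = any(px0 <= x1 & px1 >= x1 & py0 <= y1 & py1 >= y0),
      top    = any(py0 <= y0 & py1 >= y0 & px0 <= x1 & px1 >= x0),
      bottom = any(py0 <= y1 & py1 >= y1 & px0 <= x1 & px1 >= x0))
  }
  if (any(vapply(frame@exclusionEdges, hitEdge, TRUE))) return(FALSE)
  if (any(vapply(frame@inclusionEdges, hitEdge, TRUE))) return(TRUE)
  all(px0 >= x0 & px1 <= x1 & py0 >= y0 & py1 <= y1)
}

profilePixels <- function(profile) {
  if (is.logical(profile) && is.matrix(profile)) {
    w <- which(profile, arr.ind = TRUE)
    cbind(w[, 1] - 1L, w[, 2] - 1L)
  } else {
    as.matrix(profile)
  }
}

#' Assign profiles to counting frames
#'
#' Applies \code{\link{includeProfile}} over all frames of a plan;
#' profiles included by exactly one frame get that frame's ROI id.
#'
#' @param profiles list of profiles (see \code{\link{includeProfile}});
#'   names are object ids.
#' @param plan a \linkS4class{SamplingPlan}.
#' @param pixelNM pixel size (nm).
#' @return data.frame with \code{object_id}, \code{roi_id} (NA when
#'   excluded) and \code{n_frames} (frames that accepted the profile;
#'   at most 1 under a shared-edge tiling).
#' @export
assignProfiles <- function(profiles, plan, pixelNM) {
  ids <- names(profiles)
  if (is.null(ids)) ids <- as.character(seq_along(profiles))
  roi <- rep(NA_character_, length(profiles))
  nf <- integer(length(profiles))
  for (i in seq_along(profiles)) {
    hits <- character()
    for (fr in frames(plan))
      if (includeProfile(profiles[[i]], fr, pixelNM))
        hits <- c(hits, fr@roiId)
    nf[i] <- length(hits)
    if (length(hits)) roi[i] <- hits[1]
  }
  data.frame(object_id = ids, roi_id = roi, n_frames = nf,
             stringsAsFactors = FALSE)
}

#' Per-ROI density statistics
#'
#' Bouton density is included boutons per sampled neuropil volume
#' (frame area x stack depth); synapse density counts synapses on
#' included boutons; synapses-per-bouton is the mean synapse count.
#' Per-area (reference-section) densities are also emitted. With no
#' boutons in a frame, densities are 0 and synapses-per-bouton is
#' missing.
#'
#' @param complexes data.frame with one row per included bouton:
#'   \code{roi_id}, \code{n_synapse}.
#' @param plan a \linkS4class{SamplingPlan}.
#' @return data.frame with one row per ROI plus an "all" summary row;
#'   densities in um^-3 (and um^-2), areas from the plan geometry.
#' @export
densities <- function(complexes, plan) {
  depthNM <- plan@nSections * plan@thicknessNM
  out <- lapply(frames(plan), function(fr) {
    rows <- complexes[!is.na(complexes$roi_id) &
                        complexes$roi_id == fr@roiId, , drop = FALSE]
    nb <- nrow(rows)
    ns <- sum(rows$n_synapse)
    volUM3 <- frameArea(fr) * depthNM / 1e9
    areaUM2 <- frameArea(fr) / 1e6
    data.frame(roi_id = fr@roiId, n_boutons = nb, n_synapses = ns,
               bouton_density_um3 = nb / volUM3,
               synapse_density_um3 = ns / volUM3,
               bouton_density_um2 = nb / areaUM2,
               synapse_density_um2 = ns / areaUM2,
               synapses_per_bouton = if (nb > 0) ns / nb else NA_real_)
  })
  perRoi <- do.call(rbind, out)
  tot <- data.frame(
    roi_id = "all",
    n_boutons = sum(perRoi$n_boutons),
    n_synapses = sum(perRoi$n_synapses),
    bouton_density_um3 = sum(perRoi$n_boutons) /
      (sampledVolume(plan) / 1e9),
    synapse_density_um3 = sum(perRoi$n_synapses) /
      (sampledVolume(plan) / 1e9),
    bouton_density_um2 = sum(perRoi$n_boutons) / (planArea(plan) / 1e6),
    synapse_density_um2 = sum(perRoi$n_synapses) / (planArea(plan) / 1e6),
    synapses_per_bouton = if (sum(perRoi$n_boutons) > 0)
      sum(perRoi$n_synapses) / sum(perRoi$n_boutons) else NA_real_)
  rbind(perRoi, tot)
}
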