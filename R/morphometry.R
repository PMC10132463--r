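#' Measure all objects in a set of label volumes
#'
#' Meshes every bouton and mitochondrion (surface area + volume from
#' the watertight mesh) and measures every synapse from per-section
#' contact lengths. Optionally joins per-object metadata (bouton
#' assignments, ROI/animal ids) and classifies mitochondrial
#' morphology.
#'
#' @param boutons,mitochondria,synapses \linkS4class{LabelVolume}s (any
#'   may be NULL).
#' @param meta optional data.frame with columns \code{object_id},
#'   \code{channel}, \code{bouton_id}, \code{vesicle_count},
#'   \code{roi_id}, \code{animal_id}.
#' @param classifyMitos logical; run the morphology classifier on each
#'   mitochondrion.
#' @return data.frame with one row per object: \code{object_id},
#'   \code{channel}, \code{bouton_id}, \code{surface_area_nm2},
#'   \code{volume_nm3}, \code{synapse_area_nm2},
#'   \code{truncated_by_stack}, \code{roi_id}, \code{animal_id} and,
#'   when classified, \code{morph_class}, \code{max_bend_deg},
#'   \code{has_through_hole}, \code{uncertain_flag}.
#' @export
measureVolumes <- function(boutons = NULL, mitochondria = NULL,
                           synapses = NULL, meta = NULL,
                           classifyMitos = FALSE) {
  rows <- list()
  for (vol in list(boutons, mitochondria)) {
    if (is.null(vol)) next
    bb <- labelBBoxes(vol)
    for (k in seq_len(nrow(bb))) {
      id <- bb$label[k]
      bbox <- rbind(c(bb$x0[k], bb$y0[k], bb$z0[k]),
                    c(bb$x1[k], bb$y1[k], bb$z1[k]))
      mesh <- extractMesh(vol, id, bbox = bbox)
      mm <- meshMeasures(mesh)
      row <- data.frame(object_id = id, channel = channelName(vol),
                        surface_area_nm2 = mm[[1]], volume_nm3 = mm[[2]],
                        synapse_area_nm2 = NA_real_,
                        truncated_by_stack = isTruncated(mesh))
      if (classifyMitos && channelName(vol) == "mitochondrion") {
        crop <- voxelData(vol)[bbox[1, 1]:bbox[2, 1],
                               bbox[1, 2]:bbox[2, 2],
                               bbox[1, 3]:bbox[2, 3], drop = FALSE]
        rep <- classifyMito(array(crop == id, dim = dim(crop)),
                            spacing = c(pixelSize(vol), pixelSize(vol),
                                        sectionThickness(vol)),
                            truncated = isTruncated(mesh))
        row$morph_class <- rep$morphClass
        row$max_bend_deg <- rep$maxBendDeg
        row$has_through_hole <- rep$hasThroughHole
        row$uncertain_flag <- rep$uncertain
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!is.null(synapses)) {
    bb <- labelBBoxes(synapses)
    th <- sectionThickness(synapses)
    vox <- voxelData(synapses)
    for (k in seq_len(nrow(bb))) {
      id <- bb$label[k]
      crop <- vox[bb$x0[k]:bb$x1[k], bb$y0[k]:bb$y1[k],
                  bb$z0[k]:bb$z1[k], drop = FALSE]
      co <- arrayInd(which(crop == id), dim(crop))
      co[, 1] <- co[, 1] + bb$x0[k] - 1L
      co[, 2] <- co[, 2] + bb$y0[k] - 1L
      co[, 3] <- co[, 3] + bb$z0[k] - 1L
      lens <- contactLengthsCore(co, pixelSize(synapses))
      rows[[length(rows) + 1L]] <- data.frame(
        object_id = id, channel = "synapse",
        surface_area_nm2 = NA_real_, volume_nm3 = NA_real_,
        synapse_area_nm2 = synapseArea(lens, th),
        truncated_by_stack = FALSE)
    }
  }
  out <- fillBind(rows)
  joinMeta(out, meta)
}

labelBBoxes <- function(vol) {
  bb <- cpp_label_bboxes(as.vector(voxelData(vol)), dim(vol))
  bb <- as.data.frame(bb)
  names(bb) <- c("label", "x0", "x1", "y0", "y1", "z0", "z1")
  bb[bb$x1 >= bb$x0, , drop = FALSE]
}

fillBind <- function(rows) {
  if (!length(rows)) return(data.frame())
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[cols]
  })
  do.call(rbind, rows)
}

joinMeta <- function(out, meta) {
  if (is.null(meta) || !nrow(out)) {
    if (nrow(out)) {
      out$bouton_id <- NA_integer_
      out$roi_id <- NA_character_
      out$animal_id <- NA_character_
    }
    return(out)
  }
  key <- paste(out$channel, out$object_id)
  mkey <- paste(meta$channel, meta$object_id)
  idx <- match(key, mkey)
  out$bouton_id <- meta$bouton_id[idx]
  out$roi_id <- meta$roi_id[idx]
  out$animal_id <- meta$animal_id[idx]
  out
}

# Crop-wise measurement straight from the ground truth: identical voxel
# outcome to measuring the fully rasterized volumes (objects are
# disjoint by construction), without allocating the full stack.
measureComplexes <- function(gt, boutonIds = NULL, classifyMitos = FALSE,
                             meshArgs = list()) {
  cfg <- gt$config
  if (is.null(gt$mitochondria$realized_class))
    gt <- realizeMitoGeometry(gt)
  px <- cfg@pixelNM; th <- cfg@sectionThicknessNM
  sp <- c(px, px, th)
  if (is.null(boutonIds)) boutonIds <- gt$boutons$bouton_id
  rows <- list()
  measureOne <- function(what, idx, id, channel) {
    crop <- paintObjectCrop(gt, what, idx)
    mask <- array(crop$vol == id, dim = crop$dims)
    if (!any(mask)) return(NULL)
    # generator placements keep objects interior to the stack
    truncated <- FALSE
    ext <- max(crop$dims[1:2])
    k <- if (channel == "bouton" && ext > 48) min(4L, ceiling(ext / 36))
         else 1L
    mesh <- do.call(meshFromMask, c(
      list(array(as.numeric(mask), dim = crop$dims), spacing = sp,
           originVoxel = crop$origin, xyDownsample = k), meshArgs))
    mm <- meshMeasures(mesh)
    row <- data.frame(object_id = id, channel = channel,
                      surface_area_nm2 = mm[[1]], volume_nm3 = mm[[2]],
                      synapse_area_nm2 = NA_real_,
                      truncated_by_stack = truncated)
    if (classifyMitos && channel == "mitochondrion") {
      rep <- classifyMito(mask, spacing = sp)
      row$morph_class <- rep$morphClass
      row$max_bend_deg <- rep$maxBendDeg
      row$has_through_hole <- rep$hasThroughHole
      row$uncertain_flag <- rep$uncertain
    }
    row
  }
  for (i in which(gt$boutons$bouton_id %in% boutonIds)) {
    r <- measureOne("bouton", i, gt$boutons$bouton_id[i], "bouton")
    if (!is.null(r)) {
      r$bouton_id <- r$object_id
      rows[[length(rows) + 1L]] <- r
    }
  }
  for (j in which(gt$mitochondria$bouton_id %in% boutonIds)) {
    r <- measureOne("mito", j, gt$mitochondria$object_id[j],
                    "mitochondrion")
    if (!is.null(r)) {
      r$bouton_id <- gt$mitochondria$bouton_id[j]
      rows[[length(rows) + 1L]] <- r
    }
  }
  for (j in which(gt$synapses$bouton_id %in% boutonIds)) {
    crop <- paintObjectCrop(gt, "synapse", j)
    id <- gt$synapses$object_id[j]
    sel <- which(crop$vol == id)
    if (!length(sel)) next
    co <- arrayInd(sel, crop$dims)
    co[, 1] <- co[, 1] + crop$origin[1]
    co[, 2] <- co[, 2] + crop$origin[2]
    co[, 3] <- co[, 3] + crop$origin[3]
    lens <- contactLengthsCore(co, px)
    rows[[length(rows) + 1L]] <- data.frame(
      object_id = id, channel = "synapse",
      surface_area_nm2 = NA_real_, volume_nm3 = NA_real_,
      synapse_area_nm2 = synapseArea(lens, th),
      truncated_by_stack = FALSE, bouton_id = gt$synapses$bouton_id[j])
  }
  out <- fillBind(rows)
  bt <- gt$boutons
  idx <- match(out$bouton_id, bt$bouton_id)
  out$roi_id <- bt$roi_id[idx]
  out$animal_id <- bt$animal_id[idx]
  out
}
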