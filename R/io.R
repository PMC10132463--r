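#' Write a label volume to multi-page TIFF or NRRD
#'
#' TIFF: one 16-bit page per section (via the \pkg{tiff} package).
#' NRRD: minimal NRRD0004 header + little-endian raw unsigned short
#' payload with per-axis spacings in nm.
#'
#' @param volume a \linkS4class{LabelVolume} (labels < 65536).
#' @param path output path ending in .tif/.tiff or .nrrd.
#' @return \code{path}, invisibly.
#' @export
writeLabelVolume <- function(volume, path) {
  stopifnot(is(volume, "LabelVolume"))
  v <- voxelData(volume)
  if (max(v) > 65535L) stop("labels exceed 16-bit range")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(dim(v)[3]),
                    function(k) t(v[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (ext == "nrrd") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("NRRD0004",
             "# neuropilMorph label volume",
             "type: unsigned short",
             "dimension: 3",
             sprintf("sizes: %d %d %d", dim(v)[1], dim(v)[2], dim(v)[3]),
             sprintf("spacings: %g %g %g", pixelSize(volume),
                     pixelSize(volume), sectionThickness(volume)),
             "endian: little",
             "encoding: raw",
             sprintf("content: %s", channelName(volume)),
             "")
    writeLines(hdr, con, sep = "\n")
    writeBin(as.integer(v), con, size = 2L, endian = "little")
  } else stop("unsupported extension '", ext, "' (use tif/tiff/nrrd)")
  invisible(path)
}

#' Read a label volume written by \code{\link{writeLabelVolume}}
#'
#' @param path .tif/.tiff or .nrrd file.
#' @param pixelNM,thicknessNM voxel geometry; for NRRD these default to
#'   the stored spacings.
#' @param channel channel name for the returned object.
#' @return A \linkS4class{LabelVolume}.
#' @export
readLabelVolume <- function(path, pixelNM = NULL, thicknessNM = NULL,
                            channel = "bouton") {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    v <- array(0L, c(ncol(pages[[1]]), nrow(pages[[1]]),
                     length(pages)))
    for (k in seq_along(pages)) v[, , k] <- t(pages[[k]])
    if (is.null(pixelNM) || is.null(thicknessNM))
      stop("pixelNM and thicknessNM are required for TIFF input")
  } else if (ext == "nrrd") {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- c()
    repeat {
      line <- readLines(con, n = 1)
      if (!length(line) || line == "") break
      hdr <- c(hdr, line)
    }
    field <- function(key) {
      hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
      if (!length(hit)) return(NULL)
      sub(paste0("^", key, ": "), "", hit[1])
    }
    if (!identical(field("encoding"), "raw") ||
        !identical(field("type"), "unsigned short"))
      stop("only raw unsigned-short NRRD volumes are supported")
    sizes <- as.integer(strsplit(field("sizes"), " ")[[1]])
    sp <- as.numeric(strsplit(field("spacings"), " ")[[1]])
    raw <- readBin(con, "integer", n = prod(sizes), size = 2L,
                   signed = FALSE, endian = "little")
    v <- array(as.integer(raw), sizes)
    if (is.null(pixelNM)) pixelNM <- sp[1]
    if (is.null(thicknessNM)) thicknessNM <- sp[3]
    cnt <- field("content")
    if (!is.null(cnt) && cnt %in% c("bouton", "mitochondrion",
                                    "synapse"))
      channel <- cnt
  } else stop("unsupported extension '", ext, "'")
  LabelVolume(v, pixelNM, thicknessNM, channel)
}

# ---- ground truth / metadata ---------------------------------------

writeGroundTruth <- function(gt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, nm)
    utils::write.csv(df, file.path(dir, nm), row.names = FALSE)
  wr(gt$boutons, "truth_boutons.csv")
  wr(gt$synapses, "truth_synapses.csv")
  wr(gt$mitochondria, "truth_mitochondria.csv")
  wr(buildMetadata(gt), "metadata.csv")
  yaml::write_yaml(configToList(gt$config),
                   file.path(dir, "config_snapshot.yaml"))
  invisible(dir)
}

buildMetadata <- function(gt) {
  bt <- gt$boutons
  rows <- list(
    data.frame(object_id = bt$bouton_id, channel = "bouton",
               bouton_id = bt$bouton_id,
               vesicle_count = bt$vesicle_count,
               roi_id = bt$roi_id, animal_id = bt$animal_id),
    if (nrow(gt$synapses)) data.frame(
      object_id = gt$synapses$object_id, channel = "synapse",
      bouton_id = gt$synapses$bouton_id, vesicle_count = NA_integer_,
      roi_id = bt$roi_id[match(gt$synapses$bouton_id, bt$bouton_id)],
      animal_id = bt$animal_id[match(gt$synapses$bouton_id,
                                     bt$bouton_id)]),
    if (nrow(gt$mitochondria)) data.frame(
      object_id = gt$mitochondria$object_id, channel = "mitochondrion",
      bouton_id = gt$mitochondria$bouton_id,
      vesicle_count = NA_integer_,
      roi_id = bt$roi_id[match(gt$mitochondria$bouton_id,
                               bt$bouton_id)],
      animal_id = bt$animal_id[match(gt$mitochondria$bouton_id,
                                     bt$bouton_id)]))
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

configToList <- function(cfg) {
  sl <- methods::slotNames(cfg)
  out <- lapply(sl, function(s) {
    v <- methods::slot(cfg, s)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  })
  names(out) <- sl
  out
}

#' Generate a complete synthetic regime dataset on disk
#'
#' Samples ground truth for the requested regime, rasterizes the three
#' label channels, and writes label stacks (TIFF and/or NRRD), the
#' ground-truth tables and the per-object metadata CSV to a run
#' directory. Re-running with the same seed reproduces byte-identical
#' truth tables.
#'
#' @param regime "YA", "AU" or "AI", or a custom
#'   \linkS4class{RegimeConfig} (then \code{seed} is taken from it).
#' @param seed RNG seed.
#' @param outDir output directory (created).
#' @param format "tiff", "nrrd" or c("tiff", "nrrd").
#' @param writeVolumes set FALSE to write only tables.
#' @return invisibly, list(gt, volumes (or NULL), dir).
#' @export
generateRegimeDataset <- function(regime, seed = 1L, outDir,
                                  format = "tiff",
                                  writeVolumes = TRUE) {
  cfg <- if (is(regime, "RegimeConfig")) regime
         else regimeConfig(regime, seed = seed)
  gt <- realizeMitoGeometry(sampleComplexes(cfg))
  writeGroundTruth(gt, outDir)
  vols <- NULL
  if (writeVolumes) {
    vols <- rasterizeComplexes(gt)
    for (fmt in format) {
      ext <- if (fmt == "tiff") "tif" else "nrrd"
      writeLabelVolume(vols$boutons,
                       file.path(outDir, paste0("boutons.", ext)))
      writeLabelVolume(vols$mitochondria,
                       file.path(outDir, paste0("mitochondria.", ext)))
      writeLabelVolume(vols$synapses,
                       file.path(outDir, paste0("synapses.", ext)))
    }
  }
  invisible(list(gt = gt, volumes = vols, dir = outDir))
}
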