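#' Run the end-to-end synthetic-neuropil analysis pipeline
#'
#' Orchestrates generate -> sample -> measure -> classify -> stats as a
#' seeded, logged run: per regime, ground truth is sampled, boutons are
#' selected by the reference-section counting frames and the vesicle
#' rule, selected complexes are rasterized object-wise and measured
#' from their meshes/contact traces, mitochondria are optionally
#' classified, and the across-animal statistical battery is produced
#' together with per-ROI densities. One master seed drives a
#' deterministic per-stage, per-regime seed sequence.
#'
#' @param config a named list (or path to a YAML file) with any of:
#'   \code{regimes} (default c("YA","AU","AI")), \code{seed} (1),
#'   \code{outDir} (NULL = nothing written), \code{stages} (default all
#'   of generate, sample, measure, stats), \code{classify} (TRUE),
#'   \code{nFrames} (4), \code{logScale} (FALSE), \code{writeVolumes}
#'   (FALSE), \code{presetFile} (NULL), \code{overrides} (named list of
#'   RegimeConfig field overrides applied to every regime).
#' @return list: \code{complexTable}, \code{morphometry},
#'   \code{densities}, \code{report}, \code{truth}, \code{config}.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    regimes = c("YA", "AU", "AI"), seed = 1L, outDir = NULL,
    stages = c("generate", "sample", "measure", "stats"),
    classify = TRUE, nFrames = 4L, logScale = FALSE,
    writeVolumes = FALSE, presetFile = NULL, overrides = list()),
    config)
  stageOrder <- c("generate", "sample", "measure", "stats")
  stages <- intersect(stageOrder, cfg$stages)
  for (k in seq_along(stageOrder)) {
    if (stageOrder[k] %in% stages) next
    later <- intersect(stageOrder[-seq_len(k)], stages)
    if (length(later))
      stop("stage '", later[1], "' requires output of stage '",
           stageOrder[k], "'; run '", stageOrder[k], "' first")
  }
  logLines <- c(
    sprintf("neuropilMorph pipeline, seed %d", cfg$seed),
    sprintf("regimes: %s", paste(cfg$regimes, collapse = ", ")),
    sprintf("stages: %s (classify = %s)",
            paste(stages, collapse = " -> "), cfg$classify),
    "counting frame edges: inclusion top+left, exclusion bottom+right",
    "density denominator: frame area x stack depth (per-area also emitted)",
    sprintf("frames per stack: %d (one stack per animal)", cfg$nFrames),
    "correlation scale: raw surface areas",
    "bend window: 3 x local radius (distance-transform maximum)",
    "synapse length: per-section geodesic trace + one-pixel end caps",
    "truncated objects: measured and flagged; never toroidal")

  truth <- list(); morphoAll <- list(); ctAll <- list()
  densAll <- list(); mitoAll <- list()
  for (ri in seq_along(cfg$regimes)) {
    regime <- cfg$regimes[ri]
    rseed <- stageSeed(cfg$seed, ri)
    rc <- do.call(regimeConfig,
                  c(list(name = regime, seed = rseed,
                         presetFile = cfg$presetFile), cfg$overrides))
    gt <- realizeMitoGeometry(sampleComplexes(rc))
    reg <- analysisRegion(rc)
    plan <- makeSamplingPlan(rc@volumeDims, rc@pixelNM,
                             rc@sectionThicknessNM,
                             nFrames = cfg$nFrames,
                             regionDimsNM = reg$dims,
                             regionOriginNM = reg$origin)
    if ("sample" %in% stages) {
      gt <- sampleStage(gt, plan)
      logLines <- c(logLines, sprintf(
        "%s: %d/%d boutons included (frames + vesicle rule)", regime,
        sum(gt$boutons$included), nrow(gt$boutons)))
    }
    truth[[regime]] <- gt
    if ("measure" %in% stages) {
      ids <- if ("sample" %in% stages)
        gt$boutons$bouton_id[gt$boutons$included]
      else gt$boutons$bouton_id
      morpho <- measureComplexes(gt, ids, classifyMitos = cfg$classify)
      morphoAll[[regime]] <- morpho
      ct <- buildComplexTable(morpho)
      ctAll[[regime]] <- ct
      densAll[[regime]] <- cbind(animal_id = regime,
                                 densities(ct, plan))
      m <- morpho[morpho$channel == "mitochondrion", , drop = FALSE]
      if (nrow(m)) mitoAll[[regime]] <- m
    }
    if (!is.null(cfg$outDir) && isTRUE(cfg$writeVolumes)) {
      generateRegimeDataset(rc, outDir = file.path(cfg$outDir, regime))
    }
  }
  complexTable <- if (length(ctAll)) do.call(rbind, ctAll) else NULL
  morphometry <- if (length(morphoAll)) do.call(rbind, morphoAll)
                 else NULL
  densTab <- if (length(densAll)) do.call(rbind, densAll) else NULL
  mitoTab <- if (length(mitoAll)) do.call(rbind, mitoAll) else NULL
  report <- NULL
  if ("stats" %in% stages) {
    if (is.null(complexTable))
      stop("stage 'stats' requires output of stage 'measure'; run ",
           "'measure' first")
    report <- if (length(unique(complexTable$animal_id)) >= 2)
      sizePrincipleReport(complexTable, mitoTable = mitoTab,
                          logScale = cfg$logScale)
    else NULL
    if (!is.null(densTab) && !is.null(report)) {
      roiDens <- densTab[densTab$roi_id != "all", , drop = FALSE]
      report$densityTests <- tryCatch(list(
        synapse = groupTests(roiDens, "synapse_density_um3",
                             "animal_id"),
        bouton = groupTests(roiDens, "bouton_density_um3",
                            "animal_id"),
        synapsesPerBouton = groupTests(roiDens, "synapses_per_bouton",
                                       "animal_id")),
        error = function(e) NULL)
    }
  }
  out <- list(complexTable = complexTable, morphometry = morphometry,
              densities = densTab, report = report, truth = truth,
              config = cfg, log = logLines)
  if (!is.null(cfg$outDir)) writeRunDir(out, cfg)
  out
}

# deterministic per-regime/stage sub-seed below 2^31
stageSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483629) + 1L
}

# frame inclusion + vesicle qualification on the reference section
sampleStage <- function(gt, plan) {
  bt <- gt$boutons
  refZ <- referenceSection(plan)
  px <- gt$config@pixelNM
  profiles <- vector("list", nrow(bt))
  present <- logical(nrow(bt))
  for (i in seq_len(nrow(bt))) {
    crop <- paintObjectCrop(gt, "bouton", i)
    zi <- refZ - crop$origin[3]
    if (zi < 1 || zi > crop$dims[3]) next
    sl <- crop$vol[, , zi] == bt$bouton_id[i]
    if (!any(sl)) next
    w <- which(sl, arr.ind = TRUE)
    profiles[[i]] <- cbind(w[, 1] - 1L + crop$origin[1],
                           w[, 2] - 1L + crop$origin[2])
    present[i] <- TRUE
  }
  roi <- rep(NA_character_, nrow(bt))
  if (any(present)) {
    asg <- assignProfiles(profiles[present], plan, px)
    roi[present] <- asg$roi_id
  }
  bt$roi_id <- roi
  bt$on_reference_section <- present
  bt$qualifies <- qualifiesAsBouton(bt$vesicle_count)
  bt$included <- present & !is.na(roi) & bt$qualifies
  gt$boutons <- bt
  gt$plan <- plan
  gt
}

writeRunDir <- function(out, cfg) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, nm) if (!is.null(df))
    utils::write.csv(df, file.path(cfg$outDir, nm), row.names = FALSE)
  wr(out$complexTable, "complex_table.csv")
  wr(out$morphometry, "morphometry.csv")
  wr(out$densities, "densities.csv")
  for (regime in names(out$truth))
    writeGroundTruth(out$truth[[regime]],
                     file.path(cfg$outDir, paste0("truth_", regime)))
  if (!is.null(out$report))
    writeReportBundle(out$report, file.path(cfg$outDir, "stats"))
  manifest <- list(seed = cfg$seed, regimes = cfg$regimes,
                   stages = cfg$stages, classify = cfg$classify,
                   nFrames = cfg$nFrames, logScale = cfg$logScale,
                   package_version =
                     as.character(utils::packageVersion("neuropilMorph")),
                   r_version = R.version.string)
  yaml::write_yaml(manifest, file.path(cfg$outDir, "manifest.yaml"))
  writeLines(out$log, file.path(cfg$outDir, "run.log"))
  invisible(cfg$outDir)
}
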