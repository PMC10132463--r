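test_that("copula calibration handles independence and degeneracy", {
  # independent sizes at large n
  cfg <- regimeConfig("YA", seed = 2, nBoutons = 10000L, rhoMB = 0,
                      subthresholdFrac = 0)
  gt <- sampleComplexes(cfg, spatial = FALSE)
  bm <- gt$boutons[gt$boutons$has_mito, ]
  expect_lt(abs(cor(bm$area_nm2, bm$mito_area_sum_nm2)), 0.03)

  # perfect correlation with matched log-sd: affine log relation
  cfg1 <- regimeConfig("YA", seed = 3, nBoutons = 500L, rhoMB = 1,
                       mitoLogSd = 0.45, occupancySlope = 0,
                       subthresholdFrac = 0)
  gt1 <- sampleComplexes(cfg1, spatial = FALSE)
  bm1 <- gt1$boutons[gt1$boutons$has_mito, ]
  expect_equal(cor(log(bm1$area_nm2), log(bm1$mito_area_sum_nm2)), 1,
               tolerance = 1e-10)
  expect_equal(cor(bm1$area_nm2, bm1$mito_area_sum_nm2), 1,
               tolerance = 1e-10)
})

test_that("copula fidelity: mean sample r matches the generating rho", {
  # AU preset, raw-scale Pearson of the truth tables over replicates
  rs <- rm <- numeric(100)
  for (s in 1:100) {
    gt <- neuropilMorph:::realizeMitoGeometry(
      sampleComplexes(regimeConfig("AU", seed = 5000 + s)))
    b <- gt$boutons
    bm <- b[b$has_mito, ]
    rs[s] <- cor(b$area_nm2, b$synapse_area_sum_nm2)
    rm[s] <- cor(bm$area_nm2, bm$mito_area_sum_nm2)
  }
  expect_lt(abs(mean(rs) - 0.80), 0.02)
  expect_lt(abs(mean(rm) - 0.69), 0.03)
})

test_that("infeasible joint correlations are rejected with a diagnostic", {
  expect_error(sampleComplexes(tinyConfig(rhoSB = -0.999)),
               "synapse-bouton")
})

test_that("regime presets carry the published correlation anchors", {
  expect_equal(regimeConfig("AI")@rhoMB, 0.19)
  expect_equal(regimeConfig("AU")@rhoSB, 0.80)
  expect_equal(regimeConfig("YA")@rhoSB, 0.68)
  expect_equal(regimeConfig("YA")@rhoMB, 0.65)
  expect_equal(regimeConfig("AU")@densityScale, 0.72)
  expect_error(regimeConfig("XX"), "should be one of")
  expect_setequal(regimeNames(), c("YA", "AU", "AI"))
})

test_that("sampling is deterministic and invariants hold", {
  g1 <- sampleComplexes(tinyConfig(seed = 11, n = 20L))
  g2 <- sampleComplexes(tinyConfig(seed = 11, n = 20L))
  expect_identical(g1$boutons, g2$boutons)
  expect_identical(g1$synapses, g2$synapses)

  gt <- neuropilMorph:::realizeMitoGeometry(
    sampleComplexes(tinyConfig(seed = 4, n = 30L)))
  # every child references an existing bouton
  expect_true(all(gt$synapses$bouton_id %in% gt$boutons$bouton_id))
  expect_true(all(gt$mitochondria$bouton_id %in% gt$boutons$bouton_id))
  # strictly positive sizes
  expect_true(all(gt$boutons$area_nm2 > 0))
  expect_true(all(gt$synapses$area_nm2 > 0))
  expect_true(all(gt$mitochondria$realized_area_nm2 > 0))
  # occupancy flag consistent with counts
  expect_identical(gt$boutons$has_mito, gt$boutons$n_mito >= 1L)
})

test_that("occupancy matches its binomial expectation", {
  hits <- total <- 0
  for (s in 1:10) {
    gt <- sampleComplexes(regimeConfig("YA", seed = 600 + s),
                          spatial = FALSE)
    hits <- hits + sum(gt$boutons$has_mito)
    total <- total + nrow(gt$boutons)
  }
  ci <- stats::binom.test(hits, total, p = 0.45)$conf.int
  expect_true(ci[1] <= 0.45 && 0.45 <= ci[2])
})

test_that("a configurable fraction of profiles fails the vesicle rule", {
  gt <- sampleComplexes(regimeConfig("YA", seed = 8,
                                     subthresholdFrac = 0.3),
                        spatial = FALSE)
  frac <- mean(gt$boutons$vesicle_count < 3)
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.45)
  gt0 <- sampleComplexes(regimeConfig("YA", seed = 8,
                                      subthresholdFrac = 0),
                         spatial = FALSE)
  expect_true(all(gt0$boutons$vesicle_count >= 3))
})

test_that("rasterized capsule volume matches the analytic value", {
  v <- capsuleMask(10, 40)
  expect_lt(abs(sum(v > 0) / neuropilMorph:::capsuleVolume(10, 40) - 1),
            0.05)
})

test_that("a rasterized torus has exactly one through-hole", {
  v <- torusMask(16, 8)
  mesh <- extractMesh(labelVol(v), 1L)
  expect_equal(eulerCharacteristic(mesh), 0)
  expect_true(detectThroughHole(mesh))
})

test_that("impossible placements raise a placement error", {
  # boutons far larger than the placement region cannot be placed
  expect_error(
    sampleComplexes(tinyConfig(n = 4L,
                               boutonLogMean = log(5e7))),
    "fit|place")
})

test_that("rasterized complexes carry every object with its own label", {
  gt <- neuropilMorph:::realizeMitoGeometry(
    sampleComplexes(tinyConfig(seed = 5, n = 6L)))
  vols <- rasterizeComplexes(gt)
  expect_s4_class(vols$boutons, "LabelVolume")
  expect_setequal(objectIds(vols$boutons), gt$boutons$bouton_id)
  expect_setequal(objectIds(vols$synapses), gt$synapses$object_id)
  if (nrow(gt$mitochondria))
    expect_setequal(objectIds(vols$mitochondria),
                    gt$mitochondria$object_id)
  # mitochondria fully inside their bouton
  mv <- voxelData(vols$mitochondria)
  bv <- voxelData(vols$boutons)
  for (j in seq_len(nrow(gt$mitochondria))) {
    sel <- mv == gt$mitochondria$object_id[j]
    expect_true(all(bv[sel] == gt$mitochondria$bouton_id[j]))
  }
})

test_that("crop-wise painting reproduces the full-volume raster", {
  gt <- neuropilMorph:::realizeMitoGeometry(
    sampleComplexes(tinyConfig(seed = 9, n = 6L)))
  vols <- rasterizeComplexes(gt)
  for (what in c("bouton", "mito", "synapse")) {
    tab <- switch(what, bouton = gt$boutons, mito = gt$mitochondria,
                  synapse = gt$synapses)
    full <- voxelData(switch(what, bouton = vols$boutons,
                             mito = vols$mitochondria,
                             synapse = vols$synapses))
    for (idx in seq_len(min(3, nrow(tab)))) {
      id <- if (what == "bouton") tab$bouton_id[idx]
            else tab$object_id[idx]
      crop <- neuropilMorph:::paintObjectCrop(gt, what, idx)
      sub <- full[crop$origin[1] + seq_len(crop$dims[1]),
                  crop$origin[2] + seq_len(crop$dims[2]),
                  crop$origin[3] + seq_len(crop$dims[3])]
      expect_identical(unname(crop$vol == id), unname(sub == id))
    }
  }
})

test_that("regime dataset generation is byte-identical under one seed", {
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  cfg <- tinyConfig(seed = 21, n = 5L)
  generateRegimeDataset(cfg, outDir = d1, writeVolumes = FALSE)
  generateRegimeDataset(cfg, outDir = d2, writeVolumes = FALSE)
  for (f in c("truth_boutons.csv", "truth_synapses.csv",
              "truth_mitochondria.csv", "metadata.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("label volumes round-trip through TIFF and NRRD", {
  gt <- neuropilMorph:::realizeMitoGeometry(
    sampleComplexes(tinyConfig(seed = 2, n = 4L,
                               volumeDims = c(300L, 250L, 11L))))
  vols <- rasterizeComplexes(gt)
  for (ext in c("tif", "nrrd")) {
    p <- file.path(tempdir(), paste0("b.", ext))
    writeLabelVolume(vols$boutons, p)
    back <- readLabelVolume(p, pixelNM = 8, thicknessNM = 60,
                            channel = "bouton")
    expect_identical(voxelData(back), voxelData(vols$boutons))
    unlink(p)
  }
})
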