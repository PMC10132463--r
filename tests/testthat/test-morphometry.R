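test_that("digitized sphere mesh recovers analytic area and volume", {
  r <- 20
  mesh <- extractMesh(labelVol(sphereMask(r)), 1L)
  expect_true(isWatertight(mesh))
  expect_equal(eulerCharacteristic(mesh), 2)
  expect_lt(abs(meshArea(mesh) / (4 * pi * r^2) - 1), 0.03)
  expect_lt(abs(meshVolume(mesh) / (4 / 3 * pi * r^3) - 1), 0.02)
})

test_that("mesh error decreases with resolution", {
  err <- sapply(c(10, 20), function(r) {
    mesh <- extractMesh(labelVol(sphereMask(r)), 1L)
    abs(meshArea(mesh) / (4 * pi * r^2) - 1)
  })
  expect_lt(err[2], err[1])
})

test_that("digitized torus is meshed as a genus-1 surface", {
  mesh <- extractMesh(labelVol(torusMask(16, 8)), 1L)
  expect_true(isWatertight(mesh))
  expect_equal(eulerCharacteristic(mesh), 0)
  expect_lt(abs(meshArea(mesh) / neuropilMorph:::torusArea(16, 8) - 1),
            0.05)
  expect_lt(abs(meshVolume(mesh) / neuropilMorph:::torusVolume(16, 8) - 1),
            0.02)
})

test_that("capsule measures track analytic values, also anisotropically", {
  mesh <- extractMesh(labelVol(capsuleMask(10, 40)), 1L)
  expect_lt(abs(meshArea(mesh) / neuropilMorph:::capsuleArea(10, 40) - 1),
            0.05)
  expect_lt(abs(meshVolume(mesh) /
                  neuropilMorph:::capsuleVolume(10, 40) - 1), 0.02)

  # capsule along z with stretched section thickness: length-dependent
  # volume terms scale linearly with thickness
  r <- 60; l <- 480
  v1 <- capsuleMask(r, l, spacing = c(8, 8, 40), axis = "z")
  v2 <- capsuleMask(r, l * 2, spacing = c(8, 8, 80), axis = "z")
  n1 <- sum(v1 > 0); n2 <- sum(v2 > 0)
  # doubling thickness with doubled physical length keeps voxel counts
  # close (same digitization of the stretched object)
  vol1 <- n1 * 8 * 8 * 40
  vol2 <- n2 * 8 * 8 * 80
  expect_lt(abs(vol1 / neuropilMorph:::capsuleVolume(r, l) - 1), 0.06)
  expect_lt(abs(vol2 / neuropilMorph:::capsuleVolume(r, 2 * l) - 1),
            0.06)
})

test_that("mesh volume agrees with the voxel-count volume", {
  for (mk in list(sphereMask(12), capsuleMask(9, 30), torusMask(14, 7))) {
    mesh <- extractMesh(labelVol(mk), 1L)
    expect_lt(abs(meshVolume(mesh) / sum(mk > 0) - 1), 0.02)
  }
})

test_that("unit cube mesh has closed-form measures, rigid-invariantly", {
  V <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  F <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  m <- meshMeasures(SurfaceMesh(V, F))
  expect_equal(unname(m[1]), 6)
  expect_equal(unname(m[2]), 1)
  # arbitrary rotation + translation
  th <- 0.7; ph <- 1.2
  R1 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
              c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)),
              c(0, sin(ph), cos(ph)))
  V2 <- sweep(V %*% t(R2 %*% R1), 2, c(3.3, -1.7, 0.5), "+")
  m2 <- meshMeasures(SurfaceMesh(V2, F))
  expect_equal(unname(m2[1]), 6, tolerance = 1e-9)
  expect_equal(unname(m2[2]), 1, tolerance = 1e-9)
})

test_that("non-watertight meshes are rejected unless flagged truncated", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  F <- rbind(c(1, 2, 3))
  open <- SurfaceMesh(V, F, closed = FALSE, truncated = FALSE)
  expect_error(meshMeasures(open), "watertight")
  flagged <- SurfaceMesh(V, F, closed = FALSE, truncated = TRUE)
  expect_silent(meshMeasures(flagged))
})

test_that("objects touching the stack boundary are flagged truncated", {
  v <- array(0L, c(9, 9, 3)); v[1, 5, 1] <- 1L
  mesh <- extractMesh(LabelVolume(v, 1, 1, "bouton"), 1L)
  expect_true(isTruncated(mesh))
  v2 <- array(0L, c(9, 9, 3)); v2[5, 5, 2] <- 1L
  expect_false(isTruncated(extractMesh(LabelVolume(v2, 1, 1, "bouton"),
                                       1L)))
  expect_error(extractMesh(LabelVolume(v2, 1, 1, "bouton"), 7L),
               "not found")
})

test_that("contact lengths follow the per-section trace geometry", {
  # straight 1-pixel trace of 50 px at 2 nm -> 100 nm
  v <- array(0L, c(60, 7, 4)); v[6:55, 4, 1] <- 1L
  lv <- LabelVolume(v, 2, 60, "synapse")
  expect_equal(unname(contactLengths(lv, 1L)), 100)

  # duplicated on three consecutive sections -> three equal lengths
  v3 <- array(0L, c(60, 7, 4))
  for (z in 1:3) v3[6:55, 4, z] <- 1L
  l3 <- contactLengths(LabelVolume(v3, 2, 60, "synapse"), 1L)
  expect_length(l3, 3)
  expect_equal(unname(l3), rep(100, 3))

  # L-shaped trace, two 25-px arms -> within 5% of 100 nm
  vL <- array(0L, c(40, 40, 1))
  vL[6:30, 6, 1] <- 1L
  vL[30, 6:30, 1] <- 1L
  lL <- contactLengths(LabelVolume(vL, 2, 60, "synapse"), 1L)
  expect_lt(abs(unname(lL) / 100 - 1), 0.05)

  expect_error(contactLengths(lv, 99L), "empty|absent")
})

test_that("synapse area is exactly summed length times thickness", {
  expect_equal(synapseArea(c(200, 250, 300), 60), 45000)
  expect_equal(synapseArea(123.4, 55), 123.4 * 55)
  # exact linearity in thickness and in each length
  l <- c(150, 310, 80)
  expect_equal(synapseArea(l * 3, 60), 3 * synapseArea(l, 60))
  expect_equal(synapseArea(l, 180), 3 * synapseArea(l, 60))
  expect_error(synapseArea(numeric(0), 60), "no contact")
  expect_error(synapseArea(c(100, -5), 60), "positive")
  expect_error(synapseArea(100, 0), "positive")
})

test_that("synthetic contact patches recover the generated area", {
  gt <- neuropilMorph:::realizeMitoGeometry(
    sampleComplexes(tinyConfig(seed = 3, n = 8L)))
  morpho <- neuropilMorph:::measureComplexes(gt)
  sy <- morpho[morpho$channel == "synapse", ]
  i <- match(sy$object_id, gt$synapses$object_id)
  relErr <- sy$synapse_area_nm2 / gt$synapses$area_nm2[i] - 1
  # patches above ~3 px of trace per section recover within 5%;
  # patches at the resolution floor stay within 15%
  big <- gt$synapses$area_nm2[i] > 2e4
  expect_true(any(big))
  expect_true(all(abs(relErr[big]) < 0.05))
  expect_true(all(abs(relErr) < 0.15))
})

test_that("measureVolumes produces one joined row per object", {
  gt <- neuropilMorph:::realizeMitoGeometry(
    sampleComplexes(tinyConfig(seed = 6, n = 5L)))
  vols <- rasterizeComplexes(gt)
  meta <- neuropilMorph:::buildMetadata(gt)
  morpho <- measureVolumes(vols$boutons, vols$mitochondria,
                           vols$synapses, meta = meta)
  expect_equal(sum(morpho$channel == "bouton"), nrow(gt$boutons))
  expect_equal(sum(morpho$channel == "synapse"), nrow(gt$synapses))
  expect_true(all(!is.na(morpho$bouton_id)))
  b <- morpho[morpho$channel == "bouton", ]
  i <- match(b$object_id, gt$boutons$bouton_id)
  expect_true(all(abs(b$surface_area_nm2 /
                        gt$boutons$area_nm2[i] - 1) < 0.08))
})
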