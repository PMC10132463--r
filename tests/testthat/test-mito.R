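spNM <- c(8, 8, 60)

test_that("skeletons follow the tube axis, cycles, and ball degeneracy", {
  # straight capsule: skeleton within ~1 voxel of the axis
  v <- capsuleMask(10, 40)
  sk <- skeletonizeMito(v > 0, c(1, 1, 1))
  ctr <- dim(v) / 2
  offAxis <- sqrt((sk[, 2] - ctr[2])^2 + (sk[, 3] - ctr[3])^2)
  expect_lt(stats::median(offAxis), 1.5)

  # solid torus: principal cycle is closed
  vt <- torusMask(16, 8)
  skc <- skeletonizeMito(vt > 0, c(1, 1, 1), cycle = TRUE)
  expect_true(isTRUE(attr(skc, "closed")))
  expect_identical(skc[1, ], skc[nrow(skc), ])

  # ball: longest path stays below diameter + 2 voxels
  vb <- sphereMask(15)
  skb <- skeletonizeMito(vb > 0, c(1, 1, 1))
  expect_lt(sum(sqrt(rowSums(diff(skb)^2))), 32)

  # thin sheet: degenerate-skeleton error
  vs <- array(FALSE, c(20, 20, 3)); vs[3:17, 10, 2] <- TRUE
  expect_error(skeletonizeMito(vs, c(1, 1, 1)), "degenerate")
})

test_that("maxBendAngle matches line, elbow and arc geometry", {
  line <- cbind(seq(0, 100, 2), 0, 0)
  expect_equal(maxBendAngle(line, 10), 0)

  elbow <- rbind(cbind(seq(0, 50, 2), 0, 0),
                 cbind(50, seq(2, 50, 2), 0))
  expect_lt(abs(maxBendAngle(elbow, 10) - 90), 2)

  phi <- seq(0, 120 * pi / 180, length.out = 200)
  arc <- cbind(100 * sin(phi), 100 * (1 - cos(phi)), 0)
  expect_lt(abs(maxBendAngle(arc, 5) - 120), 5)

  expect_warning(maxBendAngle(elbow, 1e5), "whole polyline")
  expect_error(maxBendAngle(arc, -1), "> 0")
})

test_that("through-holes are detected from surface topology", {
  expect_false(detectThroughHole(extractMesh(labelVol(sphereMask(10)),
                                             1L)))
  expect_true(detectThroughHole(extractMesh(labelVol(torusMask(14, 7)),
                                            1L)))
  # two-tunnel block: chi = -2, genus 2
  v <- array(1L, c(40, 60, 40))
  v[11:16, , 11:16] <- 0L
  v[25:30, , 25:30] <- 0L
  block <- array(0L, c(46, 66, 46))
  block[4:43, 4:63, 4:43] <- v
  mesh <- extractMesh(labelVol(block), 1L, sigma = 0)
  expect_equal(eulerCharacteristic(mesh), -2)
  expect_true(detectThroughHole(mesh))
  # non-watertight input is rejected
  open <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)), closed = FALSE)
  expect_error(detectThroughHole(open), "watertight")
})

test_that("morphology classes follow the 90-degree bend rule", {
  r30 <- classifyMito(arcTubeMask(30, 70, 450) > 0, spNM)
  expect_identical(r30$morphClass, "straight")
  r110 <- classifyMito(arcTubeMask(110, 70, 450) > 0, spNM)
  expect_identical(r110$morphClass, "curved")
  expect_gte(r110$maxBendDeg, 90)
  tor <- classifyMito(torusMask(150, 100, spacing = spNM) > 0, spNM)
  expect_identical(tor$morphClass, "toroidal")
  expect_true(tor$hasThroughHole)
  # truncated objects are classified from the skeleton, never toroidal
  tr <- classifyMito(torusMask(150, 100, spacing = spNM) > 0, spNM,
                     truncated = TRUE)
  expect_false(tr$hasThroughHole)
  expect_true(tr$uncertain)
  expect_true(tr$morphClass %in% c("straight", "curved"))
})

test_that("the classifier is perfectly accurate away from the boundary", {
  set.seed(101)
  nPer <- 50
  ok <- 0; n <- 0
  for (i in seq_len(nPer)) {
    rr <- runif(1, 60, 85); LL <- runif(1, 5.2, 7) * rr
    bend <- runif(1, 0, 70)
    got <- classifyMito(arcTubeMask(bend, rr, LL) > 0, spNM)$morphClass
    n <- n + 1; ok <- ok + (got == "straight")

    bend <- runif(1, 105, 150)
    got <- classifyMito(arcTubeMask(bend, rr, LL) > 0, spNM)$morphClass
    n <- n + 1; ok <- ok + (got == "curved")

    Rt <- runif(1, 120, 170); rt <- runif(1, 48, 0.55 * Rt)
    got <- classifyMito(torusMask(Rt, rt, spacing = spNM) > 0,
                        spNM)$morphClass
    n <- n + 1; ok <- ok + (got == "toroidal")
  }
  expect_equal(ok, n)  # 150/150
})

test_that("classification is invariant under in-plane rotation", {
  # rotate the arc tube by an arbitrary angle about z and re-rasterize
  rot <- function(bend, ang, r, L) {
    uv <- neuropilMorph:::tubeCenterline(r, L, bend, nSeg = 12)
    R <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
    uv2 <- uv %*% t(R)
    dims <- c(250, 250, 12)
    v <- integer(prod(dims)); dim(v) <- dims
    ctr <- dims * spNM / 2
    for (k in seq_len(nrow(uv2) - 1))
      neuropilMorph:::cpp_fill_capsule(
        v, dims, 1L,
        c(ctr[1] + uv2[k, 1], ctr[2] + uv2[k, 2], ctr[3]),
        c(ctr[1] + uv2[k + 1, 1], ctr[2] + uv2[k + 1, 2], ctr[3]),
        r, spNM, c(0, 0, 0))
    v
  }
  for (bend in c(30, 120)) {
    base <- classifyMito(rot(bend, 0, 70, 430) > 0, spNM)$morphClass
    for (ang in c(0.4, 1.1, 2.3))
      expect_identical(classifyMito(rot(bend, ang, 70, 430) > 0,
                                    spNM)$morphClass, base)
  }
})

test_that("an angle sweep transitions once near 90 degrees", {
  gens <- seq(60, 120, by = 5)
  cls <- vapply(gens, function(bd)
    classifyMito(arcTubeMask(bd, 70, 450) > 0, spNM)$morphClass,
    character(1))
  flips <- which(cls[-1] != cls[-length(cls)])
  expect_length(flips, 1)
  boundary <- (gens[flips] + gens[flips + 1]) / 2
  expect_lte(abs(boundary - 90), 5)
})
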