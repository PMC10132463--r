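test_that("the default plan reproduces the published frame geometry", {
  plan <- makeSamplingPlan(c(2500L, 1375L, 41L), 8, 60)
  expect_length(frames(plan), 4)
  areas <- vapply(frames(plan), frameArea, numeric(1)) / 1e6
  expect_equal(areas, rep(40.5, 4))
  expect_equal(planArea(plan) / 1e6, 162)
  expect_equal(referenceSection(plan), 21L)  # middle of 41
  # frames tile the region without overlap
  xs <- t(vapply(frames(plan), function(f)
    c(f@originNM, f@widthNM, f@heightNM), numeric(4)))
  expect_equal(sum(xs[, 3] * xs[, 4]) / 1e6, 162)
})

test_that("a single frame degenerates to the whole analysis region", {
  plan <- makeSamplingPlan(c(2500L, 1375L, 41L), 8, 60, nFrames = 1L)
  expect_length(frames(plan), 1)
  expect_equal(frames(plan)[[1]]@widthNM, 18e3)
  expect_equal(frames(plan)[[1]]@heightNM, 9e3)
})

test_that("undersized stacks are rejected with minimum dimensions", {
  expect_error(makeSamplingPlan(c(100L, 100L, 11L), 8, 60),
               "at least")
})

test_that("the vesicle rule admits boutons with three or more vesicles", {
  expect_identical(qualifiesAsBouton(c(0, 2, 3, 10)),
                   c(FALSE, FALSE, TRUE, TRUE))
  expect_error(qualifiesAsBouton(-1), "non-negative")
})

test_that("edge-intersection patterns follow the inclusion rule", {
  # frame 10 x 8 px at 2 nm: [20, 40] x [10, 26] nm
  fr <- CountingFrame(c(20, 10), 20, 16)
  px <- 2
  bar <- function(xs, ys) as.matrix(expand.grid(xs, ys))
  rule <- function(hit) {
    if (any(hit[c("bottom", "right")])) FALSE
    else if (any(hit[c("top", "left")])) TRUE
    else NA  # fully inside / outside decided separately
  }
  cases <- list(
    interior   = list(p = bar(12:15, 7:9), edges = character()),
    outside    = list(p = bar(40:45, 30:33), edges = character()),
    top        = list(p = bar(13:14, 4:6), edges = "top"),
    left       = list(p = bar(8:11, 7:8), edges = "left"),
    bottom     = list(p = bar(13:14, 12:14), edges = "bottom"),
    right      = list(p = bar(19:22, 7:8), edges = "right"),
    topleft    = list(p = rbind(bar(8:11, 6), bar(10, 4:6)),
                      edges = c("top", "left")),
    topright   = list(p = rbind(bar(17:21, 6), bar(19, 4:6)),
                      edges = c("top", "right")),
    bottomleft = list(p = rbind(bar(8:12, 11), bar(10, 11:14)),
                      edges = c("bottom", "left")),
    bottomright = list(p = rbind(bar(17:21, 11), bar(19, 11:14)),
                       edges = c("bottom", "right")),
    topbottom  = list(p = bar(13, 4:14), edges = c("top", "bottom")),
    leftright  = list(p = bar(8:21, 8), edges = c("left", "right")),
    threeTBL   = list(p = rbind(bar(13, 4:14), bar(8:13, 8)),
                      edges = c("top", "bottom", "left")),
    threeTBR   = list(p = rbind(bar(16, 4:14), bar(16:21, 8)),
                      edges = c("top", "bottom", "right")),
    threeLRT   = list(p = rbind(bar(8:21, 8), bar(13, 4:8)),
                      edges = c("left", "right", "top")),
    all4       = list(p = rbind(bar(8:21, 8), bar(13, 4:14)),
                      edges = c("top", "bottom", "left", "right")))
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    hit <- c(top = "top" %in% cs$edges, left = "left" %in% cs$edges,
             bottom = "bottom" %in% cs$edges,
             right = "right" %in% cs$edges)
    want <- rule(hit)
    if (is.na(want)) want <- nm == "interior"
    expect_identical(includeProfile(cs$p, fr, px), want,
                     label = paste("pattern", nm))
  }
})

test_that("profiles on the reference section must be non-empty", {
  fr <- CountingFrame(c(20, 10), 20, 16)
  expect_error(includeProfile(matrix(numeric(0), 0, 2), fr, 2),
               "empty")
})

test_that("inclusion decisions are translation invariant", {
  fr <- CountingFrame(c(100, 100), 200, 150)
  set.seed(42)
  for (i in 1:25) {
    p <- as.matrix(expand.grid(0:3 + sample(40:80, 1),
                               0:3 + sample(40:80, 1)))
    base <- includeProfile(p, fr, 2)
    sh <- c(37, -21)
    fr2 <- CountingFrame(fr@originNM + sh * 2, 200, 150)
    expect_identical(includeProfile(sweep(p, 2, sh, "+"), fr2, 2),
                     base)
  }
})

test_that("a tiling of frames counts every profile at most once", {
  plan <- makeSamplingPlan(c(600L, 600L, 11L), 2, 60, nFrames = 4L,
                           regionDimsNM = c(800, 800))
  set.seed(7)
  counted <- integer(200)
  for (i in 1:200) {
    cx <- runif(1, 50, 550); cy <- runif(1, 50, 550)
    r <- runif(1, 3, 25)
    g <- expand.grid(x = 0:599, y = 0:599)
    # cheap disk profile around the centre (in px)
    sel <- (g$x * 2 + 1 - cx)^2 + (g$y * 2 + 1 - cy)^2 <= r^2
    if (!any(sel)) next
    p <- as.matrix(g[sel, ])
    counted[i] <- sum(vapply(frames(plan), function(fr)
      includeProfile(p, fr, 2), TRUE))
  }
  expect_true(all(counted <= 1))
})

test_that("density arithmetic and degenerate frames behave as stated", {
  plan <- makeSamplingPlan(c(2500L, 1375L, 41L), 8, 60)
  # 10 boutons with 12 synapses in roi1, nothing elsewhere
  cx <- data.frame(roi_id = rep("roi1", 10),
                   n_synapse = c(rep(1, 8), 2, 2))
  d <- densities(cx, plan)
  v1 <- 40.5 * 41 * 0.06  # um3 per frame
  expect_equal(d$bouton_density_um3[d$roi_id == "roi1"], 10 / v1)
  expect_equal(d$synapse_density_um3[d$roi_id == "roi1"], 12 / v1)
  expect_equal(d$synapses_per_bouton[d$roi_id == "roi1"], 1.2)
  # empty frame: zero densities, undefined synapses-per-bouton
  expect_equal(d$bouton_density_um3[d$roi_id == "roi2"], 0)
  expect_true(is.na(d$synapses_per_bouton[d$roi_id == "roi2"]))
  expect_equal(d$n_boutons[d$roi_id == "all"], 10)
})

test_that("frame counting is unbiased for homogeneous placements", {
  # Poisson ellipsoids at known intensity; profiles are lateral
  # footprints and the z associated point (top tip) must lie in the
  # stack, the unbiased-brick convention. Two object-size
  # distributions give the same expectation.
  px <- 4
  plan <- makeSamplingPlan(c(1000L, 1000L, 21L), px, 60, nFrames = 4L,
                           regionDimsNM = c(2400, 2400))
  depth <- 21 * 60
  lam <- 8e-9  # objects per nm^3
  volNM <- c(1000 * px, 1000 * px, depth)
  est <- matrix(NA_real_, 30, 2)
  set.seed(33)
  for (rep in 1:30) {
    for (sz in 1:2) {
      rMean <- c(60, 140)[sz]
      # pad so objects whose top tip is inside can extend beyond
      nObj <- rpois(1, lam * prod(volNM + c(800, 800, 800)))
      cx <- runif(nObj, -400, volNM[1] + 400)
      cy <- runif(nObj, -400, volNM[2] + 400)
      topZ <- runif(nObj, -400, volNM[3] + 400)
      rr <- pmax(rMean * runif(nObj, 0.5, 1.5), 3 * px)
      inc <- 0
      for (i in seq_len(nObj)) {
        if (topZ[i] < 0 || topZ[i] >= depth) next
        x0 <- floor((cx[i] - rr[i]) / px):ceiling((cx[i] + rr[i]) / px)
        prof <- as.matrix(expand.grid(x0, x0 - x0[1] +
          floor((cy[i] - rr[i]) / px)))
        ctr <- (prof + 0.5) * px
        sel <- (ctr[, 1] - cx[i])^2 + (ctr[, 2] - cy[i])^2 <= rr[i]^2
        if (!any(sel)) next
        prof <- prof[sel, , drop = FALSE]
        inc <- inc + sum(vapply(frames(plan), function(fr)
          includeProfile(prof, fr, px), TRUE))
      }
      est[rep, sz] <- inc / (planArea(plan) * depth)
    }
  }
  expect_lt(abs(mean(est[, 1]) / lam - 1), 0.05)
  expect_lt(abs(mean(est[, 2]) / lam - 1), 0.05)
})
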