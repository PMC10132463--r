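# Programmatic voxel fixtures shared across tests. All geometry is
# painted through the package's own rasterizers; analytic reference
# values come from closed-form surface/volume formulas.

sphereMask <- function(r, spacing = c(1, 1, 1), pad = 4) {
  n <- ceiling(2 * r / spacing) + 2 * pad
  v <- integer(prod(n)); dim(v) <- n
  ctr <- n * spacing / 2
  neuropilMorph:::cpp_fill_ellipsoid(v, n, 1L, ctr, c(r, r, r),
                                     spacing, c(0, 0, 0))
  v
}

capsuleMask <- function(r, l, spacing = c(1, 1, 1), pad = 4,
                        axis = "x") {
  ext <- c(l + 2 * r, 2 * r, 2 * r)
  if (axis == "z") ext <- rev(ext)
  n <- ceiling(ext / spacing) + 2 * pad
  v <- integer(prod(n)); dim(v) <- n
  ctr <- n * spacing / 2
  d <- switch(axis, x = c(1, 0, 0), z = c(0, 0, 1))
  neuropilMorph:::cpp_fill_capsule(v, n, 1L, ctr - d * l / 2,
                                   ctr + d * l / 2, r, spacing,
                                   c(0, 0, 0))
  v
}

torusMask <- function(R, r, spacing = c(1, 1, 1), pad = 4) {
  n <- ceiling(c(2 * (R + r), 2 * (R + r), 2 * r) / spacing) + 2 * pad
  v <- integer(prod(n)); dim(v) <- n
  ctr <- n * spacing / 2
  neuropilMorph:::cpp_fill_torus(v, n, 1L, ctr, R, r, spacing,
                                 c(0, 0, 0))
  v
}

# tube swept along a planar arc of total turn bendDeg (the generator's
# curved-mitochondrion primitive)
arcTubeMask <- function(bendDeg, r, L, spacing = c(8, 8, 60),
                        dims = c(250, 250, 12)) {
  uv <- neuropilMorph:::tubeCenterline(r, L, bendDeg, nSeg = 12)
  v <- integer(prod(dims)); dim(v) <- dims
  ctr <- dims * spacing / 2
  for (k in seq_len(nrow(uv) - 1))
    neuropilMorph:::cpp_fill_capsule(
      v, dims, 1L,
      c(ctr[1] + uv[k, 1], ctr[2] + uv[k, 2], ctr[3]),
      c(ctr[1] + uv[k + 1, 1], ctr[2] + uv[k + 1, 2], ctr[3]),
      r, spacing, c(0, 0, 0))
  v
}

labelVol <- function(v, px = 1, th = 1, channel = "mitochondrion")
  LabelVolume(v, px, th, channel)

# small-volume regime config for fast end-to-end tests
tinyConfig <- function(regime = "YA", seed = 1, n = 8L, ...) {
  regimeConfig(regime, seed = seed, nBoutons = n,
               volumeDims = c(800L, 600L, 21L), ...)
}
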