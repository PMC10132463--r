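# Geometric realization of sampled complexes.
#
# Mitochondria are tubes of radius r swept along a planar circular arc
# of length L and total turn theta (Pappus: area = 2*pi*r*L + 4*pi*r^2,
# volume = pi*r^2*L + 4/3*pi*r^3, independent of theta while the bend
# radius exceeds r), or solid tori for the toroidal class. The solver
# fits each tube inside its host ellipsoid; when a draw cannot fit at
# any allowed aspect/bend the realized area is reduced and recorded in
# the truth table (the generating copula refers to the target draws;
# realized values are what the rasterized volume can support).

mitoGeometrySolve <- function(A, bendDeg, class, a, b, cc, pixelNM,
                              thicknessNM = 60) {
  if (class == "toroidal") {
    r <- min(0.72 * cc, sqrt(A / (4 * pi^2 * 1.8)))
    r <- max(r, min(0.8 * thicknessNM, 0.72 * cc))
    R <- A / (4 * pi^2 * r)
    if (R - r < 3 * pixelNM) R <- r + 3 * pixelNM
    lim <- 0.8 * min(a, b)
    if (R + r > lim) {
      f <- lim / (R + r)
      R <- R * f; r <- r * f
    }
    if (R - r < 3 * pixelNM || r < 1.2 * pixelNM) {
      # hole no longer resolvable: realize as a stout tube instead
      return(mitoGeometrySolve(A, 30, "straight", a, b, cc, pixelNM,
                               thicknessNM))
    }
    return(list(type = "toroidal", r = r, R = R, L = NA_real_,
                thetaDeg = NA_real_,
                area = torusArea(R, r), volume = torusVolume(R, r)))
  }
  theta <- bendDeg
  thetaMax <- if (class == "curved") 150 else 55
  # curved mitochondria are realized as elongated tubes (a bend is
  # only geometrically well defined when the arc is long relative to
  # the tube radius); straight ones are stout, matching the ~200-400
  # nm diameter of real presynaptic mitochondria so they span several
  # sections and measure reliably
  lambda <- if (class == "curved") 5.5 else 1.5
  rmax <- min(0.75 * cc, 0.42 * min(a, b))
  # a tube much thinner than a section measures poorly and can fall
  # between section planes
  rmin <- min(0.8 * thicknessNM, rmax)
  Acur <- A
  for (tr in 1:24) {
    r <- max(min(sqrt(Acur / (2 * pi * (lambda + 2))), rmax), rmin)
    L <- Acur / (2 * pi * r) - 2 * r
    if (L < 0.5 * r) { L <- 0.5 * r; Acur <- 2 * pi * r * L + 4 * pi * r^2 }
    if (tubeFits(r, L, theta, a, b, vOffset = 0)) break
    if (theta + 15 <= thetaMax) theta <- theta + 15
    else Acur <- 0.9 * Acur
  }
  if (class == "curved" && (L < 4.5 * r || L < 280)) {
    # too small to express a resolvable bend (the arc radius would
    # approach the pixel scale): realize as straight
    return(mitoGeometrySolve(A, min(bendDeg, 40), "straight", a, b, cc,
                             pixelNM, thicknessNM))
  }
  list(type = class, r = r, R = NA_real_, L = L, thetaDeg = theta,
       area = 2 * pi * r * L + 4 * pi * r^2,
       volume = pi * r^2 * L + 4 / 3 * pi * r^3)
}

# Sample the arc centreline (chord along the u axis, bulge in +v,
# re-centred); s in [-L/2, L/2].
tubeCenterline <- function(r, L, thetaDeg, nSeg = 8) {
  s <- seq(-L / 2, L / 2, length.out = nSeg + 1)
  th <- thetaDeg * pi / 180
  if (th < 1e-6) {
    cbind(u = s, v = rep(0, length(s)))
  } else {
    Rarc <- L / th
    phi <- s / Rarc
    u <- Rarc * sin(phi)
    v <- Rarc * (1 - cos(phi))
    cbind(u = u, v = v - mean(range(v)))
  }
}

tubeFits <- function(r, L, thetaDeg, a, b, vOffset = 0) {
  p <- tubeCenterline(r, L, thetaDeg, nSeg = 10)
  au <- max(a, b) - r
  bv <- min(a, b) - r
  if (au <= 0 || bv <= 0) return(FALSE)
  all((p[, 1] / au)^2 + ((p[, 2] + vOffset) / bv)^2 <= 0.92^2)
}

# Attach realized geometry to the mitochondria table and refresh the
# per-bouton realized sums. Deterministic (no RNG). A draw too large
# for a single tube inside its bouton is split into side-by-side
# sibling tubes rather than censored, so extreme mito/bouton size
# ratios survive realization (censoring them would artificially
# strengthen the mito-bouton correlation); siblings that cannot sit
# side by side are merged into one tube carrying the summed area.
realizeMitoGeometry <- function(gt) {
  mt <- gt$mitochondria
  bt <- gt$boutons
  if (!nrow(mt)) {
    mt$r_nm <- mt$R_nm <- mt$len_nm <- mt$theta_deg <- numeric(0)
    mt$v_offset_nm <- mt$realized_area_nm2 <- numeric(0)
    mt$volume_nm3 <- numeric(0)
    mt$realized_class <- character(0)
    gt$mitochondria <- mt
    return(gt)
  }
  px <- gt$config@pixelNM
  th <- gt$config@sectionThicknessNM
  out <- list()
  for (bid in unique(mt$bouton_id)) {
    rows <- mt[mt$bouton_id == bid, , drop = FALSE]
    i <- match(bid, bt$bouton_id)
    a <- bt$semi_a_nm[i]; b <- bt$semi_b_nm[i]; cc <- bt$semi_c_nm[i]
    solveAll <- function(areas, bends, classes) {
      gs <- mapply(function(A, bd, cl)
        mitoGeometrySolve(A, bd, cl, a, b, cc, px, th),
        areas, bends, classes, SIMPLIFY = FALSE)
      rs <- vapply(gs, function(g)
        if (g$type == "toroidal") g$R + g$r else g$r, numeric(1))
      fits <- sum(rs) + (length(gs) - 1) * 2 * px <= 0.84 * min(a, b)
      list(gs = gs, rs = rs, fits = fits,
           realized = sum(vapply(gs, `[[`, numeric(1), "area")))
    }
    plans <- list()
    # plan 1: children as drawn
    plans[[1]] <- solveAll(rows$area_nm2, rows$bend_deg,
                           rows$morph_class)
    total <- sum(rows$area_nm2)
    if (nrow(rows) > 1 && !plans[[1]]$fits) {
      # merge: one tube carrying the summed area
      plans[[2]] <- solveAll(total, rows$bend_deg[1],
                             rows$morph_class[1])
      rows <- rows[1, , drop = FALSE]
      rows$area_nm2 <- total
      plans[[1]] <- plans[[2]]
    } else if (nrow(rows) == 1 &&
               plans[[1]]$realized < 0.92 * total) {
      # split an oversized draw across side-by-side tubes
      for (k in 2:3) {
        w <- seq(0.55, by = -0.1, length.out = k)
        w <- w / sum(w)
        cand <- solveAll(total * w, rep(rows$bend_deg, k),
                         rep(rows$morph_class, k))
        if (cand$fits && cand$realized > plans[[1]]$realized) {
          plans[[1]] <- cand
          rows <- rows[rep(1, k), , drop = FALSE]
          rows$area_nm2 <- total * w
        }
        if (plans[[1]]$realized >= 0.92 * total) break
      }
    }
    plan <- plans[[1]]
    off <- if (length(plan$rs) > 1) {
      o <- cumsum(c(0, plan$rs[-length(plan$rs)] + plan$rs[-1] +
                      2 * px))
      o - mean(o)
    } else 0
    for (k in seq_len(nrow(rows))) {
      g <- plan$gs[[k]]
      r <- rows[k, , drop = FALSE]
      r$realized_class <- g$type
      r$r_nm <- g$r; r$R_nm <- g$R; r$len_nm <- g$L
      r$theta_deg <- g$thetaDeg
      r$v_offset_nm <- off[k]
      r$realized_area_nm2 <- g$area
      r$volume_nm3 <- g$volume
      out[[length(out) + 1L]] <- r
    }
  }
  mt <- do.call(rbind, out)
  mt$object_id <- seq_len(nrow(mt))
  rownames(mt) <- NULL
  gt$mitochondria <- mt
  sums <- tapply(mt$realized_area_nm2, mt$bouton_id, sum)
  bt$mito_area_sum_nm2 <- 0
  bt$mito_area_sum_nm2[match(as.integer(names(sums)), bt$bouton_id)] <- sums
  bt$n_mito <- 0L
  cnt <- table(mt$bouton_id)
  bt$n_mito[match(as.integer(names(cnt)), bt$bouton_id)] <-
    as.integer(cnt)
  bt$has_mito <- bt$n_mito > 0L
  gt$boutons <- bt
  gt
}

# ---- painters ------------------------------------------------------

# Paint one bouton / its mitochondria / its synapses into an integer
# volume. `dims` are the volume dims, `originPx` the 0-based voxel
# offset of the volume within the global raster (so crops and the full
# volume paint identical voxels).
paintBouton <- function(vol, dims, originPx, gt, i) {
  cfg <- gt$config
  sp <- c(cfg@pixelNM, cfg@pixelNM, cfg@sectionThicknessNM)
  bt <- gt$boutons[i, ]
  cpp_fill_ellipsoid(vol, dims, bt$bouton_id,
                     c(bt$x_nm, bt$y_nm, bt$z_nm),
                     c(bt$semi_a_nm, bt$semi_b_nm, bt$semi_c_nm),
                     sp, originPx * sp)
}

paintMito <- function(vol, dims, originPx, gt, j) {
  cfg <- gt$config
  sp <- c(cfg@pixelNM, cfg@pixelNM, cfg@sectionThicknessNM)
  orig <- originPx * sp
  mt <- gt$mitochondria[j, ]
  bt <- gt$boutons[match(mt$bouton_id, gt$boutons$bouton_id), ]
  ctr <- c(bt$x_nm, bt$y_nm, bt$z_nm)
  # u along the longer lateral axis
  uIsX <- bt$semi_a_nm >= bt$semi_b_nm
  toWorld <- function(uv, vOff) {
    if (uIsX) cbind(ctr[1] + uv[, 1], ctr[2] + uv[, 2] + vOff, ctr[3])
    else cbind(ctr[1] + uv[, 2] + vOff, ctr[2] + uv[, 1], ctr[3])
  }
  if (mt$realized_class == "toroidal") {
    c3 <- toWorld(cbind(0, 0), mt$v_offset_nm)
    cpp_fill_torus(vol, dims, mt$object_id, as.numeric(c3), mt$R_nm,
                   mt$r_nm, sp, orig)
  } else {
    uv <- tubeCenterline(mt$r_nm, mt$len_nm, mt$theta_deg, nSeg = 8)
    pw <- toWorld(uv, mt$v_offset_nm)
    for (k in seq_len(nrow(pw) - 1))
      cpp_fill_capsule(vol, dims, mt$object_id, pw[k, ], pw[k + 1, ],
                       mt$r_nm, sp, orig)
  }
  invisible(NULL)
}

# Synapse ribbons: a band on the bouton surface spanning the sections
# around the bouton centre, whose per-section chord lengths follow an
# elliptic profile and satisfy sum(l_k) * thickness = contact area.
synapseRibbonPlan <- function(gt, j) {
  cfg <- gt$config
  th <- cfg@sectionThicknessNM
  sy <- gt$synapses[j, ]
  bt <- gt$boutons[match(sy$bouton_id, gt$boutons$bouton_id), ]
  sib <- which(gt$synapses$bouton_id == sy$bouton_id)
  slot <- match(j, sib)
  az0 <- 2 * pi * (slot - 1) / length(sib) + 0.35
  hh <- 0.8 * bt$semi_c_nm
  kAll <- 0:(cfg@volumeDims[3] - 1)
  zc <- (kAll + 0.5) * th
  dz <- zc - bt$z_nm
  use <- abs(dz) < hh
  w <- sqrt(pmax(1 - (dz[use] / hh)^2, 0))
  if (!length(w) || sum(w) == 0) { use <- which.min(abs(dz)); w <- 1 }
  lk <- sy$area_nm2 * w / (th * sum(w))
  list(sections = kAll[use], lengths = lk, azimuth = az0, bouton = bt)
}

paintSynapse <- function(vol, dims, originPx, gt, j) {
  cfg <- gt$config
  px <- cfg@pixelNM; th <- cfg@sectionThicknessNM
  plan <- synapseRibbonPlan(gt, j)
  bt <- plan$bouton
  id <- gt$synapses$object_id[j]
  for (m in seq_along(plan$sections)) {
    k <- plan$sections[m]
    zc <- (k + 0.5) * th
    f <- 1 - ((zc - bt$z_nm) / bt$semi_c_nm)^2
    if (f <= 0.02) next
    ae <- bt$semi_a_nm * sqrt(f)
    be <- bt$semi_b_nm * sqrt(f)
    pix <- ellipseArcPixels(bt$x_nm, bt$y_nm, ae, be, plan$azimuth,
                            plan$lengths[m], px)
    if (!nrow(pix)) next
    zi <- k - originPx[3]
    if (zi < 0 || zi >= dims[3]) next
    xi <- pix[, 1] - originPx[1]
    yi <- pix[, 2] - originPx[2]
    ok <- xi >= 0 & xi < dims[1] & yi >= 0 & yi < dims[2]
    if (any(ok)) {
      lin <- 1 + xi[ok] + as.numeric(dims[1]) * (yi[ok] + as.numeric(dims[2]) * zi)
      cpp_set_voxels(vol, lin, id)
    }
  }
  invisible(NULL)
}

# Pixels (0-based x,y) of an arc of given length centred at `azimuth`
# on the ellipse (cx, cy, ae, be), thickened by a second shell just
# outside the membrane.
ellipseArcPixels <- function(cx, cy, ae, be, azimuth, arcLen, px) {
  tt <- seq(0, 2 * pi, length.out = 720)
  ex <- ae * cos(tt); ey <- be * sin(tt)
  seg <- sqrt(diff(ex)^2 + diff(ey)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  # the measured length of an n-pixel trace is n * px (path + end
  # caps), so the painted arc spans arcLen - px for a footprint whose
  # physical extent matches the target length
  arcLen <- max(min(arcLen, 0.9 * total) - px, 0.5 * px)
  # arc-length position of the azimuth
  iAz <- which.min(abs(((tt - azimuth + pi) %% (2 * pi)) - pi))
  s0 <- cum[iAz]
  lo <- (s0 - arcLen / 2) %% total
  hi <- (s0 + arcLen / 2) %% total
  inArc <- if (lo <= hi) cum >= lo & cum <= hi else cum >= lo | cum <= hi
  if (!any(inArc)) return(matrix(integer(0), 0, 2))
  sel <- which(inArc)
  scale <- 1 + 0.6 * px / sqrt(ae * be)   # just outside the membrane
  xs <- cx + scale * ex[sel]
  ys <- cy + scale * ey[sel]
  unique(cbind(floor(xs / px), floor(ys / px)))
}

#' Rasterize sampled complexes into label volumes
#'
#' Paints each bouton as an ellipsoid, each mitochondrion as a bent
#' tube or solid torus fully inside its bouton, and each synapse as a
#' 1-2 voxel thick ribbon straddling the bouton surface, into three
#' 16-bit-ready integer label volumes (one per channel). Deterministic
#' given the ground-truth table.
#'
#' @param gt ground truth from \code{\link{sampleComplexes}} (geometry
#'   is realized on the fly if not already present).
#' @return list of three \linkS4class{LabelVolume}s (\code{boutons},
#'   \code{mitochondria}, \code{synapses}) plus the updated ground
#'   truth table \code{gt}.
#' @examples
#' gt <- sampleComplexes(regimeConfig("YA", seed = 1, nBoutons = 6L,
#'                       volumeDims = c(400L, 300L, 15L)))
#' vols <- rasterizeComplexes(gt)
#' vols$boutons
#' @export
rasterizeComplexes <- function(gt) {
  cfg <- gt$config
  if (is.null(gt$mitochondria$realized_class))
    gt <- realizeMitoGeometry(gt)
  dims <- cfg@volumeDims
  mk <- function() {
    v <- integer(prod(dims)); dim(v) <- dims; v
  }
  bv <- mk(); mv <- mk(); sv <- mk()
  orig <- c(0, 0, 0)
  for (i in seq_len(nrow(gt$boutons)))
    paintBouton(bv, dims, orig, gt, i)
  for (j in seq_len(nrow(gt$mitochondria)))
    paintMito(mv, dims, orig, gt, j)
  for (j in seq_len(nrow(gt$synapses)))
    paintSynapse(sv, dims, orig, gt, j)
  px <- cfg@pixelNM; th <- cfg@sectionThicknessNM
  list(boutons = LabelVolume(bv, px, th, "bouton"),
       mitochondria = LabelVolume(mv, px, th, "mitochondrion"),
       synapses = LabelVolume(sv, px, th, "synapse"),
       gt = gt)
}

# Crop window (0-based origin + dims) for one object with margin.
objectCropWindow <- function(gt, what, idx, marginPx = 3L) {
  cfg <- gt$config
  px <- cfg@pixelNM; th <- cfg@sectionThicknessNM
  dims <- cfg@volumeDims
  if (what == "bouton") {
    bt <- gt$boutons[idx, ]
    lo <- c(bt$x_nm - bt$semi_a_nm, bt$y_nm - bt$semi_b_nm,
            bt$z_nm - bt$semi_c_nm)
    hi <- c(bt$x_nm + bt$semi_a_nm, bt$y_nm + bt$semi_b_nm,
            bt$z_nm + bt$semi_c_nm)
  } else if (what == "mito") {
    mt <- gt$mitochondria[idx, ]
    bt <- gt$boutons[match(mt$bouton_id, gt$boutons$bouton_id), ]
    # axis-aware bounds: chord along the longer lateral axis, sagitta
    # plus sibling offset across it
    uExt <- if (mt$realized_class == "toroidal") mt$R_nm + mt$r_nm
            else mt$len_nm / 2 + mt$r_nm
    sag <- if (mt$realized_class == "toroidal") mt$R_nm
           else mt$len_nm * (mt$theta_deg * pi / 180) / 8
    vExt <- mt$r_nm + abs(mt$v_offset_nm) + sag
    uIsX <- bt$semi_a_nm >= bt$semi_b_nm
    ex <- if (uIsX) c(uExt, vExt) else c(vExt, uExt)
    lo <- c(bt$x_nm - ex[1], bt$y_nm - ex[2], bt$z_nm - mt$r_nm)
    hi <- c(bt$x_nm + ex[1], bt$y_nm + ex[2], bt$z_nm + mt$r_nm)
  } else {
    sy <- gt$synapses[idx, ]
    bt <- gt$boutons[match(sy$bouton_id, gt$boutons$bouton_id), ]
    m <- 1.15
    lo <- c(bt$x_nm - m * bt$semi_a_nm, bt$y_nm - m * bt$semi_b_nm,
            bt$z_nm - bt$semi_c_nm)
    hi <- c(bt$x_nm + m * bt$semi_a_nm, bt$y_nm + m * bt$semi_b_nm,
            bt$z_nm + bt$semi_c_nm)
  }
  sp <- c(px, px, th)
  o <- pmax(floor(lo / sp) - marginPx, 0)
  e <- pmin(ceiling(hi / sp) + marginPx, dims - 1)
  list(origin = as.integer(o), dims = as.integer(e - o + 1))
}

# Paint a single object into its own crop; returns list(vol, origin,
# dims) with `vol` an integer array.
paintObjectCrop <- function(gt, what, idx) {
  w <- objectCropWindow(gt, what, idx)
  v <- integer(prod(w$dims)); dim(v) <- w$dims
  if (what == "bouton") paintBouton(v, w$dims, w$origin, gt, idx)
  else if (what == "mito") paintMito(v, w$dims, w$origin, gt, idx)
  else paintSynapse(v, w$dims, w$origin, gt, idx)
  list(vol = v, origin = w$origin, dims = w$dims)
}
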