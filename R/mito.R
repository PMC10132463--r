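#' Skeletonize a mitochondrion mask
#'
#' For non-toroidal objects the skeleton is the longest geodesic path
#' through the voxel graph, pulled onto the medial axis by weighting
#' steps with the inverse squared distance transform; for toroidal
#' objects it is the principal cycle through the medial (high distance
#' transform) voxels, ordered around the hole. Coordinates are voxel
#' centres in nm.
#'
#' @param mask logical 3D array (single connected object).
#' @param spacing numeric(3): voxel spacing (nm).
#' @param cycle TRUE to extract the principal cycle of a toroidal
#'   object instead of the longest path.
#' @return numeric matrix (n x 3) of nm coordinates; for cycles the
#'   first point is repeated at the end and \code{attr(,"closed")} is
#'   TRUE.
#' @export
skeletonizeMito <- function(mask, spacing, cycle = FALSE) {
  stopifnot(length(dim(mask)) == 3)
  d <- dim(mask)
  lab <- cpp_label_components(as.vector(mask), d, 26L)
  if (attr(lab, "n") != 1L)
    stop("mask must contain exactly one connected object (found ",
         attr(lab, "n"), ")")
  dt <- cpp_edt(as.vector(mask), d, spacing)
  if (max(dt) <= 1.05 * min(spacing[1:2]))
    stop("degenerate skeleton: object is thinner than 2 voxels ",
         "everywhere")
  if (cycle) return(ringSkeleton(mask, dt, spacing))
  gp <- cpp_geodesic_path(as.vector(mask), d, spacing, dt, TRUE)
  poly <- (gp$path + 0.5) %*% diag(spacing)
  smoothPolyline(poly, 2L)
}

# Principal cycle of a toroidal mask: medial voxels projected on their
# PCA plane and ordered by angle about the centroid.
ringSkeleton <- function(mask, dt, spacing) {
  d <- dim(mask)
  sel <- which(mask & dt >= 0.6 * max(dt))
  co <- (arrayInd(sel, d) - 0.5) %*% diag(spacing)
  ctr <- colMeans(co)
  cc <- sweep(co, 2, ctr)
  pc <- svd(cc, nu = 0, nv = 3)$v
  uv <- cc %*% pc[, 1:2]
  ang <- atan2(uv[, 2], uv[, 1])
  ord <- order(ang)
  ring <- co[ord, , drop = FALSE]
  out <- rbind(ring, ring[1, ])
  attr(out, "closed") <- TRUE
  out
}

smoothPolyline <- function(poly, halfWindow = 2L) {
  n <- nrow(poly)
  if (n < 3 || halfWindow < 1) return(poly)
  out <- poly
  for (i in seq_len(n)) {
    lo <- max(1, i - halfWindow); hi <- min(n, i + halfWindow)
    out[i, ] <- colMeans(poly[lo:hi, , drop = FALSE])
  }
  out
}

#' Maximal bend angle of a skeleton polyline
#'
#' The polyline is resampled at uniform arc length and tangent
#' directions are averaged over sliding windows of \code{windowNM};
#' the bend is the largest angle between any two window-averaged
#' tangents, i.e. the total tangent rotation that the object sustains
#' (a circular arc subtending 120 degrees measures ~120; a right-angle
#' elbow measures 90; a straight rod measures 0).
#'
#' @param polyline numeric matrix (n x 3 or n x 2) in nm.
#' @param windowNM tangent-averaging window (nm).
#' @return bend angle in degrees, in [0, 180].
#' @export
maxBendAngle <- function(polyline, windowNM) {
  polyline <- as.matrix(polyline)
  if (ncol(polyline) == 2) polyline <- cbind(polyline, 0)
  if (nrow(polyline) < 3) return(0)
  if (windowNM <= 0) stop("windowNM must be > 0")
  seg <- sqrt(rowSums(diff(polyline)^2))
  total <- sum(seg)
  if (total <= 0) return(0)
  if (total < 2 * windowNM) {
    warning("polyline shorter than twice the window; ",
            "bend measured over the whole polyline")
    windowNM <- total / 2
  }
  step <- max(min(windowNM / 4, total / 12), total / 400)
  s <- c(0, cumsum(seg))
  grid <- seq(0, total, by = step)
  rp <- apply(polyline, 2, function(cc) stats::approx(s, cc, grid)$y)
  w <- max(1L, round(windowNM / step))
  m <- nrow(rp)
  if (m - w < 2) w <- max(1L, m - 2L)
  tang <- rp[(1 + w):m, , drop = FALSE] - rp[1:(m - w), , drop = FALSE]
  len <- sqrt(rowSums(tang^2))
  keep <- len > 0
  tang <- tang[keep, , drop = FALSE] / len[keep]
  cosMin <- min(tcrossprod(tang))
  acos(max(-1, min(1, cosMin))) * 180 / pi
}

#' Detect a through-hole from surface topology
#'
#' Genus from the Euler characteristic of the closed mesh:
#' g = (2 - chi) / 2; a through-hole exists when g >= 1 (chi <= 0).
#'
#' @param mesh a watertight \linkS4class{SurfaceMesh}.
#' @return TRUE/FALSE.
#' @export
detectThroughHole <- function(mesh) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (!mesh@closed)
    stop("through-hole detection requires a watertight mesh; ",
         "truncated objects are classified from the skeleton instead")
  eulerCharacteristic(mesh) <= 0
}

#' Classify mitochondrial morphology
#'
#' Straight / curved / toroidal per the 90-degree bend rule: toroidal
#' if the closed surface has a through-hole (topology takes precedence
#' over bend); otherwise curved when the maximal skeleton bend is >= 90
#' degrees, else straight. The bend window is \code{windowFactor}
#' times the mean local radius (distance transform along the
#' skeleton). Truncated objects are classified from the skeleton only
#' (never toroidal) and flagged uncertain.
#'
#' @param mask logical 3D array of one mitochondrion.
#' @param spacing voxel spacing (nm).
#' @param windowFactor bend window as a multiple of the local radius.
#' @param truncated was the object cut by the stack boundary?
#' @return list: \code{morphClass}, \code{maxBendDeg},
#'   \code{hasThroughHole}, \code{uncertain}, \code{skeleton}.
#' @export
classifyMito <- function(mask, spacing, windowFactor = 3,
                         truncated = FALSE) {
  mask <- array(as.logical(mask), dim = dim(mask))
  hole <- FALSE
  if (!truncated) {
    mesh <- meshFromMask(array(as.numeric(mask), dim = dim(mask)),
                         spacing = spacing, sigma = 0.8)
    hole <- detectThroughHole(mesh)
  }
  if (hole) {
    sk <- skeletonizeMito(mask, spacing, cycle = TRUE)
    return(list(morphClass = "toroidal", maxBendDeg = NA_real_,
                hasThroughHole = TRUE, uncertain = FALSE,
                skeleton = sk))
  }
  dt <- cpp_edt(as.vector(mask), dim(mask), spacing)
  rTube <- max(dt)
  sk <- slicedCenterline(mask, spacing, trim = 0.8 * rTube)
  skLen <- sum(sqrt(rowSums(diff(sk)^2)))
  if (skLen <= 0 || nrow(sk) < 3)
    return(list(morphClass = "straight", maxBendDeg = 0,
                hasThroughHole = FALSE, uncertain = truncated,
                skeleton = sk))
  # total tangent rotation assuming near-uniform curvature: fit a
  # circle to the centreline (curvature kappa = 1/R) and multiply by
  # the estimated full centreline length. The binned polyline loses
  # half a bin at each end and the cap trim removes a short arc beyond
  # each cut, both restored geometrically (a cap's axial footprint is
  # rTube * cos(theta/2)); solved with two fixed-point passes. This is
  # exact for arc-bent tubes and free of the window-length bias of
  # local tangent estimates (the windowed estimate remains available
  # through maxBendAngle for arbitrary polylines).
  R <- sagittaRadius(sk)
  bend <- 0
  if (is.finite(R) && R > 0 && R < 100 * skLen) {
    nb <- nrow(sk)
    th <- skLen / R
    for (it in 1:3) {
      ch <- max(cos(th / 2), 0.35)
      trimArc <- 2 * max(0.8 * rTube - rTube * ch, 0) / ch
      lEst <- skLen * (1 + 1 / (nb - 1)) + trimArc
      th <- min(lEst / R, pi)
    }
    bend <- th * 180 / pi
  }
  list(morphClass = if (bend >= 90) "curved" else "straight",
       maxBendDeg = bend, hasThroughHole = FALSE,
       uncertain = truncated, skeleton = sk)
}

# Bend radius from a least-squares parabola v = a + b u + c u^2 in the
# polyline's principal frame (u along PC1, v along PC2):
# R = (1 + b^2)^(3/2) / (2|c|). All points enter the fit, so residual
# pixel-grid zigzag averages out instead of being mistaken for
# curvature (as an algebraic circle fit is prone to), and the chord
# endpoints carry no special weight.
sagittaRadius <- function(sk) {
  ctr <- colMeans(sk)
  cc <- sweep(sk, 2, ctr)
  pc <- svd(cc, nu = 0, nv = min(3, ncol(sk)))$v
  u <- as.vector(cc %*% pc[, 1])
  v <- as.vector(cc %*% pc[, 2])
  if (length(u) < 4 || stats::sd(u) <= 0) return(Inf)
  fit <- tryCatch(stats::lm.fit(cbind(1, u, u^2), v),
                  error = function(e) NULL)
  if (is.null(fit)) return(Inf)
  a2 <- fit$coefficients[3]
  if (!is.finite(a2) || abs(a2) < 1e-12) return(Inf)
  # a quadratic fitted to a wide circular arc reports more than the
  # apex curvature 1/(2R); invert the exact relation numerically by
  # fitting the same quadratic to a dense model arc
  U <- max(abs(u - mean(range(u))))
  quadOfArc <- function(R) {
    uu <- seq(-U, U, length.out = 101)
    vv <- R - sqrt(pmax(R^2 - uu^2, 0))
    stats::lm.fit(cbind(1, uu, uu^2), vv)$coefficients[3]
  }
  target <- abs(a2)
  if (target <= quadOfArc(1e7 * U) * 1.0001) return(1e7 * U)
  lo <- U * 1.0001
  if (target >= quadOfArc(lo)) return(lo)
  root <- tryCatch(
    stats::uniroot(function(R) quadOfArc(R) - target, c(lo, 1e7 * U),
                   tol = 1e-3 * U)$root,
    error = function(e) (1 + fit$coefficients[2]^2)^1.5 / (2 * target))
  root
}


# Centreline of a tubular mask by slicing: voxels are binned along the
# cloud's principal axis and the per-bin centroids (all three
# coordinates, so the tube radius cancels and the bend plane need not
# be known) form the polyline. Robust for tubes bent up to ~150
# degrees (the centreline stays monotone along the chord axis).
slicedCenterline <- function(mask, spacing, nBins = 24L, trim = 0) {
  d <- dim(mask)
  co <- (arrayInd(which(mask), d) - 0.5) %*% diag(spacing)
  ctr <- colMeans(co)
  cc <- sweep(co, 2, ctr)
  pc <- svd(cc, nu = 0, nv = 3)$v
  u <- as.vector(cc %*% pc[, 1])
  rng <- range(u)
  uExtentFull <- diff(rng)
  if (trim > 0 && diff(rng) > 3 * trim) {
    # drop the spherical end caps, whose sliced centroids flatten the
    # centreline and dilute the measured turn
    keepU <- u >= rng[1] + trim & u <= rng[2] - trim
    if (sum(keepU) >= 5) {
      co <- co[keepU, , drop = FALSE]
      u <- u[keepU]
      rng <- range(u)
    }
  }
  # bins at least 2.5 pixels wide, else per-bin centroids alias
  # against the pixel grid and zigzag
  nb <- max(5L, min(nBins,
                    floor(diff(rng) / (2.5 * min(spacing)))))
  br <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = nb + 1)
  bin <- cut(u, br, labels = FALSE)
  pts <- do.call(rbind, lapply(split(seq_along(bin), bin), function(ix)
    colMeans(co[ix, , drop = FALSE])))
  out <- pts[order(tapply(u, bin, mean)), , drop = FALSE]
  out <- smoothPolyline(out, 1L)
  attr(out, "uExtentFull") <- uExtentFull
  out
}
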