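#' Regime presets and configuration for the synthetic-neuropil generator
#'
#' \code{regimeConfig} builds a \linkS4class{RegimeConfig} from the
#' preset table shipped in \code{inst/extdata/regimes.yaml} ("YA",
#' "AU", "AI") or from a custom preset file with the same layout.
#' Individual fields can be overridden through \code{...}.
#'
#' @param name regime name ("YA", "AU" or "AI"), or "custom" when all
#'   fields are supplied through \code{...}.
#' @param seed integer RNG seed stored in the config.
#' @param presetFile optional YAML preset file; defaults to the one
#'   shipped with the package.
#' @param ... field overrides, using slot names of
#'   \linkS4class{RegimeConfig} (e.g. \code{nBoutons = 40},
#'   \code{rhoMB = 0}).
#' @return A validated \linkS4class{RegimeConfig}.
#' @examples
#' regimeConfig("AU", seed = 1)
#' regimeConfig("YA", seed = 1, nBoutons = 12L, rhoMB = 0)
#' @export
regimeConfig <- function(name = c("YA", "AU", "AI", "custom"), seed = 1L,
                         presetFile = NULL, ...) {
  name <- match.arg(name)
  if (is.null(presetFile))
    presetFile <- system.file("extdata", "regimes.yaml",
                              package = "neuropilMorph")
  y <- yaml::read_yaml(presetFile)
  cm <- y$common
  base <- if (name == "custom") "YA" else name
  if (is.null(y$regimes[[base]]))
    stop("unknown regime '", base, "'; valid names: ",
         paste(names(y$regimes), collapse = ", "))
  rg <- y$regimes[[base]]
  args <- list(
    name = name,
    nBoutons = as.integer(cm$n_boutons),
    boutonLogMean = rg$bouton_log_mean, boutonLogSd = cm$bouton_log_sd,
    synapseLogMean = rg$synapse_log_mean, synapseLogSd = cm$synapse_log_sd,
    mitoLogMean = rg$mito_log_mean, mitoLogSd = cm$mito_log_sd,
    rhoSB = rg$rho_sb, rhoMB = rg$rho_mb,
    mitoOccupancy = cm$mito_occupancy, occupancySlope = cm$occupancy_slope,
    morphMix = unlist(cm$morph_mix),
    densityScale = rg$density_scale,
    sectionThicknessNM = cm$section_thickness_nm, pixelNM = cm$pixel_nm,
    volumeDims = as.integer(c(cm$volume_xy_px, rg$n_sections)),
    subthresholdFrac = cm$subthreshold_frac,
    extraSynapseRate = cm$extra_synapse_rate,
    extraMitoRate = cm$extra_mito_rate,
    seed = as.integer(seed))
  over <- list(...)
  bad <- setdiff(names(over), names(args))
  if (length(bad)) stop("unknown RegimeConfig fields: ",
                        paste(bad, collapse = ", "))
  args[names(over)] <- over
  args$nBoutons <- as.integer(args$nBoutons)
  args$volumeDims <- as.integer(args$volumeDims)
  args$seed <- as.integer(args$seed)
  do.call(new, c(list(Class = "RegimeConfig"), args))
}

#' Available regime preset names
#' @param presetFile optional custom preset YAML.
#' @return character vector of preset names.
#' @export
regimeNames <- function(presetFile = NULL) {
  if (is.null(presetFile))
    presetFile <- system.file("extdata", "regimes.yaml",
                              package = "neuropilMorph")
  names(yaml::read_yaml(presetFile)$regimes)
}

# Raw-scale Pearson correlation of two lognormals joined by a Gaussian
# copula with latent correlation rho on the log scale.
lognormalRawCor <- function(rho, s1, s2) {
  (exp(rho * s1 * s2) - 1) /
    sqrt((exp(s1^2) - 1) * (exp(s2^2) - 1))
}

# Latent log-scale correlation that yields the requested raw-scale
# Pearson correlation between two lognormals (inverse of the above).
calibrateLatentRho <- function(rRaw, s1, s2, pair = "correlation") {
  arg <- 1 + rRaw * sqrt((exp(s1^2) - 1) * (exp(s2^2) - 1))
  if (arg <= 0)
    stop("requested raw-scale correlation for the ", pair,
         " pair is infeasible for these lognormal spreads")
  rho <- log(arg) / (s1 * s2)
  if (abs(rho) > 1 + 1e-12)
    stop("requested raw-scale correlation for the ", pair,
         " pair is infeasible (|latent rho| = ", signif(abs(rho), 4),
         " > 1)")
  min(1, max(-1, rho))
}

#' Sample ground-truth synaptic complexes for one synthetic subject
#'
#' Draws \code{nBoutons} boutons with lognormal surface areas and, via
#' a trivariate Gaussian copula on log sizes, a summed synapse contact
#' area and (for occupied boutons) a summed mitochondrion surface area
#' whose \emph{raw-scale} Pearson correlations with bouton area equal
#' \code{rhoSB} and \code{rhoMB}. The synapse-mitochondrion latent
#' correlation is set to the product of the two latent correlations
#' (conditional independence given bouton size), which keeps the latent
#' matrix positive semi-definite for any feasible pair. Occupancy is
#' Bernoulli with a logistic size dependence so mitochondria-bearing
#' boutons are larger on average; summed areas are split over 1-3
#' synapses and 1-3 mitochondria; morphology classes are drawn from
#' \code{morphMix}. Spatial placements put every bouton's lateral
#' footprint inside the central analysis region, crossing the reference
#' section, without bouton-bouton overlap.
#'
#' @param config a \linkS4class{RegimeConfig}.
#' @param spatial draw spatial placements (needed for rasterization);
#'   set FALSE for purely statistical replicates at large n, where
#'   only sizes and assignments are needed (coordinates come back NA).
#' @return A list with data.frames \code{boutons}, \code{synapses},
#'   \code{mitochondria} (the ground-truth table; areas nm2, volumes
#'   nm3, coordinates nm) — see the package vignette for the column
#'   dictionary.
#' @examples
#' gt <- sampleComplexes(regimeConfig("YA", seed = 3, nBoutons = 8L))
#' nrow(gt$boutons)
#' @export
sampleComplexes <- function(config, spatial = TRUE) {
  stopifnot(is(config, "RegimeConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nBoutons
  sB <- config@boutonLogSd; sS <- config@synapseLogSd
  sM <- config@mitoLogSd
  rSB <- calibrateLatentRho(config@rhoSB, sB, sS, "synapse-bouton")
  rMB <- calibrateLatentRho(config@rhoMB, sB, sM, "mitochondrion-bouton")
  # the mito-bouton correlation is evaluated among occupied boutons;
  # size-dependent occupancy restricts the bouton-size range there, so
  # the generating correlation is pre-inflated by the classic
  # restriction-of-range relation with u = Var(z | occupied)
  if (config@occupancySlope != 0 && config@mitoOccupancy > 0 &&
      config@mitoOccupancy < 1 && abs(rMB) < 1) {
    u <- occupiedVarianceRatio(config@mitoOccupancy,
                               config@occupancySlope)
    rMB <- min(1, max(-1, rMB / sqrt(u + rMB^2 * (1 - u))))
  }
  # latent correlation matrix (bouton, synapse, mito)
  C <- rbind(c(1, rSB, rMB),
             c(rSB, 1, rSB * rMB),
             c(rMB, rSB * rMB, 1))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("latent correlation matrix is not positive semi-definite; ",
         "the synapse-bouton / mitochondrion-bouton pair is jointly ",
         "infeasible")
  L <- chol(pmax2(C))
  zs <- matrix(stats::rnorm(3 * n), n, 3) %*% L
  logB <- config@boutonLogMean + sB * zs[, 1]
  logS <- config@synapseLogMean + sS * zs[, 2]
  logM <- config@mitoLogMean + sM * zs[, 3]
  areaB <- exp(logB); areaS <- exp(logS); areaM <- exp(logM)

  # occupancy: logistic in standardized log bouton size, intercept
  # solved so the marginal occupancy matches mitoOccupancy
  zB <- (logB - config@boutonLogMean) / sB
  slope <- config@occupancySlope
  a0 <- occupancyIntercept(config@mitoOccupancy, slope)
  pOcc <- stats::plogis(a0 + slope * zB)
  hasMito <- stats::runif(n) < pOcc

  # vesicle counts: >= 3 for qualifying boutons, a configurable
  # fraction below threshold to exercise the inclusion rule
  sub <- stats::runif(n) < config@subthresholdFrac
  vesicles <- 3L + stats::rpois(n, lambda = pmax(4 + 2 * zB, 0.5))
  vesicles[sub] <- sample(0:2, sum(sub), replace = TRUE)

  nSyn <- 1L + pmin(stats::rpois(n, config@extraSynapseRate), 3L)
  nMito <- ifelse(hasMito, 1L + pmin(stats::rpois(n, config@extraMitoRate),
                                     2L), 0L)

  place <- placeBoutons(areaB, config, positions = spatial)
  boutons <- data.frame(
    bouton_id = seq_len(n),
    animal_id = config@name,
    roi_id = NA_character_,
    area_nm2 = areaB,
    volume_nm3 = ellipsoidVolume(place$a, place$b, place$c),
    semi_a_nm = place$a, semi_b_nm = place$b, semi_c_nm = place$c,
    x_nm = place$x, y_nm = place$y, z_nm = place$z,
    vesicle_count = vesicles,
    has_mito = hasMito,
    n_mito = nMito,
    n_synapse = nSyn,
    synapse_area_sum_nm2 = areaS,
    mito_area_sum_nm2 = ifelse(hasMito, areaM, 0),
    stringsAsFactors = FALSE)

  synapses <- splitAreas(boutons$bouton_id, nSyn, areaS, "synapse")
  mitos <- splitAreas(boutons$bouton_id[hasMito], nMito[hasMito],
                      areaM[hasMito], "mito")
  if (nrow(mitos)) {
    classes <- c("straight", "curved", "toroidal")
    mitos$morph_class <- sample(classes, nrow(mitos), replace = TRUE,
                                prob = config@morphMix[classes])
    mitos$bend_deg <- ifelse(
      mitos$morph_class == "curved", stats::runif(nrow(mitos), 105, 150),
      stats::runif(nrow(mitos), 0, 40))
  } else {
    mitos$morph_class <- character(0)
    mitos$bend_deg <- numeric(0)
  }
  list(boutons = boutons, synapses = synapses, mitochondria = mitos,
       config = config)
}

# clip tiny negative eigenvalue noise before Cholesky
pmax2 <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  v <- pmax(e$values, 1e-12)
  M <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(M))
  M / tcrossprod(d)
}

# Var(Z | occupied) for Z ~ N(0,1) under the logistic occupancy model
occupiedVarianceRatio <- function(target, slope) {
  a0 <- occupancyIntercept(target, slope)
  z <- seq(-6, 6, length.out = 481)
  w <- stats::plogis(a0 + slope * z) * stats::dnorm(z)
  w <- w / sum(w)
  mu <- sum(w * z)
  sum(w * (z - mu)^2)
}

# intercept a0 with E[plogis(a0 + slope*Z)] = target for Z ~ N(0,1)
occupancyIntercept <- function(target, slope) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(a) {
    z <- seq(-6, 6, length.out = 241)
    w <- stats::dnorm(z)
    sum(stats::plogis(a + slope * z) * w) / sum(w) - target
  }
  stats::uniroot(f, c(-20, 20))$root
}

# split per-bouton summed areas across k objects with Dirichlet(4)
# weights; returns one row per child object
splitAreas <- function(boutonIds, k, total, prefix) {
  rows <- data.frame(object_id = integer(0), bouton_id = integer(0),
                     area_nm2 = numeric(0))
  if (!length(boutonIds)) return(rows)
  oid <- 0L
  out <- vector("list", length(boutonIds))
  for (i in seq_along(boutonIds)) {
    ki <- k[i]
    w <- stats::rgamma(ki, shape = 4)
    w <- w / sum(w)
    out[[i]] <- data.frame(object_id = oid + seq_len(ki),
                           bouton_id = boutonIds[i],
                           area_nm2 = total[i] * w)
    oid <- oid + ki
  }
  do.call(rbind, out)
}

#' Central analysis region of a synthetic volume
#'
#' The standard analysis region is 18 x 9 um centred on the stack; for
#' volumes too small to hold it the region shrinks to the central 90%
#' so reduced test volumes remain usable. Returned in nm.
#'
#' @param config a \linkS4class{RegimeConfig}.
#' @return list with \code{origin} (x, y nm) and \code{dims}
#'   (width, height nm).
#' @export
analysisRegion <- function(config) {
  volXY <- config@volumeDims[1:2] * config@pixelNM
  dims <- pmin(c(18e3, 9e3), 0.9 * volXY)
  list(origin = (volXY - dims) / 2, dims = dims)
}

# Deterministic bouton placement: lateral footprints inside the central
# 18 x 9 um analysis region, centres jittered around the reference
# section so each bouton crosses it; bounding-sphere rejection keeps
# boutons disjoint.
placeBoutons <- function(areaB, config, maxTries = 8000L,
                         positions = TRUE) {
  n <- length(areaB)
  px <- config@pixelNM; th <- config@sectionThicknessNM
  dims <- config@volumeDims
  reg <- analysisRegion(config)
  regionDims <- reg$dims
  region0 <- reg$origin
  refZ <- (floor(dims[3] / 2) + 0.5) * th  # middle section centre
  # shape: semi-axes s*(1, q1, q2) with area matched to areaB
  q1 <- stats::runif(n, 0.75, 1.25)
  q2 <- stats::runif(n, 0.75, 1.25)
  s <- vapply(seq_len(n), function(i)
    sqrt(areaB[i] / ellipsoidArea(1, q1[i], q2[i])), numeric(1))
  a <- s; b <- s * q1; cc <- s * q2
  if (!positions)
    return(list(x = rep(NA_real_, n), y = rep(NA_real_, n),
                z = rep(NA_real_, n), a = a, b = b, c = cc))
  x <- y <- z <- numeric(n)
  rBound <- pmax(a, b)
  ord <- order(rBound, decreasing = TRUE)  # place big ones first
  for (k in seq_along(ord)) {
    i <- ord[k]
    placed <- ord[seq_len(k - 1L)]
    if (2 * a[i] > regionDims[1] || 2 * b[i] > regionDims[2])
      stop("bouton ", i, " does not fit the analysis region; ",
           "enlarge volumeDims or reduce bouton sizes")
    ok <- FALSE
    for (tr in seq_len(maxTries)) {
      xi <- stats::runif(1, region0[1] + a[i], region0[1] + regionDims[1] - a[i])
      yi <- stats::runif(1, region0[2] + b[i], region0[2] + regionDims[2] - b[i])
      zi <- refZ + stats::runif(1, -0.3, 0.3) * cc[i]
      if (!length(placed) ||
          all((x[placed] - xi)^2 + (y[placed] - yi)^2 >
              (pmax(rBound[placed], cc[placed]) + max(a[i], b[i], cc[i]))^2)) {
        x[i] <- xi; y[i] <- yi; z[i] <- zi; ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("failed to place bouton ", i, " without overlap after ",
           maxTries, " tries; the volume is too small for the ",
           "requested bouton count/size (need a larger analysis region ",
           "or fewer boutons)")
  }
  list(x = x, y = y, z = z, a = a, b = b, c = cc)
}
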