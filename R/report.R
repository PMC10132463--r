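#' Build the per-bouton complex table from morphometry rows
#'
#' Aggregates a morphometry table (one row per object) into one row
#' per bouton: measured bouton surface area and volume, summed synapse
#' contact area, mitochondrion presence/count and summed area, and the
#' synapse:bouton area ratio.
#'
#' @param morpho morphometry data.frame from
#'   \code{\link{measureVolumes}} / the pipeline (must contain bouton
#'   rows and have \code{bouton_id} populated).
#' @return data.frame (the complex table), one row per bouton.
#' @export
buildComplexTable <- function(morpho) {
  b <- morpho[morpho$channel == "bouton", , drop = FALSE]
  if (!nrow(b)) stop("no bouton rows in morphometry table")
  s <- morpho[morpho$channel == "synapse", , drop = FALSE]
  m <- morpho[morpho$channel == "mitochondrion", , drop = FALSE]
  sumBy <- function(df, col) {
    if (!nrow(df)) return(numeric(0))
    tapply(df[[col]], df$bouton_id, sum)
  }
  cntBy <- function(df) {
    if (!nrow(df)) return(integer(0))
    table(df$bouton_id)
  }
  synSum <- sumBy(s, "synapse_area_nm2")
  synCnt <- cntBy(s)
  mitSum <- sumBy(m, "surface_area_nm2")
  mitCnt <- cntBy(m)
  pick <- function(tab, ids) {
    v <- rep(0, length(ids))
    i <- match(as.character(ids), names(tab))
    v[!is.na(i)] <- tab[i[!is.na(i)]]
    v
  }
  ct <- data.frame(
    animal_id = b$animal_id, roi_id = b$roi_id,
    bouton_id = b$bouton_id,
    bouton_area_nm2 = b$surface_area_nm2,
    bouton_volume_nm3 = b$volume_nm3,
    synapse_area_sum_nm2 = pick(synSum, b$bouton_id),
    n_synapse = as.integer(pick(synCnt, b$bouton_id)),
    mito_area_sum_nm2 = pick(mitSum, b$bouton_id),
    n_mito = as.integer(pick(mitCnt, b$bouton_id)),
    truncated_by_stack = b$truncated_by_stack,
    stringsAsFactors = FALSE)
  ct$has_mito <- ct$n_mito >= 1L
  ct$ratio <- ct$synapse_area_sum_nm2 / ct$bouton_area_nm2
  ct
}

#' Full ultrastructural-size-principle analysis
#'
#' Emits, per animal and stratum (all boutons / with mitochondria /
#' without mitochondria): mean sizes and the synapse:bouton ratio;
#' Pearson correlations (with Model II regression slopes) of summed
#' synapse area vs bouton area and of summed mitochondrion area vs
#' bouton area; all pairwise Fisher-Z comparisons of those
#' correlations; one-way (ROI repeated-measures) and two-way
#' (mitochondria presence x animal) ANOVA/Tukey tables; mitochondria
#' counts and the morphology mix.
#'
#' @param complexTable from \code{\link{buildComplexTable}}.
#' @param mitoTable optional per-mitochondrion data.frame (columns
#'   \code{animal_id}, \code{roi_id}, \code{surface_area_nm2},
#'   \code{morph_class}) for the morphology analyses.
#' @param logScale correlate log-transformed areas instead of raw
#'   (default FALSE; the size principle is stated on raw sizes).
#' @param minN strata below this n omit the correlation with a logged
#'   reason (default 4).
#' @return list of data.frames and test results; see Details in the
#'   vignette.
#' @export
sizePrincipleReport <- function(complexTable, mitoTable = NULL,
                                logScale = FALSE, minN = 4L) {
  ct <- complexTable
  if (length(unique(ct$animal_id)) < 2)
    stop("need at least 2 animals/groups")
  tf <- if (logScale) log else identity
  animals <- sort(unique(ct$animal_id))
  strata <- c("all", "with_mito", "without_mito")
  pickStratum <- function(df, s)
    switch(s, all = df, with_mito = df[df$has_mito, , drop = FALSE],
           without_mito = df[!df$has_mito, , drop = FALSE])

  sizeSummary <- do.call(rbind, lapply(animals, function(a) {
    do.call(rbind, lapply(strata, function(s) {
      d <- pickStratum(ct[ct$animal_id == a, , drop = FALSE], s)
      data.frame(animal_id = a, stratum = s, n = nrow(d),
                 bouton_area_nm2 = mean(d$bouton_area_nm2),
                 synapse_area_sum_nm2 = mean(d$synapse_area_sum_nm2),
                 mito_area_sum_nm2 = mean(d$mito_area_sum_nm2),
                 ratio = mean(d$ratio),
                 mito_occupancy = mean(d$has_mito),
                 mito_per_bouton = mean(d$n_mito))
    }))
  }))

  notes <- character()
  corRows <- list()
  for (a in animals) for (s in strata) {
    d <- pickStratum(ct[ct$animal_id == a, , drop = FALSE], s)
    for (fam in c("synapse_bouton", "mito_bouton")) {
      if (fam == "mito_bouton") {
        d2 <- d[d$has_mito, , drop = FALSE]
        yv <- d2$mito_area_sum_nm2
      } else {
        d2 <- d
        yv <- d2$synapse_area_sum_nm2
      }
      xv <- d2$bouton_area_nm2
      ok <- length(xv) >= minN && stats::sd(xv) > 0 &&
        length(unique(yv)) > 1
      if (!ok) {
        notes <- c(notes, sprintf(
          "correlation omitted: %s / %s / %s (n = %d < %d or constant)",
          a, s, fam, length(xv), minN))
        next
      }
      pc <- pearsonCorrelation(tf(xv), tf(yv))
      m2 <- model2Regression(tf(xv), tf(yv))
      corRows[[length(corRows) + 1L]] <- data.frame(
        animal_id = a, stratum = s, family = fam, n = pc$n,
        r = pc$r, p = pc$p, rma_slope = m2$slope,
        rma_intercept = m2$intercept)
    }
  }
  correlations <- do.call(rbind, corRows)

  fisherRows <- list()
  for (fam in c("synapse_bouton", "mito_bouton")) {
    cc <- correlations[correlations$family == fam &
                         correlations$stratum == "all", , drop = FALSE]
    for (a1 in animals) for (a2 in animals) {
      i <- match(a1, cc$animal_id); j <- match(a2, cc$animal_id)
      if (is.na(i) || is.na(j)) next
      fz <- if (i == j) list(z = 0, p = 1)
        else fisherZCompare(cc$r[i], cc$n[i], cc$r[j], cc$n[j],
                            labels = c(a1, a2))
      fisherRows[[length(fisherRows) + 1L]] <- data.frame(
        family = fam, group1 = a1, group2 = a2,
        r1 = cc$r[i], n1 = cc$n[i], r2 = cc$r[j], n2 = cc$n[j],
        z = fz$z, p = fz$p)
    }
  }
  fisherZ <- do.call(rbind, fisherRows)

  anovas <- list()
  runSafely <- function(nm, expr) {
    res <- tryCatch(expr, error = function(e) {
      notes <<- c(notes, sprintf("ANOVA '%s' skipped: %s", nm,
                                 conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) anovas[[nm]] <<- res
  }
  hasRoi <- !all(is.na(ct$roi_id))
  roiArg <- if (hasRoi) "roi_id" else NULL
  runSafely("synapse_area_by_animal",
            groupTests(ct, "synapse_area_sum_nm2", "animal_id", roiArg))
  runSafely("bouton_area_by_animal",
            groupTests(ct, "bouton_area_nm2", "animal_id", roiArg))
  runSafely("ratio_by_animal",
            groupTests(ct, "ratio", "animal_id", roiArg))
  runSafely("occupancy_by_animal",
            groupTests(transform(ct, occ = as.numeric(has_mito)),
                       "occ", "animal_id", roiArg))
  runSafely("mito_count_by_animal",
            groupTests(ct, "n_mito", "animal_id", roiArg))
  runSafely("bouton_area_by_mito_x_animal",
            groupTests(transform(ct, mito = ifelse(has_mito, "with",
                                                   "without")),
                       "bouton_area_nm2", c("mito", "animal_id")))
  runSafely("synapse_area_by_mito_x_animal",
            groupTests(transform(ct, mito = ifelse(has_mito, "with",
                                                   "without")),
                       "synapse_area_sum_nm2", c("mito", "animal_id")))
  for (s in c("with_mito", "without_mito"))
    runSafely(paste0("ratio_by_animal_", s),
              groupTests(pickStratum(ct, s), "ratio", "animal_id",
                         roiArg))

  morphology <- NULL
  if (!is.null(mitoTable) && nrow(mitoTable) &&
      "morph_class" %in% names(mitoTable)) {
    morphology <- as.data.frame(
      table(animal_id = mitoTable$animal_id,
            morph_class = mitoTable$morph_class))
    names(morphology)[3] <- "n_mito"
    tot <- tapply(morphology$n_mito, morphology$animal_id, sum)
    morphology$fraction <- morphology$n_mito /
      as.numeric(tot[morphology$animal_id])
    runSafely("mito_size_by_animal",
              groupTests(mitoTable, "surface_area_nm2", "animal_id",
                         if (hasRoi && "roi_id" %in% names(mitoTable))
                           "roi_id" else NULL))
  }

  out <- list(sizeSummary = sizeSummary, correlations = correlations,
              fisherZ = fisherZ, anovas = anovas,
              morphology = morphology, notes = notes,
              logScale = logScale)
  class(out) <- c("sizePrincipleReport", class(out))
  out
}

#' @export
print.sizePrincipleReport <- function(x, ...) {
  cat("Ultrastructural size-principle report\n")
  cat("-------------------------------------\n")
  cc <- x$correlations[x$correlations$stratum == "all", ]
  for (i in seq_len(nrow(cc)))
    cat(sprintf("  %-4s %-14s r = %5.2f (n = %3d, p = %.2g)\n",
                cc$animal_id[i], cc$family[i], cc$r[i], cc$n[i],
                cc$p[i]))
  fz <- x$fisherZ[x$fisherZ$group1 < x$fisherZ$group2, ]
  if (nrow(fz)) {
    cat("Fisher-Z comparisons (all-bouton stratum):\n")
    for (i in seq_len(nrow(fz)))
      cat(sprintf("  %-14s %s vs %s: z = %5.2f, p = %.3g\n",
                  fz$family[i], fz$group1[i], fz$group2[i], fz$z[i],
                  fz$p[i]))
  }
  if (length(x$notes)) cat("Notes:\n ", paste(x$notes, collapse = "\n  "),
                           "\n")
  invisible(x)
}

# Write the report bundle as CSV tables + a plain-text summary.
writeReportBundle <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$sizeSummary,
                   file.path(dir, "size_summary.csv"), row.names = FALSE)
  utils::write.csv(report$correlations,
                   file.path(dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(report$fisherZ,
                   file.path(dir, "fisher_z.csv"), row.names = FALSE)
  if (!is.null(report$morphology))
    utils::write.csv(report$morphology,
                     file.path(dir, "morphology_mix.csv"),
                     row.names = FALSE)
  for (nm in names(report$anovas)) {
    utils::write.csv(report$anovas[[nm]]$anova,
                     file.path(dir, paste0("anova_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(report$anovas[[nm]]$tukey,
                     file.path(dir, paste0("tukey_", nm, ".csv")),
                     row.names = FALSE)
  }
  con <- file(file.path(dir, "report.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  invisible(dir)
}
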