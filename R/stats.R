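#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y numeric vectors (n >= 4, finite, non-constant).
#' @return list: \code{r}, \code{p}, \code{n}.
#' @examples
#' pearsonCorrelation(1:10, (1:10) + rnorm(10))
#' @export
pearsonCorrelation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs (have ", n, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)), two-sided
#' normal p. Antisymmetric under swapping groups; p = 1 when the
#' correlations and sample sizes coincide.
#'
#' @param r1,n1,r2,n2 correlations (|r| < 1) and sample sizes (>= 4).
#' @param labels optional character(2) group labels.
#' @return list: \code{z}, \code{p}, \code{r1}, \code{n1}, \code{r2},
#'   \code{n2}, \code{labels}.
#' @examples
#' fisherZCompare(0.80, 160, 0.61, 160)
#' @export
fisherZCompare <- function(r1, n1, r2, n2,
                           labels = c("group1", "group2")) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| = 1: Fisher transform is infinite")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both groups")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), r1 = r1, n1 = n1,
       r2 = r2, n2 = n2, labels = labels)
}

#' Model II (reduced major axis) regression
#'
#' slope = sign(r) * sd(y) / sd(x); intercept = mean(y) - slope *
#' mean(x). Symmetric: swapping x and y inverts the slope.
#'
#' @param x,y numeric vectors as in \code{\link{pearsonCorrelation}}.
#' @return list: \code{slope}, \code{intercept}, \code{r}, \code{n}.
#' @export
model2Regression <- function(x, y) {
  pc <- pearsonCorrelation(x, y)
  slope <- sign(pc$r) * stats::sd(y) / stats::sd(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r = pc$r, n = pc$n)
}

#' Welch's t-test (generic utility)
#'
#' @param x,y numeric vectors.
#' @return list: \code{t}, \code{df}, \code{p}, \code{meanDiff}.
#' @export
welchT <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanDiff = unname(diff(rev(tt$estimate))))
}

# Dunn's post-hoc z-tests on ranks (ties-corrected), companion to the
# Kruskal-Wallis fallback; no package in the stack provides it.
dunnTest <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  tie <- table(x)
  tieC <- sum(tie^3 - tie) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tieC
  lev <- levels(g)
  Rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  out <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    z <- (Rbar[i] - Rbar[j]) / sqrt(v0 * (1 / n[i] + 1 / n[j]))
    out[[length(out) + 1L]] <- data.frame(
      group1 = lev[i], group2 = lev[j], z = unname(z),
      p = 2 * stats::pnorm(-abs(unname(z))))
  }
  res <- do.call(rbind, out)
  res$p_adj <- stats::p.adjust(res$p, method = "holm")
  res
}

#' ANOVA battery with normality gate and Tukey HSD
#'
#' One-way ANOVA across groups on ROI-level means (the repeated-
#' measures convention: each animal contributes its per-ROI means), or
#' observation-level one-/two-way ANOVA with interaction. A
#' Shapiro-Wilk gate is applied to the residuals first; on failure
#' (p < 0.05) a Kruskal-Wallis + Dunn fallback is reported alongside
#' the parametric result, never silently replacing it.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param factors one or two factor column names.
#' @param roi optional ROI column name; when given with one factor,
#'   the ANOVA runs on per-(factor x ROI) means.
#' @return list: \code{test} ("one-way ANOVA"/"two-way ANOVA"),
#'   \code{anova} (data.frame with F, df, p per term), \code{tukey}
#'   (pairwise contrasts), \code{shapiro} (W, p), \code{fallback}
#'   (NULL or Kruskal-Wallis + Dunn), \code{data} (the analyzed
#'   table).
#' @export
groupTests <- function(data, response, factors, roi = NULL) {
  stopifnot(response %in% names(data), all(factors %in% names(data)))
  if (length(factors) == 1 && !is.null(roi)) {
    agg <- stats::aggregate(data[[response]],
                            list(g = data[[factors]], roi = data[[roi]]),
                            mean, na.rm = TRUE)
    names(agg)[3] <- "y"
    nRoi <- table(agg$g)
    if (any(nRoi < 2))
      stop("repeated-measures path needs >= 2 ROIs per group")
    df <- data.frame(y = agg$y, g = factor(agg$g))
    fit <- stats::aov(y ~ g, data = df)
  } else if (length(factors) == 1) {
    df <- data.frame(y = data[[response]], g = factor(data[[factors]]))
    fit <- stats::aov(y ~ g, data = df)
  } else if (length(factors) == 2) {
    df <- data.frame(y = data[[response]],
                     g = factor(data[[factors[1]]]),
                     h = factor(data[[factors[2]]]))
    fit <- stats::aov(y ~ g * h, data = df)
  } else stop("one or two factors supported")
  if (any(vapply(df[-1], function(f) nlevels(factor(f)) < 2, TRUE)))
    stop("each factor needs at least 2 levels")
  res <- stats::residuals(fit)
  sw <- if (length(res) >= 3 && length(res) <= 5000 &&
            stats::sd(res) > 0)
    stats::shapiro.test(res) else list(statistic = NA, p.value = NA)
  av <- summary(fit)[[1]]
  anovaTab <- data.frame(term = trimws(rownames(av)),
                         df = av$Df, F = av$`F value`,
                         p = av$`Pr(>F)`)[!is.na(av$`F value`), ]
  tk <- stats::TukeyHSD(fit)
  tukey <- do.call(rbind, lapply(names(tk), function(nm) {
    m <- tk[[nm]]
    data.frame(term = nm, contrast = rownames(m), diff = m[, "diff"],
               p = m[, "p adj"], row.names = NULL)
  }))
  fallback <- NULL
  if (is.finite(sw$p.value) && sw$p.value < 0.05 &&
      length(factors) == 1) {
    kw <- stats::kruskal.test(df$y, df$g)
    fallback <- list(kruskal = list(chisq = unname(kw$statistic),
                                    df = unname(kw$parameter),
                                    p = kw$p.value),
                     dunn = dunnTest(df$y, df$g))
  }
  list(test = if (length(factors) == 2) "two-way ANOVA"
       else "one-way ANOVA",
       anova = anovaTab, tukey = tukey,
       shapiro = list(W = unname(sw$statistic), p = sw$p.value),
       fallback = fallback, data = df)
}
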