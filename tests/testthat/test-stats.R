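test_that("Pearson correlation matches the textbook sum formula", {
  set.seed(1)
  sumFormula <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  for (i in 1:5) {
    x <- rnorm(37); y <- 0.4 * x + rnorm(37)
    pc <- pearsonCorrelation(x, y)
    expect_equal(pc$r, sumFormula(x, y), tolerance = 1e-12)
    expect_equal(pc$n, 37)
  }
  expect_equal(pearsonCorrelation(1:4, c(2, 4, 6, 8))$r, 1)
  set.seed(2)
  big <- pearsonCorrelation(rnorm(10000), rnorm(10000))
  expect_lt(abs(big$r), 0.05)
  expect_error(pearsonCorrelation(1:3, 1:3), "at least 4")
  expect_error(pearsonCorrelation(rep(1, 8), 1:8), "zero variance")
})

test_that("Fisher-Z comparison matches its closed form and symmetries", {
  # direct formula oracle
  z0 <- (atanh(0.80) - atanh(0.61)) / sqrt(1 / 157 + 1 / 157)
  fz <- fisherZCompare(0.80, 160, 0.61, 160)
  expect_equal(fz$z, z0, tolerance = 1e-9)
  expect_equal(fz$p, 2 * pnorm(-abs(z0)), tolerance = 1e-9)
  # identity
  id <- fisherZCompare(0.5, 60, 0.5, 60)
  expect_equal(id$z, 0)
  expect_equal(id$p, 1)
  # antisymmetry
  a <- fisherZCompare(0.7, 80, 0.3, 50)
  b <- fisherZCompare(0.3, 50, 0.7, 80)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  # monotonicity in |r1 - r2| and in n
  p1 <- fisherZCompare(0.6, 100, 0.5, 100)$p
  p2 <- fisherZCompare(0.7, 100, 0.5, 100)$p
  p3 <- fisherZCompare(0.8, 100, 0.5, 100)$p
  expect_true(p1 > p2 && p2 > p3)
  pn <- vapply(c(20, 80, 320), function(n)
    fisherZCompare(0.6, n, 0.4, n)$p, numeric(1))
  expect_true(all(diff(pn) < 0))
  expect_error(fisherZCompare(1, 50, 0.5, 50), "infinite")
})

test_that("reduced major axis regression has its closed form", {
  set.seed(3)
  x <- rnorm(60, sd = 1)
  y <- 5 + 2 * x + rnorm(60, sd = 0.3)
  m <- model2Regression(x, y)
  expect_equal(m$slope, sign(m$r) * sd(y) / sd(x), tolerance = 1e-12)
  expect_equal(m$intercept, mean(y) - m$slope * mean(x),
               tolerance = 1e-12)
  # swap inversion
  m2 <- model2Regression(y, x)
  expect_equal(m2$slope, 1 / m$slope, tolerance = 1e-12)
  # RMA slope exceeds OLS under noise; both approach truth as noise -> 0
  ols <- unname(coef(lm(y ~ x))[2])
  expect_gte(m$slope, ols)
  y0 <- 5 + 3 * x + rnorm(60, sd = 1e-7)
  expect_equal(model2Regression(x, y0)$slope, 3, tolerance = 1e-4)
})

test_that("Welch's t detects a mean shift between unequal groups", {
  set.seed(4)
  w <- welchT(rnorm(40, 0, 1), rnorm(25, 2.5, 2))
  expect_lt(w$p, 0.01)
  # meanDiff is mean(x) - mean(y)
  expect_lt(w$meanDiff, -1)
  tt <- t.test(rnorm(10), rnorm(10))
  expect_true(is.finite(welchT(1:10, c(2, 5, 3, 8))$t))
})

test_that("null groups give F near zero and Tukey p near one", {
  set.seed(5)
  d <- data.frame(y = rnorm(90), g = rep(c("a", "b", "c"), each = 30))
  d$y <- d$y - ave(d$y, d$g)  # identical group means
  gt <- groupTests(d, "y", "g")
  expect_lt(gt$anova$F[1], 1e-10)
  expect_true(all(gt$tukey$p > 0.999))
})

test_that("a five-sigma shift is flagged by Tukey contrasts", {
  set.seed(6)
  d <- data.frame(y = c(rnorm(30), rnorm(30), rnorm(30, 5)),
                  g = rep(c("a", "b", "c"), each = 30))
  gt <- groupTests(d, "y", "g")
  pc <- gt$tukey$p[grepl("c", gt$tukey$contrast)]
  expect_true(all(pc < 0.001))
  expect_gt(gt$tukey$p[gt$tukey$contrast == "b-a"], 0.05)
})

test_that("interaction p-values are uniform under an additive null", {
  set.seed(7)
  ps <- replicate(150, {
    d <- expand.grid(g = c("a", "b"), h = c("x", "y", "z"),
                     rep = 1:15)
    d$y <- rnorm(nrow(d)) + 0.8 * (d$g == "b") + 0.5 * (d$h == "z")
    gt <- groupTests(d, "y", c("g", "h"))
    gt$anova$p[gt$anova$term == "g:h"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ANOVA significance agrees with a permutation oracle", {
  set.seed(8)
  d <- data.frame(y = c(rnorm(8, 0), rnorm(8, 0.3), rnorm(8, 3)),
                  g = rep(c("a", "b", "c"), each = 8))
  gt <- groupTests(d, "y", "g")
  Fobs <- gt$anova$F[1]
  Fperm <- replicate(1500, {
    dp <- d; dp$y <- sample(dp$y)
    summary(aov(y ~ g, dp))[[1]]$`F value`[1]
  })
  pPerm <- mean(Fperm >= Fobs)
  expect_identical(gt$anova$p[1] < 0.05, pPerm < 0.05)
  # pairwise ranking agreement: the extreme group's contrasts dominate
  tk <- gt$tukey
  pc <- tk$p[grepl("c", tk$contrast)]
  pab <- tk$p[tk$contrast == "b-a"]
  expect_true(all(pc < pab))
})

test_that("the ROI repeated-measures path aggregates before testing", {
  set.seed(9)
  d <- expand.grid(roi = paste0("r", 1:4), animal = c("A", "B", "C"),
                   k = 1:25)
  d$y <- rnorm(nrow(d)) + 2 * (d$animal == "C")
  gt <- groupTests(d, "y", "animal", roi = "roi")
  expect_equal(nrow(gt$data), 12)  # 3 animals x 4 ROI means
  expect_lt(gt$anova$p[1], 0.01)
  expect_error(groupTests(d[d$roi == "r1", ], "y", "animal",
                          roi = "roi"), ">= 2 ROIs")
})

test_that("non-normal residuals trigger a Kruskal-Wallis fallback", {
  set.seed(10)
  d <- data.frame(y = rlnorm(120, sdlog = 2.5),
                  g = rep(c("a", "b", "c"), each = 40))
  gt <- groupTests(d, "y", "g")
  expect_lt(gt$shapiro$p, 0.05)
  expect_false(is.null(gt$fallback))
  expect_true(is.finite(gt$fallback$kruskal$p))
  expect_equal(nrow(gt$fallback$dunn), 3)  # all pairs
  kw <- kruskal.test(d$y, factor(d$g))
  expect_equal(gt$fallback$kruskal$p, kw$p.value)
})
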