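# independent Brown-Forsythe computation: one-way ANOVA on absolute
# deviations from group medians
bf_oracle <- function(values, groups) {
  dev <- abs(values - ave(values, groups, FUN = median))
  summary(aov(dev ~ as.factor(groups)))[[1]][["Pr(>F)"]][1]
}

test_that("the decision tree routes by the assumption tests", {
  set.seed(21)
  g <- rep(c("morning", "afternoon"), each = 20)

  x_norm <- rnorm(40, mean = rep(c(0, 0.5), each = 20))
  cg <- compare_groups(x_norm, g)
  resid <- x_norm - ave(x_norm, g)
  expect_equal(cg$shapiro_p, shapiro.test(resid)$p.value)
  expect_equal(cg$levene_p, bf_oracle(x_norm, g), tolerance = 1e-10)
  expect_identical(cg$test_used,
                   if (cg$shapiro_p >= 0.05 && cg$levene_p >= 0.05) "anova" else "kruskal_wallis")

  # heavy-tailed data fail normality and must take the rank path
  x_cauchy <- rcauchy(40)
  cgc <- compare_groups(x_cauchy, g)
  expect_lt(cgc$shapiro_p, 0.05)
  expect_identical(cgc$test_used, "kruskal_wallis")
  expect_equal(cgc$statistic, unname(kruskal.test(x_cauchy, as.factor(g))$statistic))

  # heteroscedastic Gaussian data fail Levene and also take the rank path
  x_het <- c(rnorm(20, 0, 0.2), rnorm(20, 0, 5))
  cgh <- compare_groups(x_het, g)
  expect_lt(cgh$levene_p, 0.05)
  expect_identical(cgh$test_used, "kruskal_wallis")
})

test_that("identical groups are never significant and constant data fall through flagged", {
  set.seed(22)
  x <- rnorm(20)
  cg <- compare_groups(c(x, x), rep(c("a", "b"), each = 20))
  expect_false(cg$significant)

  const <- compare_groups(rep(5, 10), rep(c("a", "b"), each = 5))
  expect_identical(const$test_used, "kruskal_wallis")
  expect_true("constant_data" %in% const$flags)
  expect_false(const$significant)

  expect_error(compare_groups(1:3, c("a", "a", "b")), ">= 2 observations")
})

test_that("a 3-SD effect is detected with high power", {
  hits <- sapply(1:200, function(i) {
    set.seed(3000 + i)
    x <- c(rnorm(20, 0), rnorm(20, 3))
    compare_groups(x, rep(c("m", "a"), each = 20))$significant
  })
  expect_gte(mean(hits), 0.95)
})

test_that("compare_many applies the tree per variable with optional BH correction", {
  set.seed(24)
  d <- data.frame(
    variable = rep(c("no2", "po4"), each = 20),
    session = rep(rep(c("morning", "afternoon"), each = 10), 2),
    value = c(rnorm(10, 1), rnorm(10, 3), rnorm(20))
  )
  res <- compare_many(d)
  expect_identical(nrow(res), 2L)
  expect_true(res$significant[res$variable == "no2"])
  res_bh <- compare_many(d, p_adjust = "BH")
  expect_true(all(res_bh$p_value >= res$p_value - 1e-12))
})

# brute-force Spearman: Pearson product-moment formula applied to average ranks
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

test_that("spearman_matrix matches the brute-force rank formula, including ties", {
  set.seed(25)
  tab <- data.frame(
    a = c(1, 2, 2, 3, 5, 5, 7, 8, 8, 10),   # ties
    b = rnorm(10),
    c = sample(1:5, 10, replace = TRUE),    # heavy ties
    d = runif(10)
  )
  m <- spearman_matrix(tab)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(m$rho[i, j], spearman_oracle(tab[[i]], tab[[j]]), tolerance = 1e-12)
  }
  expect_identical(diag(m$rho), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(m$rho, t(m$rho))
  expect_true(all(abs(m$rho) <= 1 + 1e-12))
})

test_that("spearman is invariant under monotone transforms and exact for monotone pairs", {
  set.seed(26)
  x <- rnorm(15)
  tab <- data.frame(x = x, ex = exp(x), neg = -x, z = rnorm(15))
  m <- spearman_matrix(tab)
  expect_equal(m$rho["x", "ex"], 1)
  expect_equal(m$rho["x", "neg"], -1)
  # transforming a variable monotonically changes nothing
  m2 <- spearman_matrix(transform(tab, z = qlogis(pnorm(z))))
  expect_equal(m2$rho, m$rho, tolerance = 1e-12)
})

test_that("pairs with too few complete observations are flagged missing", {
  tab <- data.frame(a = c(1, 2, 3, 4, NA, NA), b = c(NA, NA, NA, 4, 5, 6),
                    c = c(2, 4, 6, 8, 10, 12))
  m <- spearman_matrix(tab)
  expect_true(is.na(m$rho["a", "b"]))
  expect_true(m$insufficient["a", "b"])
  expect_identical(m$n["a", "c"], 4L)
  expect_equal(m$rho["a", "c"], 1)
})
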