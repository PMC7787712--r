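test_that("fit_ols solves exact and hand-computed cases", {
  f <- fit_ols(0:3, c(1, 3, 5, 7))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  # normal equations by hand: x=(0,1,2), y=(0,1,0) -> slope 0, intercept 1/3
  f2 <- fit_ols(0:2, c(0, 1, 0))
  expect_equal(f2$slope, 0)
  expect_equal(f2$intercept, 1 / 3)

  f3 <- fit_ols(1:5, rep(4, 5))
  expect_equal(f3$slope, 0)
  expect_equal(f3$r_squared, 0)

  expect_error(fit_ols(rep(2, 5), 1:5), "constant")
  expect_error(fit_ols(1:4, 1:3), "length")
  expect_error(fit_ols(1:2, 1:2), "3")
})

test_that("fit_ols agrees with lm and with a brute-force SSE grid search", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n, sd = 3)
    y <- 1.5 * x - 2 + rnorm(n)
    f <- fit_ols(x, y)
    m <- lm(y ~ x)
    sm <- summary(m)
    expect_equal(f$slope, unname(coef(m)[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(coef(m)[1]), tolerance = 1e-10)
    expect_equal(f$slope_se, unname(sm$coefficients[2, 2]), tolerance = 1e-10)
    expect_equal(f$intercept_se, unname(sm$coefficients[1, 2]),
                 tolerance = 1e-10)
    expect_equal(f$r_squared, sm$r.squared, tolerance = 1e-10)
    expect_equal(f$cov_slope_intercept, vcov(m)[1, 2], tolerance = 1e-10)
  }
  # brute force: no (slope, intercept) on a fine grid beats the fit's SSE
  set.seed(12)
  x <- runif(12, -5, 5); y <- 0.7 * x + 1 + rnorm(12, 0, 0.5)
  f <- fit_ols(x, y)
  sse <- function(a, b) sum((y - a * x - b)^2)
  grid <- expand.grid(a = seq(f$slope - 0.5, f$slope + 0.5, by = 0.01),
                      b = seq(f$intercept - 0.5, f$intercept + 0.5, by = 0.01))
  best <- min(mapply(sse, grid$a, grid$b))
  expect_lte(sum(f$residuals^2), best + 1e-12)
})

test_that("the normal equations hold exactly for the fitted sample", {
  set.seed(13)
  x <- rnorm(30); y <- 2 * x + rnorm(30)
  f <- fit_ols(x, y)
  expect_equal(sum(f$residuals), 0, tolerance = 1e-10)
  expect_equal(sum(f$residuals * x), 0, tolerance = 1e-10)
})

test_that("sequential ANCOVA reproduces a hand-built ANOVA table", {
  # 12-point fixture; expected values computed from the sequential
  # sums-of-squares decomposition (covariate, then factor, then interaction)
  g <- rep(c("A", "B"), each = 6)
  x <- rep(1:6, 2)
  y <- c(2, 3, 5, 4, 6, 7, 4, 6, 7, 9, 9, 11)
  a <- ancova(y, g, x)
  expect_equal(a$table$ss[1:3],
               c(44.5785714286, 30.0833333333, 1.2071428571),
               tolerance = 1e-9)
  expect_equal(a$f_covariate, 117.01875, tolerance = 1e-6)
  expect_equal(a$f_factor, 78.96875, tolerance = 1e-6)
  expect_equal(a$f_interaction, 3.16875, tolerance = 1e-6)
  expect_equal(a$df_interaction, c(1, 8))
  expect_equal(a$p_interaction, 0.11293, tolerance = 1e-4)
})

test_that("sequential ANCOVA matches the anova() oracle on random designs", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(c(16, 24, 40), 1)
    g <- factor(sample(c("small", "large"), n, replace = TRUE))
    while (min(table(g)) < 3) g <- factor(sample(c("small", "large"), n,
                                                 replace = TRUE))
    x <- rnorm(n, 25, 5)
    y <- 0.5 * x + 2 * (g == "small") + rnorm(n)
    a <- ancova(y, as.character(g), x)
    o <- anova(lm(y ~ x + g + x:g))
    expect_equal(a$table$f[1:3], o[["F value"]][1:3], tolerance = 1e-8)
    expect_equal(a$table$p[1:3], o[["Pr(>F)"]][1:3], tolerance = 1e-8)
    expect_equal(a$table$ss, c(o[["Sum Sq"]][1:3], o[["Sum Sq"]][4]),
                 tolerance = 1e-8)
    # continuous-size variant against the same oracle
    cw <- rnorm(n, 14, 2)
    y2 <- 0.4 * x + 0.2 * cw + rnorm(n)
    a2 <- ancova(y2, cw, x)
    o2 <- anova(lm(y2 ~ x + cw + x:cw))
    expect_equal(a2$table$f[1:3], o2[["F value"]][1:3], tolerance = 1e-8)
  }
})

test_that("parallel groups give a zero interaction F and a significant factor", {
  x <- rep(seq(20, 35, by = 1), 2)
  g <- rep(c("A", "B"), each = 16)
  y <- -0.3 * x + 8 + 0.7 * (g == "B")  # exactly parallel, zero noise
  a <- ancova(y, g, x)
  expect_equal(a$f_interaction, 0)
  expect_gt(a$f_factor, 1e6)
  # identical groups: factor and interaction explain nothing
  y2 <- c(-0.3 * x[1:16] + 8, -0.3 * x[1:16] + 8)
  a2 <- ancova(y2, g, x)
  expect_equal(a2$f_factor, 0)
  expect_equal(a2$f_interaction, 0)
})

test_that("a single-level ANCOVA reduces to the simple regression", {
  set.seed(31)
  x <- rnorm(20, 25, 4); y <- -0.3 * x + 8 + rnorm(20, 0, 0.5)
  a <- ancova(y, rep("only", 20), x)
  f <- fit_ols(x, y)
  expect_equal(a$group_fits[["only"]]$slope, f$slope)
  expect_equal(a$group_fits[["only"]]$intercept, f$intercept)
  expect_true(is.na(a$f_factor))
})

test_that("adding the interaction never increases the residual SS", {
  set.seed(41)
  for (i in 1:10) {
    n <- 30
    g <- sample(c("A", "B"), n, replace = TRUE)
    x <- rnorm(n); y <- rnorm(n)
    with_int <- ancova(y, g, x, include_interaction = TRUE)
    without <- ancova(y, g, x, include_interaction = FALSE)
    sse_with <- with_int$table$ss[with_int$table$term == "residual"]
    sse_without <- without$table$ss[without$table$term == "residual"]
    expect_lte(sse_with, sse_without + 1e-12)
  }
})

test_that("the offset_sqrt transform shifts to positivity before the sqrt", {
  set.seed(51)
  x <- rnorm(24, 25, 4)
  g <- rep(c("A", "B"), 12)
  y <- -0.3 * x + 5 + rnorm(24)        # includes negative values
  a <- ancova(y, g, x, transform = "offset_sqrt")
  expect_equal(a$transform_applied, "offset_sqrt")
  yt <- sqrt(y - min(y) + 0.01)
  o <- anova(lm(yt ~ x + factor(g) + x:factor(g)))
  expect_equal(a$table$f[1:3], o[["F value"]][1:3], tolerance = 1e-8)
})

test_that("ANCOVA rejects degenerate designs", {
  expect_error(ancova(1:6, rep(c("A", "B"), 3), rep(1, 6)), "constant")
  expect_error(ancova(1:6, c("A", rep("B", 5)), 1:6), "at least 2")
  expect_error(ancova(1:6, rep(c("A", "B", "C"), 2), 1:6), "at most 2")
})

test_that("the factor F-test holds its nominal size under the null", {
  set.seed(61)
  n_sim <- 500
  n <- 24
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    x <- rnorm(n, 25, 4)
    y <- 0.4 * x + rnorm(n)          # no group effect
    g <- sample(rep(c("A", "B"), n / 2))
    a <- ancova(y, g, x)
    if (a$p_factor < 0.05) rejections <- rejections + 1L
  }
  ci <- qbinom(c(0.025, 0.975), n_sim, 0.05)
  expect_gte(rejections, ci[1])
  expect_lte(rejections, ci[2])
})
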