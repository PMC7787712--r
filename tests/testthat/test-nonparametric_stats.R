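test_that("Kruskal-Wallis H is zero for identical groups and exact on hand ranks", {
  same <- list(a = rep(5, 4), b = rep(5, 3), c = rep(5, 5), d = rep(5, 4))
  k <- kruskal_wallis(same)
  expect_equal(k$h_statistic, 0)
  expect_equal(k$p_value, 1)

  # (1,2,3) vs (4,5,6): ranks 1..6, mean ranks 2 and 5,
  # H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 27/7
  k2 <- kruskal_wallis(list(a = 1:3, b = 4:6))
  expect_equal(k2$h_statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(k2$df, 1)

  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("H is invariant under monotone transforms of the data", {
  set.seed(71)
  groups <- list(a = rnorm(8, 1), b = rnorm(10, 1.5), c = rnorm(7, 2))
  h1 <- kruskal_wallis(groups)$h_statistic
  h2 <- kruskal_wallis(lapply(groups, exp))$h_statistic
  h3 <- kruskal_wallis(lapply(groups, function(g) 3 * g - 100))$h_statistic
  expect_equal(h1, h2)
  expect_equal(h1, h3)
})

test_that("tie-corrected H and p match the reference implementation", {
  set.seed(72)
  for (i in 1:15) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) {
      round(rnorm(sample(5:15, 1), mean = j * 0.3), 1)  # rounding makes ties
    })
    mine <- kruskal_wallis(groups)
    ref <- kruskal.test(groups)
    expect_equal(mine$h_statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("Dunn's comparisons apply the Bonferroni multiplication rule", {
  set.seed(73)
  groups <- list(a = rnorm(10), b = rnorm(12), c = rnorm(9), d = rnorm(11))
  d <- dunn_posthoc(groups)
  expect_equal(d$n_comparisons, 6)
  expect_equal(d$comparisons$p_adjusted,
               pmin(1, d$comparisons$p_raw * 6))
  # the z statistics recompute from pooled mean ranks and tie-corrected SE
  pooled <- unlist(groups)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  n <- length(pooled)
  tt <- table(pooled)
  v <- n * (n + 1) / 12 - sum(tt^3 - tt) / (12 * (n - 1))
  z12 <- (rbar[1] - rbar[2]) /
    sqrt(v * (1 / length(groups$a) + 1 / length(groups$b)))
  expect_equal(d$comparisons$z[1], unname(z12), tolerance = 1e-12)
})

test_that("Dunn's flags the separated pair and is inert on identical groups", {
  same <- list(a = rep(1, 5), b = rep(1, 6), c = rep(1, 5), d = rep(1, 7))
  d0 <- dunn_posthoc(same)
  expect_true(all(d0$comparisons$p_adjusted == 1))

  set.seed(74)
  groups <- list(a = rnorm(12, 0), b = rnorm(12, 0.1),
                 c = rnorm(12, 0.05), d = rnorm(12, 8))
  d1 <- dunn_posthoc(groups)
  cmp <- d1$comparisons
  d_pairs <- cmp$group_a == "d" | cmp$group_b == "d"
  expect_lt(min(cmp$p_adjusted[d_pairs]), min(cmp$p_adjusted[!d_pairs]))
})

test_that("univariate Euclidean PERMANOVA reproduces the classical F", {
  set.seed(81)
  g <- rep(c("A", "B", "C"), times = c(7, 6, 8))
  y <- rnorm(21) + 0.8 * (g == "C")
  p <- permanova(y, terms = list(group = g), n_perm = 99, seed = 1)
  f_classic <- summary(aov(y ~ g))[[1]][["F value"]][1]
  expect_equal(p$table$pseudo_f[1], f_classic, tolerance = 1e-10)

  # sequential two-term model equals the sequential ANOVA decomposition
  x <- rnorm(21, 25, 3)
  y2 <- 0.5 * x + (g == "B") + rnorm(21)
  gnum <- as.numeric(factor(g))
  p2 <- permanova(y2, terms = list(covariate = x, group = g),
                  n_perm = 99, seed = 2)
  o <- anova(lm(y2 ~ x + g))
  expect_equal(p2$table$ss[1:2], o[["Sum Sq"]][1:2], tolerance = 1e-8)
  expect_equal(p2$table$pseudo_f[1:2], o[["F value"]][1:2], tolerance = 1e-8)
})

test_that("PERMANOVA agrees with the vegan reference on a multivariate response", {
  skip_if_not_installed("vegan")
  set.seed(82)
  n <- 24
  g <- factor(rep(c("A", "B"), each = n / 2))
  x <- rnorm(n)
  y <- cbind(rnorm(n) + (g == "B"), rnorm(n))
  mine <- permanova(y, terms = list(x = x, g = g), n_perm = 199, seed = 3)
  dat <- data.frame(x = x, g = g)
  ref <- vegan::adonis2(dist(y) ~ x + g, data = dat, permutations = 199,
                        by = "terms")
  expect_equal(mine$table$ss[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(mine$table$pseudo_f[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(mine$table$df[1:2], ref$Df[1:2])
})

test_that("permutation p-values hit the floor, are seeded, and order-invariant", {
  set.seed(83)
  g <- rep(c("A", "B"), each = 10)
  y <- c(rnorm(10), rnorm(10, 50))   # overwhelming separation
  p <- permanova(y, terms = list(group = g), n_perm = 99, seed = 7)
  expect_equal(p$table$p_perm[1], 1 / 100)  # floor = 1/(n_perm + 1)

  p2 <- permanova(y, terms = list(group = g), n_perm = 99, seed = 7)
  expect_identical(p$table, p2$table)

  o <- sample(length(y))
  p3 <- permanova(y[o], terms = list(group = g[o]), n_perm = 99, seed = 7)
  expect_equal(p3$table$pseudo_f[1], p$table$pseudo_f[1], tolerance = 1e-10)
})

test_that("duplicating the data matches direct recomputation of the classical F", {
  set.seed(84)
  g <- rep(c("A", "B"), each = 6)
  y <- rnorm(12) + (g == "B")
  dup <- rep(seq_along(y), each = 2)
  p <- permanova(y[dup], terms = list(group = g[dup]), n_perm = 99, seed = 4)
  f_direct <- summary(aov(y[dup] ~ g[dup]))[[1]][["F value"]][1]
  expect_equal(p$table$pseudo_f[1], f_direct, tolerance = 1e-10)
})

test_that("PERMANOVA rejects degenerate inputs", {
  expect_error(permanova(rep(1, 10), terms = list(g = rep(c("A", "B"), 5)),
                         n_perm = 99, seed = 1), "degenerate")
  expect_error(permanova(rnorm(4), terms = list(g = c("A", "A", "B", "B")),
                         n_perm = 99, seed = 1), "at least 5")
  expect_error(permanova(rnorm(10), terms = list(g = rep(c("A", "B"), 5)),
                         n_perm = 9, seed = 1), "99")
  expect_error(permanova(rnorm(10), terms = list(g = rep(c("A", "B"), 5)),
                         n_perm = 99), "seed")
})
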