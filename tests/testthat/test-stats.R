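brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

brute_kw_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(g) length(g) * mean(g)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  expect_equal(spearman_correlation(1:10, 1:10)$r_s, 1)
  expect_equal(spearman_correlation(1:10, 10:1)$r_s, -1)

  set.seed(5)
  for (i in 1:5) {
    x <- sample(1:6, 15, replace = TRUE) # plenty of ties
    y <- sample(1:6, 15, replace = TRUE)
    expect_equal(spearman_correlation(x, y)$r_s, brute_spearman(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_correlation(1:2, 2:1), "at least 3")
})

test_that("Spearman p-values are approximately uniform under the null", {
  set.seed(77)
  p <- replicate(500, spearman_correlation(runif(50), runif(50))$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Kruskal-Wallis H matches the brute-force rank-sum formula", {
  v <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  g <- rep(c("a", "b"), each = 5)
  res <- kruskal_wallis_dunn(v, g)
  expect_equal(res$H, brute_kw_h(v, g), tolerance = 1e-12)

  # completely separated groups
  v2 <- c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15)
  res2 <- kruskal_wallis_dunn(v2, g)
  expect_equal(res2$H, brute_kw_h(v2, g), tolerance = 1e-12)

  # label permutation invariance
  set.seed(8)
  perm <- sample(10)
  res3 <- kruskal_wallis_dunn(v[perm], g[perm])
  expect_equal(res3$H, res$H, tolerance = 1e-12)

  expect_error(kruskal_wallis_dunn(1:3, c("a", "a", "b")), "at least 2")
})

test_that("identical groups give H near zero and adjusted p of 1", {
  v <- rep(c(1, 2, 3, 4), times = 3)
  g <- rep(c("a", "b", "c"), each = 4)
  res <- kruskal_wallis_dunn(v, g)
  expect_lt(res$H, 1e-10)
  expect_true(all(res$pairwise$p_adjusted == 1))
})

test_that("Dunn z and Bonferroni adjustment match a hand computation", {
  # groups a = {1, 2}, b = {3, 4}: mean ranks 1.5 and 3.5, no ties
  res <- kruskal_wallis_dunn(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  se <- sqrt((4 * 5 / 12) * (1 / 2 + 1 / 2))
  z_hand <- (1.5 - 3.5) / se
  expect_equal(res$pairwise$z, z_hand, tolerance = 1e-12)
  expect_equal(res$pairwise$p_raw, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)
  expect_equal(res$pairwise$p_adjusted, res$pairwise$p_raw) # one pair only

  # three groups: adjustment multiplies by the number of pairs, capped at 1
  res3 <- kruskal_wallis_dunn(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), 2))
  expect_equal(res3$pairwise$p_adjusted,
               pmin(1, res3$pairwise$p_raw * 3))
})

test_that("descriptive summaries match direct formulas", {
  s <- summarise_values(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(c(s$min, s$max), c(1, 3))

  expect_true(is.na(summarise_values(5)$sd))

  set.seed(13)
  x <- rnorm(101)
  s2 <- summarise_values(x)
  expect_equal(s2$mean, sum(x) / length(x))
  expect_equal(s2$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
  expect_equal(s2$median, sort(x)[51])
  expect_equal(s2$iqr, unname(quantile(x, 0.75) - quantile(x, 0.25)))
})
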