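#' Spearman rank correlation
#'
#' Rank correlation with midrank handling of ties and a two-sided p-value
#' from the t approximation, the procedure used for density-versus-location
#' associations throughout (location data are not normally distributed, so
#' a rank test is appropriate).
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped).
#' @return an object of class `correlation_result`: list `r_s`, `p`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) data_error("Spearman correlation needs at least 3 complete pairs")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  structure(list(r_s = unname(ct$estimate), p = ct$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: r_s = %.3f, p = %.3g, n = %d\n",
              x$r_s, x$p, x$n))
  invisible(x)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H test across groups (chi-squared
#' approximation), followed by Dunn's pairwise z tests over all unordered
#' group pairs with Bonferroni correction, the group-comparison procedure
#' used for between-placenta differences in vascular density.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (coerced to factor).
#' @return an object of class `group_test_result`: list with `H`, `df`,
#'   `p`, `n`, and `pairwise`, a data frame `group1, group2, z, p_raw,
#'   p_adjusted` (`p_adjusted = min(1, p_raw * n_pairs)`).
#' @export
kruskal_wallis_dunn <- function(values, groups) {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  sizes <- table(groups)
  if (length(sizes) < 2L) data_error("need at least 2 groups")
  if (any(sizes < 2L)) data_error("every group needs at least 2 observations")
  kw <- kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   z = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_,
                   stringsAsFactors = FALSE)
  for (k in seq_len(m)) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z <- (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    p_raw <- 2 * pnorm(-abs(z))
    pw$z[k] <- z
    pw$p_raw[k] <- p_raw
    pw$p_adjusted[k] <- min(1, p_raw * m)
  }
  structure(list(H = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, n = n, group_sizes = sizes,
                 pairwise = pw),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-squared = %.3f, df = %d, p = %.3g (n = %d)\n",
              x$H, x$df, x$p, x$n))
  sig <- x$pairwise[x$pairwise$p_adjusted < 0.05, , drop = FALSE]
  if (nrow(sig)) {
    cat("Dunn pairwise (Bonferroni-adjusted p < 0.05):\n")
    print(sig, row.names = FALSE, digits = 3)
  } else {
    cat("No pairwise difference significant after Bonferroni correction.\n")
  }
  invisible(x)
}

#' Descriptive summary
#'
#' Mean with sample (n - 1) SD, range, median and interquartile range
#' (linear-interpolation quantiles). The SD is undefined (flagged `NA`)
#' for a single observation.
#'
#' @param x numeric vector (missing values dropped).
#' @return list `n, mean, sd, min, max, median, q1, q3, iqr`.
#' @export
summarise_values <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) data_error("no finite values to summarise")
  qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(x),
       mean = mean(x),
       sd = if (length(x) > 1L) sd(x) else NA_real_,
       min = min(x), max = max(x),
       median = qs[2], q1 = qs[1], q3 = qs[3],
       iqr = qs[3] - qs[1])
}
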