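#' Producer fraction of the total bacterial population
#'
#' Percentage of cells carrying the geosmin synthase gene, computed from geoA
#' and total-16S copy numbers under the stated assumption of one geoA copy
#' per producer cell (and, by default, one 16S copy per cell; a multi-copy
#' correction can be supplied but is off by default).
#'
#' @param geoA,total16S copy numbers (vectors recycle).
#' @param geoA_per_cell,s16_per_cell copies per cell; defaults 1.
#' @return percent (vector). `total16S = 0` with `geoA = 0` gives 0%;
#'   `total16S = 0` with `geoA > 0` gives `NA` with a warning (undefined).
#' @export
producer_fraction <- function(geoA, total16S, geoA_per_cell = 1, s16_per_cell = 1) {
  assert_nonneg(geoA, "geoA copies")
  assert_nonneg(total16S, "total 16S copies")
  if (geoA_per_cell <= 0 || s16_per_cell <= 0)
    stop("copies-per-cell must be positive")
  producers <- geoA / geoA_per_cell
  total <- total16S / s16_per_cell
  pct <- 100 * producers / total
  zero_zero <- total == 0 & producers == 0
  pct[zero_zero] <- 0
  undef <- total == 0 & producers > 0
  if (any(undef)) {
    warning("producer fraction undefined: geoA > 0 with zero total 16S")
    pct[undef] <- NA_real_
  }
  pct
}

#' Summarise a compartment's values the way the abundance figures do
#'
#' Mean plus the 10th/25th/75th/90th percentiles (inclusive
#' linear-interpolation quantiles, R type 7); outliers are the points outside
#' the 10th-90th percentile band.
#'
#' @param values numeric vector, length >= 1.
#' @return list: `mean`, `p10`, `p25`, `p75`, `p90`, `outliers`, `n`.
#' @export
compartment_summary <- function(values) {
  if (length(values) < 1) stop("need at least one value")
  assert_finite(values, "values")
  q <- stats::quantile(values, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
  list(mean = mean(values), p10 = q[1], p25 = q[2], p75 = q[3], p90 = q[4],
       outliers = values[values < q[1] | values > q[4]], n = length(values))
}

#' One-way ANOVA with Tukey HSD across intestinal sections
#'
#' Classical fixed-effects one-way ANOVA (F from the between/within
#' sum-of-squares decomposition) followed by Tukey's honestly-significant-
#' difference pairwise comparisons via the studentized-range distribution.
#'
#' @param groups named list of numeric vectors, one per section, each with at
#'   least 2 values.
#' @return object of class `section_comparison`: `group_means`, `F_statistic`,
#'   `p_value`, `df`, and `tukey` (data.frame pair/diff/p_adj).
#' @export
section_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a list of >= 2 numeric vectors")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("every group needs >= 2 values for within-group df")
  if (is.null(names(groups))) names(groups) <- LETTERS[seq_along(groups)]
  k <- length(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  ms_between <- ss_between / df1
  ms_within <- ss_within / df2
  f_stat <- if (ms_between == 0) 0 else ms_between / ms_within
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  tukey <- data.frame(
    pair = apply(pairs, 2, function(ij) paste(names(groups)[ij], collapse = "-")),
    diff = apply(pairs, 2, function(ij) means[ij[2]] - means[ij[1]]),
    p_adj = apply(pairs, 2, function(ij) {
      se <- sqrt(ms_within / 2 * (1 / n[ij[1]] + 1 / n[ij[2]]))
      if (se == 0) return(if (means[ij[1]] == means[ij[2]]) 1 else 0)
      q <- abs(means[ij[2]] - means[ij[1]]) / se
      stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    }),
    stringsAsFactors = FALSE)
  structure(list(group_means = means, F_statistic = f_stat, p_value = p,
                 df = c(df1, df2), tukey = tukey),
            class = "section_comparison")
}

#' @export
print.section_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F_statistic, x$p_value))
  cat("Group means:\n")
  print(round(x$group_means, 6))
  cat("Tukey HSD:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation between two compartment-level series
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list `r`, `p` (two-sided t approximation), `n`. Zero variance in
#'   either vector gives an `NA` correlation with a warning.
#' @export
correlate_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need >= 3 paired observations")
  assert_finite(x, "x"); assert_finite(y, "y")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("undefined correlation: zero variance")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
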