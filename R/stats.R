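# Group statistics: per-group mean +/- SE, one-way ANOVA and Scheffe's
# multiple comparisons, built from explicit sums of squares. The F upper
# tail is evaluated through the regularized incomplete beta function
# (pbeta), keeping the arithmetic of the test itself fully explicit.

#' Mean and standard error of a sample
#'
#' SE uses the n-1 (sample) standard deviation divided by sqrt(n). With a
#' single observation the SE is undefined and returned as `NA`.
#'
#' @param values Numeric vector of measurements.
#' @return A list with `mean`, `se` and `n`.
#' @examples
#' mean_se(c(54.1, 31.1, 24.5, 32.7, 43.7, 53.9))
#' @export
mean_se <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop_aorta("aortamech_invalid_input", "no non-missing values")
  m <- sum(values) / n
  se <- if (n >= 2L) sqrt(sum((values - m)^2) / (n - 1)) / sqrt(n) else NA_real_
  list(mean = m, se = se, n = n)
}

# Upper tail P(F(df1, df2) > f) via the regularized incomplete beta
# function: P = I_{df2/(df2 + df1 f)}(df2/2, df1/2).
f_upper_tail <- function(f, df1, df2) {
  if (f <= 0) return(1)
  x <- df2 / (df2 + df1 * f)
  stats::pbeta(x, df2 / 2, df1 / 2)
}

#' One-way analysis of variance from explicit sums of squares
#'
#' Partitions the total sum of squares into between-group and within-group
#' components, forms F = MS_between / MS_within with (k - 1, N - k) degrees
#' of freedom, and evaluates the upper-tail probability.
#'
#' @param groups Named list of numeric vectors, one per group (k >= 2, each
#'   of length >= 2).
#' @return A list with `F`, `df_between`, `df_within`, `p`, `ms_within` and
#'   per-group means/sizes.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_aorta("aortamech_invalid_input", "need at least two groups")
  }
  groups <- lapply(groups, function(v) v[!is.na(v)])
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) {
    stop_aorta("aortamech_invalid_input",
               "every group needs at least two observations")
  }
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- k - 1L
  df_w <- N - k
  if (ss_within == 0 && ss_between == 0) {
    stop_aorta("aortamech_undefined_f",
               "all observations identical: F is undefined")
  }
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  F <- ms_b / ms_w
  list(F = F, df_between = df_b, df_within = df_w,
       p = f_upper_tail(F, df_b, df_w),
       ms_within = ms_w, means = means, ns = ns)
}

#' Scheffe's multiple comparisons for all group pairs
#'
#' For each pair (i, j) the contrast statistic is F_c = (mean_i - mean_j)^2
#' / (MS_within * (1/n_i + 1/n_j)); under Scheffe's procedure F_c / (k - 1)
#' is referred to the F distribution with the ANOVA's (k - 1, N - k)
#' degrees of freedom, which makes the test valid for any contrast chosen
#' after the data are seen (and hence conservative for simple pairs).
#'
#' @param groups Named list of numeric vectors, one per group.
#' @param star_thresholds p-value cut-offs for `***`, `**`, `*`.
#' @return A data.frame with one row per pair: `group1`, `group2`,
#'   `mean_diff`, `F_contrast`, `p`, `stars`.
#' @export
scheffe_pairwise <- function(groups, star_thresholds = c(0.001, 0.01, 0.05)) {
  aov_res <- one_way_anova(groups)
  k <- length(groups)
  labs <- names(groups) %||% paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(col) {
    i <- pairs[1, col]; j <- pairs[2, col]
    diff <- aov_res$means[[i]] - aov_res$means[[j]]
    Fc <- diff^2 / (aov_res$ms_within *
                      (1 / aov_res$ns[[i]] + 1 / aov_res$ns[[j]]))
    p <- f_upper_tail(Fc / aov_res$df_between,
                      aov_res$df_between, aov_res$df_within)
    data.frame(group1 = labs[i], group2 = labs[j], mean_diff = diff,
               F_contrast = Fc, p = p,
               stars = significance_stars(p, star_thresholds),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Significance star labels
#'
#' Strict-inequality thresholds as used in the report tables:
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, otherwise `ns`.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param thresholds Cut-offs for `***`, `**`, `*` in increasing order.
#' @return Character vector of labels.
#' @export
significance_stars <- function(p, thresholds = c(0.001, 0.01, 0.05)) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_aorta("aortamech_invalid_input", "p must lie in [0, 1]")
  }
  vapply(p, function(pi) {
    if (pi < thresholds[1]) "***"
    else if (pi < thresholds[2]) "**"
    else if (pi < thresholds[3]) "*"
    else "ns"
  }, character(1))
}

#' Compare one variable across study groups
#'
#' Convenience wrapper producing the full statistical surface for a single
#' measured variable: per-group mean +/- SE, the one-way ANOVA and all
#' Scheffe pairwise comparisons.
#'
#' @param values Numeric vector of measurements.
#' @param group Group label for each measurement.
#' @param variable Name of the variable (carried into the output).
#' @return A list of class `group_comparison` with `variable`, `summary`
#'   (data.frame of group/mean/se/n), `anova` and `scheffe`.
#' @export
group_compare <- function(values, group, variable = "value") {
  keep <- !is.na(values)
  values <- values[keep]; group <- group[keep]
  split_vals <- split(values, factor(group, levels = unique(group)))
  summ <- do.call(rbind, lapply(names(split_vals), function(g) {
    ms <- mean_se(split_vals[[g]])
    data.frame(group = g, mean = ms$mean, se = ms$se, n = ms$n,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(variable = variable, summary = summ,
         anova = one_way_anova(split_vals),
         scheffe = scheffe_pairwise(split_vals)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison:", x$variable, "\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  print(x$scheffe, row.names = FALSE)
  invisible(x)
}
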