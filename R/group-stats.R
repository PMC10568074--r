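# Group-comparison workflow for aMWF observations: Kolmogorov-Smirnov
# normality check, classical one-way ANOVA across groups, and Games-Howell
# pairwise post hoc (Welch-type standard errors and degrees of freedom with
# studentized-range adjustment - valid under unequal group variances).

#' Kolmogorov-Smirnov normality test
#'
#' One-sample KS test of normality. Because the mean and SD are estimated
#' from the sample, the default applies the Lilliefors correction
#' ([nortest::lillie.test()]); the uncorrected KS test against the fitted
#' normal (whose p-values are conservative in this situation) is available
#' via `variant = "ks"`.
#'
#' @param x Numeric vector, at least 5 non-missing values.
#' @param variant `"lilliefors"` (default) or `"ks"`.
#' @return A tibble with `statistic`, `p_value`, `variant`, `n`.
#' @export
ks_normality <- function(x, variant = c("lilliefors", "ks")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]
  if (length(x) < 5) abort("Need at least 5 observations.")
  if (sd(x) == 0)
    abort("Sample is constant; normality test is degenerate.",
          class = "stairmwi_degenerate_error")
  res <- if (variant == "lilliefors") {
    nortest::lillie.test(x)
  } else {
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  }
  tibble(statistic = unname(res$statistic), p_value = res$p.value,
         variant = variant, n = length(x))
}

# internal: validated split of an observation table into groups
split_groups <- function(data, value, group, min_n = 2L) {
  stopifnot(is.data.frame(data))
  if (!all(c(value, group) %in% names(data)))
    abort(paste0("Columns `", value, "` and `", group, "` are required."))
  d <- data[!is.na(data[[value]]), ]
  g <- split(d[[value]], d[[group]])
  if (length(g) < 2) abort("Need at least 2 groups.")
  small <- names(g)[vapply(g, length, 1L) < min_n]
  if (length(small))
    abort(paste0("Groups with fewer than ", min_n, " observations: ",
                 paste(small, collapse = ", ")))
  g
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way analysis of variance
#' (F = MS_between / MS_within).
#'
#' @param data Data frame of observations.
#' @param value,group Column names of the observation value and group label.
#' @return A tibble with `f`, `df_between`, `df_within`, `p_value`.
#' @export
#' @examples
#' obs <- data.frame(group = rep(c("a", "b", "c"), each = 3),
#'                   value = c(1, 2, 3, 2, 3, 4, 6, 7, 8))
#' one_way_anova(obs)  # F = 21 on (2, 6) df
one_way_anova <- function(data, value = "value", group = "group") {
  g <- split_groups(data, value, group)
  if (all(vapply(g, sd, 1) == 0))
    abort("All groups have zero within-group variance; ANOVA is degenerate.",
          class = "stairmwi_degenerate_error")
  d <- data[!is.na(data[[value]]), ]
  fit <- oneway.test(d[[value]] ~ factor(d[[group]]), var.equal = TRUE)
  tibble(f = unname(fit$statistic),
         df_between = unname(fit$parameter[1]),
         df_within = unname(fit$parameter[2]),
         p_value = fit$p.value)
}

#' Games-Howell pairwise post hoc test
#'
#' For each pair of groups (i, j):
#' \deqn{t = \frac{\bar x_i - \bar x_j}{\sqrt{s_i^2/n_i + s_j^2/n_j}}}
#' with Welch-Satterthwaite degrees of freedom, and the adjusted p-value
#' from the studentized-range distribution with \eqn{q = |t|\sqrt{2}} and
#' `k` = number of groups (range-tail probabilities via [stats::ptukey()]).
#' Unlike Tukey's HSD this does not assume equal variances or sizes.
#' Simultaneous 95% confidence intervals use the corresponding
#' studentized-range quantile.
#'
#' @inheritParams one_way_anova
#' @param conf_level Confidence level of the simultaneous intervals.
#' @return A tibble with one row per pair: `group1`, `group2`, `diff`
#'   (mean1 - mean2), `se`, `statistic` (t), `df` (Welch), `p_adj`,
#'   `conf_low`, `conf_high`.
#' @export
games_howell <- function(data, value = "value", group = "group",
                         conf_level = 0.95) {
  g <- split_groups(data, value, group)
  k <- length(g)
  degenerate <- names(g)[vapply(g, sd, 1) == 0]
  if (length(degenerate) == k)
    abort(paste0("Zero variance in group(s): ",
                 paste(degenerate, collapse = ", ")),
          class = "stairmwi_degenerate_error")
  m <- vapply(g, mean, 1); v <- vapply(g, stats::var, 1)
  n <- vapply(g, length, 1L)
  pairs <- utils::combn(names(g), 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  vni <- v[i] / n[i]; vnj <- v[j] / n[j]
  se2 <- vni + vnj
  if (any(se2 == 0))
    abort(paste0("Zero pooled variance for pair ",
                 paste(i[se2 == 0], "vs", j[se2 == 0], collapse = ", "), "."),
          class = "stairmwi_degenerate_error")
  df <- se2^2 / (vni^2 / (n[i] - 1) + vnj^2 / (n[j] - 1))
  t_stat <- (m[i] - m[j]) / sqrt(se2)
  p_adj <- ptukey(abs(t_stat) * sqrt(2), nmeans = k, df = df,
                  lower.tail = FALSE)
  hw <- qtukey(conf_level, nmeans = k, df = df) / sqrt(2) * sqrt(se2)
  tibble(group1 = i, group2 = j, diff = unname(m[i] - m[j]),
         se = unname(sqrt(se2)), statistic = unname(t_stat),
         df = unname(df), p_adj = unname(p_adj),
         conf_low = unname(m[i] - m[j] - hw),
         conf_high = unname(m[i] - m[j] + hw))
}

#' Group comparison report for a cohort
#'
#' The full statistical workflow on an observation table (one row per ROI or
#' lesion measurement): per-group mean, SD and t-based 95% confidence
#' interval of the mean, normality check per group, one-way ANOVA across
#' groups, and the Games-Howell pairwise table. Observations are pooled
#' across subjects as given - no mixed-effects correction for within-subject
#' correlation is applied, and the per-group `n` is reported explicitly so
#' the unit of analysis is visible.
#'
#' @inheritParams one_way_anova
#' @param conf_level Confidence level for the group-mean intervals.
#' @return An object of class `amwf_comparison`: list with tibbles `groups`,
#'   `normality`, `anova`, `pairwise`, and `conf_level`. Supports [tidy()]
#'   (pairwise table), [glance()] (ANOVA row) and [autoplot()].
#' @export
summarize_cohort <- function(data, value = "value", group = "group",
                             conf_level = 0.95) {
  g <- split_groups(data, value, group)
  groups <- purrr::imap_dfr(g, function(x, nm) {
    n <- length(x)
    se <- sd(x) / sqrt(n)
    tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
    tibble(group = nm, n = n, mean = mean(x), sd = sd(x),
           conf_low = mean(x) - tq * se, conf_high = mean(x) + tq * se)
  })
  normality <- purrr::imap_dfr(g, function(x, nm) {
    res <- tryCatch(ks_normality(x), error = function(e) {
      tibble(statistic = NA_real_, p_value = NA_real_,
             variant = "lilliefors", n = length(x))
    })
    dplyr::mutate(res, group = nm, .before = 1)
  })
  structure(
    list(groups = groups, normality = normality,
         anova = one_way_anova(data, value, group),
         pairwise = games_howell(data, value, group, conf_level),
         conf_level = conf_level),
    class = "amwf_comparison"
  )
}

#' @export
print.amwf_comparison <- function(x, ...) {
  cat("Group comparison of aMWF observations\n\nGroups:\n")
  print(as.data.frame(x$groups), row.names = FALSE, digits = 4)
  cat(sprintf("\nOne-way ANOVA: F(%g, %g) = %.3f, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$f,
              x$anova$p_value))
  cat("\nGames-Howell pairwise comparisons:\n")
  print(as.data.frame(x$pairwise), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname summarize_cohort
#' @param x An `amwf_comparison` object.
#' @param ... Unused.
#' @export
tidy.amwf_comparison <- function(x, ...) x$pairwise

#' @rdname summarize_cohort
#' @export
glance.amwf_comparison <- function(x, ...) x$anova

#' Write a comparison report to CSV files
#'
#' Writes `<stem>_groups.csv`, `<stem>_anova.csv` and `<stem>_pairwise.csv`.
#'
#' @param report An `amwf_comparison`.
#' @param stem Output path stem.
#' @return The three paths, invisibly.
#' @export
write_comparison <- function(report, stem) {
  stopifnot(inherits(report, "amwf_comparison"))
  paths <- paste0(stem, c("_groups.csv", "_anova.csv", "_pairwise.csv"))
  readr::write_csv(report$groups, paths[1])
  readr::write_csv(report$anova, paths[2])
  readr::write_csv(report$pairwise, paths[3])
  invisible(paths)
}
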