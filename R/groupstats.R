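# Group statistics: one-way fixed-effects ANOVA (from raw values or from
# printed summary statistics) and Tukey's HSD (Tukey-Kramer for unequal n).

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    abort_domain("need a list of >= 2 groups")
  ns <- vapply(groups, length, 1L)
  if (any(ns < 2L)) abort_domain("every group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  vars <- vapply(groups, stats::var, 1)
  if (sum((ns - 1) * vars) <= 0)
    abort_domain("pooled within-group variance is zero; ",
                 "ANOVA is undefined for constant groups")
  groups
}

.anova_result <- function(F_stat, df_between, df_within, alpha) {
  p <- stats::pf(F_stat, df_between, df_within, lower.tail = FALSE)
  structure(list(F = F_stat, df_between = df_between, df_within = df_within,
                 p_value = p, alpha = alpha, significant = p < alpha),
            class = "anova_result")
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way analysis of variance on raw measurements,
#' `F = MS_between / MS_within` against the F distribution with
#' `(k - 1, N - k)` degrees of freedom. Delegates the fit to
#' [stats::oneway.test()] with `var.equal = TRUE`.
#'
#' @param groups named list of numeric vectors, one per experimental group
#'   (`>= 2` groups, each `n >= 2`, pooled within-group variance `> 0`).
#' @param alpha significance level (default 0.05).
#' @return an object of class `anova_result` with fields `F`, `df_between`,
#'   `df_within`, `p_value`, `alpha`, `significant`.
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  groups <- .check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  .anova_result(unname(fit$statistic), unname(fit$parameter[1]),
                unname(fit$parameter[2]), alpha)
}

#' One-way ANOVA from group summary statistics
#'
#' Recomputes the one-way ANOVA from per-group `(n, mean, sd)` alone, using
#' the sums-of-squares identities
#' `SS_between = sum n_i (mean_i - grand_mean)^2` and
#' `SS_within = sum (n_i - 1) sd_i^2`. Agrees exactly with [anova_oneway()]
#' on any raw data having those summaries, and makes published group tables
#' re-testable without the raw measurements.
#'
#' @param summaries data frame (or list coercible to one) with columns
#'   `label`, `n`, `mean`, `sd`.
#' @param alpha significance level (default 0.05).
#' @return an object of class `anova_result`.
#' @examples
#' # heart rates 7 days after irradiation: control, dorsal, ventral groups
#' day7 <- data.frame(label = c("control", "DR", "VR"),
#'                    n = c(6, 6, 4),
#'                    mean = c(171, 172, 170),
#'                    sd = c(7.78, 6.99, 6.47))
#' anova_from_summary(day7)
#' @export
anova_from_summary <- function(summaries, alpha = 0.05) {
  summaries <- as.data.frame(summaries)
  req <- c("n", "mean", "sd")
  if (!all(req %in% names(summaries)))
    abort_domain("summaries must have columns n, mean, sd")
  n <- summaries$n; m <- summaries$mean; s <- summaries$sd
  if (length(n) < 2L) abort_domain("need >= 2 groups")
  if (any(n < 2)) abort_domain("every group needs n >= 2")
  if (any(s < 0)) abort_domain("sd must be >= 0")
  N <- sum(n); k <- length(n)
  ss_within <- sum((n - 1) * s^2)
  if (ss_within <= 0)
    abort_domain("pooled within-group variance is zero; ",
                 "ANOVA is undefined for all-zero sds")
  grand <- sum(n * m) / N
  ss_between <- sum(n * (m - grand)^2)
  F_stat <- (ss_between / (k - 1)) / (ss_within / (N - k))
  .anova_result(F_stat, k - 1, N - k, alpha)
}

#' Tukey's honestly-significant-difference test
#'
#' All-pairs comparisons after a one-way ANOVA, with the Tukey-Kramer
#' standard error for unequal group sizes:
#' `q_ij = |mean_i - mean_j| / sqrt(MS_within / 2 * (1/n_i + 1/n_j))`,
#' with adjusted p-values from the studentized-range distribution with
#' `(k, N - k)` degrees of freedom. Adjusted p-values are taken from
#' [stats::TukeyHSD()]; the q statistics are reported alongside.
#'
#' @param groups named list of numeric vectors (as in [anova_oneway()]).
#' @param alpha family-wise significance level (default 0.05).
#' @return an object of class `tukey_result`: a data frame with one row per
#'   unordered pair and columns `group1`, `group2`, `diff`, `q`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- .check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)))
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  N <- sum(ns); k <- length(groups)
  msw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1)) / (N - k)
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  g1 <- vapply(pairs, `[`, "", 1L)
  g2 <- vapply(pairs, `[`, "", 2L)
  se <- sqrt(msw / 2 * (1 / ns[g1] + 1 / ns[g2]))
  q <- abs(means[g1] - means[g2]) / se
  out <- data.frame(group1 = g1, group2 = g2,
                    diff = unname(tk[, "diff"]),
                    q = unname(q),
                    p_adj = unname(tk[, "p adj"]),
                    significant = unname(tk[, "p adj"]) < alpha,
                    row.names = NULL)
  structure(out, class = c("tukey_result", "data.frame"))
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g (%s at alpha = %g)\n",
              x$df_between, x$df_within, x$F, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}
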