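#' Normality-gated group comparison
#'
#' Implements the group-comparison decision tree used throughout the
#' figure-level analyses: each group's values are tested for normality
#' with a one-sample Kolmogorov-Smirnov test against a normal distribution
#' with estimated mean and SD (the Lilliefors-corrected variant is
#' available via `lilliefors = TRUE`; the plain estimated-parameter KS is
#' anti-conservative and both options are documented for that reason). If
#' every group passes at `alpha`, the parametric branch is taken — one-way
#' ANOVA with Tukey post hoc pairwise comparisons for three or more
#' groups, a t test for two; otherwise the non-parametric branch —
#' Kruskal-Wallis for three or more groups, Mann-Whitney (Wilcoxon rank
#' sum) for two. Pairwise post hoc results are produced only on the
#' parametric >= 3-group branch. A constant-valued group forces the
#' non-parametric branch with a warning.
#'
#' No multiple-testing correction is applied across features by default;
#' `p_adjust = "holm"` is available for users who want one.
#'
#' @param table A [cohort_table()].
#' @param feature Name of the feature column to compare.
#' @param alpha Significance level for the normality gate.
#' @param lilliefors Use `nortest::lillie.test()` instead of the
#'   estimated-parameter KS test.
#' @param p_adjust Adjustment method for pairwise p values (`"none"` or
#'   any [stats::p.adjust.methods] entry).
#' @return A `group_comparison`: `feature`, `groups`, `normal_per_group`,
#'   `branch` (`"anova_tukey"`, `"kruskal_wallis"`, `"t_test"`,
#'   `"mann_whitney"`), `statistic`, `p_value`, `pairwise` (data.frame or
#'   `NULL`), `stars`.
#' @export
compare_groups <- function(table, feature, alpha = 0.05,
                           lilliefors = FALSE, p_adjust = "none") {
  stopifnot(inherits(table, "cohort_table"))
  if (!feature %in% names(table)) stop("no such feature: ", feature)
  groups <- attr(table, "groups")
  vals <- lapply(groups, function(g) {
    x <- table[[feature]][table$group == g]
    x[is.finite(x)]
  })
  names(vals) <- groups
  vals <- vals[lengths(vals) > 0L]
  if (length(vals) < 2L) stop("need >= 2 non-empty groups")
  if (any(lengths(vals) < 3L)) stop("need >= 3 values per group")

  constant <- vapply(vals, function(x) stats::sd(x) == 0, logical(1))
  normal <- logical(length(vals))
  for (i in seq_along(vals)) {
    x <- vals[[i]]
    if (constant[i]) {
      normal[i] <- FALSE
      next
    }
    p <- if (lilliefors) {
      if (!requireNamespace("nortest", quietly = TRUE))
        stop("lilliefors = TRUE needs the 'nortest' package")
      nortest::lillie.test(x)$p.value
    } else {
      suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    }
    normal[i] <- p >= alpha
  }
  if (any(constant))
    warning("constant-valued group(s) ",
            paste(names(vals)[constant], collapse = ", "),
            ": non-parametric branch forced")
  parametric <- all(normal)
  k <- length(vals)
  x <- unlist(vals, use.names = FALSE)
  g <- factor(rep(names(vals), lengths(vals)), levels = names(vals))
  pairwise <- NULL
  if (parametric && k >= 3L) {
    branch <- "anova_tukey"
    fit <- stats::aov(x ~ g)
    s <- summary(fit)[[1L]]
    statistic <- s[["F value"]][1L]
    p_value <- s[["Pr(>F)"]][1L]
    tk <- stats::TukeyHSD(fit)$g
    pairwise <- data.frame(comparison = rownames(tk),
                           diff = tk[, "diff"],
                           p_value = stats::p.adjust(tk[, "p adj"], p_adjust),
                           row.names = NULL)
  } else if (parametric) {
    branch <- "t_test"
    ht <- stats::t.test(vals[[1L]], vals[[2L]], var.equal = TRUE)
    statistic <- unname(ht$statistic); p_value <- ht$p.value
  } else if (k >= 3L) {
    branch <- "kruskal_wallis"
    ht <- stats::kruskal.test(x, g)
    statistic <- unname(ht$statistic); p_value <- ht$p.value
  } else {
    branch <- "mann_whitney"
    ht <- suppressWarnings(stats::wilcox.test(vals[[1L]], vals[[2L]]))
    statistic <- unname(ht$statistic); p_value <- ht$p.value
  }
  structure(list(feature = feature, groups = names(vals),
                 n_per_group = lengths(vals),
                 normal_per_group = stats::setNames(normal, names(vals)),
                 branch = branch, statistic = statistic, p_value = p_value,
                 pairwise = pairwise, alpha = alpha,
                 stars = significance_stars(p_value)),
            class = "group_comparison")
}

#' Significance stars for a p value
#'
#' Figure-legend convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, `ns` otherwise.
#'
#' @param p P value(s).
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) NA_character_
    else if (pp < 1e-4) "****"
    else if (pp < 1e-3) "***"
    else if (pp < 1e-2) "**"
    else if (pp < 0.05) "*"
    else "ns"
  }, character(1))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> '%s' across %d groups: %s, p = %.4g %s\n",
              x$feature, length(x$groups), x$branch, x$p_value, x$stars))
  cat("  normality gate:",
      paste(sprintf("%s=%s", names(x$normal_per_group),
                    ifelse(x$normal_per_group, "normal", "non-normal")),
            collapse = ", "), "\n")
  if (!is.null(x$pairwise)) {
    cat("  Tukey pairwise:\n")
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %-25s diff %+.3g  p = %.4g %s\n",
                  x$pairwise$comparison[i], x$pairwise$diff[i],
                  x$pairwise$p_value[i],
                  significance_stars(x$pairwise$p_value[i])))
  }
  invisible(x)
}
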