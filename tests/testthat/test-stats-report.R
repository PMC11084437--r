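mk_tab <- function(...) {
  gs <- list(...)
  cohort_table(data.frame(
    group = rep(names(gs), lengths(gs)),
    value = unlist(gs, use.names = FALSE)))
}

test_that("identical groups are not significant", {
  set.seed(21)
  x <- rnorm(30)
  r <- compare_groups(mk_tab(a = x, b = x), "value")
  expect_gt(r$p_value, 0.9)
})

test_that("a 3-SD mean shift is detected on the parametric branch", {
  set.seed(22)
  tab <- mk_tab(a = rnorm(30), b = rnorm(30), c = rnorm(30, mean = 3))
  r <- compare_groups(tab, "value")
  expect_equal(r$branch, "anova_tukey")
  expect_lt(r$p_value, 1e-6)
  pw <- r$pairwise
  expect_lt(pw$p_value[pw$comparison == "c-a"], 0.001)
  expect_gt(pw$p_value[pw$comparison == "b-a"], 0.05)
})

test_that("heavily skewed data selects the non-parametric branch", {
  set.seed(23)
  tab <- mk_tab(a = exp(rnorm(40, sd = 2)), b = exp(rnorm(40, sd = 2)),
                c = exp(rnorm(40, sd = 2)))
  r <- compare_groups(tab, "value")
  expect_equal(r$branch, "kruskal_wallis")
  expect_null(r$pairwise)
})

test_that("two-group comparisons use t / Mann-Whitney per normality", {
  set.seed(24)
  rn <- compare_groups(mk_tab(a = rnorm(25), b = rnorm(25, 1)), "value")
  expect_equal(rn$branch, "t_test")
  rs <- compare_groups(mk_tab(a = exp(rnorm(40, sd = 2)),
                              b = exp(rnorm(40, sd = 2))), "value")
  expect_equal(rs$branch, "mann_whitney")
})

test_that("constant groups force the non-parametric branch with a warning", {
  set.seed(25)
  expect_warning(r <- compare_groups(mk_tab(a = rep(1, 5), b = rnorm(5)),
                                     "value"),
                 "constant")
  expect_equal(r$branch, "mann_whitney")
})

test_that("significance stars map the figure-legend convention", {
  expect_equal(significance_stars(c(0.2, 0.03, 0.005, 5e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("the branch decision is deterministic given the data", {
  set.seed(26)
  tab <- mk_tab(a = rnorm(20), b = rnorm(20))
  r1 <- compare_groups(tab, "value")
  r2 <- compare_groups(tab, "value")
  expect_identical(r1$branch, r2$branch)
  expect_identical(r1$p_value, r2$p_value)
})
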