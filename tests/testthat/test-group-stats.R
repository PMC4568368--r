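test_that("percent difference and its reciprocal identity", {
  expect_equal(percent_difference(454.1, 284.5), 100 * 169.6 / 284.5)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(1, 0), "positive")
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    d_ab <- percent_difference(a, b)
    d_ba <- percent_difference(b, a)
    expect_equal((1 + d_ab / 100) * (1 + d_ba / 100), 1)
  }
})

test_that("percent-difference table truncates to the reported two decimals", {
  ref <- reference_group_summaries()
  tab <- percent_difference_table(ref[ref$quantity == "vv_collagen_pct", ])
  get <- function(a, b) tab$pct_diff_2dp[tab$group_a == a & tab$group_b == b]
  expect_equal(get("hp5", "control"), 54.21)   # truncated, not rounded (54.2194)
  expect_equal(get("hp10", "gel_base"), 54.46)
})

test_that("exact Mann-Whitney agrees with the closed-form null distribution", {
  # tie-free oracles: pwilcox / exact wilcox.test, independent of the
  # in-package enumeration
  set.seed(9)
  for (sizes in list(c(2, 2), c(2, 3), c(3, 3), c(3, 4), c(4, 4))) {
    for (rep in 1:3) {
      pool <- sample(seq_len(40), sum(sizes))
      x <- pool[seq_len(sizes[1])]
      y <- pool[-seq_len(sizes[1])]
      mine <- mann_whitney_u(x, y, exact = TRUE)
      expect_equal(mine$statistic, unname(wilcox.test(x, y)$statistic))
      expect_equal(mine$p_value,
                   wilcox.test(x, y, exact = TRUE)$p.value)
      expect_equal(mann_whitney_u(x, y, alternative = "less", exact = TRUE)$p_value,
                   unname(pwilcox(mine$statistic, sizes[1], sizes[2])))
    }
  }
})

test_that("U = 0 for fully separated triples gives exact one-sided p = 0.05", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less",
                        exact = TRUE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 20)
})

test_that("exact path is symmetric and tie-safe", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 5)
  expect_equal(mann_whitney_u(x, y, exact = TRUE)$p_value,
               mann_whitney_u(y, x, exact = TRUE)$p_value)
  expect_equal(mann_whitney_u(x, y, exact = TRUE)$statistic +
                 mann_whitney_u(y, x, exact = TRUE)$statistic, 16)
  same <- rep(2, 4)
  expect_equal(mann_whitney_u(same, same, exact = TRUE)$p_value, 1)
})

test_that("compare_groups wires omnibus and pairwise tests together", {
  d <- tibble::tibble(
    g = factor(rep(c("lo", "hi"), each = 3), levels = c("lo", "hi")),
    y = c(1, 2, 3, 4, 5, 6)
  )
  cmp <- compare_groups(d, y, g)
  pw <- tidy(cmp)
  expect_equal(pw$group_a, "hi")
  expect_equal(pw$group_b, "lo")
  expect_equal(pw$u_statistic, 9)      # U for the comparison group
  expect_equal(pw$p_value, 0.1)        # two-sided exact
  expect_equal(pw$percent_difference, 150)
  expect_s3_class(glance(cmp), "tbl_df")

  allsame <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = 1)
  expect_equal(glance(compare_groups(allsame, y, g))$statistic, 0)

  tiny <- tibble::tibble(g = c("a", "a", "b"), y = 1:3)
  expect_error(compare_groups(tiny, y, g), "n >= 2")
  onegrp <- tibble::tibble(g = rep("a", 4), y = 1:4)
  expect_error(compare_groups(onegrp, y, g), "two groups")
})

test_that("study-style report formats cells and stars treated groups", {
  set.seed(14)
  est <- tibble::tibble(
    group = factor(rep(c("control", "gel_base", "hp5"), each = 8),
                   levels = c("control", "gel_base", "hp5")),
    nv_fibroblast = c(rnorm(8, 280, 10), rnorm(8, 235, 10), rnorm(8, 450, 15)),
    vv_collagen_pct = c(rnorm(8, 47, 2), rnorm(8, 48, 2), rnorm(8, 73, 3))
  )
  rep1 <- suppressWarnings(table1_report(est))
  s <- tidy(rep1)
  expect_true(all(s$star[s$group == "hp5"]))
  expect_false(any(s$star[s$group %in% c("control", "gel_base")]))
  expect_match(s$label[s$group == "hp5" & s$quantity == "nv_fibroblast"],
               "^\\d+\\.\\d \\(\\d+\\.\\d\\) \\*$")
  md <- table1_markdown(rep1)
  expect_match(md[1], "^\\| Group")
  expect_s3_class(autoplot(rep1), "ggplot")

  # single group: table renders without stars or comparisons
  solo <- est[est$group == "control", ]
  rep2 <- suppressWarnings(table1_report(solo))
  expect_false(any(rep2$summary$star))
})

test_that("missing quantities are warned about and left blank", {
  est <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                        nv_fibroblast = rnorm(6, 300, 10))
  expect_warning(rep1 <- table1_report(est), "absent")
  expect_true("vv_collagen_pct" %in% names(rep1$wide))
  expect_true(all(rep1$wide$vv_collagen_pct == ""))
})

test_that("report cells recover the generating group means", {
  ref <- reference_group_summaries()
  set.seed(15)
  nv <- ref[ref$quantity == "nv_fibroblast", ]
  est <- purrr::pmap(nv, function(group, n, mean, sd, ...) {
    tibble::tibble(group = group, nv_fibroblast = rnorm(n, mean, sd))
  }) |> purrr::list_rbind()
  rep1 <- suppressWarnings(table1_report(est, quantities = "nv_fibroblast"))
  s <- dplyr::inner_join(tidy(rep1), nv, by = "group",
                         suffix = c("_est", "_ref"))
  expect_true(all(abs(s$mean_est - s$mean_ref) <
                    3 * s$sd_ref / sqrt(s$n_est)))
})

test_that("reference summaries and default tissue groups are well formed", {
  ref <- reference_group_summaries()
  expect_setequal(unique(ref$group), c("control", "hp5", "hp10", "gel_base"))
  expect_equal(nrow(ref), 24)
  g <- default_group_tissue()
  expect_equal(g$nv_mean[g$group == "control"], 284.5e3)
  expect_equal(g$vv_collagen_mean[g$group == "hp10"], 0.743)
})
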