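test_that("summarize_values reports mean and n-1 SD", {
  s <- summarize_values(c(2, 4))
  expect_equal(s$mean, 3); expect_equal(s$sd, sqrt(2))
  expect_equal(summarize_values(c(5, 5, 5))$sd, 0)
  s2 <- summarize_values(1:5)
  expect_equal(s2$mean, 3)
  expect_equal(s2$sd, 1.5811388, tolerance = 1e-6)
  expect_error(summarize_values(3), ">= 2")
})

test_that("Grubbs' test flags the known single outlier at n = 5", {
  g <- grubbs_test(c(1, 2, 3, 4, 100), alpha = 0.05)
  # G = 78 / 43.61709 (mean 22, sample SD), critical value from the
  # t-quantile formula; 1.715 is the published table value for n = 5
  expect_equal(g$G, 78 / sd(c(1, 2, 3, 4, 100)), tolerance = 1e-12)
  expect_equal(g$G, 1.78829, tolerance = 1e-4)
  expect_equal(g$G_critical, 1.71504, tolerance = 1e-4)
  expect_equal(g$outlier_index, 5L)
  expect_equal(g$outlier_value, 100)

  g2 <- grubbs_test(c(1, 2, 3, 4, 5))
  expect_true(is.na(g2$outlier_index))
  expect_equal(g2$G, 2 / sqrt(2.5), tolerance = 1e-12)

  expect_error(grubbs_test(c(1, 2)), "n >= 3")
  expect_warning(g3 <- grubbs_test(c(4, 4, 4, 4)), "equal")
  expect_true(is.na(g3$outlier_index))
})

test_that("Grubbs' null rejection rate is close to alpha", {
  set.seed(801)
  for (n in c(4, 5, 6)) {
    x <- matrix(stats::rnorm(4000 * n), 4000, n)
    mu <- rowMeans(x)
    s <- sqrt(rowSums((x - mu)^2) / (n - 1))
    G <- apply(abs(x - mu), 1, max) / s
    t <- stats::qt(1 - 0.05 / (2 * n), n - 2)
    Gcrit <- (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
    expect_lt(abs(mean(G > Gcrit) - 0.05), 0.015)
  }
})

test_that("Kruskal-Wallis reproduces hand-computed H and handles ties", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 3.857143, tolerance = 1e-6)  # 12/42*(12+75) - 21
  expect_equal(kw$df, 1)
  kw2 <- kruskal_wallis(c(1, 2, 1, 2), rep(c("a", "b"), each = 2))
  expect_equal(kw2$H, 0)
  expect_gt(kw2$p, 0.9)
  # degenerate pooled data
  kw3 <- kruskal_wallis(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw3$H, 0); expect_equal(kw3$p, 1)
})

test_that("Kruskal-Wallis H matches the tie-corrected rank formula oracle", {
  set.seed(802)
  for (rep in 1:10) {
    v <- sample(1:8, 12, replace = TRUE)  # plenty of ties
    g <- rep(c("a", "b", "c"), each = 4)
    if (length(unique(v)) == 1) next
    expect_equal(kruskal_wallis(v, g)$H, oracle_kw_H(v, g), tolerance = 1e-9)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(803)
  v <- stats::rnorm(15)
  g <- rep(c("a", "b", "c"), each = 5)
  h0 <- kruskal_wallis(v, g)$H
  expect_equal(kruskal_wallis(exp(v), g)$H, h0)
  expect_equal(kruskal_wallis(2 * v + 7, g)$H, h0)
})

test_that("chi-square p tracks the exact permutation p for 3x3 designs", {
  # the chi-square approximation at N = 9 is coarse in the mid-p range
  # (deviations up to ~0.1) but accurate where decisions are made; assert
  # +-0.05 agreement for permutation p <= 0.25 and a global 0.12 bound
  set.seed(804)
  shifts <- c(0, 0.5, 1, 2, 3, 4)
  for (s in shifts) {
    v <- stats::rnorm(9) + rep(c(0, s, 2 * s), each = 3)
    g <- rep(c("a", "b", "c"), each = 3)
    p_chisq <- kruskal_wallis(v, g)$p
    p_perm <- oracle_kw_perm_p_3x3(v)
    expect_lt(abs(p_chisq - p_perm), 0.12)
    if (p_perm <= 0.25) expect_lt(abs(p_chisq - p_perm), 0.05)
  }
  # the fully separated design hits the discrete floor of the permutation
  # distribution: p_perm = 6/1680
  v_sep <- c(1:3, 11:13, 21:23)
  expect_equal(oracle_kw_perm_p_3x3(v_sep), 6 / 1680)
  expect_lt(abs(kruskal_wallis(v_sep, rep(c("a", "b", "c"), each = 3))$p -
                  6 / 1680), 0.05)
})

test_that("Dunn's test follows the z formula and inflates adjusted p", {
  same <- data.frame(v = rep(c(1, 2, 3), 3), g = rep(c("Ctrl", "a", "b"), each = 3))
  d0 <- dunns_test(same$v, same$g, "Ctrl")
  expect_equal(d0$z, c(0, 0))
  expect_equal(d0$p_adjusted, c(1, 1))
  set.seed(805)
  v <- stats::rnorm(20)
  g <- rep(c("Ctrl", "1w", "3w", "5w"), each = 5)
  d <- dunns_test(v, g, "Ctrl")
  expect_equal(nrow(d), 3)
  expect_true(all(d$p_adjusted >= d$p_raw))
  expect_true(all(d$p_adjusted <= 1))
  expect_true(all(d$p_adjusted >= pmin(1, 3 * d$p_raw) - 1e-12))
  # hand-check one z under no ties: pooled variance N(N+1)/12
  r <- rank(v)
  mr <- tapply(r, g, mean)
  z_exp <- (mr[["1w"]] - mr[["Ctrl"]]) / sqrt(20 * 21 / 12 * (1 / 5 + 1 / 5))
  expect_equal(d$z[d$comparison == "1w vs Ctrl"], z_exp, tolerance = 1e-12)
  expect_error(dunns_test(v, g, "nope"), "not present")
})

test_that("separated ordered groups: extreme comparisons reject, adjacent cannot", {
  # with four perfectly separated ordered groups of 5, the mean-rank gap
  # between adjacent groups is exactly 5, capping the adjacent z at
  # 5 / sqrt(N(N+1)/12 * 2/5) = 1.336 (p = 0.18) no matter the effect size;
  # only the more distant comparisons can reach significance
  set.seed(806)
  res <- replicate(20, {
    v <- c(stats::rnorm(5, 0, 0.1), stats::rnorm(5, 5, 0.1),
           stats::rnorm(5, 10, 0.1), stats::rnorm(5, 15, 0.1))
    g <- rep(c("Ctrl", "1w", "3w", "5w"), each = 5)
    d <- dunns_test(v, g, "Ctrl")
    c(far = all(d$p_adjusted[d$comparison %in%
                               c("3w vs Ctrl", "5w vs Ctrl")] <= 0.05),
      near_z = d$z[d$comparison == "1w vs Ctrl"])
  })
  expect_equal(mean(res["far", ]), 1)
  expect_equal(unname(res["near_z", ]),
               rep(5 / sqrt(20 * 21 / 12 * 2 / 5), 20), tolerance = 1e-12)
})

test_that("significance symbols follow the inclusive cut-offs", {
  expect_equal(significance_symbol(0.04), "*")
  expect_equal(significance_symbol(0.001), "***")
  expect_equal(significance_symbol(0.01), "**")
  expect_equal(significance_symbol(0.05), "*")
  expect_equal(significance_symbol(0.2), "n.s.")
  expect_equal(significance_symbol(0.0001), "***")
  expect_error(significance_symbol(1.2), "\\[0, 1\\]")
  expect_error(significance_symbol(-0.1), "\\[0, 1\\]")
})

test_that("Grubbs screening applies to densitometry only", {
  d <- data.frame(
    group = rep(c("Ctrl", "1w"), each = 5),
    value = c(1, 2, 3, 4, 100, 2, 3, 4, 5, 6))
  res_pct <- run_group_analysis(d, "percent_area", control = "Ctrl")
  expect_equal(nrow(res_pct$excluded_outliers), 1)
  expect_equal(res_pct$excluded_outliers$value, 100)
  expect_equal(res_pct$summary$n[res_pct$summary$group == "Ctrl"], 4)
  res_ri <- run_group_analysis(d, "mean_ri", control = "Ctrl")
  expect_equal(nrow(res_ri$excluded_outliers), 0)
  expect_equal(res_ri$summary$n[res_ri$summary$group == "Ctrl"], 5)
})

test_that("identical groups come out non-significant everywhere", {
  d <- data.frame(group = rep(c("Ctrl", "1w", "3w", "5w"), each = 5),
                  value = rep(c(1, 2, 3, 4, 5), 4))
  res <- run_group_analysis(d, "mean_ri", control = "Ctrl")
  expect_gt(res$p_global, 0.9)
  expect_true(all(res$comparisons$symbol == "n.s."))
})
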