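test_that("rank-sum test: frozen exact case and enumeration oracle", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1)                  # 2 / choose(6,3) * ... = 2/20
  same <- wilcoxon_rank_sum(c(2, 5, 9), c(2, 5, 9))
  expect_gte(same$p, 0.99)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
  # exact path equals full enumeration on random tie-free inputs
  withr::with_seed(8, {
    for (rep in 1:40) {
      m <- sample(1:6, 1L); n <- sample(1:6, 1L)
      v <- sample(seq(0.01, 1, by = 0.01), m + n)   # distinct values
      x <- v[seq_len(m)]; y <- v[-seq_len(m)]
      expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_enum_p(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("Fisher 2x2: frozen cases, enumeration and library cross-checks", {
  res <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p, 1)
  res <- fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))
  expect_equal(res$p, 0.1)                  # 2 * 1/20
  expect_equal(res$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 3), 2)), "non-negative")
  withr::with_seed(17, {
    for (rep in 1:60) {
      tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
      if (sum(tab) == 0) next
      res <- fisher_exact_2x2(tab)
      expect_equal(res$p, fisher_enum_p(tab), tolerance = 1e-12)
      expect_equal(res$p, stats::fisher.test(tab)$p.value,
                   tolerance = 1e-7)
    }
  })
})

test_that("product-limit estimator matches hand computation", {
  # no events: survival stays at 1
  km <- km_estimate(c(3, 6, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(km$surv == 1))
  expect_true(is.na(attr(km, "median")))
  # n = 4, one death at t = 2: S(2) = 3/4
  km <- km_estimate(c(2, 5, 7, 9), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(km$surv[km$time == 2], 0.75)
  # mixed events and censoring, hand-computed risk-set products:
  # death at 1 (risk 5) -> 4/5; death at 3 (risk 3) -> 8/15;
  # death at 4 (risk 2) -> 4/15
  km <- km_estimate(c(1, 2, 3, 4, 5),
                    c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(km$surv, c(4 / 5, 4 / 5, 8 / 15, 4 / 15, 4 / 15))
  expect_equal(attr(km, "median"), 4)       # first time with S <= 0.5
  expect_true(all(diff(km$surv) <= 0))      # monotone non-increasing
  expect_error(km_estimate(c(0, 1), c(TRUE, TRUE)), "positive")
})

test_that("product-limit estimator agrees with survival::survfit", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      n <- sample(5:40, 1L)
      time <- round(rexp(n, 0.1), 2) + 0.01
      event <- runif(n) < 0.7
      if (!any(event)) event[1] <- TRUE
      km <- km_estimate(time, event)
      sf <- survival::survfit(survival::Surv(time, event) ~ 1)
      expect_equal(km$surv, summary(sf, times = km$time)$surv,
                   tolerance = 1e-12)
    }
  })
})

test_that("log-rank test matches hand O/E/V tabulation and survdiff", {
  # identical groups: statistic 0, p 1
  res <- logrank_test(c(1, 2, 3), c(TRUE, TRUE, FALSE),
                      c(1, 2, 3), c(TRUE, TRUE, FALSE))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # constructed case: A = {(1,E),(2,C)}, B = {(1,E),(3,E)}
  # t=1: n1=2,n2=2,d=2,o1=1,E1=1,V=2*(1/2)(1/2)(2)/3=1/3
  # t=3: n1=0,n2=1,d=1,o1=0,E1=0,V=0
  res <- logrank_test(c(1, 2), c(TRUE, FALSE), c(1, 3), c(TRUE, TRUE))
  expect_equal(res$observed, 1)
  expect_equal(res$expected, 1)
  expect_equal(res$statistic, 0)
  # group exchange leaves the statistic unchanged
  withr::with_seed(29, {
    for (rep in 1:15) {
      na <- sample(5:30, 1L); nb <- sample(5:30, 1L)
      ta <- round(rexp(na, 0.1), 1) + 0.1; tb <- round(rexp(nb, 0.2), 1) + 0.1
      ea <- runif(na) < 0.8; eb <- runif(nb) < 0.8
      if (!any(c(ea, eb))) ea[1] <- TRUE
      r1 <- logrank_test(ta, ea, tb, eb)
      r2 <- logrank_test(tb, eb, ta, ea)
      expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
      sd <- survival::survdiff(
        survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, c(na, nb)))
      expect_equal(r1$statistic, sd$chisq, tolerance = 1e-8)
    }
  })
  expect_error(logrank_test(c(1, 2), c(FALSE, FALSE), c(3), c(FALSE)),
               "zero events")
})

test_that("expression dichotomization uses strict 'below cutoff' for low", {
  g <- dichotomize_expression(c(a = 7, b = 9), "mean")
  expect_equal(g$cutoff, 8)
  expect_equal(unname(g$labels), c("low", "high"))
  # a value exactly at the fixed cutoff is high
  g <- dichotomize_expression(c(a = 7.8, b = 5), "fixed", fixed_cutoff = 7.8)
  expect_equal(g$labels[["a"]], "high")
  expect_equal(g$labels[["b"]], "low")
  # all equal values under mean mode: everything is high
  g <- dichotomize_expression(c(a = 4, b = 4, c = 4), "mean")
  expect_true(all(g$labels == "high"))
})

test_that("combined low/low group requires low in both genes", {
  la <- c(s1 = "low", s2 = "low", s3 = "high")
  lb <- c(s1 = "low", s2 = "high", s3 = "high")
  cmb <- combined_low_group(la, lb)
  expect_equal(unname(cmb), c("low/low", "other", "other"))
  expect_error(combined_low_group(la, lb[1:2]), "s3")
})

test_that("survival separates expression groups under a planted hazard", {
  tab <- simulate_tcga_like_tables(simulation_config(seed = 41))
  clin <- tab$clinical
  expr <- tab$expression["CNTNAP2", clin$case_id]
  res <- survival_by_expression(expr,
                                stats::setNames(clin$time_months,
                                                clin$case_id),
                                stats::setNames(clin$event, clin$case_id),
                                "mean")
  expect_lt(res$p, 0.001)
  med_high <- if (is.na(res$median_high)) Inf else res$median_high
  expect_lt(res$median_low, med_high)
})
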