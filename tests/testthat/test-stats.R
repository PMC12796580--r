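test_that("within-subject ANOVA matches the independent sums-of-squares oracle", {
  fx <- build_fixture("anova_2x2_hand")
  res <- two_way_rm_anova(fx$data, design = "both_within")

  # against the frozen hand-computed fixture values
  ex <- fx$expected
  eff <- res$effects
  expect_equal(eff$ss[eff$effect == "row"], ex$row$ss, tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "row"], ex$row$F, tolerance = 1e-9)
  expect_equal(eff$p[eff$effect == "row"], ex$row$p, tolerance = 1e-6)
  expect_equal(eff$ss[eff$effect == "col"], ex$col$ss, tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "col"], ex$col$F, tolerance = 1e-9)
  expect_equal(eff$ss[eff$effect == "row:col"], ex$interaction$ss,
               tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "row:col"], ex$interaction$F,
               tolerance = 1e-9)
  expect_equal(res$total_ss, ex$total_ss, tolerance = 1e-12)

  # against the in-test brute-force marginal-mean arithmetic
  bf <- brute_force_rm_ss(fx$data)
  expect_equal(eff$F[eff$effect == "row"], bf$F_row, tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "col"], bf$F_col, tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "row:col"], bf$F_int, tolerance = 1e-9)

  # decomposition conserves total SS
  expect_equal(sum(res$strata$ss), res$total_ss, tolerance = 1e-9)
  # df consistency for within effects: df_error = df_effect x (n_subj - 1)
  expect_true(all(eff$df_error == eff$df * 3))
})

test_that("a table with no condition variance has zero effect SS", {
  tab <- expand.grid(subject = paste0("S", 1:4), row = c("a", "b"),
                     col = c("c", "d"))
  tab$value <- as.numeric(factor(tab$subject))  # varies by subject only
  res <- two_way_rm_anova(tab)
  expect_true(all(res$effects$ss < 1e-20))
})

test_that("degenerate and malformed ANOVA inputs are rejected", {
  fx <- build_fixture("anova_2x2_hand")
  expect_error(two_way_rm_anova(fx$data[fx$data$subject == "S1", ]),
               "at least 2 subjects")
  expect_error(two_way_rm_anova(fx$data[-1, ]), "one observation")
})

test_that("the mixed design tests the column factor between subjects", {
  withr::with_seed(5, {
    tab <- expand.grid(subject = paste0("S", 1:8), row = c("a", "b"))
    tab$col <- ifelse(tab$subject %in% paste0("S", 1:4), "g1", "g2")
    tab$value <- rnorm(nrow(tab))
  })
  res <- two_way_rm_anova(tab, design = "mixed")
  eff <- res$effects
  # col tested against the between-subject stratum: df = n_subj - 2
  expect_equal(eff$df_error[eff$effect == "col"], 6)
  expect_equal(eff$df_error[eff$effect == "row"], 6)
  expect_equal(sum(res$strata$ss), res$total_ss, tolerance = 1e-9)
})

test_that("Bonferroni adjustment multiplies, caps at one, and is idempotent at m = 1", {
  fx <- build_fixture("bonferroni_cases")
  for (i in seq_len(nrow(fx$data))) {
    expect_equal(bonferroni_adjust(fx$data$p[i], fx$data$m[i]),
                 fx$data$expected[i])
  }
  p <- c(0.001, 0.04, 0.2)
  expect_equal(bonferroni_adjust(p, 1), p)
  # monotone in p
  expect_true(all(diff(bonferroni_adjust(sort(runif(20)), 3)) >= 0))
  expect_error(bonferroni_adjust(1.2, 2), "input error")
  expect_error(bonferroni_adjust(0.5, 0), "input error")
})

test_that("ROUT flags a gross contaminant and nothing else", {
  fx <- build_fixture("rout_contaminant")
  v <- fx$data$value
  mask <- rout_outliers(v, Q = 1)
  expect_equal(which(mask), which(v == 100))
  # tightly clustered values: no outliers
  expect_false(any(rout_outliers(c(10.01, 10.02, 10.00, 9.99, 10.03))))
  expect_error(rout_outliers(c(1, 2)), "input error")
})

test_that("ROUT flags are invariant under affine rescaling", {
  fx <- build_fixture("rout_contaminant")
  v <- fx$data$value
  base <- rout_outliers(v, Q = 1)
  for (sc in list(c(3, 0), c(0.02, -7), c(-5, 100))) {
    expect_identical(rout_outliers(sc[1] * v + sc[2], Q = 1), base)
  }
})

test_that("smaller Q never flags more points", {
  withr::with_seed(8, v <- c(rnorm(40), 6, 9, 15))
  flags <- vapply(c(0.1, 0.5, 1, 2, 5, 10), function(q)
    sum(rout_outliers(v, Q = q)), numeric(1))
  expect_true(all(diff(flags) >= 0))
})

test_that("t tests match hand arithmetic and honor degenerate conventions", {
  x <- c(10, 12, 9, 11, 13)
  y <- c(8, 11, 9, 10, 12)
  res <- t_tests(x, y, "paired")
  # oracle: direct arithmetic on the differences
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # cross-check against the reference implementation
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)

  expect_equal(t_tests(x, x, "paired")[c("t", "p")], list(t = 0, p = 1))
  expect_equal(t_tests(c(-2, -1, 1, 2), mode = "one_sample")$t, 0)
  un <- t_tests(x, y, "unpaired")
  ref_un <- t.test(x, y, var.equal = TRUE)
  expect_equal(un$t, unname(ref_un$statistic), tolerance = 1e-12)
  expect_equal(un$df, 8)
})

test_that("linear-trend contrasts detect ordered means and match direct computation", {
  eq <- linear_trend_contrast(list(c(1, 2, 3), c(1.5, 2, 2.5), c(2, 2, 2)))
  expect_equal(eq$estimate, 0)

  withr::with_seed(3, {
    tr <- linear_trend_contrast(list(rnorm(20, 1, 1e-3), rnorm(20, 2, 1e-3),
                                     rnorm(20, 3, 1e-3)))
  })
  expect_lt(tr$p, 1e-3)

  # 3-group hand-built table against the direct contrast formula
  g <- list(c(4, 5, 6, 7), c(6, 7, 8), c(9, 10, 11, 12, 13))
  res <- linear_trend_contrast(g)
  cc <- c(-1, 0, 1)
  means <- vapply(g, mean, numeric(1))
  L <- sum(cc * means)
  msw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1))) /
    (sum(lengths(g)) - 3)
  t_hand <- L / sqrt(msw * sum(cc^2 / lengths(g)))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$F, t_hand^2, tolerance = 1e-12)
  expect_error(linear_trend_contrast(list(1:3, 4:6)), "input error")
})

test_that("type-I error of the within-subject column test sits at the nominal level", {
  # 300-replicate null simulation on a small balanced design
  withr::with_seed(44, {
    rej <- vapply(1:300, function(i) {
      tab <- expand.grid(subject = paste0("S", 1:6), row = c("a", "b"),
                         col = c("c", "d"))
      tab$value <- rnorm(nrow(tab)) +
        rep(rnorm(6), times = 4)       # subject offsets
      res <- two_way_rm_anova(tab)
      res$effects$p[res$effects$effect == "col"] < 0.05
    }, logical(1))
  })
  # 99% binomial band around 0.05 at 300 replicates
  expect_gte(mean(rej), 0.05 - 2.58 * sqrt(0.05 * 0.95 / 300))
  expect_lte(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 300))
})
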