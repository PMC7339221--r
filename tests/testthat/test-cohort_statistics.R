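test_that("stage categorisers are total on their domains and reject the rest", {
  expect_identical(as.character(categorize_t(c(1, 2, 3, 4))),
                   c("T1-2", "T1-2", "T3-4", "T3-4"))
  expect_error(categorize_t(5), class = "ihc_validation_error")
  expect_identical(as.character(categorize_n(c(0, 1, 2))),
                   c("node_negative", "node_positive", "node_positive"))
  expect_error(categorize_n(-1), class = "ihc_validation_error")
  expect_identical(as.character(categorize_tnm(0:4)),
                   c("early", "early", "early", "advanced", "advanced"))
  expect_error(categorize_tnm(7), class = "ihc_validation_error")
})

test_that("compare_paired handles degenerate differences and matches enumeration", {
  x <- rep(5, 10)
  res <- compare_paired(x, x, method = "wilcoxon")
  expect_identical(res$statistic, 0)
  expect_identical(res$flag, "degenerate_all_zero")
  expect_true(is.na(res$p_value))

  y <- rnorm(20)
  res_t <- compare_paired(y + 10, y, method = "paired_t")
  expect_identical(res_t$flag, "degenerate_zero_variance")

  # exact signed-rank p matches full 2^n enumeration
  set.seed(41)
  for (n in c(8, 10, 12)) {
    a <- rnorm(n); b <- rnorm(n)
    got <- compare_paired(a, b, method = "wilcoxon")$p_value
    expect_equal(got, oracle_signed_rank_p(a, b), tolerance = 1e-12)
  }
  expect_error(compare_paired(1:2, 2:3), class = "ihc_insufficient_data_error")
})

test_that("compare_groups matches exact Mann-Whitney enumeration", {
  res <- compare_groups(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_identical(unname(res$statistic), 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)  # 2 * 1/20 arrangements

  # identical values in both groups: U = n1 n2 / 2
  same <- compare_groups(rep(c(4, 7, 9), 2), rep(c("a", "b"), each = 3))
  expect_equal(unname(same$statistic), 4.5)

  set.seed(43)
  for (rep_i in 1:3) {
    g1 <- rnorm(8); g2 <- rnorm(8)
    got <- compare_groups(c(g1, g2), rep(c("a", "b"), each = 8))$p_value
    expect_equal(got, oracle_mann_whitney_p(g1, g2), tolerance = 1e-12)
  }
  expect_error(compare_groups(1:5, c("a", "a", "b", "b", "b")),
               class = "ihc_insufficient_data_error")
})

test_that("roc_auc equals the all-pairs oracle and honours symmetries", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(47)
  for (rep_i in 1:5) {
    s <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)  # forces ties
    l <- rbinom(50, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_identical(roc_auc(s, l), oracle_auc(s, l))
    expect_equal(roc_auc(s, 1 - l), 1 - roc_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), class = "ihc_validation_error")
  # cross-check against an established ROC implementation
  set.seed(48)
  s <- rnorm(80); l <- rbinom(80, 1, 0.5)
  expect_equal(roc_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("logistic fit is null-calibrated, matches binormal AUC, flags separation", {
  set.seed(53)
  n <- 2000
  x_null <- rnorm(n)
  y_null <- rbinom(n, 1, 0.5)
  fit0 <- fit_logistic_auc(y_null, data.frame(x = x_null))
  expect_lt(abs(fit0$coefficients$estimate[2]), 0.15)
  expect_lt(abs(fit0$auc - 0.5), 0.03)

  y <- rbinom(n, 1, 0.5)
  x <- rnorm(n, mean = y)        # binormal, d = 1
  fit1 <- fit_logistic_auc(y, data.frame(x = x))
  expect_lt(abs(fit1$auc - pnorm(1 / sqrt(2))), 0.03)
  expect_false(fit1$separation)

  sep <- fit_logistic_auc(c(0, 0, 0, 1, 1, 1, 0, 1),
                          data.frame(x = c(1, 2, 3, 10, 11, 12, 1.5, 10.5)))
  expect_true(sep$separation)
  expect_error(fit_logistic_auc(rep(1, 10), data.frame(x = rnorm(10))),
               class = "ihc_validation_error")
})

test_that("Cox fit matches a 1-D grid-search oracle on a small tie-free toy", {
  # six subjects, events interleaved across both covariate groups so the
  # partial-likelihood maximiser is finite
  toy <- data.frame(time = c(2, 4, 6, 8, 10, 12),
                    event = c(1, 1, 1, 1, 0, 0),
                    x = c(1, 0, 1, 0, 1, 0))
  fit <- fit_cox(toy, "time", "event", "x")
  expect_equal(fit$table$log_hr,
               oracle_cox_grid(toy$time, toy$event, toy$x), tolerance = 1e-4)
  expect_identical(fit$flag, "low_events")
  expect_true(fit$table$ci_low <= fit$table$hr &&
              fit$table$hr <= fit$table$ci_high)
  expect_error(fit_cox(transform(toy, event = 0), "time", "event", "x"),
               class = "ihc_validation_error")
  expect_error(fit_cox(transform(toy, x = 1), "time", "event", "x"),
               class = "ihc_validation_error")
  expect_error(fit_cox(toy, "time", "event", "missing_col"),
               class = "ihc_validation_error")
})

test_that("Cox estimates are unbiased under the null on simulated cohorts", {
  set.seed(59)
  hrs <- replicate(40, {
    n <- 500
    x <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, 0.05)
    cens <- rexp(n, 0.02)
    d <- data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens),
                    x = x)
    fit_cox(d, "time", "event", "x")$table$hr
  })
  expect_gt(mean(hrs), 0.85)
  expect_lt(mean(hrs), 1.18)
})

test_that("run_full_analysis reports the planted paired direction and survives edge cases", {
  co <- gen_cohort(cohort_spec(seed = 2024))
  rep <- run_full_analysis(co)
  row <- rep$paired[rep$paired$x == "cxcr3_nuc_gland" &
                    rep$paired$y == "cxcr3_cyt_gland", ]
  expect_gt(row$mean_x, row$mean_y)
  expect_lt(row$p_value, 0.005)
  expect_identical(nrow(rep$paired), 12L)
  expect_identical(nrow(rep$groups), 60L)
  expect_setequal(unique(rep$cox$endpoint), c("OS", "DFS"))

  # one-patient cohort: everything flagged, nothing aborts
  tiny <- run_full_analysis(co[1, ])
  expect_true(all(tiny$paired$flag != "ok"))
  expect_true(all(tiny$groups$flag != "ok"))
  expect_true(all(is.na(tiny$cox$hr)))
})

test_that("validate_cohort names the first missing column", {
  co <- gen_cohort(cohort_spec(n_patients = 5, seed = 1))
  expect_silent(validate_cohort(co))
  bad <- co[, setdiff(names(co), "os_months")]
  expect_error(validate_cohort(bad), "os_months",
               class = "ihc_validation_error")
})
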