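test_that("Mann-Whitney matches its spec examples and the enumeration oracle", {
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  sep <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(sep$statistic), 0)
  expect_equal(sep$p_value, 0.1)
  expect_equal(sep$method, "exact")

  set.seed(5)
  for (i in 1:25) {
    a <- round(rnorm(sample(3:5, 1)), 6)
    b <- round(rnorm(sample(3:5, 1)) + runif(1, -1, 1), 6)
    expect_equal(mann_whitney_u(a, b)$p_value, mw_enum_p(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("separated log-normal groups are detected at p < 0.001", {
  # iRBD vs no-RBD lower-body short-movement rate calibration
  sdl_a <- log(63.73 / 32.93) / (2 * qnorm(0.75))
  sdl_b <- log(19.17 / 5.94) / (2 * qnorm(0.75))
  set.seed(17)
  hits <- vapply(1:100, function(i) {
    a <- rlnorm(53, log(44.12), sdl_a)
    b <- rlnorm(128, log(10.90), sdl_b)
    mann_whitney_u(a, b)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("signed-rank test is exact under ties and matches enumeration", {
  # constant shift: all |differences| tied, minimal one-sided statistic
  a <- 1:10
  w <- wilcoxon_signed_rank(a, a + 5)
  expect_equal(unname(w$statistic), 0)
  expect_equal(w$p_value, 2 / 1024)
  expect_equal(w$method, "exact")

  deg <- wilcoxon_signed_rank(a, a)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  set.seed(23)
  for (i in 1:25) {
    n <- sample(6:10, 1)
    x <- round(rnorm(n), 2)
    y <- round(x + rnorm(n, 0, 1), 2)
    if (all(x == y)) next
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$p_value, sr_enum_p(x, y), tolerance = 1e-12,
                 info = paste("case", i))
  }
  # without ties, the convolution agrees with R's exact distribution
  set.seed(29)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("signed-rank p-values are uniform under the null", {
  set.seed(41)
  ps <- vapply(1:400, function(i) {
    d <- rnorm(25)
    wilcoxon_signed_rank(d, numeric(25))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Benjamini-Hochberg follows the step-up definition", {
  r1 <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r1$reject))
  r2 <- benjamini_hochberg(c(0.9, 0.95), q = 0.05)
  expect_false(any(r2$reject))
  r3 <- benjamini_hochberg(0.049, q = 0.05)
  expect_true(r3$reject)
  expect_equal(r3$adjusted_p, 0.049)

  # step-up definition: adjusted_p = min over j >= i of m p_(j) / j
  p <- c(0.003, 0.04, 0.02, 0.3, 0.7)
  got <- benjamini_hochberg(p)$adjusted_p
  m <- length(p)
  ord <- order(p)
  manual <- vapply(seq_len(m), function(i) {
    min(1, min((m * p[ord][i:m] / (i:m))))
  }, numeric(1))
  expect_equal(got[ord], manual)
  # adjusted p-values are non-decreasing in rank order
  expect_equal(got[ord], cummax(got[ord]))
  for (q1 in c(0.01, 0.05, 0.1, 0.2)) {
    for (q2 in c(0.25, 0.5)) {
      expect_true(all(benjamini_hochberg(p, q1)$reject <=
                        benjamini_hochberg(p, q2)$reject))
    }
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman correlation matches the direct rank formula", {
  expect_equal(unname(spearman_corr(1:10, (1:10)^3)$statistic), 1.0)
  expect_equal(unname(spearman_corr(1:10, -(1:10)^2)$statistic), -1.0)

  x <- c(3.2, 1.5, 4.8, 2.2, 5.1)
  y <- c(0.4, 0.9, 0.1, 1.4, 0.2)
  got <- spearman_corr(x, y)
  want <- spearman_direct(x, y)
  expect_equal(unname(got$statistic), want$rho, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)

  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("demographic tables pick the right test per variable", {
  set.seed(61)
  rec <- data.frame(
    subject_id = sprintf("s%03d", 1:181),
    group = c(rep("iRBD", 53), rep("no-RBD", 128)),
    male = c(rep(TRUE, 45), rep(FALSE, 8), rep(TRUE, 79), rep(FALSE, 49)),
    age = c(rnorm(53, 65.5, 9.5), rnorm(128, 54.3, 13.4)),
    plms = c(rlnorm(53, log(28), 0.8), rlnorm(128, log(13), 1.1)))
  tab <- demographic_table(rec)
  male_row <- tab[tab$variable == "male", ]
  expect_equal(male_row$test, "chi_squared")
  expect_lt(male_row$p_value, 0.01)
  expect_equal(male_row$p_value,
               chisq.test(table(rec$group, rec$male))$p.value)
  expect_equal(tab$test[tab$variable == "age"], "t")
  expect_equal(tab$test[tab$variable == "plms"], "mann_whitney")
  expect_true(tab$significant[tab$variable == "age"])

  # identical group composition: p near 1
  rec2 <- rec
  rec2$group <- rep(c("iRBD", "no-RBD"), length.out = 181)
  rec2$male <- rep(c(TRUE, TRUE, FALSE, FALSE), length.out = 181)
  tab2 <- suppressWarnings(demographic_table(rec2, c("male")))
  expect_gt(tab2$p_value, 0.9)

  # near-empty cell (few positives overall): flagged
  rec3 <- rec
  rec3$male <- c(TRUE, rep(FALSE, 52), TRUE, TRUE, rep(FALSE, 126))
  tab3 <- suppressWarnings(demographic_table(rec3, "male"))
  expect_equal(tab3$flag, "small_expected_counts")

  expect_error(demographic_table(rec[rec$group == "iRBD", ]), "two groups")
})

test_that("classifier comparisons pair fold metrics and control the FDR", {
  spec <- cohort_spec(n = c("iRBD" = 25, "no-RBD" = 50))
  feats <- sample_cohort_features(spec, seed = 201)
  plan <- cv_plan(n_runs = 2, n_folds = 5, seed_base = 7)
  cv_lb <- suppressWarnings(run_cv(feats, classifier_config("LB", "short"), plan))
  cv_he <- suppressWarnings(run_cv(feats, classifier_config("HE", "short"), plan))

  # self-comparison is degenerate and never rejected
  res_self <- compare_classifiers(list(a = cv_lb, b = cv_lb))
  expect_true(all(res_self$degenerate))
  expect_false(any(res_self$reject))

  # three identical configurations: zero rejections among the pairs
  res3 <- compare_classifiers(list(a = cv_he, b = cv_he, c = cv_he))
  expect_false(any(res3$reject))

  res <- compare_classifiers(list(LB = cv_lb, HE = cv_he))
  expect_equal(nrow(res), 2L)  # accuracy + f1 families
  expect_true(all(res$adjusted_p >= res$p - 1e-12))

  # run-level pairing uses 10 paired values per comparison
  res_run <- compare_classifiers(list(LB = cv_lb, HE = cv_he),
                                 level = "run")
  expect_equal(nrow(res_run), 2L)

  plan2 <- cv_plan(n_runs = 2, n_folds = 5, seed_base = 8)
  cv_other <- run_cv(feats, classifier_config("HE", "short"), plan2)
  expect_error(compare_classifiers(list(a = cv_lb, b = cv_other)),
               "same CV plan")
})

test_that("a constructed single-ROI effect is detected with FDR control", {
  # only the lower body carries signal: LB cells differ between groups,
  # head cells are identical across groups
  ref <- cohort_reference()
  cells <- ref
  he <- cells$roi == "HE"
  irbd_he <- he & cells$group == "iRBD"
  norbd_he <- he & cells$group == "no-RBD"
  cells[irbd_he, c("median", "q25", "q75")] <-
    cells[norbd_he, c("median", "q25", "q75")]
  wins <- 0L
  for (rep in 1:5) {
    feats <- sample_cohort_features(
      cohort_spec(cells, n = c("iRBD" = 40, "no-RBD" = 80)),
      seed = 300 + rep)
    plan <- cv_plan(n_runs = 2, n_folds = 5, seed_base = 400 + rep)
    cv_lb <- suppressWarnings(run_cv(feats, classifier_config("LB", "short"), plan))
    cv_he <- suppressWarnings(run_cv(feats, classifier_config("HE", "short"), plan))
    res <- compare_classifiers(list(LB = cv_lb, HE = cv_he))
    acc <- res[res$metric == "accuracy", ]
    lb_better <- mean(cv_lb$fold_metrics$accuracy) >
      mean(cv_he$fold_metrics$accuracy)
    if (lb_better && acc$reject) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("feature group tables reproduce per-cell summaries", {
  feats <- sample_cohort_features(cohort_spec(), seed = 111)
  tab <- feature_group_table(feats, "iRBD")
  expect_equal(nrow(tab), 24L)
  row <- tab[tab$feature == "LB_short_rate", ]
  expect_equal(row$median_a,
               median(feats$LB_short_rate[feats$group == "iRBD"]))
  expect_lt(row$p_value, 0.001)
})
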