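#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. The exact
#' null distribution is used when there are no ties and
#' `n_a * n_b <= 400`; otherwise the normal approximation with tie
#' correction (and continuity correction) is applied.
#'
#' @param a,b Numeric samples (non-empty).
#' @return A `comparison_result` list: `test`, `statistic` (U for the
#'   first sample), `p_value`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  assert_that(length(a) >= 1 && length(b) >= 1,
              "both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= 400
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact))
  comparison_result("mann_whitney_u", unname(res$statistic), res$p.value,
                    method = if (exact) "exact" else "normal_approx")
}

# Null distribution of the signed-rank statistic W+ over the given
# (possibly tie-averaged) positive ranks, by generating-function
# convolution. Ranks are doubled so half-integer average ranks become
# integers. Returns P(W+ = w/2) over w = 0..sum(2r).
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  pmf <- numeric(total + 1L)
  pmf[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), pmf[seq_len(total + 1L - r)])
    pmf <- (pmf + shifted) / 2
  }
  pmf
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired comparison. Zero differences are dropped; ties in
#' absolute differences get average ranks. The exact null distribution
#' of the signed-rank statistic over the (tie-averaged) ranks is
#' computed by convolution when `n <= 25` after dropping zeros, so the
#' test stays exact even under ties; larger samples use the normal
#' approximation with tie correction. All differences zero yields a
#' degenerate result (`p = 1`, flagged).
#'
#' @param a,b Paired numeric samples of equal length (>= 5 after
#'   dropping zero differences, unless degenerate).
#' @return A `comparison_result` with `statistic` (W+, sum of positive
#'   ranks), `p_value`, `method`, `degenerate` flag.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  assert_that(length(a) == length(b), "paired samples must match in length")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) {
    res <- comparison_result("wilcoxon_signed_rank", NA_real_, 1,
                             method = "degenerate")
    res$degenerate <- TRUE
    return(res)
  }
  assert_that(length(d) >= 5,
              "need >= 5 non-zero differences")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  n <- length(d)
  if (n <= 25) {
    pmf <- signed_rank_null(r)
    idx <- as.integer(round(2 * w_pos)) + 1L
    p_le <- sum(pmf[seq_len(idx)])
    p_ge <- sum(pmf[idx:length(pmf)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  res <- comparison_result("wilcoxon_signed_rank", w_pos, p, method = method)
  res$degenerate <- FALSE
  res
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: adjusted p-values are
#' `min over j >= i of m * p_(j) / j`, capped at 1; a hypothesis is
#' rejected when its adjusted p-value is at most `q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Data frame with `p`, `adjusted_p`, `reject`.
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  assert_that(all(p_values >= 0 & p_values <= 1),
              "p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  data.frame(p = p_values, adjusted_p = adj, reject = adj <= q)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties; the p-value uses the
#' t approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @return A `comparison_result` with `statistic` (rho) and `p_value`.
#' @export
spearman_corr <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_rbd("constant input: Spearman correlation undefined")
  res <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  comparison_result("spearman", unname(res$estimate), res$p.value,
                    method = "t_approx")
}

comparison_result <- function(test, statistic, p_value, adjusted_p = NA_real_,
                              reject = NA, method = NULL) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 adjusted_p = adjusted_p, reject = reject,
                 method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %s, p = %.4g%s\n", x$test,
              format(x$statistic), x$p_value,
              if (!is.null(x$method)) paste0(" (", x$method, ")") else ""))
  invisible(x)
}

#' Demographic and sleep comparison table
#'
#' Formats a two-group comparison of cohort variables: numeric
#' variables are summarised as mean +/- SD and compared with a t test
#' when both groups pass Shapiro-Wilk normality at 0.05, otherwise as
#' median [IQR] with a Mann-Whitney U test; logical/categorical
#' variables are compared with a chi-squared test (continuity-corrected
#' 2x2, flagged when any expected cell is small).
#'
#' @param records Data frame with a `group` column (exactly 2 levels
#'   after applying `group_map`) and the variables to compare.
#' @param variables Character vector of column names to compare
#'   (default: all except `subject_id` and `group`).
#' @param group_map Optional named vector collapsing fine groups into
#'   two arms, e.g. `c(iRBD = "iRBD", SRBD = "no-RBD", ...)`.
#' @return Data frame: `variable`, per-group summary strings, `test`,
#'   `p_value`, `significant` (p < 0.05), `flag`.
#' @export
demographic_table <- function(records, variables = NULL, group_map = NULL) {
  df <- as.data.frame(records)
  if (!is.null(group_map)) df$group <- unname(group_map[df$group])
  groups <- sort(unique(df$group))
  if (length(groups) < 2) stop_rbd("need two groups to compare")
  assert_that(length(groups) == 2, "demographic_table compares two groups")
  variables <- variables %||%
    setdiff(names(df), c("subject_id", "group"))
  out <- lapply(variables, function(v) {
    x <- df[[v]]
    a <- x[df$group == groups[1]]; b <- x[df$group == groups[2]]
    flag <- ""
    if (is.numeric(x)) {
      normal <- tryCatch(
        stats::shapiro.test(a)$p.value > 0.05 &&
          stats::shapiro.test(b)$p.value > 0.05,
        error = function(e) FALSE)
      if (normal) {
        p <- stats::t.test(a, b)$p.value
        test <- "t"
        fmt <- function(z) sprintf("%.1f ± %.1f", mean(z),
                                   stats::sd(z))
      } else {
        p <- mann_whitney_u(a, b)$p_value
        test <- "mann_whitney"
        fmt <- function(z) sprintf("%.1f [%.1f-%.1f]",
                                   stats::median(z),
                                   stats::quantile(z, 0.25),
                                   stats::quantile(z, 0.75))
      }
      s1 <- fmt(a); s2 <- fmt(b)
    } else {
      tab <- table(df$group, x)
      suppressWarnings({
        ct <- stats::chisq.test(tab, correct = TRUE)
      })
      if (any(ct$expected < 5)) flag <- "small_expected_counts"
      p <- ct$p.value
      test <- "chi_squared"
      pct <- function(z) 100 * mean(z == sort(unique(x), decreasing = TRUE)[1])
      s1 <- sprintf("%.1f%%", pct(a)); s2 <- sprintf("%.1f%%", pct(b))
    }
    data.frame(variable = v, g1 = s1, g2 = s2, test = test, p_value = p,
               significant = p < 0.05, flag = flag)
  })
  res <- do.call(rbind, out)
  names(res)[2:3] <- groups
  res
}

#' Paired comparison of classifier configurations
#'
#' Compares cross-validated performance between classifier
#' configurations with Wilcoxon signed-rank tests on paired metric
#' values, Benjamini-Hochberg corrected within each metric family.
#' Pairing is at the fold level by default (10 runs x 10 folds = 100
#' paired values, all results sharing one CV plan so folds align);
#' run-level pairing (10 values) is available.
#'
#' @param results Named list of `cv_result` objects from identical
#'   CV plans.
#' @param metrics Metric families to compare (default accuracy and F1).
#' @param q FDR level per metric family.
#' @param level `"fold"` (default) or `"run"` pairing.
#' @return Data frame: `metric`, `pair`, `statistic`, `p`,
#'   `adjusted_p`, `reject`, `degenerate`.
#' @export
compare_classifiers <- function(results, metrics = c("accuracy", "f1"),
                                q = 0.05, level = c("fold", "run")) {
  level <- match.arg(level)
  assert_that(is.list(results) && length(results) >= 2,
              "need at least two cv_result objects")
  assert_that(!is.null(names(results)), "results must be a named list")
  plans <- lapply(results, function(r) r$plan[c("n_runs", "n_folds",
                                                "seeds", "stratified")])
  if (length(unique(lapply(plans, identity))) != 1L)
    stop_rbd("all cv_result objects must share the same CV plan")
  tab <- if (level == "fold") "fold_metrics" else "run_metrics"
  pairs <- utils::combn(names(results), 2, simplify = FALSE)
  out <- list()
  for (m in metrics) {
    rows <- lapply(pairs, function(pr) {
      va <- results[[pr[1]]][[tab]][[m]]
      vb <- results[[pr[2]]][[tab]][[m]]
      ok <- !is.na(va) & !is.na(vb)
      # too few informative pairs (heavy metric ties) cannot be tested
      if (sum(va[ok] != vb[ok]) < 5) {
        w <- comparison_result("wilcoxon_signed_rank", NA_real_, 1,
                               method = "degenerate")
        w$degenerate <- TRUE
      } else {
        w <- wilcoxon_signed_rank(va[ok], vb[ok])
      }
      data.frame(metric = m, pair = paste(pr, collapse = " vs "),
                 statistic = w$statistic, p = w$p_value,
                 degenerate = w$degenerate)
    })
    fam <- do.call(rbind, rows)
    bh <- benjamini_hochberg(fam$p, q)
    fam$adjusted_p <- bh$adjusted_p
    fam$reject <- bh$reject & !fam$degenerate
    out[[m]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("metric", "pair", "statistic", "p", "adjusted_p", "reject",
          "degenerate")]
}

#' Group-level feature summary table
#'
#' Median [IQR] of each feature per group with Mann-Whitney U
#' comparisons — the per-cell group summary used to report the movement
#' features of an iRBD vs no-RBD cohort.
#'
#' @param features Wide feature data frame (`subject_id`, `group`,
#'   feature columns).
#' @param group_a,group_b Group labels to compare; `group_b = NULL`
#'   pools all remaining subjects.
#' @return Data frame: `feature`, per-group `median`, `q25`, `q75`,
#'   `p_value`.
#' @export
feature_group_table <- function(features, group_a = "iRBD",
                                group_b = NULL) {
  cols <- setdiff(names(features), c("subject_id", "group"))
  in_a <- features$group == group_a
  in_b <- if (is.null(group_b)) !in_a else features$group == group_b
  assert_that(any(in_a) && any(in_b), "both groups must be non-empty")
  out <- lapply(cols, function(v) {
    a <- features[[v]][in_a]; b <- features[[v]][in_b]
    data.frame(feature = v,
               median_a = stats::median(a),
               q25_a = unname(stats::quantile(a, 0.25)),
               q75_a = unname(stats::quantile(a, 0.75)),
               median_b = stats::median(b),
               q25_b = unname(stats::quantile(b, 0.25)),
               q75_b = unname(stats::quantile(b, 0.75)),
               p_value = mann_whitney_u(a, b)$p_value)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot cross-validated metrics across configurations
#'
#' Mean +/- SD (across runs) of a metric for a set of classifier
#' configurations, mirroring the bar-chart comparison of predictor
#' configurations. Requires ggplot2.
#'
#' @param results Named list of `cv_result` objects.
#' @param metric Metric to plot.
#' @return A ggplot object.
#' @export
plot_cv_metrics <- function(results, metric = "accuracy") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_rbd("ggplot2 is required for plotting")
  df <- do.call(rbind, lapply(names(results), function(nm) {
    agg <- results[[nm]]$aggregate
    row <- agg[agg$metric == metric, ]
    data.frame(config = nm, mean = row$mean, sd = row$sd)
  }))
  df$config <- factor(df$config, levels = df$config)
  df$lo <- df$mean - df$sd
  df$hi <- df$mean + df$sd
  ggplot2::ggplot(df, ggplot2::aes(x = config, y = mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
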