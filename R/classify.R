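#' The seven predictor configurations
#'
#' Per duration interval, seven classifiers are trained: each uses the
#' 3D rate and 3D ratio from one single ROI (head HE, hands HAs, upper
#' body UB, lower body LB: 2 predictors each), from head+hands+upper
#' body or head+hands+lower body (6 predictors), or from all four ROIs
#' (8 predictors).
#'
#' @return Named list of ROI-code character vectors.
#' @export
classifier_roi_sets <- function() {
  list(HE = "HE", HAs = "HAs", UB = "UB", LB = "LB",
       `HE+HAs+UB` = c("HE", "HAs", "UB"),
       `HE+HAs+LB` = c("HE", "HAs", "LB"),
       `HE+HAs+UB+LB` = c("HE", "HAs", "UB", "LB"))
}

#' Feature columns for a configuration
#' @param roi_set Character vector of ROI codes (subset of
#'   `HE`, `HAs`, `UB`, `LB`).
#' @param bin Duration bin (`short`, `medium` or `long`).
#' @return Character vector of feature column names (rate and ratio per
#'   ROI: 2, 6 or 8 columns for the seven canonical configurations).
#' @export
feature_columns <- function(roi_set, bin) {
  assert_that(all(roi_set %in% c("HE", "HAs", "UB", "LB")),
              "roi_set must use codes HE, HAs, UB, LB")
  assert_that(bin %in% c("short", "medium", "long"), "unknown bin")
  as.vector(t(outer(roi_set, c("rate", "ratio"),
                    function(r, f) paste(r, bin, f, sep = "_"))))
}

#' Classifier configuration
#'
#' @param roi_set One of the seven ROI combinations of
#'   [classifier_roi_sets()] (a character vector of ROI codes).
#' @param bin Duration bin the features come from.
#' @param ridge_lambda Ridge penalty weight on normalized features
#'   (>= 0), applied to the mean per-subject negative log-likelihood.
#'   On that scale a weakly informative default of 0.01 (comparable to
#'   the common sum-likelihood unit penalty at cohort sizes of one to
#'   two hundred) leaves percentile-normalized predictors room to act;
#'   the value used is always reported in run metadata.
#' @param decision_threshold Probability cutoff for the positive
#'   (iRBD) class, in (0, 1).
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(roi_set, bin = "short", ridge_lambda = 0.01,
                              decision_threshold = 0.5) {
  sets <- classifier_roi_sets()
  match_ok <- any(vapply(sets, function(s) setequal(s, roi_set), logical(1)))
  assert_that(match_ok,
              "roi_set must be one of the seven canonical configurations")
  assert_that(ridge_lambda >= 0, "ridge_lambda must be >= 0")
  assert_that(decision_threshold > 0 && decision_threshold < 1,
              "decision_threshold must lie in (0, 1)")
  structure(list(roi_set = roi_set, bin = bin,
                 ridge_lambda = ridge_lambda,
                 decision_threshold = decision_threshold),
            class = "classifier_config")
}

#' Percentile normalizer
#'
#' Maps each feature linearly so that the 5th percentile of the
#' training values goes to 0 and the 95th to 1; values outside the
#' training range are not clipped. Fitted on training folds only.
#'
#' @param x Numeric matrix (or data frame) of training feature values.
#' @return Object of class `percentile_normalizer` with `p5`/`p95`
#'   per feature.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= 2, "need >= 2 training rows")
  p5 <- apply(x, 2, stats::quantile, probs = 0.05, names = FALSE)
  p95 <- apply(x, 2, stats::quantile, probs = 0.95, names = FALSE)
  if (any(p95 - p5 <= 0))
    stop_rbd("constant feature(s): ",
             paste(colnames(x)[p95 - p5 <= 0], collapse = ", "))
  structure(list(p5 = p5, p95 = p95, features = colnames(x)),
            class = "percentile_normalizer")
}

#' @rdname fit_normalizer
#' @param state A fitted `percentile_normalizer`.
#' @export
apply_normalizer <- function(state, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, state$p5, `-`), 2, state$p95 - state$p5, `/`)
}

#' Ridge-regularized logistic regression
#'
#' Minimizes the mean negative log-likelihood plus
#' `lambda/2 * ||w||^2` (intercept unpenalized) by Newton iterations
#' with step halving, declaring convergence when the gradient
#' max-norm falls below `tol`.
#'
#' @param x Numeric feature matrix.
#' @param y Binary response (0/1 or logical), at least one of each
#'   class.
#' @param lambda Ridge penalty weight (>= 0).
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Iteration cap.
#' @return Object of class `ridge_logistic` with `weights`,
#'   `intercept`, `lambda`, `converged`, `n_iter`, `grad_norm`.
#' @export
fit_ridge_logistic <- function(x, y, lambda = 1, tol = 1e-8,
                               max_iter = 100L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  assert_that(all(y %in% c(0, 1)), "y must be binary 0/1")
  assert_that(any(y == 0) && any(y == 1),
              "need at least one sample of each class")
  assert_that(all(is.finite(x)), "features must be finite")
  n <- nrow(x); p <- ncol(x)
  beta <- numeric(p + 1L)  # (intercept, weights)
  xa <- cbind(1, x)
  penal <- c(0, rep(lambda, p))
  obj <- function(b) {
    eta <- drop(xa %*% b)
    # numerically stable log(1 + exp(eta)) - y*eta
    mean(pmax(eta, 0) - y * eta + log1p(exp(-abs(eta)))) +
      sum(penal * b^2) / 2
  }
  grad_norm <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(xa %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(xa, mu - y)) / n + penal * beta
    grad_norm <- max(abs(g))
    if (grad_norm < tol) break
    wgt <- pmax(mu * (1 - mu), 1e-10)
    hess <- crossprod(xa * wgt, xa) / n + diag(penal, p + 1L)
    step <- solve(hess, g)
    f0 <- obj(beta)
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      if (obj(cand) <= f0 + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    beta <- beta - alpha * step
  }
  if (grad_norm >= tol)
    stop_rbd(sprintf(
      "ridge logistic did not converge in %d iterations (grad norm %.3g)",
      max_iter, grad_norm))
  structure(list(intercept = beta[1L], weights = beta[-1L],
                 lambda = lambda, converged = TRUE, n_iter = it,
                 grad_norm = grad_norm, features = colnames(x)),
            class = "ridge_logistic")
}

#' @export
predict.ridge_logistic <- function(object, newdata, ...) {
  eta <- drop(as.matrix(newdata) %*% object$weights) + object$intercept
  stats::plogis(eta)
}

#' Classification performance metrics
#'
#' Confusion-matrix metrics for the positive class (iRBD): accuracy,
#' F1 (harmonic mean of PPV and sensitivity), sensitivity, specificity,
#' positive and negative predictive value. Ratios with a zero
#' denominator are returned as `NA` with a warning and are excluded
#' from downstream aggregation.
#'
#' @param prob Predicted positive-class probabilities.
#' @param truth Logical (or 0/1) true positive-class indicators.
#' @param threshold Decision threshold on `prob`.
#' @return Named numeric vector of the six metrics.
#' @export
compute_metrics <- function(prob, truth, threshold = 0.5) {
  assert_that(length(prob) == length(truth),
              "prob and truth must have equal length")
  truth <- as.logical(truth)
  pred <- prob >= threshold
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
  safe <- function(num, den, name) {
    if (den == 0) {
      warning(name, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  ppv <- safe(tp, tp + fp, "ppv")
  npv <- safe(tn, tn + fn, "npv")
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_
        else 2 * ppv * sens / (ppv + sens)
  c(accuracy = (tp + tn) / length(truth), f1 = f1, sensitivity = sens,
    specificity = spec, ppv = ppv, npv = npv)
}

#' Cross-validation plan
#'
#' @param n_runs Number of repeated runs (default 10), each with its
#'   own fold-assignment seed `seed_base + run - 1`.
#' @param n_folds Folds per run (default 10).
#' @param seed_base Base RNG seed.
#' @param stratified Preserve class proportions in each fold
#'   (default TRUE; with 53/181 prevalence unstratified folds can lose
#'   a class).
#' @return Object of class `cv_plan`.
#' @export
cv_plan <- function(n_runs = 10L, n_folds = 10L, seed_base = 42L,
                    stratified = TRUE) {
  assert_that(n_runs >= 1 && n_folds >= 2, "need n_runs >= 1, n_folds >= 2")
  structure(list(n_runs = as.integer(n_runs), n_folds = as.integer(n_folds),
                 seeds = as.integer(seed_base) + seq_len(n_runs) - 1L,
                 stratified = isTRUE(stratified)),
            class = "cv_plan")
}

# stratified fold assignment: shuffle within class, deal round-robin
assign_folds <- function(y, n_folds, stratified) {
  n <- length(y)
  folds <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  }
  folds
}

#' Repeated stratified cross-validation of the movement classifier
#'
#' For each run, subjects are assigned to stratified folds from the
#' run's seed; per fold, the percentile normalizer and the ridge
#' logistic model are fitted on the training folds only and applied to
#' the held-out fold. Per-run metrics are computed on the pooled
#' out-of-fold predictions (each subject exactly once per run), and
#' per-fold metrics are retained for paired statistical comparisons.
#'
#' @param features Wide feature data frame (`subject_id`, `group`,
#'   feature columns), e.g. from [sample_cohort_features()].
#' @param config A [classifier_config()].
#' @param plan A [cv_plan()].
#' @param positive_group Group label treated as the positive class.
#' @return Object of class `cv_result`: `predictions`
#'   (`run, fold, subject_id, prob, pred, label`), `run_metrics`,
#'   `fold_metrics`, `aggregate` (mean and SD over runs), `config`,
#'   `plan`, and `settings` metadata.
#' @export
run_cv <- function(features, config, plan = cv_plan(),
                   positive_group = "iRBD") {
  assert_that(inherits(config, "classifier_config"),
              "config must be a classifier_config")
  cols <- feature_columns(config$roi_set, config$bin)
  assert_that(all(cols %in% names(features)),
              "features lack required columns for this configuration")
  y <- as.integer(features$group == positive_group)
  assert_that(any(y == 1) && any(y == 0),
              "need both positive and negative subjects")
  x <- as.matrix(features[, cols, drop = FALSE])
  n <- nrow(x)
  preds <- list()
  run_metrics <- list()
  fold_metrics <- list()
  for (r in seq_len(plan$n_runs)) {
    folds <- with_local_seed(plan$seeds[r],
                             assign_folds(y, plan$n_folds, plan$stratified))
    prob <- rep(NA_real_, n)
    for (f in seq_len(plan$n_folds)) {
      test <- folds == f
      if (all(y[!test] == y[!test][1]))
        stop_rbd("fold lacks both classes; re-stratify")
      norm <- fit_normalizer(x[!test, , drop = FALSE])
      xtr <- apply_normalizer(norm, x[!test, , drop = FALSE])
      xte <- apply_normalizer(norm, x[test, , drop = FALSE])
      fit <- fit_ridge_logistic(xtr, y[!test], lambda = config$ridge_lambda)
      prob[test] <- predict(fit, xte)
      fold_metrics[[length(fold_metrics) + 1L]] <- data.frame(
        run = r, fold = f,
        t(suppressWarnings(compute_metrics(prob[test], y[test],
                                           config$decision_threshold))))
    }
    preds[[r]] <- data.frame(run = r, fold = folds,
                             subject_id = features$subject_id,
                             prob = prob,
                             pred = prob >= config$decision_threshold,
                             label = y)
    run_metrics[[r]] <- data.frame(
      run = r, t(compute_metrics(prob, y, config$decision_threshold)))
  }
  run_df <- do.call(rbind, run_metrics)
  metric_names <- c("accuracy", "f1", "sensitivity", "specificity",
                    "ppv", "npv")
  agg <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(run_df[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_names, function(m) stats::sd(run_df[[m]][
      !is.na(run_df[[m]])]), numeric(1)))
  structure(list(predictions = do.call(rbind, preds),
                 run_metrics = run_df,
                 fold_metrics = do.call(rbind, fold_metrics),
                 aggregate = agg, config = config, plan = plan,
                 settings = list(ridge_lambda = config$ridge_lambda,
                                 decision_threshold =
                                   config$decision_threshold,
                                 stratified = plan$stratified,
                                 seeds = plan$seeds,
                                 positive_group = positive_group)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s / %s bin; %d runs x %d folds\n",
              paste(x$config$roi_set, collapse = "+"), x$config$bin,
              x$plan$n_runs, x$plan$n_folds))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  invisible(x)
}

#' Subgroup test performance
#'
#' Recomputes per-run metrics on the pooled out-of-fold predictions
#' restricted to the positive class plus a subgroup of the negative
#' class (models are not retrained), mirroring the subgroup analyses
#' iRBD vs SRBD, iRBD vs RLS/PLMS and iRBD vs INS/NRSD.
#'
#' @param cv A `cv_result` from the full training.
#' @param groups Named group label per subject (aligned with the
#'   feature table used for `cv`, or a data frame with `subject_id`
#'   and `group`).
#' @param subgroup Character vector of negative-class group labels to
#'   keep (e.g. `c("RLS", "PLMS")`).
#' @return List with `run_metrics` and `aggregate` (mean/SD over runs).
#' @export
subgroup_metrics <- function(cv, groups, subgroup) {
  assert_that(inherits(cv, "cv_result"), "cv must be a cv_result")
  assert_that(length(subgroup) >= 1, "subgroup must be non-empty")
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$subject_id)
  }
  pos <- cv$settings$positive_group
  pr <- cv$predictions
  g <- groups[as.character(pr$subject_id)]
  keep <- g == pos | g %in% subgroup
  if (!any(keep & g %in% subgroup)) stop_rbd("subgroup has no subjects")
  pr <- pr[keep, , drop = FALSE]
  runs <- sort(unique(pr$run))
  rm_list <- lapply(runs, function(r) {
    sub <- pr[pr$run == r, ]
    data.frame(run = r, t(compute_metrics(
      sub$prob, sub$label, cv$config$decision_threshold)))
  })
  run_df <- do.call(rbind, rm_list)
  metric_names <- c("accuracy", "f1", "sensitivity", "specificity",
                    "ppv", "npv")
  agg <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(run_df[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_names, function(m) stats::sd(run_df[[m]][
      !is.na(run_df[[m]])]), numeric(1)))
  list(run_metrics = run_df, aggregate = agg)
}
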