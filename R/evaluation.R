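#' Confusion table for pCR prediction
#'
#' Counts of predicted vs observed pathologic complete response.
#'
#' @param TP,FP,FN,TN non-negative integer counts (predicted pCR that was /
#'   was not observed; predicted residual that was / was not pCR).
#' @return object of class `confusion_table`.
#' @export
confusion_table <- function(TP, FP, FN, TN) {
  cnt <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(cnt) == 0) stop("confusion table is empty", call. = FALSE)
  structure(as.list(cnt), class = "confusion_table")
}

#' Build a confusion table from predicted and observed labels
#' @param predicted,observed logical vectors (TRUE = pCR).
#' @return a `confusion_table`.
#' @export
confusion_from_labels <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  confusion_table(TP = sum(predicted & observed),
                  FP = sum(predicted & !observed),
                  FN = sum(!predicted & observed),
                  TN = sum(!predicted & !observed))
}

#' Evaluation settings
#'
#' @param level confidence level (default 0.95).
#' @param bootstrap_replicates bootstrap resamples for AUROC CIs
#'   (default 1000).
#' @param bootstrap_seed,cv_seed RNG seeds for reproducibility.
#' @param cv_folds cross-validation folds for the logistic comparator
#'   (default 3).
#' @param survival_horizon horizon in years for reported survival
#'   (default 5).
#' @return object of class `stats_config`.
#' @export
stats_config <- function(level = 0.95, bootstrap_replicates = 1000,
                         bootstrap_seed = 1, cv_folds = 3, cv_seed = 1,
                         survival_horizon = 5) {
  if (level <= 0 || level >= 1) stop("level must lie in (0,1)", call. = FALSE)
  if (bootstrap_replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(level = level,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 bootstrap_seed = as.integer(bootstrap_seed),
                 cv_folds = as.integer(cv_folds),
                 cv_seed = as.integer(cv_seed),
                 survival_horizon = survival_horizon),
            class = "stats_config")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Central exact interval from Beta quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0),
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n).
#' The interval always contains the point estimate x/n.
#'
#' @param successes x, with `0 <= x <= n`.
#' @param trials n >= 1.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)` as proportions.
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  x <- successes; n <- trials
  if (n < 1 || x < 0 || x > n)
    stop("need 0 <= successes <= trials, trials >= 1", call. = FALSE)
  a <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Sensitivity, specificity and accuracy with exact CIs
#'
#' Point estimates are proportions of the confusion-table counts; intervals
#' are Clopper-Pearson. A metric whose denominator is zero is returned as
#' NA with a flag rather than an error.
#'
#' @param tab a `confusion_table`.
#' @param cfg a `stats_config`.
#' @return data.frame with columns metric, estimate, lower, upper (all
#'   proportions), x, n, flag.
#' @export
confusion_metrics <- function(tab, cfg = stats_config()) {
  stopifnot(inherits(tab, "confusion_table"))
  n_all <- tab$TP + tab$FP + tab$FN + tab$TN
  one <- function(metric, x, n) {
    if (n == 0)
      return(data.frame(metric = metric, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_, x = x, n = n,
                        flag = "zero_denominator"))
    ci <- clopper_pearson(x, n, cfg$level)
    data.frame(metric = metric, estimate = x / n, lower = ci[["lower"]],
               upper = ci[["upper"]], x = x, n = n, flag = "ok")
  }
  rbind(one("sensitivity", tab$TP, tab$TP + tab$FN),
        one("specificity", tab$TN, tab$TN + tab$FP),
        one("accuracy", tab$TP + tab$TN, n_all))
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' The probability that a random positive case scores above a random
#' negative case, with ties counted one half — computed from midranks, so
#' it equals the all-pairs count exactly.
#'
#' @param scores continuous predictor values.
#' @param labels binary truth (logical or 0/1), TRUE = positive.
#' @return AUROC in [0, 1]; NA with a warning when only one class is
#'   present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile CI for the AUROC
#'
#' Case resampling (stratification-free, as a plain nonparametric
#' bootstrap) with a fixed seed; resamples with a single class are redrawn.
#'
#' @param scores,labels as in [auroc()].
#' @param cfg a `stats_config` (replicates and seed).
#' @return named numeric `c(lower, upper)`.
#' @export
auroc_bootstrap_ci <- function(scores, labels, cfg = stats_config()) {
  labels <- as.logical(labels)
  n <- length(scores)
  vals <- numeric(cfg$bootstrap_replicates)
  set.seed(cfg$bootstrap_seed)
  for (b in seq_len(cfg$bootstrap_replicates)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    vals[b] <- auroc(scores[idx], labels[idx])
  }
  a <- 1 - cfg$level
  q <- stats::quantile(vals, c(a / 2, 1 - a / 2), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

# stratified fold assignment: each class split as evenly as possible
.stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated logistic comparator
#'
#' The clinical benchmark: a logistic regression on clinical covariates,
#' trained on all folds but one and scored on the held-out fold, so every
#' case is scored exactly once by a model never trained on it. Folds are
#' stratified by label. Categorical features are one-hot encoded with the
#' first level as reference (via `model.matrix`). A training fold that
#' degenerates to a single class triggers a refit with merged folds and a
#' flag.
#'
#' @param features data.frame of clinical covariates (factors and
#'   numerics).
#' @param labels binary outcome (logical or 0/1).
#' @param cfg a `stats_config` (folds and CV seed).
#' @return list with `scores` (out-of-fold predicted probabilities),
#'   `fold` (assignment), `auroc`, `flag`.
#' @export
cv_logistic_comparator <- function(features, labels, cfg = stats_config()) {
  labels <- as.logical(labels)
  n <- length(labels)
  if (n < cfg$cv_folds) stop("n must be >= folds", call. = FALSE)
  features <- as.data.frame(features)
  # drop constant columns (single-level factors break the design matrix)
  keep <- vapply(features, function(col) length(unique(col)) > 1, logical(1))
  if (!any(keep))
    stop("no informative features for the comparator", call. = FALSE)
  features <- features[, keep, drop = FALSE]
  fold <- .stratified_folds(labels, cfg$cv_folds, cfg$cv_seed)
  X <- stats::model.matrix(~ ., data = features)
  scores <- rep(NA_real_, n)
  flag <- "ok"
  for (f in seq_len(cfg$cv_folds)) {
    if (!any(fold == f)) next
    tr <- fold != f
    if (length(unique(labels[tr])) < 2L) {
      # degenerate split: fall back to training on the full data, flagged
      tr <- rep(TRUE, n)
      flag <- "merged_folds"
    }
    df_tr <- data.frame(y = labels[tr], X[tr, -1, drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                       family = stats::binomial()))
    df_te <- data.frame(X[fold == f, -1, drop = FALSE])
    scores[fold == f] <- suppressWarnings(
      stats::predict(fit, newdata = df_te, type = "response"))
  }
  list(scores = scores, fold = fold, auroc = auroc(scores, labels),
       flag = flag)
}

#' Compare survival between prediction groups
#'
#' Log-rank test, Kaplan-Meier survival at the horizon per group, and a
#' hazard ratio from a single-covariate proportional-hazards fit. When one
#' group has no events the hazard ratio is flagged, not computed.
#'
#' @param times follow-up times in years (>= 0).
#' @param events event indicator (1 = event, 0 = censored).
#' @param groups binary group label (TRUE/1 = predicted residual disease,
#'   the reference for the hazard ratio is FALSE/0 = predicted pCR).
#' @param cfg a `stats_config` (survival horizon).
#' @return list with `logrank_chisq`, `logrank_p`, `survival_at_horizon`
#'   (named per group), `hazard_ratio` (estimate, lower, upper or NA),
#'   `flag`.
#' @export
survival_compare <- function(times, events, groups, cfg = stats_config()) {
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  grp <- factor(as.integer(as.logical(groups)), levels = c(0, 1))
  if (sum(events) == 0) {
    return(list(logrank_chisq = NA_real_, logrank_p = NA_real_,
                survival_at_horizon = c(`0` = 1, `1` = 1),
                hazard_ratio = c(estimate = NA, lower = NA, upper = NA),
                flag = "no_events"))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(times, events) ~ grp)
  surv_h <- vapply(c("0", "1"), function(g) {
    sub <- summary(sf[paste0("grp=", g)], times = cfg$survival_horizon,
                   extend = TRUE)
    sub$surv[1]
  }, numeric(1))
  ev_per_grp <- tapply(events, grp, sum)
  if (any(ev_per_grp == 0, na.rm = TRUE)) {
    hr <- c(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
    flag <- "hr_not_computed_no_events_in_group"
  } else {
    cx <- survival::coxph(survival::Surv(times, events) ~ grp)
    ci <- stats::confint(cx, level = cfg$level)
    hr <- c(estimate = unname(exp(stats::coef(cx))),
            lower = exp(ci[1]), upper = exp(ci[2]))
    flag <- "ok"
  }
  list(logrank_chisq = unname(sd$chisq), logrank_p = p,
       survival_at_horizon = surv_h, hazard_ratio = hr, flag = flag)
}

#' Pearson correlation with Fisher-transformation test
#'
#' Sample correlation r; significance from `z = atanh(r) sqrt(n - 3)`
#' against the standard normal, two-sided.
#'
#' @param x,y numeric vectors, `n >= 4`, each with nonzero variance.
#' @return list with `r`, `z`, `p`, `n`, `flag`.
#' @export
pearson_fisher <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, z = NA_real_, p = NA_real_, n = n,
                flag = "zero_variance"))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    return(list(r = r, z = Inf * sign(r), p = 0, n = n, flag = "perfect"))
  }
  z <- atanh(r) * sqrt(n - 3)
  list(r = r, z = z, p = 2 * stats::pnorm(-abs(z)), n = n, flag = "ok")
}

#' Outcome-metrics report, overall and by subgroup
#'
#' For the whole cohort and each subgroup: n, predicted-pCR count, and
#' accuracy / sensitivity / specificity with exact CIs. Percentages in the
#' text rendering are rounded to one decimal for display only; the returned
#' data frame keeps raw proportions. Subgroups below `min_n` are flagged;
#' empty subgroup levels are omitted with a flag.
#'
#' @param predicted,observed logical vectors (TRUE = pCR).
#' @param subgroup factor/character of subgroup labels (e.g. receptor
#'   subtype or regimen class), or NULL for the overall row only.
#' @param cfg a `stats_config`.
#' @param min_n subgroups smaller than this are flagged (default 5).
#' @return object of class `table2_report`: list with `rows` (data.frame)
#'   and `flags`.
#' @export
table2_report <- function(predicted, observed, subgroup = NULL,
                          cfg = stats_config(), min_n = 5) {
  predicted <- as.logical(predicted); observed <- as.logical(observed)
  stopifnot(length(predicted) == length(observed))
  groups <- list(Overall = rep(TRUE, length(predicted)))
  flags <- character(0)
  if (!is.null(subgroup)) {
    subgroup <- as.character(subgroup)
    if (anyNA(subgroup)) stop("unknown subgroup label (NA)", call. = FALSE)
    for (lv in unique(subgroup)) groups[[lv]] <- subgroup == lv
  }
  rows <- do.call(rbind, lapply(names(groups), function(gname) {
    sel <- groups[[gname]]
    if (!any(sel)) {
      flags <<- c(flags, paste0("empty_subgroup:", gname))
      return(NULL)
    }
    tab <- confusion_from_labels(predicted[sel], observed[sel])
    m <- confusion_metrics(tab, cfg)
    if (sum(sel) < min_n && gname != "Overall")
      flags <<- c(flags, paste0("small_subgroup:", gname))
    get <- function(met, col) m[m$metric == met, col]
    data.frame(group = gname, n = sum(sel), n_pred_pcr = sum(predicted[sel]),
               accuracy = get("accuracy", "estimate"),
               accuracy_lower = get("accuracy", "lower"),
               accuracy_upper = get("accuracy", "upper"),
               sensitivity = get("sensitivity", "estimate"),
               sensitivity_lower = get("sensitivity", "lower"),
               sensitivity_upper = get("sensitivity", "upper"),
               specificity = get("specificity", "estimate"),
               specificity_lower = get("specificity", "lower"),
               specificity_upper = get("specificity", "upper"))
  }))
  structure(list(rows = rows, flags = flags, level = cfg$level),
            class = "table2_report")
}

#' @export
print.table2_report <- function(x, ...) {
  fmt <- function(est, lo, hi) {
    ifelse(is.na(est), "-",
           sprintf("%.1f (%.1f-%.1f)", 100 * est, 100 * lo, 100 * hi))
  }
  r <- x$rows
  out <- data.frame(Group = r$group, n = r$n, `n pCR` = r$n_pred_pcr,
                    Accuracy = fmt(r$accuracy, r$accuracy_lower,
                                   r$accuracy_upper),
                    Sensitivity = fmt(r$sensitivity, r$sensitivity_lower,
                                      r$sensitivity_upper),
                    Specificity = fmt(r$specificity, r$specificity_lower,
                                      r$specificity_upper),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Write a table2_report to CSV (raw proportions retained)
#' @param report a `table2_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table2_csv <- function(report, path) {
  utils::write.csv(report$rows, path, row.names = FALSE)
  invisible(path)
}
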