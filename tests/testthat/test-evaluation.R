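test_that("clopper_pearson reproduces the printed outcome intervals", {
  r1 <- round(100 * clopper_pearson(44, 50), 1)
  expect_equal(unname(r1), c(75.7, 95.5))
  r2 <- round(100 * clopper_pearson(84, 94), 1)
  expect_equal(unname(r2), c(81.3, 94.8))
  r3 <- round(100 * clopper_pearson(128, 144), 1)
  expect_equal(unname(r3), c(82.6, 93.5))
  # x = 0 closed form
  r0 <- clopper_pearson(0, 10)
  expect_equal(unname(r0["lower"]), 0)
  expect_equal(unname(r0["upper"]), 1 - 0.025^(1 / 10))
  # x = n closed form
  rn <- clopper_pearson(10, 10)
  expect_equal(unname(rn["upper"]), 1)
  expect_error(clopper_pearson(5, 4), "successes")
})

test_that("clopper_pearson contains x/n, shrinks with n, covers exactly", {
  for (n in c(5, 20, 60)) for (x in c(0, 1, n %/% 2, n)) {
    ci <- clopper_pearson(x, n)
    expect_lte(ci[["lower"]], x / n)
    expect_gte(ci[["upper"]], x / n)
  }
  w <- vapply(c(10, 40, 160), function(n)
    diff(clopper_pearson(n %/% 2, n)), numeric(1))
  expect_true(all(diff(w) < 0))
  # exhaustive coverage >= nominal for all n <= 30 (binomial-tail oracle)
  p_grid <- seq(0.01, 0.99, by = 0.01)
  min_cov <- 1
  for (n in 1:30) {
    ci <- t(vapply(0:n, function(x) clopper_pearson(x, n), numeric(2)))
    for (p in p_grid) {
      covered <- ci[, 1] <= p & p <= ci[, 2]
      min_cov <- min(min_cov, sum(dbinom(0:n, n, p)[covered]))
    }
  }
  expect_gte(min_cov, 0.95)
})

test_that("confusion_metrics reproduces the overall outcome-table row", {
  tab <- confusion_table(TP = 44, FP = 10, FN = 6, TN = 84)
  m <- confusion_metrics(tab)
  get <- function(met) m[m$metric == met, ]
  expect_equal(round(100 * get("sensitivity")$estimate, 1), 88.0)
  expect_equal(round(100 * get("specificity")$estimate, 1), 89.4)
  expect_equal(round(100 * get("accuracy")$estimate, 1), 88.9)
  expect_equal(round(100 * c(get("sensitivity")$lower,
                             get("sensitivity")$upper), 1), c(75.7, 95.5))
  # HER2+ subgroup arithmetic forced by the published counts
  her2 <- confusion_metrics(confusion_table(TP = 21, FP = 2, FN = 2,
                                            TN = 24))
  expect_equal(round(100 * her2[her2$metric == "sensitivity",
                                c("estimate", "lower", "upper")], 1),
               data.frame(estimate = 91.3, lower = 72.0, upper = 98.9))
  expect_equal(round(100 * her2[her2$metric == "specificity", "estimate"],
                     1), 92.3)
  expect_equal(round(100 * her2[her2$metric == "accuracy", "estimate"], 1),
               91.8)
  # all correct: point estimates and upper bounds at 100
  perf <- confusion_metrics(confusion_table(10, 0, 0, 10))
  expect_equal(perf$estimate, c(1, 1, 1))
  expect_equal(perf$upper, c(1, 1, 1))
  # zero denominator flagged, not an error
  nod <- confusion_metrics(confusion_table(0, 0, 0, 5))
  expect_equal(nod[nod$metric == "sensitivity", "flag"],
               "zero_denominator")
})

test_that("auroc equals the brute-force all-pairs statistic", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_warning(expect_true(is.na(auroc(1:5, rep(1, 5)))), "one class")
  brute <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    pr <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(pr)
  }
  set.seed(13)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(0:2, 1))   # ties likely
    expect_equal(auroc(s, l), brute(s, l))
  }
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  s <- rnorm(60); l <- rbinom(60, 1, plogis(s))
  skip_if(length(unique(l)) < 2)
  expect_equal(auroc(s, l),
               as.numeric(suppressMessages(pROC::auc(l, s))))
})

test_that("bootstrap AUROC CI is reproducible and sane", {
  set.seed(4)
  s <- rnorm(80); l <- rbinom(80, 1, plogis(2 * s))
  cfg <- stats_config(bootstrap_replicates = 200, bootstrap_seed = 99)
  ci1 <- auroc_bootstrap_ci(s, l, cfg)
  ci2 <- auroc_bootstrap_ci(s, l, cfg)
  expect_identical(ci1, ci2)
  a <- auroc(s, l)
  expect_lte(ci1[["lower"]], a)
  expect_gte(ci1[["upper"]], a)
})

test_that("cv_logistic_comparator scores each case exactly once", {
  set.seed(31)
  n <- 90
  x <- rnorm(n)
  y <- x + rnorm(n, 0, 0.1) > 0          # nearly separable
  res <- cv_logistic_comparator(data.frame(x = x), y,
                                stats_config(cv_folds = 3, cv_seed = 5))
  expect_false(anyNA(res$scores))
  expect_equal(sort(unique(res$fold)), 1:3)
  expect_equal(length(res$scores), n)
  expect_gte(res$auroc, 0.95)
  # stratification: every fold carries both classes
  expect_true(all(table(res$fold, y) > 0))
})

test_that("cv comparator is unbiased on label-independent features", {
  aucs <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 300
    f <- data.frame(a = rnorm(n), b = factor(sample(letters[1:3], n,
                                                    replace = TRUE)))
    y <- rbinom(n, 1, 0.4)
    cv_logistic_comparator(f, y, stats_config(cv_folds = 3,
                                              cv_seed = s))$auroc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("survival_compare: identical groups, HR recovery, no events", {
  # two identical groups: no separation
  tt <- rep(c(1, 2, 3, 4, 5), 2)
  ev <- rep(c(1, 0, 1, 0, 1), 2)
  gr <- rep(c(0, 1), each = 5)
  r <- survival_compare(tt, ev, gr)
  expect_lt(r$logrank_chisq, 1e-10)
  expect_equal(r$logrank_p, 1)
  # exponential hazards 2:1 recovered within 15%
  set.seed(3)
  n <- 500
  t1 <- rexp(n, 2); t0 <- rexp(n, 1)
  cens <- runif(2 * n, 0.5, 4)
  tt2 <- pmin(c(t0, t1), cens)
  ev2 <- as.integer(c(t0, t1) <= cens)
  gr2 <- rep(c(0, 1), each = n)
  r2 <- survival_compare(tt2, ev2, gr2)
  expect_lt(abs(r2$hazard_ratio[["estimate"]] - 2) / 2, 0.15)
  expect_lt(r2$logrank_p, 1e-6)
  # a group with no events: KM stays at 1, HR flagged not computed
  ev3 <- ev; ev3[gr == 0] <- 0
  r3 <- survival_compare(tt, ev3, gr)
  expect_equal(unname(r3$survival_at_horizon["0"]), 1)
  expect_true(is.na(r3$hazard_ratio[["estimate"]]))
  expect_match(r3$flag, "no_events_in_group")
  # no events at all: test undefined
  expect_equal(survival_compare(tt, rep(0, 10), gr)$flag, "no_events")
})

test_that("pearson_fisher matches the transformation closed form", {
  x <- 1:20
  expect_equal(pearson_fisher(x, 2 * x + 1)$flag, "perfect")
  expect_equal(pearson_fisher(x, 2 * x + 1)$r, 1)
  set.seed(8)
  a <- rnorm(28); b <- 0.5 * a + rnorm(28)
  res <- pearson_fisher(a, b)
  r <- cor(a, b)
  expect_equal(res$z, atanh(r) * sqrt(25))
  expect_equal(res$p, 2 * pnorm(-abs(res$z)))
  expect_equal(pearson_fisher(a, rep(1, 28))$flag, "zero_variance")
  expect_error(pearson_fisher(1:3, 1:3), "n >= 4")
})

test_that("pearson_fisher holds its nominal type-I error", {
  rejections <- vapply(1:200, function(s) {
    set.seed(s)
    pearson_fisher(rnorm(1000), rnorm(1000))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("table2_report reproduces designed rates and totals", {
  # cohort constructed with exactly the published confusion counts
  predicted <- rep(c(TRUE, TRUE, FALSE, FALSE), c(44, 10, 6, 84))
  observed <- rep(c(TRUE, FALSE, TRUE, FALSE), c(44, 10, 6, 84))
  rep1 <- table2_report(predicted, observed)
  ov <- rep1$rows[rep1$rows$group == "Overall", ]
  expect_equal(round(100 * ov$accuracy, 1), 88.9)
  expect_equal(round(100 * ov$sensitivity, 1), 88.0)
  expect_equal(round(100 * ov$specificity, 1), 89.4)
  expect_equal(ov$n, 144)
  expect_equal(ov$n_pred_pcr, 54)
  # single subgroup: equals the overall row
  rep2 <- table2_report(predicted, observed,
                        subgroup = rep("TNBC", 144))
  expect_equal(unlist(rep2$rows[2, -1]), unlist(rep2$rows[1, -1]))
  # subgroup totals sum to the overall
  sub <- rep(c("A", "B"), 72)
  rep3 <- table2_report(predicted, observed, subgroup = sub)
  expect_equal(sum(rep3$rows$n[-1]), rep3$rows$n[1])
  expect_equal(sum(rep3$rows$n_pred_pcr[-1]), rep3$rows$n_pred_pcr[1])
  # CSV rendering retains raw proportions
  path <- tempfile(fileext = ".csv")
  write_table2_csv(rep1, path)
  back <- read.csv(path)
  expect_equal(back$sensitivity[1], 44 / 50)
})
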