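make_table <- function(n = 94, n_feat = 5, betas = NULL, seed = 1,
                       frac_event = 0.44) {
  set.seed(seed)
  x <- matrix(rnorm(n * n_feat), n,
              dimnames = list(paste0("p", seq_len(n)),
                              paste0("f", seq_len(n_feat))))
  lp <- if (is.null(betas)) rep(0, n) else as.numeric(x %*% betas)
  time <- rexp(n, rate = 0.01 * exp(lp))
  cens <- pmin(96, runif(n, 0, 114))
  ann <- data.frame(sample = rownames(x),
                    time_months = pmax(pmin(time, cens), 4),
                    event = as.integer(time <= cens))
  suppressMessages(build_feature_table(as.data.frame(x), ann))
}

test_that("feature tables are filtered, scaled, and one-hot encoded", {
  feats <- data.frame(age = c(50, 60, 70, 55, 65),
                      grade = c("g1", "g2", "g3", "g2", "g1"),
                      row.names = paste0("p", 1:5))
  ann <- data.frame(sample = paste0("p", 1:5),
                    time_months = c(2.9, 12, 24, 36, 48),  # p1 < 100 days
                    event = c(0L, 1L, 0L, 1L, 0L))
  tab <- suppressMessages(build_feature_table(feats, ann))
  expect_false("p1" %in% tab$sample)   # 2.9 months ~ 88 days, excluded
  expect_equal(mean(tab$age), 0, tolerance = 1e-12)
  expect_equal(sd(tab$age), 1, tolerance = 1e-12)
  expect_setequal(setdiff(names(tab), c("sample", "time_months", "event")),
                  c("age", "grade_g2", "grade_g3"))
  expect_identical(attr(tab, "reference_levels")$grade, "g1")
  expect_true("age" %in% names(attr(tab, "scaling")))
  feats$age[3] <- NA
  tab2 <- suppressMessages(build_feature_table(feats, ann))
  expect_false("p3" %in% tab2$sample)
  ann$time_months <- rep(1, 5)
  expect_error(suppressMessages(build_feature_table(feats, ann)),
               "no samples left")
})

test_that("a survival-independent feature has a near-unity hazard ratio at large n", {
  tab <- make_table(n = 2000, n_feat = 3, seed = 2)
  res <- univariate_cox_screen(tab)
  expect_true(all(res$hr > 0.9 & res$hr < 1.1))
  expect_true(all(res$q >= res$p))
})

test_that("the Cox score test on a binary covariate equals the hand log-rank statistic", {
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 0, 1, 1, 1, 0)
  grp <- rep(c(0, 1), each = 3)
  fit <- survival::coxph(survival::Surv(time, event) ~ grp)
  hand <- logrank_by_hand(time, event, grp)
  expect_equal(unname(summary(fit)$sctest["test"]),
               unname(hand$chisq_2group), tolerance = 1e-6)
})

test_that("planted hazards rank at the top of the univariate screen", {
  tab <- make_table(n = 500, n_feat = 6,
                    betas = c(log(2), 0, 0, 0, 0, 0), seed = 3)
  res <- univariate_cox_screen(tab)
  expect_identical(res$feature[1], "f1")
  expect_gt(res$hr[1], 1.5)
})

test_that("a constant risk score gives AUC 0.5 under the tie convention", {
  expect_equal(deconvMM:::binary_auc(rep(1, 20), rep(0:1, 10)), 0.5)
})

test_that("the specificity operating point meets the target sensitivity", {
  score <- c(5, 4, 3, 2, 1, 0)
  event <- c(1, 1, 1, 0, 0, 0)
  op <- deconvMM:::spec_at_sensitivity(score, event, target = 0.87)
  expect_gte(op["sensitivity"], 0.87)
  expect_equal(unname(op["specificity"]), 1)
  op2 <- deconvMM:::spec_at_sensitivity(rev(score), event, target = 0.9)
  expect_lte(op2["specificity"], 1 / 3)
})

test_that("repeated cross-validation is seed-reproducible and well-formed", {
  tab <- make_table(n = 60, n_feat = 4, betas = c(1, 0, 0, 0), seed = 5)
  a <- repeated_cv_evaluate(tab, paste0("f", 1:4), k = 5, repeats = 3,
                            seed = 11)
  b <- repeated_cv_evaluate(tab, paste0("f", 1:4), k = 5, repeats = 3,
                            seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a$per_repeat), 3)
  expect_true(all(a$per_repeat$auc >= 0 & a$per_repeat$auc <= 1))
  expect_true(all(a$per_repeat$specificity_at_sensitivity >= 0 &
                    a$per_repeat$specificity_at_sensitivity <= 1))
  expect_true(all(a$per_repeat$sensitivity >= 0.878 |
                    a$per_repeat$sensitivity == 1))
  expect_error(repeated_cv_evaluate(tab, "nope", seed = 1), "absent")
})

test_that("fold partitions are disjoint, exhaustive, and event-stratified", {
  set.seed(4)
  event <- rep(c(0, 1), c(40, 30))
  fold <- deconvMM:::stratified_folds(event, 5)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 70)
  per_fold_events <- tapply(event, fold, sum)
  expect_true(all(per_fold_events == 6))
})

test_that("planted multi-gene hazards yield informative out-of-fold AUC", {
  aucs <- vapply(1:3, function(s) {
    tab <- make_table(n = 94, n_feat = 5, betas = rep(log(1.8), 5),
                      seed = s)
    cv <- repeated_cv_evaluate(tab, paste0("f", 1:5), k = 5, repeats = 5,
                               seed = s)
    cv$summary$mean[cv$summary$metric == "auc"]
  }, numeric(1))
  expect_gt(mean(aucs), 0.65)
})

test_that("nested LASSO selection finds the planted feature and survives empty fits", {
  freqs <- vapply(1:3, function(s) {
    tab <- make_table(n = 94, n_feat = 10, betas = c(log(3), rep(0, 9)),
                      seed = s)
    cv <- nested_cv_lasso(tab, k = 5, repeats = 2, seed = s)
    cv$selection_frequency["f1"]
  }, numeric(1))
  expect_gt(mean(freqs), 0.9)
})

test_that("all-noise features keep nested-CV AUC near chance (leakage canary)", {
  aucs <- vapply(1:4, function(s) {
    tab <- make_table(n = 80, n_feat = 15, seed = s + 50)
    cv <- nested_cv_lasso(tab, k = 5, repeats = 2, seed = s)
    cv$summary$mean[cv$summary$metric == "auc"]
  }, numeric(1))
  expect_gt(mean(aucs), 0.40)
  expect_lt(mean(aucs), 0.60)
})

test_that("tertile stratification reproduces a hand-computed log-rank test", {
  time <- c(1, 3, 5, 2, 4, 6, 7, 8, 9)
  event <- c(1, 1, 0, 1, 1, 0, 1, 0, 1)
  score <- c(9, 8, 7, 5, 4, 6, 1, 2, 3)
  names(score) <- paste0("p", 1:9)
  lr <- tertile_logrank(score, time, event)
  expect_equal(as.vector(table(lr$group)), c(3L, 3L, 3L))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ lr$group)
  expect_equal(lr$chisq, unname(sd_fit$chisq))
  expect_equal(lr$p, pchisq(sd_fit$chisq, 2, lower.tail = FALSE))
  expect_equal(dim(lr$at_risk), c(3L, 6L))
  expect_true(all(lr$at_risk[, 1] == 3))
  expect_error(tertile_logrank(rep(1, 9), time, event), "distinct")
})

test_that("a two-group toy log-rank matches direct observed-vs-expected arithmetic", {
  time <- c(2, 4, 6, 1, 3, 5)
  event <- c(1, 1, 0, 1, 0, 1)
  grp <- rep(c("A", "B"), each = 3)
  hand <- logrank_by_hand(time, event, grp)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(unname(sd_fit$obs), unname(hand$O))
  expect_equal(unname(sd_fit$exp), unname(hand$E))
  expect_equal(unname(sd_fit$chisq), unname(hand$chisq_2group),
               tolerance = 1e-6)
})

test_that("tied scores spanning a tertile boundary fall back to deterministic order", {
  score <- setNames(c(rep(1, 7), 2, 3), paste0("p", 1:9))
  time <- 1:9; event <- rep(1L, 9)
  expect_message(lr <- tertile_logrank(score, time, event), "tie")
  expect_equal(as.vector(table(lr$group)), c(3L, 3L, 3L))
  lr2 <- suppressMessages(tertile_logrank(score, time, event))
  expect_identical(lr$group, lr2$group)
})
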