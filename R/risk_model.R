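DAYS_PER_MONTH <- 365.25 / 12

#' Build the survival feature table
#'
#' Joins a feature matrix to survival annotation, keeps only patients with
#' at least `min_followup_days` of follow-up, drops rows with missing
#' values (counts reported via message), z-scores continuous features
#' (scaling statistics stored for reuse on held-out data) and one-hot
#' encodes categorical features dropping a recorded reference level.
#'
#' @param features data.frame or matrix of per-sample features, rownames =
#'   sample ids. Numeric columns are scaled; character/factor columns are
#'   one-hot encoded.
#' @param annotation data.frame with columns sample, time_months, event
#'   (1 = metachronous metastasis, 0 = right-censored).
#' @param min_followup_days Inclusion threshold on follow-up (default 100).
#' @return A `risk_feature_table` data.frame (sample, time_months, event,
#'   feature columns) with attributes `scaling` (center/scale per
#'   continuous feature), `reference_levels`, and `n_excluded`.
#' @export
build_feature_table <- function(features, annotation,
                                min_followup_days = 100) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "time_months", "event") %in% names(annotation)))
  common <- intersect(annotation$sample, rownames(features))
  ann <- annotation[match(common, annotation$sample), , drop = FALSE]
  feat <- features[common, , drop = FALSE]

  keep_fu <- ann$time_months * DAYS_PER_MONTH >= min_followup_days
  n_short <- sum(!keep_fu)
  ann <- ann[keep_fu, , drop = FALSE]
  feat <- feat[keep_fu, , drop = FALSE]

  cc <- complete.cases(feat) & !is.na(ann$time_months) & !is.na(ann$event)
  n_missing <- sum(!cc)
  ann <- ann[cc, , drop = FALSE]
  feat <- feat[cc, , drop = FALSE]
  if (!nrow(feat))
    stop("no samples left after the follow-up and missing-value filters")
  if (n_short || n_missing)
    message(n_short, " sample(s) below ", min_followup_days,
            " days follow-up and ", n_missing,
            " with missing values excluded")

  num <- vapply(feat, is.numeric, logical(1))
  scaling <- list()
  cols <- list()
  for (nm in names(feat)[num]) {
    ctr <- mean(feat[[nm]]); scl <- sd(feat[[nm]])
    if (scl == 0) scl <- 1
    scaling[[nm]] <- c(center = ctr, scale = scl)
    cols[[nm]] <- (feat[[nm]] - ctr) / scl
  }
  reference_levels <- list()
  for (nm in names(feat)[!num]) {
    f <- factor(feat[[nm]])
    reference_levels[[nm]] <- levels(f)[1]
    for (lv in levels(f)[-1])
      cols[[paste(nm, lv, sep = "_")]] <- as.numeric(f == lv)
  }
  out <- data.frame(sample = ann$sample, time_months = ann$time_months,
                    event = ann$event, cols, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, scaling = scaling, reference_levels = reference_levels,
            n_excluded = c(short_followup = n_short, missing = n_missing),
            class = c("risk_feature_table", "data.frame"))
}

feature_cols <- function(table)
  setdiff(names(table), c("sample", "time_months", "event"))

#' Univariate Cox screen of candidate features
#'
#' One proportional-hazards fit per feature (Efron ties); hazard ratios are
#' per 1 SD for continuous features (the table is z-scored) or versus the
#' recorded reference level for one-hot indicators. Features are ranked by
#' Wald p with BH q-values attached; non-converging fits are flagged, not
#' fatal.
#'
#' @param table A [build_feature_table()] result.
#' @return data.frame (feature, hr, p, q, converged) ordered by p.
#' @export
univariate_cox_screen <- function(table) {
  if (sum(table$event) < 1L) stop("at least one event is required")
  feats <- feature_cols(table)
  res <- lapply(feats, function(nm) {
    fit <- tryCatch(
      survival::coxph(survival::Surv(time_months, event) ~ x,
                      data = data.frame(time_months = table$time_months,
                                        event = table$event,
                                        x = table[[nm]]),
                      ties = "efron"),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fit) || is.na(coef(fit)))
      return(data.frame(feature = nm, hr = NA_real_, p = NA_real_,
                        converged = FALSE))
    s <- summary(fit)
    data.frame(feature = nm, hr = unname(exp(coef(fit))),
               p = s$coefficients[1, "Pr(>|z|)"], converged = TRUE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- NA_real_
  ok <- !is.na(res$p)
  if (any(ok)) res$q[ok] <- bh_adjust(res$p[ok])
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Stratified k-fold assignment preserving event balance; redraws (up to
# `retries`) folds whose training part would hold zero events.
stratified_folds <- function(event, k, retries = 20L) {
  n <- length(event)
  for (r in seq_len(retries)) {
    fold <- integer(n)
    for (lv in unique(event)) {
      idx <- which(event == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f)
      sum(event[fold != f]) > 0 && sum(fold == f) > 0, logical(1)))
    if (ok) return(fold)
    message("fold draw ", r, " left a fold without events; redrawing")
  }
  stop("could not draw folds with events in every training set")
}

# Binary AUC of a score for event vs censored, ties counting 1/2.
binary_auc <- function(score, event) {
  pos <- score[event == 1]; neg <- score[event == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = event, predictor = score,
                                 direction = "<", quiet = TRUE,
                                 levels = c(0, 1))))
}

fold_cindex <- function(time, event, lp) {
  if (sum(event) == 0 || length(unique(lp)) < 2L) return(NA_real_)
  survival::concordance(survival::Surv(time, event) ~ lp,
                        reverse = TRUE)$concordance
}

# Operating point: the threshold (classify positive when score >= t)
# achieving sensitivity >= target with the highest specificity.
spec_at_sensitivity <- function(score, event, target) {
  thr <- sort(unique(score), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(score[event == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(score[event == 0] < t), numeric(1))
  ok <- which(sens >= target)
  if (!length(ok)) return(c(sensitivity = max(sens), specificity = 0))
  i <- ok[1]
  c(sensitivity = sens[i], specificity = spec[i])
}

#' Repeated stratified k-fold cross-validation of a Cox signature
#'
#' Per repeat: samples are split into `k` event-stratified folds; a
#' multivariate Cox model on the signature is fitted on the training folds
#' (features re-standardized with training statistics only) and the linear
#' risk score computed on the held-out fold. AUC (event vs censored),
#' concordance index, AIC and the likelihood-ratio p-value are averaged
#' over the folds of the repeat; the specificity at the target sensitivity
#' is evaluated on the pooled out-of-fold scores of the repeat (per-fold
#' operating points are unstable at ~19 samples, whereas per-fold AUC
#' averaging avoids the pessimistic bias pooling induces when fold models
#' disagree). Aggregate means and standard deviations across repeats are
#' reported.
#'
#' @param table A [build_feature_table()] result.
#' @param signature Character vector of feature columns forming the model.
#' @param k Folds (default 5).
#' @param repeats Repeats (default 100).
#' @param target_sensitivity Sensitivity anchor for the specificity
#'   operating point (default 0.878).
#' @param seed Integer seed; identical seeds reproduce the report exactly.
#' @return A `cv_report` list: `per_repeat` data.frame (repeat, auc,
#'   c_index, aic, lrt_p, sensitivity, specificity_at_sensitivity),
#'   `summary` (means and sds), and call parameters.
#' @export
repeated_cv_evaluate <- function(table, signature, k = 5L, repeats = 100L,
                                 target_sensitivity = 0.878, seed = 1L) {
  stopifnot(k >= 2L)
  miss <- setdiff(signature, feature_cols(table))
  if (length(miss))
    stop("signature feature(s) absent: ", paste(miss, collapse = ", "))
  x <- as.matrix(table[signature])
  time <- table$time_months; event <- table$event
  n <- nrow(x)
  set.seed(seed)
  per <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(event, k)
    lp <- numeric(n)
    aics <- numeric(k); lrps <- numeric(k)
    aucs <- numeric(k); cidxs <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      ctr <- colMeans(x[tr, , drop = FALSE])
      scl <- apply(x[tr, , drop = FALSE], 2L, sd)
      scl[scl == 0] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2L, ctr), 2L, scl, "/")
      xte <- sweep(sweep(x[te, , drop = FALSE], 2L, ctr), 2L, scl, "/")
      dtr <- data.frame(time = time[tr], event = event[tr], xtr,
                        check.names = FALSE)
      fit <- survival::coxph(
        survival::Surv(time, event) ~ .,
        data = dtr, ties = "efron",
        control = survival::coxph.control(iter.max = 50))
      aics[f] <- AIC(fit)
      lrps[f] <- summary(fit)$logtest["pvalue"]
      beta <- coef(fit); beta[is.na(beta)] <- 0
      lp[te] <- as.numeric(xte %*% beta)
      aucs[f] <- binary_auc(lp[te], event[te])
      cidxs[f] <- fold_cindex(time[te], event[te], lp[te])
    }
    op <- spec_at_sensitivity(lp, event, target_sensitivity)
    per[[r]] <- data.frame(
      rep = r, auc = mean(aucs, na.rm = TRUE),
      c_index = mean(cidxs, na.rm = TRUE),
      aic = mean(aics), lrt_p = mean(lrps),
      sensitivity = op["sensitivity"],
      specificity_at_sensitivity = op["specificity"], row.names = NULL)
  }
  per <- do.call(rbind, per)
  new_cv_report(per, k = k, repeats = repeats,
                target_sensitivity = target_sensitivity, seed = seed,
                signature = signature)
}

new_cv_report <- function(per_repeat, ..., selection_frequency = NULL) {
  metrics <- setdiff(names(per_repeat), "rep")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_repeat[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metrics, function(m) sd(per_repeat[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL)
  structure(list(per_repeat = per_repeat, summary = summary,
                 selection_frequency = selection_frequency,
                 params = list(...)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation report (", x$params$repeats, " repeats x ",
      x$params$k, " folds)\n", sep = "")
  print(x$summary, digits = 3)
  if (!is.null(x$selection_frequency)) {
    cat("Feature selection frequency:\n")
    print(round(sort(x$selection_frequency, decreasing = TRUE), 3))
  }
  invisible(x)
}

#' Nested cross-validation with LASSO feature selection
#'
#' Within each outer training set an L1-penalized Cox model
#' ([glmnet::cv.glmnet()], penalty chosen by inner cross-validation)
#' selects features; the outer test fold is scored by an unpenalized Cox
#' model refitted on the selected features. An empty selection yields a
#' constant score for that fold (AUC recorded as 0.5 by the tie
#' convention). AUC and concordance are per-fold averages; the specificity
#' operating point uses the pooled out-of-fold scores. Per-feature
#' selection frequencies are aggregated over all outer folds and repeats.
#'
#' @inheritParams repeated_cv_evaluate
#' @param features Candidate feature columns (default: all).
#' @param inner_k Inner folds for penalty selection (default 5).
#' @return A `cv_report` with `selection_frequency`.
#' @export
nested_cv_lasso <- function(table, features = NULL, k = 5L, repeats = 10L,
                            target_sensitivity = 0.878, inner_k = 5L,
                            seed = 1L) {
  features <- features %||% feature_cols(table)
  if (length(features) < 2L)
    stop("nested LASSO selection needs at least 2 candidate features")
  x <- as.matrix(table[features])
  time <- table$time_months; event <- table$event
  n <- nrow(x)
  if (n < 2L * k) stop("need at least 2*k samples")
  set.seed(seed)
  sel_count <- setNames(numeric(length(features)), features)
  n_folds_total <- 0L
  per <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(event, k)
    lp <- numeric(n)
    aics <- rep(NA_real_, k); lrps <- rep(NA_real_, k)
    aucs <- rep(NA_real_, k); cidxs <- rep(NA_real_, k)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      y <- survival::Surv(time[tr], event[tr])
      inner_id <- stratified_folds(event[tr], inner_k)
      cvfit <- glmnet::cv.glmnet(x[tr, , drop = FALSE], y,
                                 family = "cox", alpha = 1,
                                 foldid = inner_id)
      b <- as.numeric(coef(cvfit, s = "lambda.min"))
      sel <- features[b != 0]
      n_folds_total <- n_folds_total + 1L
      sel_count[sel] <- sel_count[sel] + 1L
      if (!length(sel)) { lp[te] <- 0; aucs[f] <- 0.5; next }
      ctr <- colMeans(x[tr, sel, drop = FALSE])
      scl <- apply(x[tr, sel, drop = FALSE], 2L, sd); scl[scl == 0] <- 1
      xtr <- sweep(sweep(x[tr, sel, drop = FALSE], 2L, ctr), 2L, scl, "/")
      xte <- sweep(sweep(x[te, sel, drop = FALSE], 2L, ctr), 2L, scl, "/")
      fit <- tryCatch(
        survival::coxph(survival::Surv(time[tr], event[tr]) ~ xtr,
                        ties = "efron",
                        control = survival::coxph.control(iter.max = 50)),
        warning = function(w) suppressWarnings(
          survival::coxph(survival::Surv(time[tr], event[tr]) ~ xtr,
                          ties = "efron")),
        error = function(e) NULL)
      if (is.null(fit)) { lp[te] <- 0; aucs[f] <- 0.5; next }
      aics[f] <- AIC(fit)
      lrps[f] <- summary(fit)$logtest["pvalue"]
      beta <- coef(fit); beta[is.na(beta)] <- 0
      lp[te] <- as.numeric(xte %*% beta)
      aucs[f] <- binary_auc(lp[te], event[te])
      cidxs[f] <- fold_cindex(time[te], event[te], lp[te])
    }
    op <- spec_at_sensitivity(lp, event, target_sensitivity)
    per[[r]] <- data.frame(
      rep = r, auc = mean(aucs, na.rm = TRUE),
      c_index = mean(cidxs, na.rm = TRUE),
      aic = mean(aics, na.rm = TRUE), lrt_p = mean(lrps, na.rm = TRUE),
      sensitivity = op["sensitivity"],
      specificity_at_sensitivity = op["specificity"], row.names = NULL)
  }
  per <- do.call(rbind, per)
  new_cv_report(per, k = k, repeats = repeats,
                target_sensitivity = target_sensitivity, seed = seed,
                features = features,
                selection_frequency = sel_count / n_folds_total)
}

#' Tertile stratification and log-rank test of a risk score
#'
#' Splits patients into low/medium/high groups at the 1/3 and 2/3 score
#' quantiles (inclusive linear-interpolation quantiles) and compares their
#' survival with a k-group log-rank test. When score ties span a tertile
#' boundary and collapse a group, assignment falls back to score order with
#' ties broken by sample id (deterministic, message emitted). A per-group
#' number-at-risk table over time is included.
#'
#' @param scores Named numeric risk score vector (names = sample ids).
#' @param time,event Survival time and event indicator, aligned to
#'   `scores`.
#' @param at_risk_times Time grid for the at-risk table (default: 6
#'   equally spaced points from 0 to the maximum time).
#' @return List: `group` (factor low/medium/high), `chisq`, `df`, `p`,
#'   `at_risk` (group-by-time matrix).
#' @export
tertile_logrank <- function(scores, time, event, at_risk_times = NULL) {
  if (length(unique(scores)) < 3L)
    stop("need at least 3 distinct score values for tertiles")
  qs <- quantile(scores, c(1, 2) / 3, type = 7)
  group <- if (qs[1] < qs[2])
    cut(scores, breaks = c(-Inf, qs[1], qs[2], Inf),
        labels = c("low", "medium", "high"))
  else factor(character(length(scores)),
              levels = c("low", "medium", "high"))
  if (length(unique(group)) < 3L) {
    message("ties span a tertile boundary; assigning by score order ",
            "with sample-id tie-break")
    ids <- names(scores) %||% as.character(seq_along(scores))
    ord <- order(scores, ids)
    n <- length(scores)
    bins <- rep(c("low", "medium", "high"),
                times = diff(round(n * c(0, 1, 2, 3) / 3)))
    group <- factor(character(n), levels = c("low", "medium", "high"))
    group[ord] <- bins
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd_fit$n) - 1L
  p <- pchisq(sd_fit$chisq, df, lower.tail = FALSE)
  times <- at_risk_times %||% round(seq(0, max(time), length.out = 6))
  at_risk <- t(vapply(levels(group), function(g)
    vapply(times, function(tt) sum(time[group == g] >= tt), numeric(1)),
    numeric(length(times))))
  colnames(at_risk) <- times
  list(group = group, chisq = unname(sd_fit$chisq), df = df, p = p,
       at_risk = at_risk)
}
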