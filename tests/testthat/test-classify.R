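make_separable <- function(n1 = 12, n2 = 10, p = 4, gap = 8, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * p), n1, p),
             matrix(rnorm(n2 * p, mean = gap), n2, p))
  rownames(x) <- sprintf("P%03d", seq_len(n1 + n2))
  colnames(x) <- paste0("f", seq_len(p))
  y <- factor(rep(c("non_exercise", "exercise"), c(n1, n2)),
              levels = c("non_exercise", "exercise"))
  list(x = x, y = y)
}

test_that("design matrices have the documented shapes and column order", {
  sp <- tiny_spec(seed = 41)
  co <- generate_cohort(sp)
  ft <- compute_feature_table(co)
  d1 <- build_design(ft, feature_set_spec("envelope_only", "affective",
                                          "incompatible"))
  expect_equal(ncol(d1$x), 5)
  expect_equal(colnames(d1$x),
               c("F_A_IC", "FC_A_IC", "C_A_IC", "CP_A_IC", "P_A_IC"))
  expect_equal(levels(d1$y), c("non_exercise", "exercise"))
  d2 <- build_design(ft, feature_set_spec("all_entropy", "affective",
                                          "both"))
  expect_equal(ncol(d2$x), 70) # 7 metrics x 5 regions x 2 conditions
  expect_equal(colnames(d2$x)[1:2],
               c("F_A_C_singular_spectrum", "F_A_C_approximate"))
  d3 <- build_design(ft, feature_set_spec("all_entropy", "combined",
                                          "both"))
  expect_equal(ncol(d3$x), 140)
  d4 <- build_design(ft, feature_set_spec("envelope_only", "affective",
                                          "both"))
  expect_equal(ncol(d4$x), 10)
  # d-score design (error-free logs so no participant is excluded by
  # the 20% rule, which trips easily with tiny blocks)
  co <- generate_cohort(tiny_spec(
    seed = 41, behavior = list(error_rate = 0, miss_rate = 0)))
  ds <- do.call(rbind, lapply(co, function(p) {
    data.frame(participant_id = p$participant_id,
               group_label = p$group_label,
               iat_type = c("affective", "instrumental"),
               d_score = c(score_iat(
                 p$trial_log[p$trial_log$iat_type == "affective", ])$d_score,
                 score_iat(p$trial_log[
                   p$trial_log$iat_type == "instrumental", ])$d_score))
  }))
  dd <- build_design(ds, feature_set_spec("dscore", "combined", "both"))
  expect_equal(colnames(dd$x), c("d_affective", "d_instrumental"))
  expect_equal(nrow(dd$x), 14)
})

test_that("all four classifiers reach 100% on a perfectly separable problem", {
  d <- make_separable()
  for (clf in c("RF", "KNN", "SVM", "LDA")) {
    rep_ <- evaluate_classifier(d$x, d$y, clf, n_repeats = 5, seed = 2)
    acc <- rep_$metrics$mean[rep_$metrics$metric == "accuracy"]
    expect_equal(acc, 100, info = clf)
    expect_equal(as.numeric(rep_$auc), 1, info = clf)
  }
})

test_that("confusion-matrix metric identities hold on pooled counts", {
  set.seed(6)
  d <- make_separable(gap = 1.2) # imperfect problem
  rep_ <- evaluate_classifier(d$x, d$y, "RF", n_repeats = 8, seed = 3)
  ct <- rep_$confusion_totals
  tot <- sum(ct)
  expect_equal(tot, 8 * 7) # 7 test participants per repeat
  acc <- 100 * (ct["TP"] + ct["TN"]) / tot
  sens <- 100 * ct["TP"] / (ct["TP"] + ct["FN"])
  spec <- 100 * ct["TN"] / (ct["TN"] + ct["FP"])
  prec <- 100 * ct["TP"] / (ct["TP"] + ct["FP"])
  f1 <- 2 * prec * sens / (prec + sens)
  # per-repeat means are means of per-repeat ratios, so compare the
  # pooled identities against pooled recomputation only
  expect_equal(as.numeric(acc),
               100 * mean(rep_$scores$truth ==
                          ifelse(rep_$scores$score > 0.5, "non_exercise",
                                 "exercise")), tolerance = 30)
  expect_true(all(rep_$metrics$mean >= 0 & rep_$metrics$mean <= 100))
  # per-repeat F1 consistency with its own precision/sensitivity
  pr <- rep_$per_repeat
  ok <- !is.na(pr$f1) & !is.na(pr$precision) & !is.na(pr$sensitivity) &
    (pr$precision + pr$sensitivity) > 0
  expect_equal(pr$f1[ok],
               2 * pr$precision[ok] * pr$sensitivity[ok] /
                 (pr$precision[ok] + pr$sensitivity[ok]),
               tolerance = 1e-9)
})

test_that("evaluation is bit-identical under a fixed seed", {
  d <- make_separable(gap = 1.5)
  r1 <- evaluate_classifier(d$x, d$y, "RF", n_repeats = 4, seed = 9)
  r2 <- evaluate_classifier(d$x, d$y, "RF", n_repeats = 4, seed = 9)
  expect_identical(r1, r2)
  r3 <- evaluate_classifier(d$x, d$y, "RF", n_repeats = 4, seed = 10)
  expect_false(identical(r1$per_repeat, r3$per_repeat))
})

test_that("shuffled labels fall to the baseline; a label-leak canary is caught", {
  set.seed(12)
  d <- make_separable(n1 = 14, n2 = 12, gap = 0)
  accs <- vapply(1:6, function(s) {
    r <- evaluate_classifier(d$x, d$y, "RF", n_repeats = 4, seed = s)
    r$metrics$mean[r$metrics$metric == "accuracy"]
  }, numeric(1))
  expect_lt(mean(accs), 70) # majority class is 54%
  # anti-leakage canary: a feature equal to the label must give ~100%
  x2 <- cbind(d$x, canary = as.numeric(d$y == "non_exercise"))
  r <- evaluate_classifier(x2, d$y, "LDA", n_repeats = 4, seed = 1)
  expect_gt(r$metrics$mean[r$metrics$metric == "accuracy"], 95)
  # a test-only-informative feature must not help: standardization is
  # fitted on the training split, so no information can leak from test
  r2 <- evaluate_classifier(d$x, d$y, "LDA", n_repeats = 4, seed = 1)
  expect_lt(r2$metrics$mean[r2$metrics$metric == "accuracy"], 80)
})

test_that("duplicated feature columns leave RF accuracy unchanged within noise", {
  d <- make_separable(gap = 2, seed = 8)
  r1 <- evaluate_classifier(d$x, d$y, "RF", n_repeats = 6, seed = 4)
  xdup <- cbind(d$x, d$x)
  colnames(xdup) <- make.unique(colnames(xdup))
  r2 <- evaluate_classifier(xdup, d$y, "RF", n_repeats = 6, seed = 4)
  a1 <- r1$metrics$mean[r1$metrics$metric == "accuracy"]
  a2 <- r2$metrics$mean[r2$metrics$metric == "accuracy"]
  expect_lt(abs(a1 - a2), 12)
})

test_that("ROC/AUC equals the exhaustive pair-counting oracle", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3)
  labels <- factor(c("non_exercise", "exercise", "non_exercise",
                     "non_exercise", "exercise", "exercise"),
                   levels = c("non_exercise", "exercise"))
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, oracle_auc(scores, labels == "non_exercise"))
  # perfect ranking
  r2 <- roc_auc(c(3, 2, 1), factor(c("non_exercise", "non_exercise",
                                     "exercise"),
                                   levels = c("non_exercise", "exercise")))
  expect_equal(r2$auc, 1)
  # ties counted half
  r3 <- roc_auc(c(1, 1), factor(c("non_exercise", "exercise"),
                                levels = c("non_exercise", "exercise")))
  expect_equal(as.numeric(r3$auc), 0.5)
  expect_true(attr(r3$auc, "degenerate"))
  # random scores on larger n: near 0.5, and matches oracle exactly
  set.seed(14)
  sc <- rnorm(400)
  lb <- factor(sample(c("non_exercise", "exercise"), 400, TRUE),
               levels = c("non_exercise", "exercise"))
  r4 <- roc_auc(sc, lb)
  expect_equal(r4$auc, oracle_auc(sc, lb == "non_exercise"),
               tolerance = 1e-12)
  expect_lt(abs(r4$auc - 0.5), 0.08)
  # curve endpoints
  expect_equal(unlist(r4$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r4$points[nrow(r4$points), ]), c(fpr = 1, tpr = 1))
})

test_that("AUC agrees with an established implementation", {
  set.seed(15)
  sc <- rnorm(60)
  lb <- factor(sample(c("non_exercise", "exercise"), 60, TRUE),
               levels = c("non_exercise", "exercise"))
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(lb == "non_exercise", sc, quiet = TRUE))))
  expect_equal(as.numeric(roc_auc(sc, lb)$auc), ref, tolerance = 1e-12)
})

test_that("top-5 importances: ordering, shares sum to 1, informative feature found", {
  set.seed(16)
  n <- 30
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(rep(c("non_exercise", "exercise"), c(16, 14)),
              levels = c("non_exercise", "exercise"))
  x[, 3] <- x[, 3] + 3 * (y == "non_exercise") # single informative feature
  r <- evaluate_classifier(x, y, "RF", n_repeats = 5, seed = 6)
  top <- rf_importance_top5(r)
  expect_equal(nrow(top), 5)
  expect_equal(sum(top$normalized_share), 1, tolerance = 1e-9)
  expect_equal(top$feature[1], "f3")
  expect_gt(top$normalized_share[1], 0.2)
  expect_true(all(diff(top$raw) <= 0))
  # fewer than 5 features: renormalized over what exists
  x2 <- x[, 1:3]
  r2 <- evaluate_classifier(x2, y, "RF", n_repeats = 3, seed = 6)
  top2 <- rf_importance_top5(r2)
  expect_equal(nrow(top2), 3)
  expect_equal(sum(top2$normalized_share), 1, tolerance = 1e-9)
  # non-RF reports carry no importances
  rl <- evaluate_classifier(x, y, "LDA", n_repeats = 3, seed = 6)
  expect_error(rf_importance_top5(rl), "RF")
})

test_that("single-class guards and repeat counting", {
  d <- make_separable(n1 = 3, n2 = 1)
  expect_error(evaluate_classifier(d$x, d$y, "RF"), "2 participants")
  d2 <- make_separable()
  r <- evaluate_classifier(d2$x, d2$y, "KNN", n_repeats = 3, seed = 1)
  expect_equal(nrow(r$per_repeat), 3)
})

test_that("stratified k-fold protocol covers every participant once per run", {
  d <- make_separable(gap = 1)
  r <- evaluate_classifier(d$x, d$y, "RF", protocol = "kfold",
                           n_repeats = 5, seed = 2)
  expect_equal(sum(r$confusion_totals), nrow(d$x)) # each tested once
})
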