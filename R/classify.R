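#' Specification of a classifier feature set
#'
#' Selects which features enter a classification design: D-scores, all
#' seven entropy metrics, or envelope entropy only; which IAT type(s);
#' and which task condition(s).
#'
#' @param source `"dscore"`, `"all_entropy"` or `"envelope_only"`.
#' @param iat_scope `"affective"`, `"instrumental"` or `"combined"`.
#' @param condition_scope `"compatible"`, `"incompatible"` or `"both"`.
#' @return object of class `feature_set_spec`.
#' @export
feature_set_spec <- function(source = c("envelope_only", "all_entropy",
                                        "dscore"),
                             iat_scope = c("affective", "instrumental",
                                           "combined"),
                             condition_scope = c("incompatible",
                                                 "compatible", "both")) {
  structure(list(source = match.arg(source),
                 iat_scope = match.arg(iat_scope),
                 condition_scope = match.arg(condition_scope)),
            class = "feature_set_spec")
}

region_codes <- c(frontal = "F", fronto_central = "FC", central = "C",
                  centro_parietal = "CP", parietal = "P")
iat_codes <- c(affective = "A", instrumental = "I")
cond_codes <- c(compatible = "C", incompatible = "IC")

spec_conditions <- function(spec) {
  iats <- if (spec$iat_scope == "combined") c("affective", "instrumental")
          else spec$iat_scope
  blocks <- if (spec$condition_scope == "both")
    c("compatible", "incompatible") else spec$condition_scope
  as.vector(outer(iats, blocks, paste, sep = "_"))
}

#' Build a participants x features design matrix
#'
#' Assembles the design for one [feature_set_spec()]: entropy features
#' are labelled `<region>_<iat>_<block>` (e.g. `FC_A_IC` =
#' fronto-central, affective incompatible) with a `_<metric>` suffix
#' when more than one metric is included; columns are ordered
#' condition-major, region-minor, metric-innermost. D-score designs
#' have one column per IAT type. Participants with any missing feature
#' are dropped with a message.
#'
#' @param table a [compute_feature_table()] result, or for
#'   `source = "dscore"` a data frame with `participant_id`,
#'   `iat_type`, `d_score`.
#' @param spec a [feature_set_spec()].
#' @param labels named vector participant_id -> group label; defaults
#'   to the table's `group_label` column.
#' @return list with `x` (numeric matrix), `y` (factor with levels
#'   `non_exercise`, `exercise`; `non_exercise` is the positive class).
#' @export
build_design <- function(table, spec, labels = NULL) {
  if (is.null(labels)) {
    u <- unique(table[, c("participant_id", "group_label")])
    labels <- setNames(u$group_label, u$participant_id)
  }
  if (spec$source == "dscore") {
    iats <- if (spec$iat_scope == "combined")
      c("affective", "instrumental") else spec$iat_scope
    ids <- unique(table$participant_id)
    x <- sapply(iats, function(it) {
      v <- table$d_score[match(paste(ids, it),
                               paste(table$participant_id, table$iat_type))]
      v
    })
    x <- matrix(x, nrow = length(ids),
                dimnames = list(ids, paste0("d_", iats)))
  } else {
    metrics <- if (spec$source == "envelope_only") "envelope"
               else entropy_metrics()
    conds <- spec_conditions(spec)
    regions <- names(region_map())
    ids <- unique(table$participant_id)
    cols <- list()
    for (cond in conds) {
      bl <- block_of_condition(cond)
      for (r in regions) for (m in metrics) {
        lab <- paste(region_codes[[r]], iat_codes[[bl$iat_type]],
                     cond_codes[[bl$block]], sep = "_")
        if (length(metrics) > 1) lab <- paste(lab, m, sep = "_")
        sub <- table[table$condition == cond & table$region == r &
                       table$metric == m, , drop = FALSE]
        cols[[lab]] <- sub$value[match(ids, sub$participant_id)]
      }
    }
    x <- do.call(cbind, cols)
    rownames(x) <- ids
  }
  ok <- stats::complete.cases(x)
  if (any(!ok))
    message(sum(!ok), " participant(s) with missing features dropped")
  x <- x[ok, , drop = FALSE]
  y <- factor(labels[rownames(x)], levels = c("non_exercise", "exercise"))
  list(x = x, y = y)
}

confusion_metrics <- function(pred, truth, positive = "non_exercise") {
  tp <- sum(pred == positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       metrics = 100 * c(accuracy = (tp + tn) / length(truth),
                         sensitivity = sens, specificity = spec,
                         precision = prec, f1 = f1))
}

stratified_split <- function(y, train_frac) {
  train <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    n_tr <- max(1, round(train_frac * length(idx)))
    n_tr <- min(n_tr, length(idx) - 1) # keep >=1 of each class in test
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

median_heuristic_gamma <- function(x) {
  d <- as.numeric(stats::dist(x))
  med <- median(d[d > 0])
  if (!is.finite(med) || med == 0) return(1 / ncol(x))
  1 / (2 * med^2)
}

fit_predict <- function(classifier, x_tr, y_tr, x_te, standardize) {
  positive <- "non_exercise"
  if (standardize && classifier != "RF") {
    mu <- colMeans(x_tr)
    sdv <- apply(x_tr, 2, sd)
    sdv[sdv == 0] <- 1
    x_tr <- scale(x_tr, mu, sdv)
    x_te <- scale(x_te, mu, sdv)
  }
  if (classifier == "RF") {
    fit <- randomForest::randomForest(x_tr, y_tr, ntree = 100, nodesize = 5)
    prob <- predict(fit, x_te, type = "prob")[, positive]
    pred <- predict(fit, x_te)
    imp <- fit$importance[, 1]
  } else if (classifier == "KNN") {
    pr <- class::knn(x_tr, x_te, y_tr, k = 5, prob = TRUE)
    win <- attr(pr, "prob")
    prob <- ifelse(pr == positive, win, 1 - win)
    pred <- pr
    imp <- NULL
  } else if (classifier == "SVM") {
    fit <- e1071::svm(x_tr, y_tr, kernel = "radial", cost = 1,
                      gamma = median_heuristic_gamma(x_tr),
                      probability = FALSE)
    dv <- attr(predict(fit, x_te, decision.values = TRUE),
               "decision.values")
    # orient the decision value toward the positive class
    s <- if (grepl(paste0("^", positive, "/"), colnames(dv)[1])) 1 else -1
    prob <- s * dv[, 1]
    pred <- predict(fit, x_te)
    imp <- NULL
  } else if (classifier == "LDA") {
    fit <- tryCatch(MASS::lda(x_tr, grouping = y_tr),
                    error = function(e) NULL)
    if (is.null(fit)) {
      # ridge fallback for singular within-class covariance
      S <- stats::cov(x_tr - rowsum(x_tr, y_tr)[y_tr, ] /
                        as.vector(table(y_tr)[y_tr]))
      S <- S + diag(1e-3 * mean(diag(S)) + 1e-12, ncol(S))
      mu1 <- colMeans(x_tr[y_tr == positive, , drop = FALSE])
      mu0 <- colMeans(x_tr[y_tr != positive, , drop = FALSE])
      w <- solve(S, mu1 - mu0)
      thr <- as.numeric((mu1 + mu0) %*% w / 2)
      sc <- as.numeric(x_te %*% w)
      prob <- stats::plogis(sc - thr)
      pred <- factor(ifelse(sc > thr, positive,
                            setdiff(levels(y_tr), positive)),
                     levels = levels(y_tr))
    } else {
      pr <- predict(fit, x_te)
      prob <- pr$posterior[, positive]
      pred <- pr$class
    }
    imp <- NULL
  } else stop("unknown classifier: ", classifier)
  list(pred = pred, score = as.numeric(prob), importance = imp)
}

#' Evaluate a classifier under the repeated-split protocol
#'
#' Default protocol: `n_repeats` (10) stratified random 70/30
#' train/test splits; metrics (accuracy, sensitivity, specificity,
#' precision, F1, in percent, positive class = non-exercise) are
#' computed on each test-set confusion matrix and reported mean +- SD
#' across repeats. Alternatively `protocol = "kfold"` runs one
#' stratified 10-fold cross-validation, with folds as repeats. KNN,
#' SVM and LDA features are standardized with training-split statistics
#' only; random forests use raw features. Hyperparameters are fixed:
#' RF 100 trees / min 5 samples per leaf, KNN 5 neighbors (Euclidean),
#' SVM RBF kernel with box constraint 1 and median-heuristic kernel
#' scale, LDA with a ridge fallback when the within-class covariance is
#' singular.
#'
#' @param x numeric design matrix (participants x features).
#' @param y factor with levels `non_exercise`, `exercise`.
#' @param classifier one of `"RF"`, `"KNN"`, `"SVM"`, `"LDA"`.
#' @param protocol `"repeated_split"` (default) or `"kfold"`.
#' @param n_repeats repeats (splits or folds).
#' @param train_frac training fraction for repeated splits.
#' @param standardize standardize features for KNN/SVM/LDA?
#' @param seed root seed; one substream per repeat.
#' @return object of class `model_report`: `classifier`, `metrics`
#'   (mean/sd per metric), `per_repeat`, `confusion_totals`, `auc`,
#'   `roc`, `scores`, and for RF `importance` (mean impurity decrease
#'   per feature).
#' @export
evaluate_classifier <- function(x, y, classifier = c("RF", "KNN", "SVM",
                                                     "LDA"),
                                protocol = c("repeated_split", "kfold"),
                                n_repeats = 10, train_frac = 0.7,
                                standardize = TRUE, seed = 1) {
  classifier <- match.arg(classifier)
  protocol <- match.arg(protocol)
  if (min(table(y)) < 2) stop("need at least 2 participants per class")
  folds <- NULL
  if (protocol == "kfold") {
    folds <- with_seed(substream_seed(seed, "folds"), {
      f <- integer(length(y))
      for (lev in levels(y)) {
        idx <- sample(which(y == lev))
        f[idx] <- rep_len(seq_len(n_repeats), length(idx))
      }
      f
    })
  }
  per <- list(); counts <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  scores <- numeric(0); truths <- character(0)
  imps <- NULL
  for (rep_i in seq_len(n_repeats)) {
    res <- with_seed(substream_seed(seed, "repeat", rep_i), {
      if (protocol == "repeated_split") {
        tr <- stratified_split(y, train_frac)
      } else {
        tr <- which(folds != rep_i)
      }
      te <- setdiff(seq_along(y), tr)
      fit_predict(classifier, x[tr, , drop = FALSE], y[tr],
                  x[te, , drop = FALSE], standardize) |>
        c(list(te = te))
    })
    cm <- confusion_metrics(res$pred, y[res$te])
    per[[rep_i]] <- cm$metrics
    counts <- counts + cm$counts
    scores <- c(scores, res$score)
    truths <- c(truths, as.character(y[res$te]))
    if (!is.null(res$importance)) {
      if (is.null(imps)) imps <- res$importance else
        imps <- imps + res$importance
    }
  }
  per <- do.call(rbind, per)
  roc <- roc_auc(scores, factor(truths, levels = levels(y)))
  structure(list(
    classifier = classifier, protocol = protocol,
    metrics = data.frame(metric = colnames(per),
                         mean = colMeans(per, na.rm = TRUE),
                         sd = apply(per, 2, sd, na.rm = TRUE),
                         row.names = NULL),
    per_repeat = as.data.frame(per),
    confusion_totals = counts,
    auc = roc$auc, roc = roc$points,
    scores = data.frame(score = scores, truth = truths),
    importance = if (!is.null(imps)) imps / n_repeats else NULL
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s (%s), AUC %.3f\n", x$classifier,
              x$protocol, x$auc))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-11s %5.1f +- %.1f %%\n", m$metric[i], m$mean[i],
                m$sd[i]))
  invisible(x)
}

#' ROC curve and AUC from classification scores
#'
#' AUC is computed as the normalized Mann-Whitney rank statistic of the
#' positive-class scores (ties counted half), with curve points at every
#' distinct threshold. Constant scores yield AUC 0.5 with attribute
#' `degenerate = TRUE`.
#'
#' @param scores numeric vector, larger = more positive-class.
#' @param labels factor; the first level is the positive class.
#' @return list with `points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == levels(labels)[1]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (length(unique(scores)) == 1) {
    return(list(points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                auc = structure(0.5, degenerate = TRUE)))
  }
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(th) {
    c(fpr = sum(scores >= th & !pos) / n0,
      tpr = sum(scores >= th & pos) / n1)
  }, numeric(2)))
  pts <- rbind(c(fpr = 0, tpr = 0), pts)
  list(points = as.data.frame(pts), auc = auc)
}

#' Top-5 normalized random-forest feature importances
#'
#' Averages impurity-decrease importances over evaluation repeats (as
#' returned in a `model_report`), keeps the five largest, and
#' normalizes each as its share of the top-five total, so the shares
#' sum to 1.
#'
#' @param report a `model_report` from an RF [evaluate_classifier()]
#'   run, or a named numeric vector of importances.
#' @return data frame `feature`, `raw`, `normalized_share`, sorted
#'   descending.
#' @export
rf_importance_top5 <- function(report) {
  imp <- if (inherits(report, "model_report")) report$importance
         else report
  if (is.null(imp)) stop("no importances available (RF only)")
  imp <- sort(imp, decreasing = TRUE)
  k <- min(5, length(imp))
  top <- imp[seq_len(k)]
  data.frame(feature = names(top), raw = as.numeric(top),
             normalized_share = as.numeric(top) / sum(top),
             row.names = NULL)
}
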