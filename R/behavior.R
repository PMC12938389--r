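#' Trial-level filters for IAT D-score computation
#'
#' Applies the improved-algorithm preprocessing rules to one
#' participant's trials of a single IAT type: practice trials are
#' dropped; formal trials with missing responses or reaction times below
#' 350 ms are discarded; and the participant is flagged for exclusion if
#' the error rate (incorrect responses among formal trials) exceeds 20%
#' in either block.
#'
#' The error-rate check is computed on all formal trials, before the
#' reaction-time filter, so that fast errors still count against the
#' participant. See the methods vignette for this ordering choice.
#'
#' @param trials data frame of trials with columns `block`
#'   ("compatible"/"incompatible"), `practice` (logical), `rt_ms`
#'   (numeric, NA = missing response), `correct` (logical).
#' @return list with `retained` (filtered data frame), `participant_ok`
#'   (logical) and `reason` (character, `""` when ok).
#' @examples
#' tr <- data.frame(block = "compatible", practice = FALSE,
#'                  rt_ms = c(340, 350, 360), correct = TRUE)
#' filter_trials(tr)$retained$rt_ms  # 350 360
#' @export
filter_trials <- function(trials) {
  required <- c("block", "practice", "rt_ms", "correct")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols))
    stop("trial log lacks columns: ", paste(missing_cols, collapse = ", "))
  formal <- trials[!trials$practice, , drop = FALSE]
  if (nrow(formal) == 0)
    return(list(retained = formal, participant_ok = FALSE,
                reason = "no formal trials"))
  # 20% rule per block, on formal trials (missing response = incorrect)
  bad <- FALSE
  for (b in unique(formal$block)) {
    fb <- formal[formal$block == b, , drop = FALSE]
    err <- mean(!fb$correct | is.na(fb$rt_ms))
    if (err > 0.20) bad <- TRUE
  }
  keep <- !is.na(formal$rt_ms) & formal$rt_ms >= 350
  retained <- formal[keep, , drop = FALSE]
  list(retained = retained,
       participant_ok = !bad,
       reason = if (bad) "error rate above 20% in a block" else "")
}

#' Replace incorrect-trial reaction times by the block penalty
#'
#' Incorrect trials receive an effective reaction time equal to the mean
#' of the correct trials in the same block plus 400 ms; correct trials
#' are unchanged.
#'
#' @param retained filtered trials of one block (see [filter_trials()]).
#' @param block block label to process; defaults to all rows.
#' @return the trials with an `rt_effective` column.
#' @export
apply_error_penalty <- function(retained, block = NULL) {
  x <- if (is.null(block)) retained else
    retained[retained$block == block, , drop = FALSE]
  x$rt_effective <- x$rt_ms
  for (b in unique(x$block)) {
    sel <- x$block == b
    corr <- sel & x$correct
    if (!any(corr))
      stop("block '", b, "' has no correct trials; cannot compute penalty")
    pen <- mean(x$rt_ms[corr]) + 400
    x$rt_effective[sel & !x$correct] <- pen
  }
  x
}

#' Compute the IAT D-score for one participant and IAT type
#'
#' D = (mean incompatible RT - mean compatible RT) / pooled SD, where
#' the means use penalty-adjusted effective reaction times and the
#' pooled SD is, by default, the sample standard deviation (n-1) of the
#' union of correct-trial raw reaction times from both blocks
#' (`sd_method = "union"`). The classical two-sample pooled estimator is
#' available via `sd_method = "two_sample"`.
#'
#' @param compatible,incompatible data frames with `rt_ms`, `correct`
#'   and `rt_effective` columns (see [apply_error_penalty()]).
#' @param sd_method `"union"` (default) or `"two_sample"`.
#' @return list with `d_score`, `n_trials_used`, `excluded_participant`,
#'   `exclusion_reason`.
#' @export
compute_dscore <- function(compatible, incompatible,
                           sd_method = c("union", "two_sample")) {
  sd_method <- match.arg(sd_method)
  if (nrow(compatible) == 0 || nrow(incompatible) == 0)
    stop("both blocks must be non-empty after filtering")
  rc <- compatible$rt_ms[compatible$correct]
  ri <- incompatible$rt_ms[incompatible$correct]
  pooled_sd <- if (sd_method == "union") {
    sd(c(rc, ri))
  } else {
    n1 <- length(rc); n2 <- length(ri)
    sqrt(((n1 - 1) * var(rc) + (n2 - 1) * var(ri)) / (n1 + n2 - 2))
  }
  if (!is.finite(pooled_sd) || pooled_sd == 0)
    stop("pooled SD of correct-trial reaction times is zero; D undefined")
  d <- (mean(incompatible$rt_effective) - mean(compatible$rt_effective)) /
    pooled_sd
  list(d_score = d,
       n_trials_used = nrow(compatible) + nrow(incompatible),
       excluded_participant = FALSE,
       exclusion_reason = "")
}

#' Score one participant's trial log for one IAT type
#'
#' Convenience wrapper chaining [filter_trials()],
#' [apply_error_penalty()] and [compute_dscore()].
#'
#' @param trials trial data frame for one participant and IAT type.
#' @inheritParams compute_dscore
#' @return a `DScoreResult`-like list; when the participant fails the
#'   error-rate screen, `d_score` is `NA` and `excluded_participant` is
#'   `TRUE` with a reason.
#' @export
score_iat <- function(trials, sd_method = c("union", "two_sample")) {
  sd_method <- match.arg(sd_method)
  f <- filter_trials(trials)
  if (!f$participant_ok)
    return(list(d_score = NA_real_, n_trials_used = 0L,
                excluded_participant = TRUE, exclusion_reason = f$reason))
  pen <- apply_error_penalty(f$retained)
  compute_dscore(pen[pen$block == "compatible", , drop = FALSE],
                 pen[pen$block == "incompatible", , drop = FALSE],
                 sd_method = sd_method)
}

#' IPAQ MET-min/week components of a 7-day exercise recall
#'
#' Each component is MET value x minutes/day x days/week, with
#' walking = 3.3 METs, moderate = 4 METs and vigorous = 8 METs. The
#' moderate-to-vigorous total (`mvpa_total`) excludes walking, since
#' exercise behavior is operationalized as presence of
#' moderate-to-vigorous activity.
#'
#' @param report list or one-row data frame with `walking_days`,
#'   `walking_min`, `moderate_days`, `moderate_min`, `vigorous_days`,
#'   `vigorous_min`.
#' @return list with `walking`, `moderate`, `vigorous`, `mvpa_total`
#'   in MET-min/week.
#' @examples
#' compute_met_minutes(list(walking_days = 3, walking_min = 30,
#'   moderate_days = 0, moderate_min = 0,
#'   vigorous_days = 3, vigorous_min = 40))
#' @export
compute_met_minutes <- function(report) {
  met <- c(walking = 3.3, moderate = 4, vigorous = 8)
  for (f in c("walking", "moderate", "vigorous")) {
    d <- report[[paste0(f, "_days")]]
    m <- report[[paste0(f, "_min")]]
    if (is.null(d) || is.null(m) || d < 0 || m < 0 || d > 7)
      stop("invalid exercise report field: ", f)
  }
  w <- met[["walking"]] * report$walking_min * report$walking_days
  mo <- met[["moderate"]] * report$moderate_min * report$moderate_days
  v <- met[["vigorous"]] * report$vigorous_min * report$vigorous_days
  list(walking = w, moderate = mo, vigorous = v, mvpa_total = mo + v)
}

#' Assign the exercise / non-exercise group label
#'
#' A participant is `non_exercise` if and only if their
#' moderate-to-vigorous MET-min/week total is exactly zero; any positive
#' total makes them `exercise`. Walking does not count.
#'
#' @inheritParams compute_met_minutes
#' @return list with `label` and `mvpa_met_min_week`.
#' @export
assign_group <- function(report) {
  met <- compute_met_minutes(report)
  list(label = if (met$mvpa_total > 0) "exercise" else "non_exercise",
       mvpa_met_min_week = met$mvpa_total)
}
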