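#' Compute the participant x condition x region x metric feature table
#'
#' For every participant-condition epoch set: each of the seven entropy
#' metrics is estimated per epoch and electrode on the configured
#' segment (full -500..1000 ms epoch by default), averaged across
#' epochs, then across the region's representative electrodes. Sample
#' entropy values that are undefined (no template matches) are excluded
#' from the averages and counted in `n_undefined`.
#'
#' @param cohort list of participant records, each with `participant_id`
#'   and `epoch_sets` (see [generate_cohort()]); epoch sets should be
#'   preprocessed. Participant-conditions with zero kept epochs are
#'   omitted with a message.
#' @param regions named list region -> electrodes ([region_map()]).
#' @param cfg an [entropy_config()].
#' @param metrics subset of [entropy_metrics()] to compute.
#' @param conditions subset of [iat_conditions()] to process (all by
#'   default); restricting conditions proportionally reduces compute in
#'   large simulation studies.
#' @return long data frame (class `feature_table`): `participant_id`,
#'   `group_label`, `condition`, `region`, `metric`, `value`,
#'   `n_epochs`, `n_undefined`.
#' @export
compute_feature_table <- function(cohort, regions = region_map(),
                                  cfg = entropy_config(),
                                  metrics = entropy_metrics(),
                                  conditions = iat_conditions()) {
  metrics <- match.arg(metrics, entropy_metrics(), several.ok = TRUE)
  acc <- list(participant_id = character(0), group_label = character(0),
              condition = character(0), region = character(0),
              metric = character(0), value = numeric(0),
              n_epochs = integer(0), n_undefined = integer(0))
  n_reg <- length(regions)
  n_met <- length(metrics)
  region_of <- rep(names(regions), lengths(regions))
  for (p in cohort) {
    for (cond in intersect(names(p$epoch_sets), conditions)) {
      es <- p$epoch_sets[[cond]]
      n_ep <- dim(es$data)[1]
      if (n_ep == 0) {
        message("participant ", p$participant_id, ", condition ", cond,
                ": zero kept epochs; row omitted")
        next
      }
      seg <- segment_index(es, cfg)
      chan_idx <- match(unlist(regions, use.names = FALSE),
                        es$channel_names)
      if (anyNA(chan_idx))
        stop("epoch set lacks region electrodes for participant ",
             p$participant_id)
      # per epoch x channel metric values for region electrodes,
      # batched: one kernel call per participant-condition
      vals <- batch_channel_metrics(es$data, chan_idx, seg, cfg, metrics)
      # average over epochs, then over the region's electrodes
      reg_val <- matrix(NA_real_, n_met, n_reg)
      reg_und <- matrix(0L, n_met, n_reg)
      for (ri in seq_len(n_reg)) {
        cols <- which(region_of == names(regions)[ri])
        v <- vals[, , cols, drop = FALSE]
        reg_val[, ri] <- apply(v, 1, mean, na.rm = TRUE)
        reg_und[, ri] <- apply(v, 1, function(z) sum(is.na(z)))
      }
      k <- n_reg * n_met
      acc$participant_id <- c(acc$participant_id,
                              rep(p$participant_id, k))
      acc$group_label <- c(acc$group_label,
                           rep(p$group_label %||% NA_character_, k))
      acc$condition <- c(acc$condition, rep(cond, k))
      acc$region <- c(acc$region, rep(names(regions), each = n_met))
      acc$metric <- c(acc$metric, rep(metrics, n_reg))
      acc$value <- c(acc$value, as.numeric(reg_val))
      acc$n_epochs <- c(acc$n_epochs, rep(n_ep, k))
      acc$n_undefined <- c(acc$n_undefined, as.integer(reg_und))
    }
  }
  out <- as.data.frame(acc)
  class(out) <- c("feature_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# metrics x epoch x channel array of estimator values for the selected
# channels/segment of an epochs x channels x samples array. Matches
# channel_metrics() per segment but computes whole epoch sets per call.
batch_channel_metrics <- function(data, chan_idx, seg, cfg, metrics) {
  n_ep <- dim(data)[1]
  n_ch <- length(chan_idx)
  N <- length(seg)
  # columns: epoch fastest, then channel
  X <- matrix(aperm(data[, chan_idx, seg, drop = FALSE], c(3, 1, 2)),
              nrow = N)
  vals <- array(NA_real_, dim = c(length(metrics), n_ep, n_ch))
  kernel_metrics <- c("approximate", "sample", "fuzzy", "permutation",
                      "singular_spectrum")
  want <- kernel_metrics %in% metrics
  if (any(want)) {
    L <- min(cfg$sse_window, floor(2 * N / 3))
    if (want[5] && L < 2) stop("segment too short for singular spectrum")
    res <- .entropy_batch_cpp(X, cfg$m_embed, cfg$r_tol,
                              cfg$r_mode == "sd_scaled",
                              cfg$fuzzy_power, cfg$m_perm, cfg$tau,
                              max(L, 2L), cfg$sse_weight == "sigma_sq",
                              want)
    rownames(res) <- kernel_metrics
    if ("permutation" %in% metrics && cfg$perm_normalize)
      res["permutation", ] <- res["permutation", ] /
        log(factorial(cfg$m_perm))
    for (m in intersect(metrics, kernel_metrics))
      vals[match(m, metrics), , ] <- res[m, ]
  }
  if ("envelope" %in% metrics) {
    w <- numeric(N)
    if (N %% 2 == 0) { w[1] <- 1; w[N / 2 + 1] <- 1; w[2:(N / 2)] <- 2 }
    else { w[1] <- 1; w[2:((N + 1) / 2)] <- 2 }
    an <- stats::mvfft(stats::mvfft(X) * w, inverse = TRUE) / N
    a <- Mod(an)
    tot <- colSums(a)
    if (any(tot == 0)) stop("all-zero signal has no envelope")
    p <- sweep(a, 2, tot, "/")
    vals[match("envelope", metrics), , ] <-
      -colSums(ifelse(p > 0, p * log(p), 0))
  }
  if ("log_energy" %in% metrics) {
    vals[match("log_energy", metrics), , ] <-
      colSums(log(X^2 + .Machine$double.xmin))
  }
  vals
}

segment_index <- function(es, cfg) {
  if (cfg$segment == "post_stimulus") {
    t <- epoch_times(es)
    which(t >= 0)
  } else {
    seq_len(dim(es$data)[3])
  }
}

#' Preprocess every epoch set of a cohort
#'
#' Applies [preprocess_epochs()] (downsampling to `target_rate_hz`,
#' baseline correction, amplitude rejection) to each
#' participant-condition.
#'
#' @param cohort a cohort (see [generate_cohort()]).
#' @inheritParams preprocess_epochs
#' @return the cohort with preprocessed epoch sets; each record gains
#'   `n_rejected` (named by condition).
#' @export
preprocess_cohort <- function(cohort, target_rate_hz = 500,
                              reject_uv = 100) {
  for (i in seq_along(cohort)) {
    nr <- integer(0)
    for (cond in names(cohort[[i]]$epoch_sets)) {
      pr <- preprocess_epochs(cohort[[i]]$epoch_sets[[cond]],
                              target_rate_hz, reject_uv)
      cohort[[i]]$epoch_sets[[cond]] <- pr$kept
      nr[cond] <- pr$n_rejected
    }
    cohort[[i]]$n_rejected <- nr
  }
  cohort
}
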