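#' Wilcoxon rank-sum test with a standardized z statistic
#'
#' Two-sided rank-sum test using the normal approximation with tie
#' correction and continuity correction. By convention (matching the
#' reporting layout of the group-comparison tables, where the
#' exercise group's higher entropy appears as negative z), the sign is
#' flipped so z is negative when `values_a` (exercise) has the higher
#' mean rank; set `sign = "raw"` for the unflipped statistic.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param sign `"exercise_negative"` (default) or `"raw"`.
#' @return list with `z` and `p_raw`.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b,
                              sign = c("exercise_negative", "raw")) {
  sign <- match.arg(sign)
  n1 <- length(values_a); n2 <- length(values_b)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  x <- c(values_a, values_b)
  if (length(unique(x)) == 1)
    return(list(z = 0, p_raw = 1))
  r <- rank(x)
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  n <- n1 + n2
  ties <- table(x)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(z = 0, p_raw = 1))
  cc <- base::sign(W - mu) * 0.5  # continuity correction toward the mean
  z <- (W - mu - cc) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  p <- min(p, 1)
  if (sign == "exercise_negative") z <- -z
  list(z = z, p_raw = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; input
#' order is preserved.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Task-wise FDR-controlled group comparison of entropy features
#'
#' For each of the four task conditions, the 5 regions x 7 metrics = 35
#' entropy-region combinations are compared between the exercise and
#' non-exercise groups with Wilcoxon rank-sum tests and adjusted as a
#' single Benjamini-Hochberg family at level `q`. Conditions form
#' separate families because they reflect distinct processing contexts.
#'
#' @param table a [compute_feature_table()] result.
#' @param labels named character vector participant_id -> group label;
#'   defaults to the `group_label` column of `table`.
#' @param q FDR level (default 0.05).
#' @param sign sign convention for z (see [wilcoxon_rank_sum()]).
#' @return data frame of class `stat_table`: `condition`, `region`,
#'   `metric`, `n_exercise`, `n_nonexercise`, `z`, `p_raw`, `p_fdr`,
#'   `significant`, ordered condition x region x metric.
#' @export
compare_groups <- function(table, labels = NULL, q = 0.05,
                           sign = "exercise_negative") {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  if (is.null(labels)) {
    u <- unique(table[, c("participant_id", "group_label")])
    labels <- setNames(u$group_label, u$participant_id)
  }
  conds <- intersect(iat_conditions(), unique(table$condition))
  regions <- intersect(names(region_map()), unique(table$region))
  metrics <- intersect(entropy_metrics(), unique(table$metric))
  fam <- list()
  for (cond in conds) {
    rows <- list()
    for (r in regions) for (m in metrics) {
      sub <- table[table$condition == cond & table$region == r &
                     table$metric == m, , drop = FALSE]
      if (nrow(sub) == 0) {
        message("condition ", cond, ", ", r, "/", m,
                ": no feature rows; test skipped, family reduced")
        next
      }
      grp <- labels[sub$participant_id]
      a <- sub$value[grp == "exercise"]
      b <- sub$value[grp == "non_exercise"]
      if (length(a) < 2 || length(b) < 2) {
        message("condition ", cond, ", ", r, "/", m,
                ": insufficient data; test skipped, family reduced")
        next
      }
      w <- wilcoxon_rank_sum(a, b, sign = sign)
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, region = r, metric = m,
        n_exercise = length(a), n_nonexercise = length(b),
        z = w$z, p_raw = w$p_raw)
    }
    if (!length(rows)) next
    f <- do.call(rbind, rows)
    f$p_fdr <- bh_fdr(f$p_raw)
    f$significant <- f$p_fdr <= q
    fam[[cond]] <- f
  }
  out <- do.call(rbind, fam)
  rownames(out) <- NULL
  class(out) <- c("stat_table", "data.frame")
  attr(out, "q") <- q
  out
}
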