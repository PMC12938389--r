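#' Run configuration for the end-to-end pipeline
#'
#' Bundles and validates the stage configurations. Every random draw in
#' a run derives from `root_seed` through named substreams, so a fixed
#' configuration is fully deterministic.
#'
#' @param cohort a [cohort_spec()] (its own seed is overridden by
#'   `root_seed`).
#' @param entropy an [entropy_config()].
#' @param q FDR level in (0, 1].
#' @param protocol classifier evaluation protocol.
#' @param classify_specs list of [feature_set_spec()]s to evaluate
#'   (with random forests as the primary classifier).
#' @param target_rate_hz preprocessing target sampling rate.
#' @param output_dir where stage outputs are written.
#' @param root_seed integer root seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       entropy = entropy_config(),
                       q = 0.05,
                       protocol = c("repeated_split", "kfold"),
                       classify_specs = list(feature_set_spec(
                         "envelope_only", "affective", "incompatible")),
                       target_rate_hz = 500,
                       output_dir = tempfile("iatentropy_run_"),
                       root_seed = 1L) {
  protocol <- match.arg(protocol)
  if (!inherits(cohort, "cohort_spec")) stop("cohort must be a cohort_spec")
  if (!inherits(entropy, "entropy_config"))
    stop("entropy must be an entropy_config")
  if (!is.numeric(q) || q <= 0 || q > 1) stop("q must be in (0, 1]")
  if (!is.numeric(root_seed)) stop("root_seed must be an integer")
  cohort$seed <- as.integer(root_seed)
  structure(list(cohort = cohort, entropy = entropy, q = q,
                 protocol = protocol, classify_specs = classify_specs,
                 target_rate_hz = target_rate_hz,
                 output_dir = output_dir,
                 root_seed = as.integer(root_seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys `cohort`, `entropy`, `q`, `protocol`,
#' `target_rate_hz`, `output_dir`, `root_seed` map to the
#' [run_config()] arguments; `classify_specs` is a list of
#' `source`/`iat_scope`/`condition_scope` triples.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_spec, y$cohort)
  if (!is.null(y$entropy)) args$entropy <- do.call(entropy_config, y$entropy)
  if (!is.null(y$classify_specs))
    args$classify_specs <- lapply(y$classify_specs, function(s)
      do.call(feature_set_spec, s))
  for (f in c("q", "protocol", "target_rate_hz", "output_dir",
              "root_seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(run_config, args)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL # hash the scientific configuration only
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 15)),
             collapse = "\n")
  sprintf("%08x", substream_seed(0, s))
}

#' Run the full pipeline: synth -> score -> preprocess -> features ->
#' compare -> classify
#'
#' Executes every stage on a synthetic cohort, writes stage outputs
#' (cohort data, D-score and group TSVs, feature table, comparison
#' table, classifier reports) under `config$output_dir`, and returns a
#' manifest recording the configuration hash, seeds and per-stage
#' summaries. A failed stage aborts with the stage name; outputs of a
#' failed run are left in a `quarantine` subdirectory rather than
#' overwritten silently on the next attempt.
#'
#' @param config a [run_config()].
#' @param write_epochs serialize the raw cohort EEG (large) too?
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, write_epochs = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  if (dir.exists(out) && length(list.files(out)) > 0) {
    qdir <- file.path(out, "quarantine")
    dir.create(qdir, showWarnings = FALSE, recursive = TRUE)
    old <- setdiff(list.files(out, full.names = TRUE), qdir)
    file.rename(old, file.path(qdir, basename(old)))
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config),
                   root_seed = config$root_seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # synth
  cohort <- stage("synth", generate_cohort(config$cohort))
  if (write_epochs)
    stage("synth", write_cohort(cohort, file.path(out, "cohort")))
  manifest$stages$synth <- list(n_participants = length(cohort))
  # score-behavior
  scores <- stage("score-behavior", {
    rows <- list()
    for (p in cohort) for (it in c("affective", "instrumental")) {
      tl <- p$trial_log[p$trial_log$iat_type == it, , drop = FALSE]
      s <- score_iat(tl)
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = p$participant_id, iat_type = it,
        d_score = s$d_score, n_trials_used = s$n_trials_used,
        excluded = s$excluded_participant)
    }
    do.call(rbind, rows)
  })
  groups <- do.call(rbind, lapply(cohort, function(p) {
    g <- assign_group(p$exercise_report)
    data.frame(participant_id = p$participant_id, label = g$label,
               mvpa_met_min_week = g$mvpa_met_min_week)
  }))
  write.table(scores, file.path(out, "dscores.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(groups, file.path(out, "groups.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  manifest$stages$score_behavior <-
    list(n_excluded = sum(scores$excluded),
         mean_d = mean(scores$d_score, na.rm = TRUE))
  # preprocess
  cohort <- stage("preprocess",
                  preprocess_cohort(cohort, config$target_rate_hz))
  manifest$stages$preprocess <- list(
    n_rejected = sum(vapply(cohort, function(p)
      sum(p$n_rejected), numeric(1))))
  # features
  feats <- stage("features",
                 compute_feature_table(cohort, cfg = config$entropy))
  write_feature_table(feats, file.path(out, "features.tsv"))
  manifest$stages$features <- list(n_rows = nrow(feats))
  # compare
  stats_tab <- stage("compare", compare_groups(feats, q = config$q))
  write.table(stats_tab, file.path(out, "group_comparison.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  manifest$stages$compare <- list(
    n_tests = nrow(stats_tab), n_significant = sum(stats_tab$significant))
  # classify
  reports <- stage("classify", lapply(config$classify_specs, function(sp) {
    des <- build_design(feats, sp)
    rep_ <- evaluate_classifier(des$x, des$y, "RF",
                                protocol = config$protocol,
                                seed = substream_seed(config$root_seed,
                                                      "classify"))
    list(spec = unclass(sp), metrics = rep_$metrics, auc = rep_$auc,
         top5 = rf_importance_top5(rep_))
  }))
  jsonlite::write_json(reports, file.path(out, "classification.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest$stages$classify <- list(
    accuracy = vapply(reports, function(r)
      r$metrics$mean[r$metrics$metric == "accuracy"], numeric(1)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
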