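#' Serialize a cohort to disk
#'
#' One directory per participant: per-condition epochs as a flat
#' little-endian float64 binary file plus a JSON sidecar (channel
#' names, sampling rate, epoch count, time offsets, array dimensions),
#' the trial log and the exercise report as TSV.
#'
#' @param cohort a cohort (see [generate_cohort()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort) {
    pd <- file.path(dir, p$participant_id)
    dir.create(pd, showWarnings = FALSE)
    for (cond in names(p$epoch_sets)) {
      es <- p$epoch_sets[[cond]]
      bin <- file.path(pd, paste0("epochs_", cond, ".bin"))
      con <- file(bin, "wb")
      writeBin(as.numeric(aperm(es$data, c(3, 2, 1))), con,
               size = 8, endian = "little")
      close(con)
      side <- list(condition = cond, dims = dim(es$data),
                   channel_names = es$channel_names,
                   sampling_rate_hz = es$sampling_rate_hz,
                   t_start_ms = es$t_start_ms,
                   baseline_window_ms = es$baseline_window_ms,
                   order = "sample-fastest (sample, channel, epoch)")
      jsonlite::write_json(side, file.path(pd,
        paste0("epochs_", cond, ".json")), auto_unbox = TRUE, digits = NA)
    }
    write.table(p$trial_log, file.path(pd, "trial_log.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(as.data.frame(p$exercise_report),
                file.path(pd, "exercise_report.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(p$group_label, file.path(pd, "group_label.txt"))
  }
  invisible(dir)
}

#' Read a serialized cohort
#'
#' @param dir directory written by [write_cohort()].
#' @return a cohort list.
#' @export
read_cohort <- function(dir) {
  pids <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  out <- lapply(pids, function(pid) {
    pd <- file.path(dir, pid)
    sides <- list.files(pd, pattern = "^epochs_.*\\.json$")
    epoch_sets <- list()
    for (sf in sides) {
      side <- jsonlite::read_json(file.path(pd, sf), simplifyVector = TRUE)
      bin <- sub("\\.json$", ".bin", sf)
      con <- file(file.path(pd, bin), "rb")
      v <- readBin(con, "numeric", n = prod(side$dims), size = 8,
                   endian = "little")
      close(con)
      arr <- aperm(array(v, dim = rev(side$dims)), c(3, 2, 1))
      epoch_sets[[side$condition]] <- epoch_set(
        arr, side$channel_names, side$sampling_rate_hz,
        condition = side$condition, t_start_ms = side$t_start_ms,
        baseline_window_ms = side$baseline_window_ms)
    }
    list(participant_id = pid,
         group_label = readLines(file.path(pd, "group_label.txt"))[1],
         epoch_sets = epoch_sets[intersect(iat_conditions(),
                                           names(epoch_sets))],
         trial_log = read.table(file.path(pd, "trial_log.tsv"),
                                header = TRUE, sep = "\t"),
         exercise_report = as.list(read.table(
           file.path(pd, "exercise_report.tsv"), header = TRUE,
           sep = "\t")))
  })
  structure(out, class = "cohort")
}

#' Write a feature table as long-format TSV
#' @param table a [compute_feature_table()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format feature table TSV
#' @param path file written by [write_feature_table()].
#' @return a `feature_table` data frame.
#' @export
read_feature_table <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}
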