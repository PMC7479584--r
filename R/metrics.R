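# Performance summaries and usability-questionnaire scoring.

#' Summarize one session log
#'
#' The per-task performance measures: number of trials completed,
#' average time per trial in seconds, proportion of correct responses
#' (correct rows over completed trials — abandoned or reset attempts
#' are never in the log, so they never enter the denominator), and
#' cumulative completion time in seconds. Times are sums of logged
#' per-trial response times; inter-trial loading and feedback time is
#' not captured and therefore not included. Seconds are derived from
#' millisecond storage at 3-decimal precision.
#'
#' @param log an `ef_session_log` with at least one row.
#' @return an `ef_task_summary` list: `task`, `n_trials_completed`,
#'   `avg_time_per_trial_s`, `proportion_correct`, `cumulative_time_s`.
#' @export
summarize_task <- function(log) {
  stopifnot(inherits(log, "ef_session_log"))
  if (nrow(log$rows) == 0L) {
    ef_stop("cannot summarize an empty session log", "ef_validation_error")
  }
  ms <- parse_response_time(log$rows$response_time)
  n <- nrow(log$rows)
  structure(
    list(task = log$header$task,
         n_trials_completed = n,
         avg_time_per_trial_s = round(mean(ms) / 1000, 3L),
         proportion_correct = sum(log$rows$correct == "yes") / n,
         cumulative_time_s = round(sum(ms) / 1000, 3L)),
    class = "ef_task_summary")
}

#' @export
print.ef_task_summary <- function(x, ...) {
  cat(sprintf("<%s> %d trials, %.1f s/trial, %.0f%% correct, %.1f s total\n",
              x$task, x$n_trials_completed, x$avg_time_per_trial_s,
              100 * x$proportion_correct, x$cumulative_time_s))
  invisible(x)
}

#' @export
summary.ef_session_log <- function(object, ...) summarize_task(object)

#' Score the simulator-sickness questionnaire
#'
#' The 16-item instrument with each item rated 0-3. The default score
#' is the raw sum (range 0-48), the range the usability instrument
#' reports. `method = "kennedy"` instead applies the standard weighted
#' scoring: nausea, oculomotor and disorientation subscale sums
#' weighted by 9.54, 7.58 and 13.92 respectively, with the total scaled
#' by 3.74.
#'
#' @param items numeric vector of 16 item responses, each in 0..3.
#' @param method `"raw"` (default) or `"kennedy"`.
#' @return for `"raw"` a single integer 0-48; for `"kennedy"` a list
#'   with `nausea`, `oculomotor`, `disorientation` and `total`.
#' @export
score_ssq <- function(items, method = c("raw", "kennedy")) {
  method <- match.arg(method)
  if (length(items) != 16L) {
    ef_stop(sprintf("SSQ needs 16 items, got %d", length(items)),
            "ef_validation_error")
  }
  bad <- which(!items %in% 0:3)
  if (length(bad) > 0L) {
    ef_stop(sprintf("SSQ item %d out of range 0..3", bad[1L]),
            "ef_validation_error")
  }
  if (method == "raw") return(as.integer(sum(items)))
  # standard subscale membership over the 16 items
  nausea <- c(1, 6, 7, 8, 9, 15, 16)
  oculomotor <- c(1, 2, 3, 4, 5, 9, 11)
  disorientation <- c(5, 8, 10, 11, 12, 13, 14)
  list(nausea = sum(items[nausea]) * 9.54,
       oculomotor = sum(items[oculomotor]) * 7.58,
       disorientation = sum(items[disorientation]) * 13.92,
       total = (sum(items[nausea]) + sum(items[oculomotor]) +
                  sum(items[disorientation])) * 3.74)
}

#' Score the usability questionnaires
#'
#' Validates and totals the post-session instruments: the 16-item
#' simulator-sickness questionnaire (raw sum, 0-48), the perceived
#' physical-exertion rating (a single value on the 6-20 scale), and the
#' custom virtual-reality experience items, each rated 0 (not at all)
#' to 100 (very much). Out-of-range input is rejected with the
#' offending item named, never clamped.
#'
#' @param ssq_items numeric vector of 16 responses in 0..3.
#' @param borg single exertion rating in 6..20.
#' @param vr_items optional named numeric vector of experience ratings,
#'   each in 0..100.
#' @return an `ef_questionnaire_scores` list: `ssq_total`,
#'   `borg_rating`, `vr_experience`.
#' @export
score_questionnaires <- function(ssq_items, borg, vr_items = numeric(0L)) {
  ssq_total <- score_ssq(ssq_items)
  if (length(borg) != 1L || is.na(borg) || borg < 6 || borg > 20 ||
      borg != as.integer(borg)) {
    ef_stop("exertion rating must be a single integer in 6..20",
            "ef_validation_error")
  }
  if (length(vr_items) > 0L) {
    bad <- which(is.na(vr_items) | vr_items < 0 | vr_items > 100)
    if (length(bad) > 0L) {
      nm <- names(vr_items)[bad[1L]]
      ef_stop(sprintf("VR experience item %s out of range 0..100",
                      if (!is.null(nm) && nzchar(nm)) nm else bad[1L]),
              "ef_validation_error")
    }
  }
  structure(
    list(ssq_total = ssq_total, borg_rating = as.integer(borg),
         vr_experience = vr_items),
    class = "ef_questionnaire_scores")
}

#' Batch performance report over many logs
#'
#' Aggregates session logs into a per-task table: number of sessions,
#' the range of completed-trial counts, and the across-session mean and
#' SD of average time per trial and of percent correct. Each session is
#' summarized first and the statistics taken across sessions (not
#' pooled over trials). Times are reported to 1 decimal second and
#' accuracy as percentages, the conventional reporting precision;
#' underlying logs keep millisecond precision.
#'
#' @param logs list of `ef_session_log`.
#' @param format `"csv"` or `"tsv"`; only affects [write_batch_report()].
#' @return a data frame with one row per task present.
#' @export
batch_report <- function(logs, format = c("csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(length(logs) > 0L,
            all(vapply(logs, inherits, logical(1L), "ef_session_log")))
  sums <- lapply(logs, summarize_task)
  tasks <- vapply(sums, `[[`, "", "task")
  out <- do.call(rbind, lapply(intersect(TASKS, unique(tasks)), function(tk) {
    s <- sums[tasks == tk]
    n_done <- vapply(s, `[[`, 0L, "n_trials_completed")
    avg_t <- vapply(s, `[[`, 0, "avg_time_per_trial_s")
    pc <- 100 * vapply(s, `[[`, 0, "proportion_correct")
    data.frame(task = tk, n_sessions = length(s),
               trials_completed_min = min(n_done),
               trials_completed_max = max(n_done),
               avg_time_per_trial_mean_s = round(mean(avg_t), 1L),
               avg_time_per_trial_sd_s = round(stats::sd(avg_t), 1L),
               percent_correct_mean = round(mean(pc), 1L),
               percent_correct_sd = round(stats::sd(pc), 1L),
               stringsAsFactors = FALSE)
  }))
  # a single session per task has no across-session spread
  out$avg_time_per_trial_sd_s[is.na(out$avg_time_per_trial_sd_s)] <- 0
  out$percent_correct_sd[is.na(out$percent_correct_sd)] <- 0
  attr(out, "format") <- format
  out
}

#' @rdname batch_report
#' @param report a data frame from [batch_report()].
#' @param path output path.
#' @export
write_batch_report <- function(report, path) {
  sep <- if (identical(attr(report, "format"), "tsv")) "\t" else ","
  utils::write.table(report, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
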