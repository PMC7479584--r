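# Trial-level CSV persistence.
#
# One file per (study_id, session_number, task). The dialect is plain
# RFC-4180-style CSV preceded by '#'-prefixed header lines carrying the
# study id, session number, task, seed, schema version and completeness
# flag — everything needed to replay or resume the session. The column
# set per task is fixed (the schema below); the writer refuses any other
# column so no code path can leak a person-identifying field into a log.

# Required columns (the instrument's collection schema, in its order)
# followed by extension columns used for replay and validation.
LOG_SCHEMAS <- list(
  inhibitory_control = c("location_of_arrow", "direction_of_arrow",
                         "condition", "response", "response_time", "correct",
                         "trial", "character_id"),
  working_memory = c("order", "number_of_items", "level", "response_time",
                     "correct", "trial", "door", "presented_sequence",
                     "response_sequence"),
  cognitive_flexibility = c("rule_applied", "stimulus_amount",
                            "stimulus_color", "stimulus_shape", "response",
                            "response_time", "correct", "trial",
                            "chosen_target", "unambiguous")
)

INTEGER_COLUMNS <- c("trial", "character_id", "number_of_items", "level",
                     "door", "stimulus_amount", "chosen_target")

yesno <- function(x) ifelse(x, "yes", "no")

format_id_sequence <- function(ids) paste(ids, collapse = "-")

parse_id_sequence <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0L))
  as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])
}

# Assemble the typed data frame for one task's records.
rows_from_records <- function(task, records) {
  empty <- function() {
    df <- as.data.frame(setNames(
      lapply(LOG_SCHEMAS[[task]], function(cn) {
        if (cn %in% INTEGER_COLUMNS) integer(0L) else character(0L)
      }), LOG_SCHEMAS[[task]]), stringsAsFactors = FALSE)
    df
  }
  if (length(records) == 0L) return(empty())
  one <- function(r) {
    switch(task,
      inhibitory_control = data.frame(
        location_of_arrow = r$arrow_position,
        direction_of_arrow = r$arrow_direction,
        condition = r$condition,
        response = r$response,
        response_time = format_response_time(r$elapsed_ms),
        correct = yesno(r$correct),
        trial = r$trial_index,
        character_id = r$character_id,
        stringsAsFactors = FALSE),
      working_memory = data.frame(
        order = r$order,
        number_of_items = length(r$presented_sequence),
        level = r$level,
        response_time = format_response_time(r$elapsed_ms),
        correct = yesno(r$correct),
        trial = r$trial_index,
        door = r$door_index,
        presented_sequence = format_id_sequence(r$presented_sequence),
        response_sequence = format_id_sequence(r$response_sequence),
        stringsAsFactors = FALSE),
      cognitive_flexibility = data.frame(
        rule_applied = r$active_rule,
        stimulus_amount = r$stimulus$amount,
        stimulus_color = r$stimulus$color,
        stimulus_shape = r$stimulus$shape,
        response = paste0(r$chosen_target, ":", r$matched_dimension),
        response_time = format_response_time(r$elapsed_ms),
        correct = yesno(r$correct),
        trial = r$trial_index,
        chosen_target = r$chosen_target,
        unambiguous = yesno(r$unambiguous),
        stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(records, one))
}

#' Session log container
#'
#' A header (study id, session number, task, seed, schema version,
#' completeness flag) plus one typed row per completed trial, in trial
#' order. Constructed by [run_session()] or [read_session_csv()];
#' [summarize_task()] and [batch_report()] consume it.
#'
#' @param header named list with `study_id`, `session_number`, `task`,
#'   `seed`, `schema_version`, `complete`.
#' @param rows data frame of trial records in the task's schema.
#' @return an `ef_session_log`.
#' @export
session_log <- function(header, rows) {
  needed <- c("study_id", "session_number", "task", "seed",
              "schema_version", "complete")
  if (!all(needed %in% names(header))) {
    ef_stop(sprintf("log header missing fields: %s",
                    paste(setdiff(needed, names(header)), collapse = ", ")),
            "ef_validation_error")
  }
  if (!header$task %in% names(LOG_SCHEMAS)) {
    ef_stop(sprintf("unknown task '%s' in log header", header$task),
            "ef_config_error")
  }
  structure(list(header = header, rows = rows), class = "ef_session_log")
}

session_log_from_state <- function(state, complete) {
  cfg <- state$config
  session_log(
    header = list(study_id = cfg$study_id,
                  session_number = cfg$session_number,
                  task = cfg$task, seed = cfg$seed,
                  schema_version = SCHEMA_VERSION,
                  complete = complete),
    rows = rows_from_records(cfg$task, state$records))
}

#' Write a session log as CSV
#'
#' Writes the '#'-prefixed header lines followed by the trial rows with
#' RFC-4180-style quoting, UTF-8. The writer enforces the privacy
#' schema: any column outside the task's declared set — in particular
#' anything that could identify a person beyond the study id and
#' session number — is refused.
#'
#' @param log an `ef_session_log`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(log, path) {
  stopifnot(inherits(log, "ef_session_log"))
  schema <- LOG_SCHEMAS[[log$header$task]]
  extra <- setdiff(names(log$rows), schema)
  if (length(extra) > 0L) {
    ef_stop(sprintf("refusing to write undeclared column(s) %s: only the task schema may be persisted",
                    paste(extra, collapse = ", ")),
            "ef_privacy_error")
  }
  missing_cols <- setdiff(schema, names(log$rows))
  if (length(missing_cols) > 0L) {
    ef_stop(sprintf("log rows missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "ef_validation_error")
  }
  con <- tryCatch(file(path, open = "wb", encoding = "UTF-8"),
                  error = function(e) {
                    ef_stop(sprintf("cannot open '%s' for writing", path),
                            "ef_io_error")
                  })
  on.exit(close(con))
  hdr <- log$header
  writeLines(c(
    sprintf("# study_id: %s", hdr$study_id),
    sprintf("# session_number: %d", as.integer(hdr$session_number)),
    sprintf("# task: %s", hdr$task),
    sprintf("# seed: %d", as.integer(hdr$seed)),
    sprintf("# schema_version: %s", hdr$schema_version),
    sprintf("# complete: %s", yesno(isTRUE(hdr$complete)))), con)
  utils::write.table(log$rows[, schema, drop = FALSE], con, sep = ",",
                     row.names = FALSE, col.names = TRUE, quote = TRUE,
                     qmethod = "double")
  invisible(path)
}

#' Read a session log written by [write_session_csv()]
#'
#' Parses the header lines, types the rows per the task's schema, and
#' validates every row (correctness flags must be yes/no, response
#' times must parse); a malformed row fails with its row number, and an
#' unknown schema version is rejected rather than guessed at.
#'
#' @param path path to a log file.
#' @return an `ef_session_log` equal, field for field, to the one
#'   written.
#' @export
read_session_csv <- function(path) {
  if (!file.exists(path)) {
    ef_stop(sprintf("no such log file: %s", path), "ef_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  hdr_lines <- grep("^# ", lines, value = TRUE)
  body <- lines[!grepl("^# ", lines)]
  kv <- regmatches(hdr_lines, regexec("^# ([a-z_]+): (.*)$", hdr_lines))
  header <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
  for (f in c("study_id", "session_number", "task", "seed",
              "schema_version", "complete")) {
    if (is.null(header[[f]])) {
      ef_stop(sprintf("log header missing '%s'", f), "ef_parse_error")
    }
  }
  if (header$schema_version != SCHEMA_VERSION) {
    ef_stop(sprintf("unsupported schema version '%s'", header$schema_version),
            "ef_version_error")
  }
  header$session_number <- as.integer(header$session_number)
  header$seed <- as.integer(header$seed)
  header$complete <- identical(header$complete, "yes")
  task <- header$task
  if (!task %in% names(LOG_SCHEMAS)) {
    ef_stop(sprintf("unknown task '%s' in log header", task), "ef_parse_error")
  }
  schema <- LOG_SCHEMAS[[task]]
  rows <- utils::read.csv(text = paste(body, collapse = "\n"),
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!identical(names(rows), schema)) {
    ef_stop(sprintf("log columns do not match the %s schema", task),
            "ef_parse_error")
  }
  for (cn in intersect(INTEGER_COLUMNS, schema)) {
    v <- suppressWarnings(as.integer(rows[[cn]]))
    if (nrow(rows) > 0L && anyNA(v)) {
      ef_stop(sprintf("row %d: column '%s' is not an integer",
                      which(is.na(v))[1L], cn), "ef_parse_error")
    }
    rows[[cn]] <- v
  }
  if (nrow(rows) > 0L) {
    bad <- which(!rows$correct %in% c("yes", "no"))
    if (length(bad) > 0L) {
      ef_stop(sprintf("row %d: correct must be 'yes' or 'no', got '%s'",
                      bad[1L], rows$correct[bad[1L]]), "ef_parse_error")
    }
    for (i in seq_len(nrow(rows))) {
      tryCatch(parse_response_time(rows$response_time[i]),
               ef_parse_error = function(e) {
                 ef_stop(sprintf("row %d: %s", i, conditionMessage(e)),
                         "ef_parse_error")
               })
    }
  }
  session_log(header = as.list(header), rows = rows)
}

#' @export
print.ef_session_log <- function(x, ...) {
  cat(sprintf("<session log> study %s session %d, %s: %d trials%s\n",
              x$header$study_id, x$header$session_number, x$header$task,
              nrow(x$rows),
              if (isTRUE(x$header$complete)) "" else " (incomplete)"))
  invisible(x)
}

#' @export
as.data.frame.ef_session_log <- function(x, ...) x$rows

#' Plot a session log
#'
#' Base-graphics view of a session: cumulative accuracy over trials,
#' and for working-memory logs the presented sequence-length (staircase)
#' trajectory on a second axis.
#'
#' @param x an `ef_session_log`.
#' @param ... passed to [plot()].
#' @export
plot.ef_session_log <- function(x, ...) {
  if (nrow(x$rows) == 0L) {
    ef_stop("cannot plot an empty log", "ef_validation_error")
  }
  correct <- x$rows$correct == "yes"
  acc <- cumsum(correct) / seq_along(correct)
  plot(seq_along(acc), acc, type = "l", ylim = c(0, 1),
       xlab = "trial", ylab = "cumulative accuracy",
       main = sprintf("%s (study %s)", x$header$task, x$header$study_id), ...)
  if (x$header$task == "working_memory") {
    graphics::par(new = TRUE)
    plot(seq_along(acc), x$rows$number_of_items, type = "s", col = "grey40",
         axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4)
    graphics::mtext("sequence length", side = 4, line = 2, col = "grey40")
  }
  invisible(x)
}
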