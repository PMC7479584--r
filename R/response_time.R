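#' Response-time text format
#'
#' Trial response times are persisted in the log files as
#' `minutes:seconds:milliseconds` text (for example `"00:03:250"` is
#' 3250 ms). `format_response_time()` renders non-negative millisecond
#' counts into that form and `parse_response_time()` inverts it; the two
#' are exact inverses on their respective domains, so round-tripping a
#' log file never loses timing precision. Minutes widen beyond two digits
#' as needed; seconds and milliseconds are always zero-padded to 2 and 3
#' digits.
#'
#' @param ms vector of non-negative integer millisecond counts.
#' @param x character vector of `minutes:seconds:milliseconds` strings.
#' @return `format_response_time()` a character vector;
#'   `parse_response_time()` an integer vector of milliseconds.
#' @examples
#' format_response_time(3250)   # "00:03:250"
#' parse_response_time("01:02:005")  # 62005
#' @export
format_response_time <- function(ms) {
  if (!is.numeric(ms) || any(is.na(ms)) || any(ms < 0) ||
      any(ms != as.integer(ms))) {
    ef_stop("response time must be non-negative integer milliseconds",
            "ef_validation_error")
  }
  ms <- as.integer(ms)
  sprintf("%02d:%02d:%03d", ms %/% 60000L, (ms %% 60000L) %/% 1000L,
          ms %% 1000L)
}

#' @rdname format_response_time
#' @export
parse_response_time <- function(x) {
  if (!is.character(x) || any(is.na(x))) {
    ef_stop("response time string must be character", "ef_parse_error")
  }
  ok <- grepl("^[0-9]{2,}:[0-5][0-9]:[0-9]{3}$", x)
  if (!all(ok)) {
    ef_stop(sprintf("malformed response time '%s' (expected minutes:seconds:milliseconds)",
                    x[!ok][1L]), "ef_parse_error")
  }
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    as.integer(p[1L]) * 60000L + as.integer(p[2L]) * 1000L + as.integer(p[3L])
  }, integer(1L))
}
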