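#' Daily song presence from duty-cycled file logs
#'
#' Passive acoustic recorders write one file per duty cycle (e.g. 630 s of
#' recording per 900 s cycle, 96 files per day); each file is manually
#' graded 0 (no song), 1 (song present, low signal-to-noise ratio) or
#' 2 (high-SNR song, suitable for transcription). Song presence is any
#' file containing song regardless of quality (category >= 1). This
#' summarises a file log to the percentage of files per calendar day
#' containing song, per recording site. The denominator is always the
#' number of files recorded that day, never seconds; days with no files
#' are absent from the output, not zero.
#'
#' @param records Data frame with columns `site`, `start_time`
#'   (parseable timestamp, local recorder time) and `category` (0/1/2).
#' @return Data frame with columns `site`, `date` (`Date`), `percent`
#'   (0-100) and `n_files`, ordered by site then date.
#' @export
daily_presence <- function(records) {
  records <- check_columns(records, c("site", "start_time", "category"),
                           "file log")
  cat_ <- suppressWarnings(as.integer(as.character(records$category)))
  bad <- is.na(cat_) | !(cat_ %in% 0:2)
  if (any(bad)) {
    stop("file log: invalid category in row(s) ",
         paste(which(bad), collapse = ", "),
         " (must be 0, 1 or 2)", call. = FALSE)
  }
  if (any(!nzchar(as.character(records$site)))) {
    stop("file log: empty site label", call. = FALSE)
  }
  ts <- as.POSIXct(as.character(records$start_time), tz = "UTC")
  if (any(is.na(ts))) {
    stop("file log: unparseable start_time in row(s) ",
         paste(which(is.na(ts)), collapse = ", "), call. = FALSE)
  }
  day <- as.Date(ts)
  site_in <- as.character(records$site)
  grp <- factor(paste(site_in, day, sep = "\x1f"))
  n_files <- as.integer(tapply(cat_, grp, length))
  n_song <- as.integer(tapply(cat_ >= 1L, grp, sum))
  lev <- strsplit(levels(grp), "\x1f", fixed = TRUE)
  site <- vapply(lev, `[[`, character(1), 1L)
  date <- as.Date(vapply(lev, `[[`, character(1), 2L))
  out <- data.frame(site = site, date = date,
                    percent = 100 * n_song / n_files,
                    n_files = n_files, stringsAsFactors = FALSE)
  out <- out[order(out$site, out$date), ]
  rownames(out) <- NULL
  out
}

#' Song cessation under the five-clear-day rule
#'
#' Song presence (a proxy for vocal animal presence) is deemed to have
#' ceased on the last day with song at any site that is followed by at
#' least `clear_days` consecutive *fully recorded* days with zero presence
#' at every site. A fully recorded day is one on which every reporting
#' site logged the duty-cycle-expected file count (within `tolerance`
#' files); partial days — deployment/retrieval days or recorder gaps — do
#' not count towards the clear run. If the record ends before the run
#' completes, the result is right-censored and no cessation date is
#' declared.
#'
#' @param daily Output of [daily_presence()] (possibly several sites).
#' @param expected_files Files per full day implied by the duty cycle
#'   (96 for a 900 s cycle).
#' @param tolerance Allowed shortfall in the daily file count.
#' @param clear_days Required length of the song-free run.
#' @return A list: `last_presence` (`Date`, or `NA` if no song at all or
#'   the rule is not met), `ceased` (logical), `censored` (logical: the
#'   record ended before the rule could be evaluated), `clear_run`
#'   (number of qualifying days observed after the last presence) and
#'   `gaps` (`Date` vector of days missing from the record between first
#'   and last covered day, flagged for the caller).
#' @export
cessation_date <- function(daily, expected_files = 96, tolerance = 0,
                           clear_days = 5) {
  stopifnot(all(c("site", "date", "percent", "n_files") %in% names(daily)))
  if (nrow(daily) == 0L) {
    return(list(last_presence = as.Date(NA), ceased = FALSE,
                censored = FALSE, clear_run = 0L, gaps = as.Date(character(0))))
  }
  daily$date <- as.Date(daily$date)
  days <- seq(min(daily$date), max(daily$date), by = "day")
  covered <- days %in% daily$date
  gaps <- days[!covered]
  present <- vapply(days, function(d) {
    any(daily$percent[daily$date == d] > 0)
  }, logical(1))
  full <- vapply(days, function(d) {
    n <- daily$n_files[daily$date == d]
    length(n) > 0L && all(n >= expected_files - tolerance)
  }, logical(1))

  if (!any(present)) {
    return(list(last_presence = as.Date(NA), ceased = FALSE,
                censored = FALSE, clear_run = 0L, gaps = gaps))
  }
  last_idx <- max(which(present))
  after <- if (last_idx < length(days)) {
    seq(last_idx + 1L, length(days))
  } else integer(0)
  # consecutive qualifying days immediately following the last presence
  run <- 0L
  for (i in after) {
    if (!present[i] && full[i]) run <- run + 1L else break
  }
  ceased <- run >= clear_days
  censored <- !ceased && (last_idx + run >= length(days))
  list(last_presence = if (ceased) days[last_idx] else as.Date(NA),
       ceased = ceased, censored = censored, clear_run = run,
       gaps = gaps)
}

#' @rdname corpus-io
#' @export
read_file_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character")
  check_columns(df, c("site", "start_time", "category"), "file log")
}

#' @rdname corpus-io
#' @export
write_daily_presence <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
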