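#' Song transcription data model
#'
#' Transcribed song is held in plain data frames with a fixed column
#' contract, mirroring the hierarchical structure of humpback song:
#' units -> phrases -> themes -> songs.
#'
#' * **phrase table** — one row per transcribed phrase:
#'   `location`, `year`, `recording_id`, `song_type_tag`, `phrase_type`,
#'   `units` (space-delimited unit labels, in sung order).
#' * **song table** — one row per song cycle: `location`, `year`,
#'   `recording_id`, `song_type_tag`, `cycle`, `themes` (space-delimited
#'   theme IDs, each theme once, in first-occurrence order).
#' * **theme presence table** — one row per recording: same keys plus
#'   `themes` as an unordered set.
#' * **unit table** — one row per measured unit: the 12 acoustic
#'   parameters (see [derive_features()]) plus `qualitative_name`.
#' * **file log** — one row per recorded file: `site`, `start_time`,
#'   `category` (see [daily_presence()]).
#'
#' Phrase-type labels are an integer with an optional single uppercase
#' variant letter (`"1"`, `"2A"`); the integer part is the theme ID. Unit
#' labels are case-sensitive opaque tokens without internal whitespace
#' (space is the sequence delimiter). All tables are UTF-8 CSV with a
#' header row; row order is preserved and is authoritative for
#' within-recording phrase order.
#'
#' @name corpus-format
NULL

phrase_table_cols <- c("location", "year", "recording_id", "song_type_tag",
                       "phrase_type", "units")
song_table_cols <- c("location", "year", "recording_id", "song_type_tag",
                     "cycle", "themes")
presence_table_cols <- c("location", "year", "recording_id", "song_type_tag",
                         "themes")

#' Parse phrase-type labels
#'
#' A phrase type is a positive integer with an optional single uppercase
#' variant letter, e.g. `"1"`, `"2A"`, `"16B"`. Variant letters denote
#' consistently occurring alternative forms of the same numbered phrase.
#' The numeric part identifies the theme the phrase belongs to.
#'
#' @param x Character vector of phrase-type labels.
#' @return A data frame with columns `phrase_type`, `theme` (integer) and
#'   `variant` (`""` when unlettered).
#' @examples
#' parse_phrase_type(c("1", "2A", "16B"))
#' @export
parse_phrase_type <- function(x) {
  x <- as.character(x)
  ok <- grepl("^[0-9]+[A-Z]?$", x)
  if (any(!ok)) {
    stop("invalid phrase type label(s): ",
         paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  }
  theme <- as.integer(sub("[A-Z]$", "", x))
  if (any(theme < 1L)) {
    stop("phrase type numeric part must be >= 1", call. = FALSE)
  }
  variant <- sub("^[0-9]+", "", x)
  data.frame(phrase_type = x, theme = theme, variant = variant,
             stringsAsFactors = FALSE)
}

#' Theme ID of a phrase type
#' @param x Character vector of phrase-type labels.
#' @return Integer vector of theme IDs.
#' @export
phrase_theme <- function(x) parse_phrase_type(x)$theme

#' Build a song string from a sung theme sequence
#'
#' A song cycle repeats each phrase (and hence theme) many times; the song
#' string records each theme once, in the order it first occurs,
#' regardless of how often its constituent phrase was repeated. Later
#' re-occurrences of an earlier theme do not re-enter the string.
#'
#' @param theme_sequence Integer vector of theme IDs as sung (repeats
#'   allowed). An empty input yields an empty song string.
#' @return Integer vector of distinct theme IDs in first-occurrence order.
#' @examples
#' song_string_from_theme_sequence(c(1, 1, 1, 2, 2, 3, 3, 1))  # 1 2 3
#' @export
song_string_from_theme_sequence <- function(theme_sequence) {
  th <- as.integer(theme_sequence)
  if (length(th) == 0L) return(integer(0))
  if (any(is.na(th)) || any(th < 1L)) {
    stop("theme IDs must be positive integers", call. = FALSE)
  }
  unique(th)
}

#' Theme presence of a song string
#'
#' @param song Integer vector of theme IDs (a song string).
#' @return Sorted integer vector: the unordered set of themes present.
#' @export
theme_presence_from_song <- function(song) {
  sort(unique(as.integer(song)))
}

split_units <- function(units) {
  strsplit(trimws(as.character(units)), "[[:space:]]+")
}

join_symbols <- function(x) {
  vapply(x, paste, character(1), collapse = " ")
}

check_columns <- function(df, cols, what, optional = character(0)) {
  missing <- setdiff(setdiff(cols, optional), names(df))
  if (length(missing)) {
    stop(what, ": missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (opt in setdiff(optional, names(df))) df[[opt]] <- ""
  df[cols]
}

#' Validate a phrase table
#'
#' Checks the column contract, that every unit sequence is non-empty and
#' whitespace-delimited, and that every phrase-type label parses. Errors
#' name the offending row.
#'
#' @param df Data frame in the phrase-table layout (see [corpus-format]).
#' @return The validated data frame (with `song_type_tag` filled in if
#'   absent), invisibly usable downstream.
#' @export
validate_phrase_table <- function(df) {
  df <- check_columns(df, phrase_table_cols, "phrase table",
                      optional = "song_type_tag")
  df$year <- as.integer(df$year)
  df$units <- as.character(df$units)
  toks <- split_units(df$units)
  n_units <- vapply(toks, function(x) sum(nzchar(x)), integer(1))
  if (any(n_units == 0L)) {
    stop("phrase table: empty unit sequence in row(s) ",
         paste(which(n_units == 0L), collapse = ", "), call. = FALSE)
  }
  parse_phrase_type(df$phrase_type)   # errors on malformed labels
  df
}

#' Read and write corpus tables
#'
#' CSV readers/writers for the tables described in [corpus-format]. Readers
#' validate every row and preserve row order; writers emit a header and no
#' row names, so a write/read round trip reproduces the table exactly.
#'
#' @param path CSV file path.
#' @param df Table to write.
#' @return Readers return the validated data frame; writers return `df`
#'   invisibly.
#' @name corpus-io
NULL

#' @rdname corpus-io
#' @export
read_phrase_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_phrase_table(df)
}

#' @rdname corpus-io
#' @export
write_phrase_table <- function(df, path) {
  df <- validate_phrase_table(df)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Validate a song table
#' @param df Data frame in the song-table layout (see [corpus-format]).
#' @return The validated data frame.
#' @export
validate_song_table <- function(df) {
  df <- check_columns(df, song_table_cols, "song table",
                      optional = c("song_type_tag", "cycle"))
  df$year <- as.integer(df$year)
  df$cycle <- ifelse(nzchar(as.character(df$cycle)),
                     as.integer(df$cycle), 1L)
  seqs <- split_units(df$themes)
  for (i in seq_along(seqs)) {
    th <- suppressWarnings(as.integer(seqs[[i]]))
    if (length(th) == 0L || any(is.na(th)) || any(th < 1L)) {
      stop("song table: invalid theme sequence in row ", i, call. = FALSE)
    }
    if (anyDuplicated(th)) {
      stop("song table: repeated theme ID in row ", i,
           " (each theme enters a song string once)", call. = FALSE)
    }
  }
  df
}

#' @rdname corpus-io
#' @export
read_song_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_song_table(df)
}

#' @rdname corpus-io
#' @export
write_song_table <- function(df, path) {
  df <- validate_song_table(df)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname corpus-io
#' @export
read_theme_presence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df <- check_columns(df, presence_table_cols, "theme presence table",
                      optional = "song_type_tag")
  df$year <- as.integer(df$year)
  sets <- split_units(df$themes)
  for (i in seq_along(sets)) {
    th <- suppressWarnings(as.integer(sets[[i]]))
    if (length(th) == 0L || any(is.na(th)) || any(th < 1L)) {
      stop("theme presence table: invalid theme set in row ", i,
           call. = FALSE)
    }
  }
  df
}

#' @rdname corpus-io
#' @export
write_theme_presence <- function(df, path) {
  df <- check_columns(df, presence_table_cols, "theme presence table",
                      optional = "song_type_tag")
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Theme sequences and sets from tables
#'
#' `song_sequences()` extracts the theme sequences of a song table as a
#' named list of integer vectors; `presence_sets()` does the same for the
#' unordered theme sets of a presence table. Names follow the
#' `Location_Year[_Tag]_Recording[.cycle]` labelling convention.
#'
#' @param df A validated song or theme presence table.
#' @return Named list of integer vectors.
#' @export
song_sequences <- function(df) {
  df <- validate_song_table(df)
  seqs <- lapply(split_units(df$themes), as.integer)
  lab <- recording_label(df$location, df$year, df$song_type_tag,
                         df$recording_id)
  if (anyDuplicated(lab)) lab <- paste0(lab, ".", df$cycle)
  names(seqs) <- lab
  seqs
}

#' @rdname song_sequences
#' @export
presence_sets <- function(df) {
  sets <- lapply(split_units(df$themes),
                 function(x) sort(unique(as.integer(x))))
  names(sets) <- recording_label(df$location, df$year, df$song_type_tag,
                                 df$recording_id)
  sets
}

#' Recording labels
#'
#' Builds the `Location_Year[_Tag]_Recording` labels used throughout for
#' matrix dimnames and dendrogram leaves (e.g. `NewCaledonia_2015_A_X`).
#'
#' @param location,year,song_type_tag,recording_id Key columns.
#' @return Character vector of labels.
#' @export
recording_label <- function(location, year, song_type_tag = "",
                            recording_id = NULL) {
  loc <- gsub("[[:space:]]+", "", as.character(location))
  parts <- paste(loc, year, sep = "_")
  tag <- as.character(song_type_tag)
  has_tag <- !is.na(tag) & nzchar(tag)
  parts[has_tag] <- paste(parts[has_tag], tag[has_tag], sep = "_")
  if (!is.null(recording_id)) {
    parts <- paste(parts, as.character(recording_id), sep = "_")
  }
  parts
}

#' Corpus summary counts
#'
#' `count_themes()` counts the distinct theme IDs present in a song or
#' theme presence table; `count_variant_themes()` counts themes whose
#' phrase table contains more than one phrase type (i.e. lettered
#' variants); `count_recording_events()` counts distinct recording events
#' (location/year/song-type/recording combinations) in any keyed table.
#'
#' @param df A corpus table (see [corpus-format]).
#' @return An integer count.
#' @export
count_themes <- function(df) {
  length(unique(unlist(lapply(split_units(df$themes), as.integer))))
}

#' @rdname count_themes
#' @export
count_variant_themes <- function(df) {
  p <- parse_phrase_type(unique(as.character(df$phrase_type)))
  sum(tapply(p$phrase_type, p$theme, function(x) length(unique(x))) > 1L)
}

#' @rdname count_themes
#' @export
count_recording_events <- function(df) {
  tag <- if ("song_type_tag" %in% names(df)) df$song_type_tag else ""
  nrow(unique(data.frame(location = df$location, year = df$year,
                         tag = tag, id = df$recording_id,
                         stringsAsFactors = FALSE)))
}
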