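#' Configure the synthetic song-culture generator
#'
#' The generator emulates multi-population humpback song cultures at the
#' symbolic (transcription) level. A *scenario* fixes the cultural state:
#' one row per population/year/song-type combination, giving its lineage
#' and its ordered theme set. On top of the scenario, the generator draws
#' phrase templates (ordered unit sequences) per theme, optional lettered
#' phrase variants for selected themes, and then emits noisy transcriptions:
#' each recording contributes several song cycles and phrase renditions,
#' perturbed by symbol-level substitution/insertion/deletion noise
#' mirroring the three Levenshtein edit operations (so the noise magnitude
#' maps directly onto expected LSI).
#'
#' @param scenario Data frame with columns `population`, `year`,
#'   `song_type_tag` (`""` when a single song type), `lineage` and
#'   `themes` (space-delimited theme IDs in sung order). See
#'   [table3_scenario()] for the shipped default and [random_scenario()]
#'   for a generative alternative with evolution and revolution.
#' @param n_unit_types Size of the unit-label inventory.
#' @param units_per_phrase Integer range (min, max) of units per phrase
#'   template.
#' @param variant_themes Theme IDs given a second, consistently produced
#'   phrase form (lettered `A`/`B`).
#' @param phrase_repeats Integer range of phrase repetitions per theme per
#'   recording.
#' @param recordings_per_group Recordings (individuals) per scenario row.
#' @param songs_per_recording Transcribed song cycles per recording.
#' @param noise Named numeric vector of per-symbol `substitution`,
#'   `insertion` and `deletion` probabilities applied at transcription, to
#'   both unit sequences and theme sequences.
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(scenario,
                             n_unit_types = 71L,
                             units_per_phrase = c(4L, 8L),
                             variant_themes = integer(0),
                             phrase_repeats = c(2L, 4L),
                             recordings_per_group = 3L,
                             songs_per_recording = 5L,
                             noise = c(substitution = 0.02,
                                       insertion = 0.015,
                                       deletion = 0.015)) {
  need <- c("population", "year", "song_type_tag", "lineage", "themes")
  scenario <- check_columns(scenario, need, "scenario",
                            optional = "song_type_tag")
  theme_sets <- lapply(split_units(scenario$themes), as.integer)
  if (any(vapply(theme_sets, length, integer(1)) == 0L)) {
    stop("scenario: every group needs at least one theme", call. = FALSE)
  }
  if (any(vapply(theme_sets, anyDuplicated, integer(1)) > 0L)) {
    stop("scenario: repeated theme within a group's song", call. = FALSE)
  }
  stopifnot(length(units_per_phrase) == 2L,
            units_per_phrase[1] >= 1L,
            units_per_phrase[2] >= units_per_phrase[1],
            length(phrase_repeats) == 2L, phrase_repeats[1] >= 1L,
            recordings_per_group >= 1L, songs_per_recording >= 1L,
            n_unit_types >= 2L)
  noise <- noise[c("substitution", "insertion", "deletion")]
  if (any(is.na(noise)) || any(noise < 0) || any(noise > 1) ||
      sum(noise[c("substitution", "deletion")]) > 1) {
    stop("invalid noise probabilities", call. = FALSE)
  }
  cfg <- list(scenario = scenario, theme_sets = theme_sets,
              n_unit_types = as.integer(n_unit_types),
              units_per_phrase = as.integer(units_per_phrase),
              variant_themes = as.integer(variant_themes),
              phrase_repeats = as.integer(phrase_repeats),
              recordings_per_group = as.integer(recordings_per_group),
              songs_per_recording = as.integer(songs_per_recording),
              noise = noise)
  class(cfg) <- "generator_config"
  cfg
}

#' Shipped default scenario: two populations, two lineages
#'
#' A two-population, three-year scenario with 16 themes of which five
#' carry lettered phrase variants. One population starts the period with
#' its own song lineage which is wholly replaced mid-season by the other
#' lineage — a cultural revolution, with no shared themes across the two
#' lineages — while the surviving lineage evolves across years, always
#' keeping at least one theme in common between consecutive states.
#'
#' @param ... Overrides passed on to [generator_config()]
#'   (e.g. `songs_per_recording`, `noise`).
#' @return A `"generator_config"`.
#' @export
table3_scenario <- function(...) {
  scenario <- data.frame(
    population = c(rep("NewCaledonia", 4L), rep("EastAustralia", 4L)),
    year = c(2015L, 2015L, 2016L, 2017L, 2015L, 2015L, 2016L, 2017L),
    song_type_tag = c("A", "B", "", "", "north", "south", "", ""),
    lineage = c("green", "blue", "blue", "blue",
                "blue", "blue", "blue", "blue"),
    themes = c("12 13 14 15 16", "5 6 8", "1 2 3 4 5 6 7 8", "3 9 10 11",
               "5 6 8", "1 2 3 4 5", "3 9 10 11", "3 9 10 11"),
    stringsAsFactors = FALSE
  )
  generator_config(scenario, variant_themes = c(1L, 3L, 5L, 6L, 9L), ...)
}

#' Generative scenario with evolution and revolution
#'
#' Draws a scenario rather than fixing one: each population starts with
#' its own lineage (a disjoint block of themes). Year to year, a lineage
#' evolves — with probability `evolution_rate` it gains a fresh theme from
#' the unused inventory, and with the same probability loses one — always
#' retaining at least one theme shared with the previous year. Listed
#' revolution events replace a population's song with an entirely fresh,
#' disjoint theme block under a new lineage ID (zero theme sharing by
#' construction). Errors if the theme inventory is exhausted.
#'
#' @param populations Character vector of population names.
#' @param years Integer vector of consecutive years.
#' @param themes_per_song Themes in each initial (and revolutionary) song.
#' @param evolution_rate Per-year probability of a theme gain and of a
#'   theme loss.
#' @param revolutions Data frame with columns `population`, `year`.
#' @param inventory Total theme IDs available.
#' @param seed Integer seed.
#' @return A scenario data frame for [generator_config()].
#' @export
random_scenario <- function(populations = c("PopA", "PopB"),
                            years = 2015:2017, themes_per_song = 5L,
                            evolution_rate = 0.3,
                            revolutions = NULL, inventory = 40L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- seq_len(inventory)
  take <- function(n) {
    if (length(pool) < n) {
      stop("theme inventory exhausted; increase `inventory`",
           call. = FALSE)
    }
    picked <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    picked
  }
  lineage_n <- 0L
  rows <- list()
  for (p in populations) {
    lineage_n <- lineage_n + 1L
    lineage <- paste0("L", lineage_n)
    current <- take(themes_per_song)
    for (y in years) {
      revolt <- !is.null(revolutions) &&
        any(revolutions$population == p & revolutions$year == y)
      if (revolt) {
        lineage_n <- lineage_n + 1L
        lineage <- paste0("L", lineage_n)
        current <- take(themes_per_song)
      } else if (y != years[1L]) {
        if (runif(1) < evolution_rate) current <- c(current, take(1L))
        if (length(current) > 2L && runif(1) < evolution_rate) {
          current <- current[-sample.int(length(current), 1L)]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, year = y, song_type_tag = "", lineage = lineage,
        themes = paste(current, collapse = " "),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Symbol-level transcription noise: per input symbol, possibly insert a
# random symbol before it, then delete or substitute it. Mirrors the
# three Levenshtein edit operations.
mutate_sequence <- function(x, noise, alphabet) {
  n <- length(x)
  out <- vector(mode = mode(x), length = 0L)
  for (i in seq_len(n)) {
    if (runif(1) < noise[["insertion"]]) {
      out <- c(out, alphabet[sample.int(length(alphabet), 1L)])
    }
    u <- runif(1)
    if (u < noise[["deletion"]]) next
    s <- x[i]
    if (u < noise[["deletion"]] + noise[["substitution"]]) {
      s <- alphabet[sample.int(length(alphabet), 1L)]
    }
    out <- c(out, s)
  }
  out
}

recording_ids <- function(n) {
  if (n <= 3L) c("X", "Y", "Z")[seq_len(n)]
  else c("X", "Y", "Z", paste0("R", seq(4L, n)))
}

#' Generate a synthetic song corpus with ground truth
#'
#' Draws a full corpus from a generator configuration: phrase templates
#' per theme (with lettered variants for the configured themes), then per
#' recording the transcribed song cycles (theme sequences) and phrase
#' renditions (unit sequences), all perturbed by the configured
#' transcription noise. Output is deterministic given the seed.
#'
#' Theme presence per recording is called by majority vote over its song
#' cycles (a theme is present if it appears in more than half of the
#' cycles), which equals the true theme set at zero noise.
#'
#' @param config A `"generator_config"` (e.g. [table3_scenario()]).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `"song_corpus"`:
#'   * `phrases`, `songs`, `presence`: corpus tables (see
#'     [corpus-format]);
#'   * `ground_truth`: list with `groups` (scenario rows plus group
#'     `label`), `templates` (named list phrase type -> unit vector),
#'     `recordings` (data frame with recording `label`, `lineage` and
#'     true song string) and `lineages` (named list lineage ->
#'     recording labels).
#' @export
generate_corpus <- function(config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  sc <- config$scenario
  themes_used <- sort(unique(unlist(config$theme_sets)))
  units <- sprintf("U%02d", seq_len(config$n_unit_types))

  # 1. phrase templates (stream order: per theme ascending, then variants)
  templates <- list()
  for (t in themes_used) {
    len <- sample(seq(config$units_per_phrase[1L],
                      config$units_per_phrase[2L]), 1L)
    base <- units[sample.int(length(units), len, replace = TRUE)]
    if (t %in% config$variant_themes) {
      var <- base
      pos <- sample.int(len, min(2L, len))
      for (p in pos) {
        var[p] <- sample(setdiff(units, var[p]), 1L)
      }
      templates[[paste0(t, "A")]] <- base
      templates[[paste0(t, "B")]] <- var
    } else {
      templates[[as.character(t)]] <- base
    }
  }

  # 2. per-group recordings, song cycles and phrase renditions
  phr <- list()
  sng <- list()
  prs <- list()
  rec_rows <- list()
  ids <- recording_ids(config$recordings_per_group)
  for (g in seq_len(nrow(sc))) {
    order_g <- config$theme_sets[[g]]
    for (r in ids) {
      lab <- recording_label(sc$population[g], sc$year[g],
                             sc$song_type_tag[g], r)
      cycles <- vector("list", config$songs_per_recording)
      for (cy in seq_len(config$songs_per_recording)) {
        noisy <- mutate_sequence(order_g, config$noise, themes_used)
        song <- song_string_from_theme_sequence(noisy)
        if (length(song) == 0L) song <- order_g
        cycles[[cy]] <- song
        sng[[length(sng) + 1L]] <- data.frame(
          location = sc$population[g], year = sc$year[g],
          recording_id = r, song_type_tag = sc$song_type_tag[g],
          cycle = cy, themes = paste(song, collapse = " "),
          stringsAsFactors = FALSE)
      }
      maj <- table(unlist(cycles))
      present <- sort(as.integer(names(maj)[
        maj > config$songs_per_recording / 2]))
      if (length(present) == 0L) present <- order_g
      prs[[length(prs) + 1L]] <- data.frame(
        location = sc$population[g], year = sc$year[g],
        recording_id = r, song_type_tag = sc$song_type_tag[g],
        themes = paste(present, collapse = " "),
        stringsAsFactors = FALSE)
      for (t in order_g) {
        reps <- sample(seq(config$phrase_repeats[1L],
                           config$phrase_repeats[2L]), 1L)
        for (k in seq_len(reps)) {
          ptype <- if (t %in% config$variant_themes) {
            paste0(t, sample(c("A", "B"), 1L))
          } else as.character(t)
          rendition <- mutate_sequence(templates[[ptype]], config$noise,
                                       units)
          if (length(rendition) == 0L) rendition <- templates[[ptype]]
          phr[[length(phr) + 1L]] <- data.frame(
            location = sc$population[g], year = sc$year[g],
            recording_id = r, song_type_tag = sc$song_type_tag[g],
            phrase_type = ptype,
            units = paste(rendition, collapse = " "),
            stringsAsFactors = FALSE)
        }
      }
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        label = lab, population = sc$population[g], year = sc$year[g],
        song_type_tag = sc$song_type_tag[g], lineage = sc$lineage[g],
        themes = paste(order_g, collapse = " "),
        stringsAsFactors = FALSE)
    }
  }

  recordings <- do.call(rbind, rec_rows)
  groups <- cbind(sc, label = recording_label(sc$population, sc$year,
                                              sc$song_type_tag))
  out <- list(
    phrases = validate_phrase_table(do.call(rbind, phr)),
    songs = validate_song_table(do.call(rbind, sng)),
    presence = do.call(rbind, prs),
    ground_truth = list(
      groups = groups,
      templates = templates,
      recordings = recordings,
      lineages = split(recordings$label, recordings$lineage)
    )
  )
  class(out) <- "song_corpus"
  out
}

#' @export
print.song_corpus <- function(x, ...) {
  cat("Synthetic song corpus:",
      nrow(x$ground_truth$recordings), "recordings,",
      nrow(x$phrases), "phrase strings,",
      nrow(x$songs), "song strings,",
      count_themes(x$songs), "themes\n")
  invisible(x)
}

#' Write / read a corpus directory
#'
#' `write_corpus()` writes `phrases.csv`, `songs.csv` and
#' `theme_presence.csv` under `dir`; `read_corpus()` reads them back.
#' Ground truth is not serialised (it is reproducible from the config and
#' seed).
#'
#' @param corpus A `"song_corpus"`.
#' @param dir Directory path (created if needed).
#' @return `write_corpus()` the corpus invisibly; `read_corpus()` a list
#'   with `phrases`, `songs`, `presence`.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_phrase_table(corpus$phrases, file.path(dir, "phrases.csv"))
  write_song_table(corpus$songs, file.path(dir, "songs.csv"))
  write_theme_presence(corpus$presence,
                       file.path(dir, "theme_presence.csv"))
  invisible(corpus)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  list(phrases = read_phrase_table(file.path(dir, "phrases.csv")),
       songs = read_song_table(file.path(dir, "songs.csv")),
       presence = read_theme_presence(file.path(dir,
                                                "theme_presence.csv")))
}

#' Group song cycles by recording
#'
#' Splits a song table into the per-recording string collections used by
#' [bootstrap_support()]: one group per
#' location/year/song-type/recording, each holding that recording's song
#' cycles as symbol sequences.
#'
#' @param songs A validated song table.
#' @return Named list of lists of character vectors.
#' @export
song_groups <- function(songs) {
  songs <- validate_song_table(songs)
  lab <- recording_label(songs$location, songs$year, songs$song_type_tag,
                         songs$recording_id)
  seqs <- split_units(songs$themes)
  split(seqs, factor(lab, unique(lab)))
}

#' Generate synthetic unit measurements
#'
#' Draws per-class unit acoustic measurements honouring the unit
#' invariants by construction (all frequencies positive, high >= low,
#' frequency range > 1, bandwidth = high - low). Class means sit at
#' mutual Euclidean distance `separation` (in within-class standard
#' deviation units) in a latent 8-dimensional space that maps onto
#' duration, centre frequency, range, start/end/peak position within the
#' band, inflection count and pulse rate; `separation = 0` makes the
#' classes indistinguishable.
#'
#' @param n_classes Number of unit types (at most 8 mutually equidistant;
#'   more are placed on random directions).
#' @param separation Standardised distance between class means (>= 0).
#' @param n_per_class Observations per class.
#' @param seed Integer seed.
#' @return A unit table as produced by [derive_features()], with
#'   `qualitative_name` `"type01"`, `"type02"`, ...
#' @export
generate_unit_features <- function(n_classes = 2L, separation = 5,
                                   n_per_class = 100L, seed = 1L) {
  stopifnot(n_classes >= 1L, separation >= 0, n_per_class >= 1L)
  set.seed(seed)
  d <- 8L
  if (n_classes <= d) {
    q <- qr.Q(qr(matrix(rnorm(d * n_classes), d, n_classes)))
    means <- t(q) * separation / sqrt(2)
  } else {
    dirs <- matrix(rnorm(n_classes * d), n_classes, d)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    means <- dirs * separation / sqrt(2)
  }
  rows <- list()
  for (k in seq_len(n_classes)) {
    z <- matrix(rnorm(n_per_class * d), n_per_class, d)
    z <- sweep(z, 2L, means[k, ], `+`)
    centre <- exp(log(400) + 0.5 * z[, 2L])
    range_r <- 1 + exp(-0.3 + 0.5 * z[, 3L])
    high <- centre * sqrt(range_r)
    low <- centre / sqrt(range_r)
    rows[[k]] <- data.frame(
      duration = exp(-0.5 + 0.35 * z[, 1L]),
      peak_frequency = low + (high - low) * stats::plogis(z[, 6L]),
      high_frequency = high,
      low_frequency = low,
      start_frequency = low + (high - low) * stats::plogis(z[, 4L]),
      end_frequency = low + (high - low) * stats::plogis(z[, 5L]),
      inflections = pmax(0, round(1 + 0.8 * z[, 7L])),
      pulse_rate = pmax(0, 6 + 2.5 * z[, 8L]),
      qualitative_name = sprintf("type%02d", k),
      stringsAsFactors = FALSE
    )
  }
  derive_features(do.call(rbind, rows))
}

#' Simulate a duty-cycled file log
#'
#' Builds a per-file song-presence log for one site: `files_per_day`
#' files per day (96 for a 900 s duty cycle), with a target percentage of
#' song-bearing files per day. Song files are graded 2 (high SNR) with
#' probability `high_quality_frac`, otherwise 1.
#'
#' @param site Site label.
#' @param start_date First day (`Date` or string).
#' @param percents Numeric vector: target percentage of files containing
#'   song on each consecutive day.
#' @param files_per_day Files recorded per full day.
#' @param cycle_seconds Duty-cycle length in seconds (file start-time
#'   spacing).
#' @param high_quality_frac Probability a song file is category 2.
#' @param seed Optional seed for the placement of song files in the day.
#' @return A file log data frame (`site`, `start_time`, `category`).
#' @export
simulate_file_log <- function(site, start_date, percents,
                              files_per_day = 96L, cycle_seconds = 900L,
                              high_quality_frac = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start_date <- as.Date(start_date)
  rows <- list()
  for (i in seq_along(percents)) {
    n_song <- round(percents[i] / 100 * files_per_day)
    cat_ <- integer(files_per_day)
    if (n_song > 0L) {
      pos <- sample.int(files_per_day, n_song)
      cat_[pos] <- ifelse(runif(n_song) < high_quality_frac, 2L, 1L)
    }
    t0 <- as.POSIXct(paste(start_date + (i - 1L), "00:00:00"),
                     tz = "UTC")
    rows[[i]] <- data.frame(
      site = site,
      start_time = format(t0 + (seq_len(files_per_day) - 1L) *
                            cycle_seconds, "%Y-%m-%d %H:%M:%S"),
      category = cat_, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
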