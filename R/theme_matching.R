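#' Verify qualitative phrase-type assignments with the LSI
#'
#' During transcription, unit sequences are assigned to phrase types by
#' eye. This check makes the classification quantitative and repeatable:
#' for every phrase type it computes the within-type mean LSI (how similar
#' renditions of the type are to each other), the mean LSI to every other
#' type, and the median string; a type is *consistent* when its within-type
#' similarity strictly exceeds its similarity to every other type, and is
#' flagged otherwise.
#'
#' A singleton type has within-type similarity 1 by convention (a single
#' rendition is perfectly self-consistent).
#'
#' @param phrases A validated phrase table (see [corpus-format]).
#' @return An object of class `"phrase_type_report"`: a list with
#'   * `types`: data frame with `phrase_type`, `n`, `within`
#'     (within-type mean LSI), `max_between`, `consistent`;
#'   * `between`: symmetric matrix of mean between-type LSI values
#'     (diagonal holds the within-type values);
#'   * `medians`: named list of per-type median strings
#'     (as [median_string()] objects);
#'   * `flagged`: character vector of inconsistent phrase types.
#' @export
verify_phrase_types <- function(phrases) {
  phrases <- validate_phrase_table(phrases)
  seqs <- split_units(phrases$units)
  types <- as.character(phrases$phrase_type)
  utypes <- unique(types)
  if (length(utypes) < 2L) {
    stop("verify_phrase_types() needs at least 2 phrase types",
         call. = FALSE)
  }
  # encode against the global alphabet so cross-group comparisons are valid
  enc <- encode_sequences(seqs)
  groups <- lapply(utypes, function(t) enc[types == t])
  k <- length(utypes)
  between <- matrix(NA_real_, k, k, dimnames = list(utypes, utypes))
  medians <- vector("list", k)
  names(medians) <- utypes
  for (i in seq_len(k)) {
    gi <- groups[[i]]
    m <- lsi_matrix_cpp(gi)
    between[i, i] <- if (length(gi) > 1L) mean(m[upper.tri(m)]) else 1
    medians[[i]] <- median_string(seqs[types == utypes[i]])
    if (i < k) {
      for (j in seq(i + 1L, k)) {
        cross <- lsi_cross_cpp(gi, groups[[j]])
        between[i, j] <- between[j, i] <- mean(cross)
      }
    }
  }
  within <- diag(between)
  max_between <- vapply(seq_len(k),
                        function(i) max(between[i, -i]), numeric(1))
  consistent <- within > max_between
  report <- list(
    types = data.frame(phrase_type = utypes,
                       n = as.integer(table(factor(types, utypes))),
                       within = within, max_between = max_between,
                       consistent = consistent,
                       stringsAsFactors = FALSE, row.names = NULL),
    between = between,
    medians = medians,
    flagged = utypes[!consistent]
  )
  class(report) <- "phrase_type_report"
  report
}

#' @export
print.phrase_type_report <- function(x, ...) {
  cat("Phrase type verification over", nrow(x$types), "types\n")
  cat("  consistent:", sum(x$types$consistent), " flagged:",
      length(x$flagged), "\n")
  if (length(x$flagged)) {
    cat("  flagged types:", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Song-level LSI similarity matrix
#'
#' Runs the LSI over theme-ID sequences, treating each theme as a single
#' symbol. Two modes:
#' * `"full"`: every song cycle in the table is an item, retaining all
#'   between-cycle variability;
#' * `"median"`: one median song string per
#'   location/year/song-type/recording group (a point estimate), computed
#'   with [median_string()] over that group's cycles.
#'
#' @param songs A validated song table (see [corpus-format]).
#' @param mode `"full"` or `"median"`.
#' @return A similarity matrix; the underlying theme sequences are
#'   attached as `attr(, "sequences")` (named list, matrix row order).
#' @export
song_lsi_matrix <- function(songs, mode = c("full", "median")) {
  mode <- match.arg(mode)
  seqs <- song_sequences(songs)
  if (mode == "median") {
    songs <- validate_song_table(songs)
    grp <- recording_label(songs$location, songs$year, songs$song_type_tag,
                           songs$recording_id)
    med <- lapply(split(seqs, factor(grp, unique(grp))),
                  function(s) median_string(s)$string)
    seqs <- med
  }
  m <- similarity_matrix(lapply(seqs, as.character), labels = names(seqs))
  attr(m, "sequences") <- seqs
  m
}

#' Dice's similarity index on theme presence
#'
#' DSI ignores the order themes are sung in and scores only their sharing:
#' \deqn{DSI(A, B) = 2 |A \cap B| / (|A| + |B|)}
#' where A and B are the theme sets of two recordings. 1 means identical
#' theme content, 0 none shared.
#'
#' @param a,b Theme sets (vectors of theme IDs; duplicates ignored).
#' @return A proportion in \[0, 1\].
#' @examples
#' dice_similarity(1:5, c(3, 9, 10, 11))  # 2/9
#' @export
dice_similarity <- function(a, b) {
  a <- unique(as.integer(a))
  b <- unique(as.integer(b))
  if (length(a) == 0L || length(b) == 0L) {
    stop("dice_similarity() is undefined for empty theme sets",
         call. = FALSE)
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pairwise DSI matrix over recordings
#'
#' @param presences A theme presence table (see [corpus-format]) or a
#'   named list of theme sets.
#' @return A symmetric similarity matrix with unit diagonal.
#' @export
dsi_matrix <- function(presences) {
  sets <- if (is.data.frame(presences)) presence_sets(presences)
          else lapply(presences, function(x) unique(as.integer(x)))
  n <- length(sets)
  if (n < 2L) stop("dsi_matrix() needs at least 2 recordings",
                   call. = FALSE)
  m <- diag(1, n)
  dimnames(m) <- list(names(sets), names(sets))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      m[i, j] <- m[j, i] <- dice_similarity(sets[[i]], sets[[j]])
    }
  }
  m
}
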