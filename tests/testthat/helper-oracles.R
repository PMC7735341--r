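# Independent quadratic-space dynamic-programming edit distance, used as
# the oracle against the package implementation. Kept deliberately naive.
lev_oracle <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  d <- matrix(0L, na + 1L, nb + 1L)
  d[, 1L] <- 0:na
  d[1L, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d[i + 1L, j + 1L] <- min(d[i, j] + (a[i] != b[j]),
                               d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L)
    }
  }
  d[na + 1L, nb + 1L]
}

lsi_oracle <- function(a, b) 1 - lev_oracle(a, b) / max(length(a), length(b))

random_seq <- function(len, alphabet) {
  alphabet[sample.int(length(alphabet), len, replace = TRUE)]
}

# All sequences over `alphabet` of length 0..maxlen, as a list.
all_seqs <- function(maxlen, alphabet) {
  out <- list(character(0))
  frontier <- list(character(0))
  for (l in seq_len(maxlen)) {
    frontier <- unlist(lapply(frontier,
                              function(s) lapply(alphabet, function(x) c(s, x))),
                       recursive = FALSE)
    out <- c(out, frontier)
  }
  out
}

# Minimal valid phrase table for constructing fixtures in code.
toy_phrase_table <- function(units, phrase_type,
                             location = "Loc", year = 2016,
                             recording_id = "X", song_type_tag = "") {
  data.frame(location = location, year = year, recording_id = recording_id,
             song_type_tag = song_type_tag, phrase_type = phrase_type,
             units = units, stringsAsFactors = FALSE)
}

toy_song_table <- function(themes, location = "Loc", year = 2016,
                           recording_id = "X", song_type_tag = "",
                           cycle = seq_along(themes)) {
  data.frame(location = location, year = year, recording_id = recording_id,
             song_type_tag = song_type_tag, cycle = cycle, themes = themes,
             stringsAsFactors = FALSE)
}
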