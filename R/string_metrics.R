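#' String-edit similarity of transcribed song sequences
#'
#' Humpback whale song is transcribed as ordered sequences of symbols: unit
#' labels within a phrase, or theme identifiers within a song. These
#' functions quantify sequence similarity with the Levenshtein (edit)
#' distance and its length-normalised similarity form, the Levenshtein
#' similarity index (LSI):
#' \deqn{LSI(a, b) = 1 - LD(a, b) / \max(|a|, |b|)}
#' where LD is the minimal number of single-symbol insertions, deletions and
#' substitutions (all at unit cost) turning one sequence into the other.
#' LSI is 1 for identical sequences and 0 for maximally dissimilar ones.
#'
#' @param a,b Symbol sequences: character vectors, one symbol per element.
#'   Numeric vectors (e.g. theme IDs) are coerced with `as.character()`.
#' @return `levenshtein()` returns a non-negative integer edit count;
#'   `lsi()` a similarity in \[0, 1\].
#' @examples
#' levenshtein(c("U1", "U2", "U3", "U4"), c("U1", "U3", "U4"))
#' lsi(c("U1", "U2", "U3", "U4"), c("U1", "U3", "U4"))
#' @export
levenshtein <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  syms <- unique(c(a, b))
  lev_dist_cpp(match(a, syms), match(b, syms))
}

#' @rdname levenshtein
#' @export
lsi <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  m <- max(length(a), length(b))
  if (m == 0L) {
    stop("lsi() is undefined when both sequences are empty", call. = FALSE)
  }
  1 - levenshtein(a, b) / m
}

# Coerce sequence input to a named list of character vectors. Accepts a list
# of symbol vectors or a character vector of space-delimited strings.
as_symbol_sequences <- function(strings) {
  if (is.character(strings)) {
    nm <- names(strings)
    strings <- strsplit(trimws(strings), "[[:space:]]+")
    names(strings) <- nm
  }
  if (!is.list(strings)) {
    stop("expected a list of symbol vectors or a character vector",
         call. = FALSE)
  }
  lapply(strings, as.character)
}

# Integer-encode a list of symbol sequences against their common alphabet.
encode_sequences <- function(seqs) {
  syms <- unique(unlist(seqs, use.names = FALSE))
  lapply(seqs, function(s) match(s, syms))
}

#' Pairwise LSI similarity matrix
#'
#' Computes the full symmetric matrix of pairwise [lsi()] values over a
#' collection of symbol sequences, e.g. all phrase strings (a "theme
#' similarity matrix") or all song strings.
#'
#' @param strings A list of symbol sequences (character vectors), or a
#'   character vector of space-delimited strings. Names, if present, become
#'   matrix dimnames.
#' @param labels Optional item labels overriding `names(strings)`.
#' @return A symmetric numeric matrix with unit diagonal and entries in
#'   \[0, 1\].
#' @export
similarity_matrix <- function(strings, labels = NULL) {
  seqs <- as_symbol_sequences(strings)
  if (length(seqs) < 2L) {
    stop("similarity_matrix() needs at least 2 strings", call. = FALSE)
  }
  len <- vapply(seqs, length, integer(1))
  if (any(len == 0L)) {
    bad <- which(len == 0L)
    nm <- names(seqs)[bad]
    id <- if (is.null(nm) || any(!nzchar(nm))) paste(bad, collapse = ", ")
          else paste(nm, collapse = ", ")
    stop("empty string(s) in similarity_matrix() input: ", id, call. = FALSE)
  }
  if (is.null(labels)) labels <- names(seqs)
  m <- lsi_matrix_cpp(encode_sequences(seqs))
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Validate a similarity matrix
#'
#' Checks the contract every similarity matrix in this package obeys:
#' square, symmetric, unit diagonal, entries in \[0, 1\].
#'
#' @param m Numeric matrix.
#' @param tol Numerical tolerance for symmetry and the unit diagonal.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_similarity_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop("not a square numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < -tol) || any(m > 1 + tol)) {
    stop("similarity values must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop("similarity matrix is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(m) - 1)) > tol) {
    stop("similarity matrix diagonal must be 1", call. = FALSE)
  }
  invisible(m)
}

#' Median string of a sequence set
#'
#' The median string is the member of a set most similar to all other
#' members: pairwise LSI values to every other string are summed and the
#' string with the largest sum wins. It condenses within-set variability
#' into one representative sequence, e.g. one unit string per phrase type
#' per location and year. Ties are broken by the smallest input index, so
#' the result is order-stable. A singleton set returns its only string with
#' score 0 and within-set similarity 1 by convention.
#'
#' @inheritParams similarity_matrix
#' @return An object of class `"median_string"`: a list with elements
#'   `index` (position of the winner in input order), `string` (the winning
#'   symbol sequence), `score` (its summed pairwise LSI, self excluded) and
#'   `within_set_similarity` (mean pairwise LSI of the whole set).
#' @export
median_string <- function(strings) {
  seqs <- as_symbol_sequences(strings)
  n <- length(seqs)
  if (n == 0L) stop("median_string() of an empty collection", call. = FALSE)
  if (n == 1L) {
    out <- list(index = 1L, string = seqs[[1L]], score = 0,
                within_set_similarity = 1)
    class(out) <- "median_string"
    return(out)
  }
  m <- similarity_matrix(seqs)
  score <- rowSums(m) - 1          # exclude self-similarity
  idx <- which.max(score)          # which.max takes the first maximum
  out <- list(index = idx, string = seqs[[idx]], score = score[[idx]],
              within_set_similarity = mean(m[upper.tri(m)]))
  class(out) <- "median_string"
  out
}

#' @export
print.median_string <- function(x, ...) {
  cat("Median string (index ", x$index, ", score ",
      format(x$score, digits = 4), "):\n  ",
      paste(x$string, collapse = " "), "\n",
      "within-set similarity: ",
      format(x$within_set_similarity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Within-set similarity
#'
#' Mean pairwise LSI over all distinct pairs of a string set (the diagonal
#' is excluded, since self-similarity is 1 by definition and would inflate
#' the statistic). Reports how variable the renditions of one phrase type
#' or song are.
#'
#' @inheritParams similarity_matrix
#' @return A proportion in \[0, 1\].
#' @export
within_set_similarity <- function(strings) {
  seqs <- as_symbol_sequences(strings)
  if (length(seqs) < 2L) {
    stop("within_set_similarity() needs at least 2 strings", call. = FALSE)
  }
  m <- similarity_matrix(seqs)
  mean(m[upper.tri(m)])
}

#' Export a similarity matrix
#'
#' Writes a labelled square CSV table, and optionally the long pair format
#' (`item_i,item_j,lsi`, upper triangle only).
#'
#' @param m Similarity matrix with dimnames.
#' @param path Output CSV path for the square form.
#' @param long_path Optional output path for the long pair table.
#' @return `m`, invisibly.
#' @export
write_similarity_matrix <- function(m, path, long_path = NULL) {
  validate_similarity_matrix(m)
  write.csv(as.data.frame(m), path, row.names = TRUE)
  if (!is.null(long_path)) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    labs <- rownames(m)
    if (is.null(labs)) labs <- as.character(seq_len(nrow(m)))
    long <- data.frame(item_i = labs[idx[, 1L]], item_j = labs[idx[, 2L]],
                       lsi = m[idx], stringsAsFactors = FALSE)
    write.csv(long, long_path, row.names = FALSE)
  }
  invisible(m)
}
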