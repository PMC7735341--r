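#' Derived acoustic features of song units
#'
#' From the measured parameters of each unit's fundamental frequency
#' (duration, peak/high/low frequency, start/end frequency, inflection
#' count, pulse repetition rate) this computes the derived parameters:
#' bandwidth (high - low, Hz), frequency trend (start / end) and frequency
#' range (high / low), giving the 12-parameter description used to test
#' unit classifications (11 numeric parameters + the qualitative name).
#'
#' @param raw Data frame with columns `duration` (s), `peak_frequency`,
#'   `high_frequency`, `low_frequency`, `start_frequency`,
#'   `end_frequency` (Hz), `inflections` (count), `pulse_rate` (per s;
#'   0 for non-pulsed units) and `qualitative_name`.
#' @return Data frame with the 11 numeric parameters (`duration`,
#'   `bandwidth`, `peak_frequency`, `high_frequency`, `low_frequency`,
#'   `start_frequency`, `end_frequency`, `frequency_trend`,
#'   `frequency_range`, `inflections`, `pulse_rate`) and
#'   `qualitative_name`.
#' @export
derive_features <- function(raw) {
  need <- c("duration", "peak_frequency", "high_frequency",
            "low_frequency", "start_frequency", "end_frequency",
            "inflections", "pulse_rate", "qualitative_name")
  raw <- check_columns(raw, need, "unit measurements")
  freq_cols <- c("peak_frequency", "high_frequency", "low_frequency",
                 "start_frequency", "end_frequency")
  for (col in freq_cols) {
    v <- as.numeric(raw[[col]])
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("unit measurements: ", col, " must be positive in row(s) ",
           paste(which(!is.finite(v) | v <= 0), collapse = ", "),
           call. = FALSE)
    }
    raw[[col]] <- v
  }
  bad <- raw$high_frequency < raw$low_frequency
  if (any(bad)) {
    stop("unit measurements: high_frequency < low_frequency in row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (any(as.numeric(raw$inflections) < 0)) {
    stop("unit measurements: inflections must be >= 0", call. = FALSE)
  }
  data.frame(
    duration = as.numeric(raw$duration),
    bandwidth = raw$high_frequency - raw$low_frequency,
    peak_frequency = raw$peak_frequency,
    high_frequency = raw$high_frequency,
    low_frequency = raw$low_frequency,
    start_frequency = raw$start_frequency,
    end_frequency = raw$end_frequency,
    frequency_trend = raw$start_frequency / raw$end_frequency,
    frequency_range = raw$high_frequency / raw$low_frequency,
    inflections = as.numeric(raw$inflections),
    pulse_rate = as.numeric(raw$pulse_rate),
    qualitative_name = as.character(raw$qualitative_name),
    stringsAsFactors = FALSE
  )
}

#' Names of the numeric unit parameters
#' @return Character vector of the 11 numeric feature names used by
#'   [rf_agreement()].
#' @export
unit_feature_names <- function() {
  c("duration", "bandwidth", "peak_frequency", "high_frequency",
    "low_frequency", "start_frequency", "end_frequency",
    "frequency_trend", "frequency_range", "inflections", "pulse_rate")
}

#' Random-forest agreement of qualitative unit classification
#'
#' Tests whether qualitative unit-type labels are supported by the
#' measured acoustics: a random forest is grown with the qualitative name
#' as the response and the 11 numeric parameters as predictors
#' (defaults: 1000 trees, 3 variables tried per split). A low out-of-bag
#' (OOB) error indicates that the subjective classification is recoverable
#' from the measurements, i.e. robust and repeatable. No class balancing
#' is applied; the raw OOB rate is reported.
#'
#' @param units Unit table as returned by [derive_features()] (or read
#'   with the corpus readers): the 11 numeric parameters plus
#'   `qualitative_name`.
#' @param trees Number of trees grown.
#' @param vars_per_split Variables sampled at each split (`mtry`).
#' @param seed Integer seed; the report is fully determined by it.
#' @return An object of class `"rf_report"`: list with `oob_error`
#'   (proportion), `confusion` (count matrix, rows = true class),
#'   `importance` (mean decrease in accuracy per parameter, permutation
#'   based) and `config` (echo of trees, vars_per_split, seed, n, classes).
#' @export
rf_agreement <- function(units, trees = 1000, vars_per_split = 3,
                         seed = NULL) {
  feats <- unit_feature_names()
  units <- check_columns(units, c(feats, "qualitative_name"),
                         "unit table")
  x <- units[feats]
  for (f in feats) {
    v <- as.numeric(x[[f]])
    if (any(!is.finite(v))) {
      stop("non-finite ", f, " in unit record(s) ",
           paste(which(!is.finite(v)), collapse = ", "), call. = FALSE)
    }
    x[[f]] <- v
  }
  y <- factor(units$qualitative_name)
  if (nlevels(y) < 2L) {
    stop("rf_agreement() needs at least 2 unit classes", call. = FALSE)
  }
  if (any(table(y) < 2L)) {
    stop("every unit class needs at least 2 observations", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = trees,
                                   mtry = vars_per_split,
                                   importance = TRUE)
  conf <- rf$confusion[, levels(y), drop = FALSE]
  storage.mode(conf) <- "double"
  oob <- 1 - sum(diag(conf)) / sum(conf)
  imp <- rf$importance[, "MeanDecreaseAccuracy"]
  out <- list(oob_error = oob, confusion = conf, importance = imp,
              config = list(trees = trees,
                            vars_per_split = vars_per_split,
                            seed = seed, n = length(y),
                            classes = levels(y)))
  class(out) <- "rf_report"
  out
}

#' @export
print.rf_report <- function(x, ...) {
  cat("Random-forest unit classification agreement\n")
  cat("  n =", x$config$n, "units,", length(x$config$classes),
      "classes;", x$config$trees, "trees, mtry =",
      x$config$vars_per_split, "\n")
  cat("  OOB error rate:", sprintf("%.2f%%", 100 * x$oob_error), "\n")
  top <- names(sort(x$importance, decreasing = TRUE))[1L]
  cat("  most informative parameter:", top, "\n")
  invisible(x)
}

#' Export a random-forest report
#'
#' @param report An `"rf_report"` from [rf_agreement()].
#' @param confusion_path,importance_path Output CSV paths.
#' @return `report`, invisibly.
#' @export
write_rf_report <- function(report, confusion_path, importance_path) {
  write.csv(as.data.frame(report$confusion), confusion_path,
            row.names = TRUE)
  write.csv(data.frame(parameter = names(report$importance),
                       mean_decrease_accuracy = report$importance,
                       row.names = NULL),
            importance_path, row.names = FALSE)
  invisible(report)
}
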