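# Evaluation: accuracy and confusion matrices, the Wolpaw information
# transfer rate, and summary statistics over the bundled reference accuracy
# tables.

#' Classification accuracy
#'
#' `100 * correct / total`. Idle decisions on attended trials count as
#' errors.
#'
#' @param predicted,truth Equal-length command vectors (integers 0-6, 0 =
#'   idle).
#' @return Accuracy in percent.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth)) {
    stop_config("predicted and truth must be non-empty and of equal length")
  }
  100 * mean(predicted == truth)
}

#' Confusion matrix including the idle state
#'
#' @inheritParams accuracy
#' @return 7 x 7 integer matrix (rows = truth, columns = predicted) with
#'   dimnames `idle`, `1`-`6`.
#' @export
confusion_matrix <- function(predicted, truth) {
  lev <- c(0:6)
  labs <- c("idle", as.character(1:6))
  out <- table(factor(truth, levels = lev, labels = labs),
               factor(predicted, levels = lev, labels = labs))
  unclass(as.matrix(out))
}

#' Wolpaw information transfer rate
#'
#' `ITR = (log2 N + P log2 P + (1 - P) log2((1 - P)/(N - 1))) * 60 / T`
#' bits/min for `N` commands, accuracy fraction `P` and selection time `T`
#' seconds. The `P = 0` and `P = 1` limits are handled by continuity
#' (`0 log 0 = 0`).
#'
#' @param n_commands Number of selectable commands (>= 2).
#' @param accuracy_fraction Probability of a correct selection, in `[0, 1]`.
#' @param selection_time_s Time per selection in seconds (> 0).
#' @return Bits per minute.
#' @examples
#' itr(6, 1, 5)     # 31.02 bits/min
#' itr(6, 1/6, 5)   # chance level: 0
#' @export
itr <- function(n_commands, accuracy_fraction, selection_time_s) {
  if (n_commands < 2) stop_config("n_commands must be at least 2")
  p <- accuracy_fraction
  if (any(p < 0 | p > 1)) stop_config("accuracy_fraction must lie in [0, 1]")
  if (any(selection_time_s <= 0)) stop_config("selection_time_s must be positive")
  xlx <- function(q) ifelse(q > 0, q * log2(q), 0)
  bits <- log2(n_commands) + xlx(p) +
    ifelse(p < 1, (1 - p) * log2((1 - p) / (n_commands - 1)), 0)
  bits * 60 / selection_time_s
}

#' Column mean and standard deviation
#'
#' Arithmetic mean and sample (n - 1) standard deviation of a numeric fixture
#' column, as used for the "Mean +/- S.D." rows of the reference tables
#' (values are conventionally displayed rounded to one decimal).
#'
#' @param table Data frame.
#' @param column Column name.
#' @return List with `mean`, `sd`, `n` (unrounded).
#' @export
column_stats <- function(table, column) {
  if (!column %in% names(table)) {
    stop_config("no column '", column, "' in table")
  }
  v <- table[[column]]
  if (!is.numeric(v)) stop_config("column '", column, "' is not numeric")
  if (anyNA(v)) stop_config("column '", column, "' contains non-numeric cells")
  if (length(v) < 2L) stop_config("column '", column, "' needs n >= 2")
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Bundled reference accuracy tables
#'
#' Participant-level classification accuracy tables from the original
#' experiments, bundled as plain CSV. `"offline"` holds per-participant
#' accuracies of the circle checkerboard patterns (CB1-CB3) under the
#' relative-PSD and PSD detection methods; `"online"` holds the online
#' six-command accuracies for the mutual versus individually personalized
#' stimulus patterns (command groups 1-3 and 4-6).
#'
#' See the README in `inst/extdata` for column notes: a few published means
#' differ from the transcribed column means by 0.1-0.2 in the last digit.
#'
#' @param study `"offline"` or `"online"`.
#' @return Data frame with a `participant` column plus accuracy columns in
#'   percent.
#' @export
reference_accuracy_table <- function(study = c("offline", "online")) {
  study <- match.arg(study)
  path <- system.file("extdata", paste0(study, "_accuracy.csv"),
                      package = "ssvepdetect", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Headline accuracy of the individualized stimuli
#'
#' The mean of the two individual-pattern column means of the online
#' reference table (command groups 1-3 and 4-6): the single-number summary of
#' six-command online performance with personalized stimuli.
#'
#' @param table Online reference table; default
#'   `reference_accuracy_table("online")`.
#' @return Accuracy in percent.
#' @export
headline_individual_accuracy <- function(table = reference_accuracy_table("online")) {
  cols <- c("individual_cmd13", "individual_cmd46")
  if (!all(cols %in% names(table))) {
    stop_config("table must contain columns ", paste(cols, collapse = " and "))
  }
  mean(c(column_stats(table, cols[1])$mean, column_stats(table, cols[2])$mean))
}
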