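# Two-stage personalized stimulus selection and per-user channel assignment:
# candidates are scored by classification accuracy minus comfort penalties,
# ties are broken by stated user preference and then canonical order.

CB_LEVELS <- c("CB0", "CB1", "CB2", "CB3")
COND_LEVELS <- c("SFF", "MFH", "MFF")

#' Total score of a candidate stimulus
#'
#' `Total Score = classification accuracy - eye irritation score - visual
#' fatigue score`. Accuracy is in percent (0-100) and the two comfort scores
#' on the 1 (comfortable) to 5 (highly uncomfortable / severe) rating scale;
#' the subtraction is performed on these raw scales.
#'
#' @param accuracy_pct Classification accuracy in percent, in `[0, 100]`.
#' @param irritation Eye irritation score, integer 1-5.
#' @param fatigue Visual fatigue score, integer 1-5.
#' @return Numeric total score (vectorised).
#' @export
total_score <- function(accuracy_pct, irritation, fatigue) {
  if (any(accuracy_pct < 0 | accuracy_pct > 100)) {
    stop_config("accuracy_pct must lie in [0, 100]")
  }
  if (any(irritation < 1 | irritation > 5) || any(fatigue < 1 | fatigue > 5)) {
    stop_config("comfort scores must lie in [1, 5]")
  }
  accuracy_pct - irritation - fatigue
}

canonical_rank <- function(checkerboard, condition) {
  match(checkerboard, CB_LEVELS) * 10L + match(condition, COND_LEVELS)
}

pick_candidate <- function(cand, preferences) {
  score <- total_score(cand$accuracy, cand$irritation, cand$fatigue)
  best <- which(score == max(score))
  if (length(best) > 1L && !is.null(preferences) && nrow(preferences) > 0L) {
    pref_rank <- match(paste(cand$checkerboard[best], cand$condition[best]),
                       paste(preferences$checkerboard, preferences$condition))
    pref_rank[is.na(pref_rank)] <- Inf
    best <- best[pref_rank == min(pref_rank)]
  }
  if (length(best) > 1L) {
    best <- best[order(canonical_rank(cand$checkerboard[best],
                                      cand$condition[best]))][1]
  }
  i <- best[1]
  list(checkerboard = cand$checkerboard[i], condition = cand$condition[i],
       score = score[i])
}

#' Select a personalized stimulus assignment
#'
#' Two-stage selection per command group. Commands 1-3 choose among SFF and
#' MFH candidates, commands 4-6 among MFF candidates. Stage 1 maximises the
#' [total_score()] within each group; stage 2 breaks exact ties by the user's
#' preference ranking and, failing that, by canonical order (checkerboard
#' index, then SFF < MFH < MFF).
#'
#' @param candidates Data frame with columns `checkerboard` (`"CB0"`-
#'   `"CB3"`), `condition` (`"SFF"`, `"MFH"`, `"MFF"`), `accuracy` (percent),
#'   `irritation` and `fatigue` (1-5).
#' @param preferences Optional data frame (`checkerboard`, `condition`) in
#'   decreasing preference order.
#' @param user Optional user identifier stored on the result.
#' @param channel Optional channel label (`"O1"`/`"O2"`), e.g. from
#'   [select_channel()].
#' @return Object of class `stimulus_assignment`: list with `user`, `channel`,
#'   and per-group choices `cmds_1_3`, `cmds_4_6` (each `checkerboard`,
#'   `condition`, `score`).
#' @export
select_assignment <- function(candidates, preferences = NULL, user = NULL,
                              channel = NA_character_) {
  req <- c("checkerboard", "condition", "accuracy", "irritation", "fatigue")
  if (!all(req %in% names(candidates))) {
    stop_config("candidates must have columns: ", paste(req, collapse = ", "))
  }
  g13 <- candidates[candidates$condition %in% c("SFF", "MFH"), , drop = FALSE]
  g46 <- candidates[candidates$condition == "MFF", , drop = FALSE]
  if (nrow(g13) == 0L || nrow(g46) == 0L) {
    stop_config("candidates must cover both command groups ",
                "(SFF/MFH for 1-3 and MFF for 4-6)")
  }
  structure(list(user = user, channel = channel,
                 cmds_1_3 = pick_candidate(g13, preferences),
                 cmds_4_6 = pick_candidate(g46, preferences)),
            class = "stimulus_assignment")
}

#' @export
print.stimulus_assignment <- function(x, ...) {
  cat("Personalized stimulus assignment",
      if (!is.null(x$user)) paste0("(user ", x$user, ")"), "\n")
  cat(sprintf("  commands 1-3: %s / %s (score %.1f)\n",
              x$cmds_1_3$checkerboard, x$cmds_1_3$condition, x$cmds_1_3$score))
  cat(sprintf("  commands 4-6: %s / %s (score %.1f)\n",
              x$cmds_4_6$checkerboard, x$cmds_4_6$condition, x$cmds_4_6$score))
  cat("  EEG channel:", x$channel, "\n")
  invisible(x)
}

#' Select the better occipital channel
#'
#' Picks the channel with the larger mean total gated feature energy over the
#' calibration stimulation epochs; ties go to the first channel (O1).
#'
#' @param epochs An `ssvep_epochs` object containing stimulation epochs.
#' @param detector A fitted [ssvep_detector()].
#' @return Channel label (`"O1"` or `"O2"`).
#' @export
select_channel <- function(epochs, detector) {
  fm <- build_feature_matrix(epochs, detector)
  stim <- attr(fm, "labels") != "rest"
  if (!any(stim)) stop_config("no stimulation epochs to compare channels on")
  energy <- apply(fm[stim, , , drop = FALSE], 2, sum) / sum(stim)
  names(energy)[which.max(energy)]
}

#' Group-level (mutual) assignment across users
#'
#' The modal per-group (checkerboard, condition) choice over a set of
#' per-user assignments; ties resolved in canonical order.
#'
#' @param assignments List of [select_assignment()] results.
#' @return Object of class `stimulus_assignment` with `user = "mutual"`.
#' @export
mutual_assignment <- function(assignments) {
  stopifnot(length(assignments) >= 1L)
  modal <- function(group) {
    keys <- vapply(assignments, function(a) {
      paste(a[[group]]$checkerboard, a[[group]]$condition)
    }, "")
    tab <- table(keys)
    top <- names(tab)[tab == max(tab)]
    parts <- strsplit(top, " ")
    ord <- order(vapply(parts, function(p) canonical_rank(p[1], p[2]), 0L))
    p <- parts[[ord[1]]]
    list(checkerboard = p[1], condition = p[2], score = NA_real_)
  }
  ch <- vapply(assignments, function(a) a$channel, "")
  ch_tab <- table(ch[!is.na(ch)])
  structure(list(user = "mutual",
                 channel = if (length(ch_tab)) names(ch_tab)[which.max(ch_tab)]
                           else NA_character_,
                 cmds_1_3 = modal("cmds_1_3"),
                 cmds_4_6 = modal("cmds_4_6")),
            class = "stimulus_assignment")
}
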