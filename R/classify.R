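# Element detection (largest / second-largest gated feature) and the
# decision rules mapping features to six commands plus an idle state,
# including two-channel fusion and a simulated online loop.

#' Index of the largest feature element
#'
#' `m1 = argmax_i Sfi`, ties broken by the lowest index; `NA` (the idle
#' sentinel) when every feature is zero.
#'
#' @param fv Numeric feature vector (an [extract_features()] result).
#' @return Integer index or `NA`.
#' @export
detect_primary <- function(fv) {
  s <- as.numeric(fv)
  if (all(s <= 0)) return(NA_integer_)
  which.max(s)
}

#' Index of the second-largest feature element
#'
#' `m2 = argmax_{i != m1} Sfi`; `NA` when no second element is positive.
#'
#' @inheritParams detect_primary
#' @param m1 Index returned by [detect_primary()].
#' @return Integer index or `NA`.
#' @export
detect_secondary <- function(fv, m1) {
  s <- as.numeric(fv)
  if (is.na(m1)) return(NA_integer_)
  s[m1] <- -Inf
  if (all(s <= 0)) return(NA_integer_)
  which.max(s)
}

#' Fuse the two occipital channels
#'
#' Selects the feature vector used for the decision. `"max_energy"` picks the
#' channel with the larger total gated feature energy (ties go to the first
#' listed channel); naming a channel (`"O1"`, `"O2"`, or `"single:O2"`)
#' passes that channel through regardless of energy.
#'
#' @param fv_list Named list of feature vectors, one per channel.
#' @param strategy `"max_energy"` or a channel selector.
#' @return The chosen feature vector, with its `channel` attribute set.
#' @export
fuse_channels <- function(fv_list, strategy = "max_energy") {
  stopifnot(is.list(fv_list), length(fv_list) >= 1L, !is.null(names(fv_list)))
  pick <- if (identical(strategy, "max_energy")) {
    sums <- vapply(fv_list, function(f) sum(as.numeric(f)), 0)
    names(fv_list)[which.max(sums)]
  } else {
    ch <- sub("^single:", "", strategy)
    if (!ch %in% names(fv_list)) {
      stop_config("unknown channel-fusion strategy: ", strategy)
    }
    ch
  }
  fv <- fv_list[[pick]]
  attr(fv, "channel") <- pick
  fv
}

# family of the frequency at index i of a feature vector (uses names when
# present, so permuting the axis with its labels permutes consistently)
feature_family <- function(fv, i) {
  f <- names(fv)
  if (!is.null(f)) family_of(as.numeric(f[i])) else FOI_FAMILY[i]
}

#' Classify one feature vector into a command or idle
#'
#' Two-stage rule-based decision. In `SFF_MFH` mode the command (1-3) is the
#' frequency family of the largest gated feature; a harmonic peak counts
#' towards its fundamental. In `MFF` mode the two largest features must fall
#' in two distinct families, whose unordered fundamental pair selects command
#' 4-6 (7+13 -> 4, 7+17 -> 5, 13+17 -> 6); a same-family pair or a missing
#' second element yields idle. Idle (command 0) is returned whenever every
#' feature on the decision channel is zero.
#'
#' @param fv A feature vector, or a named list of per-channel feature vectors
#'   (fused via [fuse_channels()]).
#' @param mode `"SFF_MFH"` or `"MFF"` — which stimulus group is active.
#' @param channel Fusion strategy, see [fuse_channels()].
#' @return Object of class `ssvep_decision`: list with `command` (integer 0-6,
#'   0 = idle), `m1`, `m2`, `channel`, `mode`.
#' @export
decide <- function(fv, mode = c("SFF_MFH", "MFF"), channel = "max_energy") {
  mode <- match.arg(mode)
  if (is.list(fv) && !inherits(fv, "ssvep_features")) {
    fv <- fuse_channels(fv, channel)
  }
  ch <- attr(fv, "channel") %||% NA_character_
  m1 <- detect_primary(fv)
  m2 <- NA_integer_
  command <- 0L
  if (!is.na(m1)) {
    fam1 <- feature_family(fv, m1)
    if (mode == "SFF_MFH") {
      command <- FAMILY_COMMAND[[as.character(fam1)]]
    } else {
      m2 <- detect_secondary(fv, m1)
      if (!is.na(m2)) {
        fam2 <- feature_family(fv, m2)
        if (fam1 != fam2) {
          key <- paste(sort(c(fam1, fam2)), collapse = "+")
          command <- PAIR_COMMAND[[key]]
        }
      }
    }
  }
  structure(list(command = command, m1 = m1, m2 = m2, channel = ch,
                 mode = mode),
            class = "ssvep_decision")
}

#' @export
print.ssvep_decision <- function(x, ...) {
  lab <- if (x$command == 0L) "idle" else paste("command", x$command)
  cat(sprintf("%s (mode %s, m1 = %s, m2 = %s, channel %s)\n", lab, x$mode,
              x$m1, x$m2, x$channel))
  invisible(x)
}

#' Frequency family of the spectral peak
#'
#' Parameter-recovery helper: the fundamental family (7, 13 or 17) of the
#' largest raw PSD value among the nine frequencies of interest, bypassing
#' the threshold gates.
#'
#' @param est An [welch_psd()] estimate.
#' @return 7, 13 or 17.
#' @export
dominant_family <- function(est) {
  p <- est$power[bin_index(est, FOI)]
  FOI_FAMILY[which.max(p)]
}

#' Sliding-window online classification
#'
#' Emulates the online loop: a window slides over a (filtered) recording and
#' each window is classified independently with the calibrated detector.
#'
#' @param rec An `eeg_recording` (the stream).
#' @param detector A fitted [ssvep_detector()].
#' @param mode Decision mode for every window, see [decide()].
#' @param window_s,step_s Window length and hop in seconds (defaults 4 and 1,
#'   mirroring the offline analysis length).
#' @param channel Fusion strategy, see [fuse_channels()].
#' @return Data frame with one row per window: `t_start`, `t_end`, `command`,
#'   `m1`, `m2`, `channel`.
#' @export
online_classify <- function(rec, detector, mode = c("SFF_MFH", "MFF"),
                            window_s = 4, step_s = 1, channel = "max_energy") {
  mode <- match.arg(mode)
  if (!inherits(detector, "ssvep_detector")) {
    stop_config("online classification requires a calibrated ssvep_detector")
  }
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  n_win <- round(window_s * fs)
  total <- ncol(rec$samples)
  starts <- if (total >= n_win) {
    seq(0L, total - n_win, by = round(step_s * fs))
  } else integer(0)
  rows <- lapply(starts, function(s0) {
    fvs <- lapply(stats::setNames(nm = rownames(rec$samples)), function(ch) {
      est <- welch_psd(rec$samples[ch, s0 + seq_len(n_win)], fs = fs,
                      n = detector$n, overlap = detector$overlap)
      extract_features(est, detector$calibration[[ch]],
                       eq5_mode = detector$eq5_mode, channel = ch)
    })
    d <- decide(fvs, mode = mode, channel = channel)
    data.frame(t_start = s0 / fs, t_end = (s0 + n_win) / fs,
               command = d$command, m1 = d$m1, m2 = d$m2,
               channel = d$channel, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      command = integer(0), m1 = integer(0), m2 = integer(0),
                      channel = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
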