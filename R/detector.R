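# The central fitted object: a calibrated threshold detector over both
# occipital channels, with the usual modelling verbs (print, summary, coef,
# predict, plot).

#' Fit a calibrated SSVEP threshold detector
#'
#' Calibrates per-frequency baselines and thresholds on labeled rest and
#' stimulation epochs (see [calibrate()]) for every channel of an epoch set,
#' returning a detector object that classifies new epochs into six commands
#' plus idle via [predict.ssvep_detector()].
#'
#' Calibration uses all rest epochs plus the first `calibration_trials`
#' stimulation epochs of each stimulus (the remaining stimulation epochs are
#' available for evaluation; their indices are recorded in the fit).
#'
#' @param epochs An `ssvep_epochs` object whose labels are `"rest"` or
#'   canonical flicker symbols.
#' @param method `"psd"` (raw spectra, default) or `"relative"`
#'   (frequency-of-interest normalised spectra throughout Eqs. 1-5).
#' @param calibration_trials Stimulation trials per stimulus used for
#'   calibration (default 1, the first trial of each stimulus).
#' @param eq5_mode Feature gate variant, see [extract_features()].
#' @param n,overlap Welch parameters, see [welch_psd()].
#' @param tr_coef,ts_range Threshold coefficients, see [calibrate()].
#' @return Object of class `ssvep_detector`: list with `calibration` (named
#'   list of [calibrate()] results per channel), `method`, `eq5_mode`, `n`,
#'   `overlap`, `fs`, `channels`, `calibration_index` (epoch indices used for
#'   calibration) and `call`.
#' @examples
#' rec <- simulate_session(ssvep_profile(), trial_protocol(trials_per_flicker = 2),
#'                         seed = 1)
#' ep <- segment_epochs(apply_filters(rec), 4, 0.5)
#' fit <- ssvep_detector(ep)
#' fit
#' @export
ssvep_detector <- function(epochs, method = c("psd", "relative"),
                           calibration_trials = 1, eq5_mode = c("band", "min_only"),
                           n = 1024, overlap = 0.5, tr_coef = 1.5,
                           ts_range = c(0.75, 1.25)) {
  stopifnot(inherits(epochs, "ssvep_epochs"))
  method <- match.arg(method)
  eq5_mode <- match.arg(eq5_mode)
  labels <- epochs$labels
  rest_idx <- which(labels == "rest")
  stim_idx <- which(labels != "rest")
  if (!length(rest_idx) || !length(stim_idx)) {
    stop_config("epochs must contain both rest and stimulation trials")
  }
  cal_stim <- unlist(lapply(split(stim_idx, labels[stim_idx]), function(ix) {
    utils::head(ix, calibration_trials)
  }), use.names = FALSE)
  cal_stim <- sort(cal_stim)
  slice <- function(idx, ch) {
    matrix(epochs$x[idx, ch, , drop = FALSE], nrow = length(idx))
  }
  calib <- lapply(stats::setNames(nm = epochs$channels), function(ch) {
    calibrate(slice(rest_idx, ch), slice(cal_stim, ch),
              labels = labels[cal_stim], method = method, fs = epochs$fs,
              n = n, overlap = overlap, tr_coef = tr_coef, ts_range = ts_range)
  })
  structure(list(calibration = calib, method = method, eq5_mode = eq5_mode,
                 n = n, overlap = overlap, fs = epochs$fs,
                 channels = epochs$channels,
                 calibration_index = sort(c(rest_idx, cal_stim)),
                 call = match.call()),
            class = "ssvep_detector")
}

#' @export
print.ssvep_detector <- function(x, ...) {
  cat("Calibrated SSVEP threshold detector\n")
  cat("  method:", x$method, "| gate:", x$eq5_mode,
      sprintf("| Welch N = %d (r = %g Hz) @ %g Hz\n", x$n, x$fs / x$n, x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  np <- vapply(x$calibration, function(c) sum(c$response_present), 0L)
  cat("  frequencies with detectable response:",
      paste(sprintf("%s: %d/9", names(np), np), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ssvep_detector <- function(object, ...) {
  out <- coef(object)
  class(out) <- c("summary.ssvep_detector", class(out))
  out
}

#' @export
print.summary.ssvep_detector <- function(x, digits = 4, ...) {
  cat("Per-frequency calibration (BLR/BLS baselines, TR resting threshold,\n")
  cat("TS acceptance band):\n\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Calibration coefficients of a detector
#'
#' @param object A fitted [ssvep_detector()].
#' @param ... Unused.
#' @return Data frame of the per-channel, per-frequency baselines and
#'   thresholds (`channel`, `fi`, `BLR`, `BLS`, `TR`, `TS_min`, `TS_max`,
#'   `response_present`).
#' @export
coef.ssvep_detector <- function(object, ...) {
  do.call(rbind, lapply(names(object$calibration), function(ch) {
    cc <- object$calibration[[ch]]
    cbind(data.frame(channel = ch, stringsAsFactors = FALSE),
          as.data.frame(cc))
  }))
}

#' Classify epochs with a fitted detector
#'
#' Extracts gated features per channel, fuses channels, and applies the
#' two-stage decision rules. The decision mode follows each epoch's label by
#' default (`"auto"`: MFF-labeled epochs use the dual-frequency rule, all
#' others — including rest — the single-frequency rule); pass `"SFF_MFH"` or
#' `"MFF"` to force one rule.
#'
#' @param object A fitted [ssvep_detector()].
#' @param newdata An `ssvep_epochs` object.
#' @param mode `"auto"`, `"SFF_MFH"` or `"MFF"`.
#' @param channel Fusion strategy, see [fuse_channels()].
#' @param ... Unused.
#' @return Data frame with one row per epoch: `label`, `truth` (encoded
#'   command, 0 for rest), `mode`, `command` (0 = idle), `m1`, `m2`,
#'   `channel`, `correct`.
#' @export
predict.ssvep_detector <- function(object, newdata, mode = "auto",
                                   channel = "max_energy", ...) {
  stopifnot(inherits(newdata, "ssvep_epochs"))
  tab <- flicker_table()
  n_ep <- dim(newdata$x)[1]
  rows <- vector("list", n_ep)
  for (i in seq_len(n_ep)) {
    lab <- newdata$labels[i]
    ep_mode <- if (mode == "auto") {
      if (lab %in% tab$symbol && tab$condition[match(lab, tab$symbol)] == "MFF")
        "MFF" else "SFF_MFH"
    } else mode
    fvs <- lapply(stats::setNames(nm = newdata$channels), function(ch) {
      est <- welch_psd(newdata$x[i, ch, ], fs = newdata$fs, n = object$n,
                      overlap = object$overlap)
      extract_features(est, object$calibration[[ch]],
                       eq5_mode = object$eq5_mode, channel = ch)
    })
    d <- decide(fvs, mode = ep_mode, channel = channel)
    truth <- if (lab %in% tab$symbol) tab$command_id[match(lab, tab$symbol)] else 0L
    rows[[i]] <- data.frame(label = lab, truth = truth, mode = ep_mode,
                            command = d$command, m1 = d$m1, m2 = d$m2,
                            channel = d$channel, correct = d$command == truth,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Plot calibration spectra and thresholds
#'
#' Shows, per channel, the calibrated values at the nine frequencies of
#' interest: the stimulated acceptance band (TS_min-TS_max) and the resting
#' threshold TR.
#'
#' @param x A fitted [ssvep_detector()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ssvep_detector <- function(x, ...) {
  k <- length(x$calibration)
  old <- graphics::par(mfrow = c(k, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ch in names(x$calibration)) {
    cc <- x$calibration[[ch]]
    ylim <- range(0, cc$TS_max, cc$TR)
    graphics::plot(cc$fi, cc$BLS, pch = 19, ylim = ylim,
                   xlab = "Frequency (Hz)",
                   ylab = if (x$method == "psd") "PSD" else "relative PSD",
                   main = paste("Channel", ch), ...)
    graphics::segments(cc$fi, cc$TS_min, cc$fi, cc$TS_max, lwd = 3,
                       col = "grey60")
    graphics::points(cc$fi, cc$TR, pch = 4, col = "red")
    graphics::legend("topright", legend = c("BLS", "TS band", "TR"),
                     pch = c(19, NA, 4), lty = c(NA, 1, NA), lwd = c(NA, 3, NA),
                     col = c("black", "grey60", "red"), bty = "n")
  }
  invisible(x)
}
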