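# Preprocessing: zero-phase bandpass + notch filtering and epoch segmentation.

#' Filter specification
#'
#' The two filtering configurations used by the pipeline: offline analysis
#' uses a 2-40 Hz bandpass, the online (streaming) configuration a 3-35 Hz
#' bandpass; both add a 50 Hz notch against power-line interference. The
#' realisation is a 4th-order Butterworth bandpass and a biquad notch
#' (quality factor 30, ~1.7 Hz bandwidth), both applied forward-backward for
#' zero phase.
#'
#' @param mode `"offline"` (2-40 Hz) or `"online"` (3-35 Hz).
#' @param low,high Optional custom passband edges (Hz); defaults follow
#'   `mode`.
#' @param notch Notch centre frequency (Hz), default 50.
#' @param notch_q Notch quality factor, default 30.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(mode = c("offline", "online"), low = NULL, high = NULL,
                        notch = 50, notch_q = 30) {
  mode <- match.arg(mode)
  low <- low %||% if (mode == "offline") 2 else 3
  high <- high %||% if (mode == "offline") 40 else 35
  if (low >= high) stop_config("bandpass low edge must be below the high edge")
  structure(list(mode = mode, low = low, high = high, notch = notch,
                 notch_q = notch_q),
            class = "filter_spec")
}

# Biquad notch coefficients (RBJ cookbook form), normalised so a[1] = 1.
design_notch <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

filter_channel <- function(x, spec, fs) {
  bp <- signal::butter(2, c(spec$low, spec$high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bp, x)
  nf <- design_notch(spec$notch, fs, spec$notch_q)
  signal::filtfilt(nf$b, nf$a, y)
}

#' Apply bandpass and notch filters to a recording
#'
#' Filters every channel with the zero-phase bandpass + notch cascade of a
#' [filter_spec()]. Attenuation at the notch frequency exceeds 30 dB and
#' mid-passband ripple stays below 1 dB.
#'
#' @param rec An `eeg_recording`.
#' @param spec A [filter_spec()] (default offline mode).
#' @return The filtered recording (annotations unchanged).
#' @export
apply_filters <- function(rec, spec = filter_spec("offline")) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * spec$high) {
    stop_config("sampling rate ", rec$fs, " Hz is too low for a ", spec$high,
                " Hz passband edge")
  }
  for (i in seq_len(nrow(rec$samples))) {
    rec$samples[i, ] <- filter_channel(rec$samples[i, ], spec, rec$fs)
  }
  rec
}

#' Segment a recording into labeled epochs
#'
#' Cuts one fixed-length window out of every annotated interval, starting
#' `offset_s` after the interval onset (the default 0.5 s skips the transient
#' onset response). Every annotation yields exactly one epoch; a window that
#' does not fit inside its interval is an error.
#'
#' @param rec An `eeg_recording` with annotations.
#' @param window_s Epoch length in seconds (default 4).
#' @param offset_s Latency after interval onset (default 0.5).
#' @param keep `"all"`, `"stim"` or `"rest"`: which annotations to segment.
#' @return Object of class `ssvep_epochs`: list with `x` (array epochs x
#'   channels x samples), `labels`, `channels`, `fs`.
#' @export
segment_epochs <- function(rec, window_s = 4, offset_s = 0.5,
                           keep = c("all", "stim", "rest")) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- match.arg(keep)
  ann <- rec$annotations
  sel <- switch(keep,
                all = rep(TRUE, nrow(ann)),
                stim = ann$label != "rest",
                rest = ann$label == "rest")
  ann <- ann[sel, , drop = FALSE]
  if (nrow(ann) == 0L) stop_config("no annotations to segment")
  fs <- rec$fs
  n_win <- round(window_s * fs)
  channels <- rownames(rec$samples)
  x <- array(NA_real_, dim = c(nrow(ann), length(channels), n_win),
             dimnames = list(NULL, channels, NULL))
  for (i in seq_len(nrow(ann))) {
    start <- round(ann$onset_s[i] * fs) + round(offset_s * fs) + 1L
    end <- start + n_win - 1L
    int_end <- round((ann$onset_s[i] + ann$duration_s[i]) * fs)
    if (end > int_end || end > ncol(rec$samples)) {
      stop_config("window of ", window_s, " s (+", offset_s,
                  " s offset) overruns annotation ", i, " ('", ann$label[i],
                  "' at ", ann$onset_s[i], " s)")
    }
    x[i, , ] <- rec$samples[, start:end, drop = FALSE]
  }
  structure(list(x = x, labels = ann$label, channels = channels, fs = fs),
            class = "ssvep_epochs")
}

#' @export
print.ssvep_epochs <- function(x, ...) {
  cat(sprintf("%d epochs x %d channel(s) x %d samples @ %g Hz (%d stimulation, %d rest)\n",
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3], x$fs,
              sum(x$labels != "rest"), sum(x$labels == "rest")))
  invisible(x)
}

# Row-bind epoch sets with identical channel layout.
epochs_bind <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  ch <- parts[[1]]$channels
  fs <- parts[[1]]$fs
  for (p in parts) stopifnot(identical(p$channels, ch), p$fs == fs)
  n <- sum(vapply(parts, function(p) dim(p$x)[1], 0L))
  x <- array(NA_real_, dim = c(n, length(ch), dim(parts[[1]]$x)[3]),
             dimnames = list(NULL, ch, NULL))
  labels <- character(n)
  at <- 0L
  for (p in parts) {
    k <- dim(p$x)[1]
    x[at + seq_len(k), , ] <- p$x
    labels[at + seq_len(k)] <- p$labels
    at <- at + k
  }
  structure(list(x = x, labels = labels, channels = ch, fs = fs),
            class = "ssvep_epochs")
}

# Subset epochs by index.
epochs_subset <- function(epochs, idx) {
  structure(list(x = epochs$x[idx, , , drop = FALSE],
                 labels = epochs$labels[idx],
                 channels = epochs$channels, fs = epochs$fs),
            class = "ssvep_epochs")
}
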