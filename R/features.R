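# Spectral estimation and the calibration / thresholding / feature-gating
# computations: Welch PSD, relative PSD, neighbourhood-max baselines BLR/BLS,
# thresholds TR = 1.5*BLR and TS = [0.75, 1.25]*BLS, and the gated SSVEP
# features Sfi.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Welch power spectral density
#'
#' One-sided PSD by Welch's method: the signal is cut into overlapping
#' windowed segments, and squared FFT magnitudes are averaged. Density
#' scaling: for a sinusoid of amplitude A centred on a bin, the integrated
#' peak power is A^2/2. With the defaults used throughout the pipeline
#' (fs = 256 Hz, N = 1024, i.e. a 4 s window) the bin resolution is
#' r = fs/N = 0.25 Hz, and a 4 s epoch gives a single windowed segment.
#'
#' @param x Numeric time series (at least `n` samples).
#' @param fs Sampling rate (Hz).
#' @param n Segment / FFT length in samples (default 1024).
#' @param overlap Fractional segment overlap in `[0, 1)` (default 0.5).
#' @param window `"hann"` (default) or `"rect"`.
#' @return Object of class `ssvep_psd`: list with `freq` (0 .. fs/2), `power`
#'   (one-sided density, unit^2/Hz), `fs`, `n`, `r = fs/n`, `nseg`.
#' @examples
#' x <- sin(2 * pi * 7 * (0:1023) / 256)
#' est <- welch_psd(x, 256)
#' est$freq[which.max(est$power)]  # 7 Hz
#' @export
welch_psd <- function(x, fs = 256, n = 1024, overlap = 0.5,
                      window = c("hann", "rect")) {
  window <- match.arg(window)
  if (length(x) < n) {
    stop_config("epoch of ", length(x), " samples is shorter than the ", n,
                "-sample analysis window")
  }
  if (overlap < 0 || overlap >= 1) stop_config("overlap must be in [0, 1)")
  w <- if (window == "hann") hann_window(n) else rep(1, n)
  u <- sum(w^2)
  step <- max(1L, n - floor(n * overlap))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  half <- n %/% 2
  acc <- numeric(half + 1L)
  for (s in starts) {
    X <- stats::fft(x[s:(s + n - 1L)] * w)
    acc <- acc + Mod(X[seq_len(half + 1L)])^2
  }
  p <- acc / (length(starts) * fs * u)
  if (half >= 2L) p[2:half] <- 2 * p[2:half]
  structure(list(freq = (0:half) * fs / n, power = p, fs = fs, n = n,
                 r = fs / n, nseg = length(starts)),
            class = "ssvep_psd")
}

#' @export
print.ssvep_psd <- function(x, ...) {
  cat(sprintf("Welch PSD: N = %d, r = %g Hz, %d segment(s), 0-%g Hz\n",
              x$n, x$r, x$nseg, max(x$freq)))
  invisible(x)
}

#' @export
plot.ssvep_psd <- function(x, xlim = c(0, 45), ...) {
  sel <- x$freq >= xlim[1] & x$freq <= xlim[2]
  graphics::plot(x$freq[sel], x$power[sel], type = "l",
                 xlab = "Frequency (Hz)", ylab = "PSD", ...)
  invisible(x)
}

# Bin index of frequency f; errors unless f sits on the bin grid.
bin_index <- function(est, f) {
  i <- as.integer(round(f / est$r)) + 1L
  if (any(i < 1L | i > length(est$freq)) ||
      any(abs(est$freq[pmin(pmax(i, 1L), length(est$freq))] - f) > est$r / 100)) {
    stop_config("frequency ", paste(f, collapse = ", "),
                " Hz is not on the ", est$r, " Hz bin grid of the estimate")
  }
  i
}

#' Relative PSD of a frequency family
#'
#' Normalised SSVEP feature: the summed PSD at a family's fundamental and
#' harmonics divided by the total PSD across all nine flicker frequencies of
#' interest. Returns 0 when the denominator is 0.
#'
#' @param est An [welch_psd()] estimate.
#' @param family Fundamental identifying the family (7, 13 or 17), or an
#'   explicit numeric vector of family frequencies.
#' @param flicker_band Frequencies forming the denominator; default all nine
#'   frequencies of interest.
#' @return Scalar in `[0, 1]`.
#' @export
relative_psd <- function(est, family, flicker_band = frequencies_of_interest()) {
  if (length(family) == 1L && family %in% names(foi_families())) {
    family <- foi_families()[[as.character(family)]]
  }
  num <- sum(est$power[bin_index(est, family)])
  den <- sum(est$power[bin_index(est, flicker_band)])
  if (den == 0) return(0)
  num / den
}

# The per-bin value series Eqs. 1-5 operate on: raw PSD, or the whole
# spectrum divided by the summed PSD over the nine frequency-of-interest bins
# ("substitution throughout" for the relative method).
spectrum_values <- function(est, method = c("psd", "relative")) {
  method <- match.arg(method)
  if (method == "psd") return(est$power)
  den <- sum(est$power[bin_index(est, FOI)])
  if (den == 0) return(est$power * 0)
  est$power / den
}

#' Neighbourhood maximum baseline
#'
#' Baseline value at a frequency of interest: the maximum of the PSD at the
#' bin and its two neighbours, `max(P(fi - r), P(fi), P(fi + r))`, absorbing
#' spectral leakage into adjacent bins.
#'
#' @param est An [welch_psd()] estimate (or any object with `freq`, `power`,
#'   `r`).
#' @param fi Frequency of interest (Hz); `fi - r` and `fi + r` must lie within
#'   the estimate.
#' @return Scalar baseline value.
#' @export
neighborhood_max <- function(est, fi) {
  i <- bin_index(est, fi)
  if (i <= 1L || i >= length(est$power)) {
    stop_config("frequency ", fi, " Hz has no neighbouring bins in the estimate")
  }
  max(est$power[(i - 1L):(i + 1L)])
}

# neighbourhood max on a raw value vector laid out on est's bin grid
neighborhood_max_values <- function(values, est, fi) {
  i <- bin_index(est, fi)
  if (i <= 1L || i >= length(values)) {
    stop_config("frequency ", fi, " Hz has no neighbouring bins in the estimate")
  }
  max(values[(i - 1L):(i + 1L)])
}

#' Calibrate per-frequency baselines and thresholds
#'
#' Computes, for every frequency of interest, the resting baseline `BLR`
#' (neighbourhood max of the mean resting spectrum), the stimulated baseline
#' `BLS` (neighbourhood max of the mean spectrum of the calibration
#' stimulation epochs relevant to that frequency), the resting threshold
#' `TR = 1.5 * BLR`, and the stimulated acceptance band
#' `TS_min = 0.75 * BLS`, `TS_max = 1.25 * BLS`. An SSVEP response is deemed
#' detectable at fi when `BLS > TR`.
#'
#' When `labels` are supplied, the epochs relevant to fi are those whose
#' attended stimulus structurally elicits fi (its components and their 2nd/3rd
#' harmonics, see [stimulus_frequencies()]); otherwise all stimulation epochs
#' are pooled.
#'
#' @param rest_epochs,stim_epochs Numeric matrices, one epoch per row
#'   (single channel); at least one row each.
#' @param labels Optional attended-stimulus symbol per stimulation epoch.
#' @param method `"psd"` or `"relative"` — whether Eqs. 1-5 operate on raw or
#'   relative (frequency-of-interest normalised) spectra.
#' @param fs,n,overlap Welch parameters, see [welch_psd()].
#' @param tr_coef Resting threshold coefficient (default 1.5).
#' @param ts_range Stimulated band coefficients (default `c(0.75, 1.25)`).
#' @return Object of class `ssvep_calibration`: data frame with columns `fi`,
#'   `BLR`, `BLS`, `TR`, `TS_min`, `TS_max`, `response_present`, and
#'   attributes `method`, `fs`, `n`, `overlap`.
#' @export
calibrate <- function(rest_epochs, stim_epochs, labels = NULL,
                      method = c("psd", "relative"), fs = 256, n = 1024,
                      overlap = 0.5, tr_coef = 1.5, ts_range = c(0.75, 1.25)) {
  method <- match.arg(method)
  rest_epochs <- as.matrix(rest_epochs)
  stim_epochs <- as.matrix(stim_epochs)
  if (nrow(rest_epochs) == 0L || nrow(stim_epochs) == 0L) {
    stop_config("calibration needs at least one resting and one stimulation epoch")
  }
  if (!is.null(labels) && length(labels) != nrow(stim_epochs)) {
    stop_config("labels must match the number of stimulation epochs")
  }
  est0 <- welch_psd(rest_epochs[1, ], fs = fs, n = n, overlap = overlap)
  epoch_values <- function(m) {
    t(apply(m, 1, function(x) {
      spectrum_values(welch_psd(x, fs = fs, n = n, overlap = overlap), method)
    }))
  }
  rest_v <- epoch_values(rest_epochs)
  stim_v <- epoch_values(stim_epochs)
  rest_mean <- colMeans(rest_v)
  stim_mean_all <- colMeans(stim_v)
  blr <- bls <- numeric(length(FOI))
  for (j in seq_along(FOI)) {
    blr[j] <- neighborhood_max_values(rest_mean, est0, FOI[j])
    mean_v <- stim_mean_all
    if (!is.null(labels)) {
      rel <- vapply(labels, function(s) FOI[j] %in% stimulus_frequencies(s),
                    logical(1))
      if (any(rel)) mean_v <- colMeans(stim_v[rel, , drop = FALSE])
    }
    bls[j] <- neighborhood_max_values(mean_v, est0, FOI[j])
  }
  out <- data.frame(fi = FOI, BLR = blr, BLS = bls,
                    TR = tr_coef * blr,
                    TS_min = ts_range[1] * bls,
                    TS_max = ts_range[2] * bls)
  out$response_present <- out$BLS > out$TR
  structure(out, method = method, fs = fs, n = n, overlap = overlap,
            tr_coef = tr_coef, ts_range = ts_range,
            class = c("ssvep_calibration", "data.frame"))
}

#' Extract gated SSVEP features
#'
#' Applies the calibrated decision rule at every frequency of interest:
#' `Sfi = P(fi) - TR(i)` when `P(fi)` exceeds the resting threshold *and*
#' falls inside the stimulated acceptance band `[TS_min, TS_max]`; otherwise
#' `Sfi = 0`. With `eq5_mode = "min_only"` the upper band edge is ignored.
#'
#' @param est An [welch_psd()] estimate of one epoch.
#' @param calib An [calibrate()] result (carries the psd/relative method).
#' @param eq5_mode `"band"` (default) or `"min_only"`.
#' @param channel Optional channel label stored on the result.
#' @return Object of class `ssvep_features`: named numeric vector of the nine
#'   `Sfi` values (names = frequencies), with attributes `channel` and
#'   `response_present` (TRUE iff any `Sfi > 0`).
#' @export
extract_features <- function(est, calib, eq5_mode = c("band", "min_only"),
                             channel = NA_character_) {
  eq5_mode <- match.arg(eq5_mode)
  stopifnot(inherits(calib, "ssvep_calibration"))
  v <- spectrum_values(est, attr(calib, "method"))
  p <- v[bin_index(est, calib$fi)]
  accept <- p > calib$TR & p >= calib$TS_min
  if (eq5_mode == "band") accept <- accept & p <= calib$TS_max
  s <- ifelse(accept, p - calib$TR, 0)
  structure(stats::setNames(s, as.character(calib$fi)),
            channel = channel, response_present = any(s > 0),
            class = "ssvep_features")
}

#' Feature matrix over an epoch set
#'
#' Welch PSD + gated feature extraction for every epoch and channel,
#' organised as a trials x channels x frequencies array (e.g. 288 x 2 x 9 for
#' the full four-checkerboard protocol).
#'
#' @param epochs An `ssvep_epochs` object with both occipital channels.
#' @param detector An [ssvep_detector()] fit (supplies per-channel
#'   calibration and Welch settings).
#' @return Numeric array `(n_trials, n_channels, 9)` with dimnames and a
#'   `labels` attribute aligned to trial order.
#' @export
build_feature_matrix <- function(epochs, detector) {
  stopifnot(inherits(epochs, "ssvep_epochs"), inherits(detector, "ssvep_detector"))
  if (length(epochs$channels) < 2L) {
    stop_config("feature matrix needs both occipital channels; got ",
                paste(epochs$channels, collapse = ", "))
  }
  missing <- setdiff(epochs$channels, names(detector$calibration))
  if (length(missing)) {
    stop_config("detector has no calibration for channel(s): ",
                paste(missing, collapse = ", "))
  }
  n_ep <- dim(epochs$x)[1]
  out <- array(NA_real_,
               dim = c(n_ep, length(epochs$channels), length(FOI)),
               dimnames = list(NULL, epochs$channels, as.character(FOI)))
  for (i in seq_len(n_ep)) {
    for (ch in epochs$channels) {
      est <- welch_psd(epochs$x[i, ch, ], fs = epochs$fs, n = detector$n,
                       overlap = detector$overlap)
      out[i, ch, ] <- extract_features(est, detector$calibration[[ch]],
                                       eq5_mode = detector$eq5_mode,
                                       channel = ch)
    }
  }
  attr(out, "labels") <- epochs$labels
  out
}
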