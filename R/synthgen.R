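# Synthetic EEG generator: occipital recordings with narrowband SSVEP
# responses at the attended stimulus frequencies and their harmonics,
# superimposed on a 1/f background, an alpha rhythm and 50 Hz line noise,
# following the rest/stimulation trial protocol the detector assumes.

#' Synthetic SSVEP response profile
#'
#' Parametrises the statistical structure of simulated occipital EEG. Each
#' explicit component of an attended stimulus evokes a sinusoid of the given
#' amplitude (per channel); its 2nd and 3rd harmonics inside the
#' frequencies-of-interest set are evoked with geometric roll-off. Rest
#' epochs contain only background (1/f noise, alpha, line noise).
#'
#' @param amplitude Response amplitude at explicit component frequencies, in
#'   microvolt (default 2).
#' @param channel_gain Named per-channel multipliers applied to `amplitude`;
#'   the default `c(O1 = 1, O2 = 0.8)` gives a left-lateralised response so
#'   channel selection has something to find.
#' @param harmonic_rolloff Amplitude factor per harmonic order above 1
#'   (default 0.5: the 2nd harmonic has half, the 3rd a quarter of the
#'   component amplitude).
#' @param background One-sided background PSD `scale / f^exponent` (microvolt
#'   squared per Hz), flat below `f_min`. Default scale 1, exponent 1,
#'   f_min 1 Hz.
#' @param alpha Alpha rhythm: centre frequency (Hz) and amplitude (microvolt).
#' @param line Power-line component: frequency (Hz) and amplitude (microvolt).
#' @param trial_jitter Coefficient of variation of the lognormal per-trial,
#'   per-component amplitude jitter (default 0.2).
#' @param scale_jitter Coefficient of variation of a whole-epoch multiplicative
#'   gain (default 0; exercise it to see why relative PSD normalisation
#'   helps).
#' @param fs Sampling rate in Hz (default 256).
#' @return Object of class `ssvep_profile`.
#' @seealso [simulate_epoch()], [simulate_session()], [noise_floor_amplitude()]
#' @export
ssvep_profile <- function(amplitude = 2, channel_gain = c(O1 = 1, O2 = 0.8),
                          harmonic_rolloff = 0.5,
                          background = list(scale = 1, exponent = 1, f_min = 1),
                          alpha = list(freq = 10, amplitude = 1.5),
                          line = list(freq = 50, amplitude = 2),
                          trial_jitter = 0.2, scale_jitter = 0, fs = 256) {
  stopifnot(amplitude >= 0, harmonic_rolloff >= 0, trial_jitter >= 0,
            scale_jitter >= 0, fs > 2 * max(FOI))
  if (is.null(names(channel_gain)) || any(channel_gain < 0)) {
    stop_config("channel_gain must be a named vector of non-negative gains")
  }
  component_freqs <- sort(unique(unlist(
    lapply(flicker_table()$symbol, flicker_components))))
  gain <- lapply(channel_gain, function(g) {
    stats::setNames(rep(amplitude * g, length(component_freqs)),
                    as.character(component_freqs))
  })
  structure(list(gain = gain, harmonic_rolloff = harmonic_rolloff,
                 background = background, alpha = alpha, line = line,
                 trial_jitter = trial_jitter, scale_jitter = scale_jitter,
                 fs = fs),
            class = "ssvep_profile")
}

#' @export
print.ssvep_profile <- function(x, ...) {
  cat("Synthetic SSVEP response profile\n")
  cat("  channels:", paste(names(x$gain), collapse = ", "),
      sprintf("(amplitudes %s uV at explicit components)",
              paste(vapply(x$gain, max, 0), collapse = "/")), "\n")
  cat(sprintf("  background: %.3g/f^%.2g uV^2/Hz; alpha %.3g uV @ %g Hz; line %.3g uV @ %g Hz\n",
              x$background$scale, x$background$exponent, x$alpha$amplitude,
              x$alpha$freq, x$line$amplitude, x$line$freq))
  cat(sprintf("  trial jitter CV %.2g, scale jitter CV %.2g, fs %g Hz\n",
              x$trial_jitter, x$scale_jitter, x$fs))
  invisible(x)
}

#' Background noise-floor amplitude at a frequency
#'
#' The amplitude of a bin-centred sinusoid whose spectral peak matches the
#' expected background PSD level in one analysis bin,
#' `sqrt(2 * r * P_background(f))` with `r = fs / n`. "Gain k times the noise
#' floor" in the simulation experiments means a response amplitude of
#' `k * noise_floor_amplitude(profile, f)`.
#'
#' @param profile An [ssvep_profile()].
#' @param f Frequencies (Hz).
#' @param n Analysis window length in samples (default 1024).
#' @return Amplitudes in microvolt.
#' @export
noise_floor_amplitude <- function(profile, f = frequencies_of_interest(),
                                  n = 1024) {
  bg <- profile$background
  p <- bg$scale / pmax(f, bg$f_min)^bg$exponent
  sqrt(2 * (profile$fs / n) * p)
}

#' Set response gains relative to the noise floor
#'
#' Returns a copy of `profile` whose explicit-component amplitudes are
#' `snr * noise_floor_amplitude(profile, f)` per component frequency and
#' channel (channel gain ratios preserved).
#'
#' @inheritParams noise_floor_amplitude
#' @param snr Amplitude ratio to the per-frequency noise floor.
#' @return Modified `ssvep_profile`.
#' @export
profile_with_snr <- function(profile, snr, n = 1024) {
  base <- profile$gain[[1]]
  rel <- vapply(profile$gain, function(g) {
    if (max(base) == 0) 1 else max(g) / max(base)
  }, 0)
  freqs <- as.numeric(names(base))
  floor_amp <- noise_floor_amplitude(profile, freqs, n = n)
  profile$gain <- lapply(rel, function(r) {
    stats::setNames(snr * r * floor_amp, names(base))
  })
  profile
}

# Expected evoked amplitude (uV) at every frequency of interest for an
# attended stimulus on one channel: explicit components at their profile gain,
# 2nd/3rd harmonics with roll-off, overlapping contributions combined by max.
amplitude_map <- function(profile, stimulus, channel) {
  g <- profile$gain[[channel]]
  if (is.null(g)) stop_config("profile has no channel ", channel)
  amp <- stats::setNames(numeric(length(FOI)), as.character(FOI))
  for (fc in flicker_components(stimulus)) {
    contrib <- c(fc = g[[as.character(fc)]])
    names(contrib) <- as.character(fc)
    for (k in 2:3) {
      fh <- fc * k
      if (fh %in% FOI) {
        contrib[as.character(fh)] <- g[[as.character(fc)]] *
          profile$harmonic_rolloff^(k - 1)
      }
    }
    keep <- names(contrib)
    amp[keep] <- pmax(amp[keep], contrib)
  }
  amp
}

# 1/f^beta gaussian background synthesised in the frequency domain so that the
# expected one-sided periodogram equals the profile's background PSD exactly.
background_noise <- function(n, fs, scale, exponent, f_min) {
  if (n < 2L) return(numeric(n))
  half <- n %/% 2
  f <- (1:half) * fs / n
  p <- scale / pmax(f, f_min)^exponent
  amp <- sqrt(p * fs * n / 4)
  X <- complex(real = stats::rnorm(half) * amp,
               imaginary = stats::rnorm(half) * amp)
  if (n %% 2 == 0) X[half] <- complex(real = stats::rnorm(1) * sqrt(p[half] * fs * n / 2))
  spec <- complex(real = numeric(n))
  k <- seq_len(half)
  spec[k + 1L] <- X
  mirror <- n - k + 1L
  keep <- mirror != k + 1L
  spec[mirror[keep]] <- Conj(X[keep])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Simulate one single-channel EEG epoch
#'
#' Generates an epoch of synthetic occipital EEG: a sum of sinusoids at the
#' attended stimulus's evoked frequencies (random phases, lognormal amplitude
#' jitter) plus 1/f background noise, an alpha rhythm and line noise. With
#' `attended = "rest"` only the background is generated.
#'
#' @param profile An [ssvep_profile()].
#' @param attended `"rest"`, a flicker symbol (e.g. `"MFH1"`), or a one-row
#'   flicker-table slice.
#' @param duration_s Epoch length in seconds (> 0).
#' @param channel Channel name present in the profile (default `"O1"`).
#' @param seed Optional integer seed; identical seeds reproduce identical
#'   epochs without disturbing the caller's RNG stream. `NULL` draws from the
#'   current stream.
#' @return Numeric vector of `round(duration_s * fs)` samples (microvolt).
#' @examples
#' e <- simulate_epoch(ssvep_profile(), "SFF1", 4, seed = 1)
#' @export
simulate_epoch <- function(profile, attended = "rest", duration_s = 5,
                           channel = "O1", seed = NULL) {
  stopifnot(inherits(profile, "ssvep_profile"), duration_s > 0)
  with_seed(seed, {
    fs <- profile$fs
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    bg <- profile$background
    x <- background_noise(n, fs, bg$scale, bg$exponent, bg$f_min)
    if (profile$alpha$amplitude > 0) {
      x <- x + profile$alpha$amplitude * rlnorm_cv(1, profile$trial_jitter) *
        sin(2 * pi * profile$alpha$freq * t + stats::runif(1, 0, 2 * pi))
    }
    if (profile$line$amplitude > 0) {
      x <- x + profile$line$amplitude *
        sin(2 * pi * profile$line$freq * t + stats::runif(1, 0, 2 * pi))
    }
    is_rest <- is.character(attended) && length(attended) == 1L &&
      attended == "rest"
    if (!is_rest) {
      amp <- amplitude_map(profile, attended, channel)
      active <- which(amp > 0)
      for (i in active) {
        f <- FOI[i]
        a <- amp[i] * rlnorm_cv(1, profile$trial_jitter)
        x <- x + a * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      }
    }
    if (profile$scale_jitter > 0) x <- x * rlnorm_cv(1, profile$scale_jitter)
    x
  })
}

#' Trial protocol
#'
#' Timing of a recording session: alternating rest and stimulation intervals,
#' by default 5 s rest + 5 s stimulation, 36 trials per session (four trials
#' for each of the nine stimuli), giving a 6 min session at 256 Hz.
#'
#' @param rest_s,stim_s Rest / stimulation interval lengths (s).
#' @param trials_per_flicker Trials per stimulus per session (default 4).
#' @param fs Sampling rate (Hz).
#' @return Object of class `trial_protocol` with fields `rest_s`, `stim_s`,
#'   `trials_per_flicker`, `trials_per_session`, `fs`.
#' @export
trial_protocol <- function(rest_s = 5, stim_s = 5, trials_per_flicker = 4,
                           fs = 256) {
  stopifnot(rest_s > 0, stim_s > 0, trials_per_flicker >= 1, fs > 2 * max(FOI))
  structure(list(rest_s = rest_s, stim_s = stim_s,
                 trials_per_flicker = as.integer(trials_per_flicker),
                 trials_per_session = 9L * as.integer(trials_per_flicker),
                 fs = fs),
            class = "trial_protocol")
}

#' Simulate a recording session
#'
#' Produces a multichannel recording that alternates rest and stimulation
#' epochs according to the protocol, with annotations marking every interval.
#' The default flicker sequence cycles through the nine canonical stimuli in
#' presentation order, `trials_per_flicker` times.
#'
#' @param profile An [ssvep_profile()].
#' @param protocol A [trial_protocol()].
#' @param flicker_sequence Character vector of stimulus symbols, one per
#'   trial; must cover all nine canonical stimuli when using the default
#'   protocol length.
#' @param seed Optional integer seed (see [simulate_epoch()]).
#' @return Object of class `eeg_recording`: list with `samples` (channels x
#'   time matrix, microvolt, rownames = channel labels), `fs`, and
#'   `annotations` (data frame `onset_s`, `duration_s`, `label`; label is
#'   `"rest"` or the attended symbol).
#' @examples
#' rec <- simulate_session(ssvep_profile(), seed = 1)
#' nrow(rec$annotations)  # 72 = 36 rest + 36 stimulation
#' @export
simulate_session <- function(profile, protocol = trial_protocol(),
                             flicker_sequence = NULL, seed = NULL) {
  stopifnot(inherits(profile, "ssvep_profile"),
            inherits(protocol, "trial_protocol"))
  if (is.null(flicker_sequence)) {
    flicker_sequence <- rep(flicker_table()$symbol, protocol$trials_per_flicker)
  }
  if (!all(flicker_sequence %in% flicker_table()$symbol)) {
    stop_config("flicker_sequence contains unknown symbols")
  }
  fs <- protocol$fs
  channels <- names(profile$gain)
  with_seed(seed, {
    n_rest <- round(protocol$rest_s * fs)
    n_stim <- round(protocol$stim_s * fs)
    n_trial <- n_rest + n_stim
    n_total <- n_trial * length(flicker_sequence)
    samples <- matrix(0, nrow = length(channels), ncol = n_total,
                      dimnames = list(channels, NULL))
    ann <- vector("list", 2L * length(flicker_sequence))
    for (i in seq_along(flicker_sequence)) {
      off <- (i - 1L) * n_trial
      for (ch in channels) {
        samples[ch, off + seq_len(n_rest)] <-
          simulate_epoch(profile, "rest", protocol$rest_s, channel = ch)
        samples[ch, off + n_rest + seq_len(n_stim)] <-
          simulate_epoch(profile, flicker_sequence[i], protocol$stim_s,
                         channel = ch)
      }
      ann[[2L * i - 1L]] <- data.frame(onset_s = off / fs,
                                       duration_s = protocol$rest_s,
                                       label = "rest",
                                       stringsAsFactors = FALSE)
      ann[[2L * i]] <- data.frame(onset_s = (off + n_rest) / fs,
                                  duration_s = protocol$stim_s,
                                  label = flicker_sequence[i],
                                  stringsAsFactors = FALSE)
    }
    structure(list(samples = samples, fs = fs,
                   annotations = do.call(rbind, ann)),
              class = "eeg_recording")
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channel(s) [%s], %.1f s @ %g Hz, %d annotations\n",
              nrow(x$samples), paste(rownames(x$samples), collapse = ", "),
              ncol(x$samples) / x$fs, x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Write / read a recording (CSV dialect)
#'
#' Serialises a recording as a long-format CSV (`sample`, `channel`, `value`)
#' with a JSON sidecar (`<path>.events.json`) holding the sampling rate,
#' channel order and annotations. Sample values are written with 17
#' significant digits so the round trip is bit-exact.
#'
#' @param rec An `eeg_recording`.
#' @param path CSV file path.
#' @param events_path JSON sidecar path; default `<path>.events.json`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the reconstructed `eeg_recording`.
#' @export
write_recording <- function(rec, path, events_path = paste0(path, ".events.json")) {
  stopifnot(inherits(rec, "eeg_recording"))
  channels <- rownames(rec$samples)
  n <- ncol(rec$samples)
  df <- data.frame(
    sample = rep(seq_len(n), times = length(channels)),
    channel = rep(channels, each = n),
    value = sprintf("%.17g", as.vector(t(rec$samples))),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channels = channels, n_samples = n,
         annotations = rec$annotations),
    events_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, events_path = paste0(path, ".events.json")) {
  if (!file.exists(path)) stop_config("no such recording file: ", path)
  if (!file.exists(events_path)) stop_config("missing events sidecar: ", events_path)
  meta <- jsonlite::read_json(events_path, simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", "character", "numeric"))
  if (!identical(names(df), c("sample", "channel", "value"))) {
    stop_config("parse error in ", path, ": expected columns sample,channel,value")
  }
  n <- meta$n_samples
  channels <- meta$channels
  if (nrow(df) != n * length(channels)) {
    stop_config("parse error in ", path, ": expected ", n * length(channels),
                " rows, found ", nrow(df), " (file truncated?)")
  }
  samples <- matrix(NA_real_, nrow = length(channels), ncol = n,
                    dimnames = list(channels, NULL))
  for (ch in channels) {
    rows <- df[df$channel == ch, , drop = FALSE]
    if (nrow(rows) != n || !identical(rows$sample, seq_len(n))) {
      stop_config("parse error in ", path, ": channel ", ch,
                  " has missing or out-of-order samples")
    }
    samples[ch, ] <- rows$value
  }
  ann <- as.data.frame(meta$annotations, stringsAsFactors = FALSE)
  if (nrow(ann) > 0 &&
      any(ann$onset_s < 0 | (ann$onset_s + ann$duration_s) * meta$fs > n + 0.5)) {
    stop_config("parse error in ", events_path,
                ": annotation outside recording bounds")
  }
  structure(list(samples = samples, fs = meta$fs, annotations = ann),
            class = "eeg_recording")
}
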