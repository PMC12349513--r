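# Shared fixtures for the test suite: quiet profiles, hand-built epoch sets
# and spectra.

# A profile with no stochastic nuisance components: pure tones on a weak 1/f
# background (or none at all when `background_scale = 0`).
quiet_profile <- function(amplitude = 2, background_scale = 0,
                          trial_jitter = 0, ...) {
  ssvep_profile(amplitude = amplitude,
                background = list(scale = background_scale, exponent = 1,
                                  f_min = 1),
                alpha = list(freq = 10, amplitude = 0),
                line = list(freq = 50, amplitude = 0),
                trial_jitter = trial_jitter, ...)
}

# Deterministic sinusoid epoch at fs = 256 Hz.
tone <- function(freq, amplitude = 1, duration_s = 4, fs = 256, phase = 0) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  amplitude * sin(2 * pi * freq * t + phase)
}

# Minimal ssvep_epochs object from per-channel lists of epoch matrices.
make_epochs <- function(channel_list, labels, fs = 256) {
  channels <- names(channel_list)
  n_ep <- nrow(channel_list[[1]])
  x <- array(NA_real_, dim = c(n_ep, length(channels),
                               ncol(channel_list[[1]])),
             dimnames = list(NULL, channels, NULL))
  for (ch in channels) x[, ch, ] <- channel_list[[ch]]
  structure(list(x = x, labels = labels, channels = channels, fs = fs),
            class = "ssvep_epochs")
}

# Evaluate code under a temporary seed without disturbing the suite's RNG.
with_seed_local <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Independent averaged-periodogram reference for welch_psd (straight loop,
# no shared code path beyond stats::fft).
reference_welch <- function(x, fs, n, overlap = 0.5) {
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  step <- n - floor(n * overlap)
  starts <- seq(1, length(x) - n + 1, by = step)
  half <- n %/% 2
  p <- numeric(half + 1)
  for (s in starts) {
    seg <- x[s:(s + n - 1)] * w
    X <- stats::fft(seg)
    p <- p + (Mod(X[1:(half + 1)])^2) / (fs * sum(w^2))
  }
  p <- p / length(starts)
  p[2:half] <- 2 * p[2:half]
  p
}
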