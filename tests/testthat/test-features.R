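# Hand-built spectral estimate with prescribed power at chosen frequencies.
fake_est <- function(power_at = c(), fs = 256, n = 1024) {
  freq <- (0:(n %/% 2)) * fs / n
  power <- numeric(length(freq))
  for (f in names(power_at)) {
    power[round(as.numeric(f) / (fs / n)) + 1] <- power_at[[f]]
  }
  structure(list(freq = freq, power = power, fs = fs, n = n, r = fs / n,
                 nseg = 1L),
            class = "ssvep_psd")
}

# Calibration table with prescribed thresholds (method attribute "psd").
fake_calib <- function(TR, TS_min, TS_max) {
  foi <- frequencies_of_interest()
  out <- data.frame(fi = foi, BLR = TR / 1.5, BLS = TS_min / 0.75,
                    TR = TR, TS_min = TS_min, TS_max = TS_max)
  out$response_present <- out$BLS > out$TR
  structure(out, method = "psd", fs = 256, n = 1024,
            class = c("ssvep_calibration", "data.frame"))
}

test_that("welch_psd recovers pure tones with the documented scaling", {
  x <- tone(7, 1, 4)
  est <- welch_psd(x, 256)
  expect_equal(est$r, 0.25)
  expect_equal(est$freq[which.max(est$power)], 7)
  i <- which(est$freq == 7)
  integrated <- sum(est$power[(i - 1):(i + 1)]) * est$r
  expect_equal(integrated, 0.5, tolerance = 0.05)  # A^2/2

  expect_true(all(welch_psd(numeric(1024), 256)$power == 0))
  expect_error(welch_psd(tone(7, 1, 2), 256), "shorter")
})

test_that("white-noise PSD integrates to the signal variance (Parseval)", {
  tot <- vapply(1:50, function(s) {
    x <- with_seed_local(s, stats::rnorm(2048))
    est <- welch_psd(x, 256, n = 1024)
    sum(est$power) * est$r
  }, 0)
  expect_equal(mean(tot), 1, tolerance = 0.1)
})

test_that("welch_psd equals an independent averaged-periodogram reference", {
  for (s in 1:3) {
    x <- with_seed_local(100 + s, stats::rnorm(2048)) + tone(13, 2, 8)
    est <- welch_psd(x, 256, n = 1024, overlap = 0.5)
    ref <- reference_welch(x, 256, 1024, 0.5)
    expect_lt(max(abs(est$power - ref)) / max(ref), 1e-10)
  }
  # also on a shorter non-overlapping configuration
  x <- with_seed_local(7, stats::rnorm(1536))
  est <- welch_psd(x, 256, n = 512, overlap = 0)
  ref <- reference_welch(x, 256, 512, 0)
  expect_lt(max(abs(est$power - ref)) / max(ref), 1e-10)
})

test_that("relative PSD is the family share of the flicker-band power", {
  est <- fake_est(c("7" = 4, "14" = 2))
  expect_equal(relative_psd(est, 7), 1)
  est_u <- fake_est(stats::setNames(rep(1, 9),
                                    as.character(frequencies_of_interest())))
  expect_equal(relative_psd(est_u, 7), 3 / 9)
  expect_equal(relative_psd(fake_est(), 7), 0)  # zero denominator

  # hand-summed oracle on a synthetic MFH1 epoch
  x <- simulate_epoch(ssvep_profile(), "MFH1", 4, seed = 3)
  est <- welch_psd(x, 256)
  bins <- function(f) est$power[round(f / 0.25) + 1]
  oracle <- sum(bins(c(7, 14, 21))) / sum(bins(frequencies_of_interest()))
  expect_equal(relative_psd(est, 7), oracle)

  # the three family shares on a common denominator sum to <= 1
  shares <- vapply(c(7, 13, 17), function(f) relative_psd(est, f), 0)
  expect_true(all(shares >= 0 & shares <= 1))
  expect_equal(sum(shares), 1)  # the nine bins partition into the families
})

test_that("neighbourhood max takes the largest of the three adjacent bins", {
  est <- fake_est(c("6.75" = 1, "7" = 2, "7.25" = 3))
  expect_equal(neighborhood_max(est, 7), 3)
  est_t <- fake_est(c("6.75" = 2, "7" = 2, "7.25" = 2))
  expect_equal(neighborhood_max(est_t, 7), 2)
  expect_error(neighborhood_max(est, 0), "neighbouring")
  expect_error(neighborhood_max(est, 7.1), "bin grid")
})

test_that("calibration applies the threshold coefficients of Eqs. 2-4", {
  rest <- rbind(tone(7, 1, 4), tone(7, 1, 4, phase = 1))
  stim <- rbind(tone(7, 2, 4), tone(13, 2, 4))
  cal <- calibrate(rest, stim, labels = c("SFF1", "SFF2"))
  expect_equal(cal$TR, 1.5 * cal$BLR)
  expect_equal(cal$TS_min, 0.75 * cal$BLS)
  expect_equal(cal$TS_max, 1.25 * cal$BLS)
  expect_true(all(cal$BLR >= 0 & cal$BLS >= 0))
  # label-aware: BLS(7) comes from the SFF1 epoch only, BLS(13) from SFF2
  est1 <- welch_psd(stim[1, ], 256)
  expect_equal(cal$BLS[cal$fi == 7], neighborhood_max(est1, 7))

  # identical rest and stimulation epochs: no response anywhere
  same <- calibrate(rest, rest, labels = c("SFF1", "SFF1"))
  expect_true(all(!same$response_present))  # BLS = BLR < TR = 1.5 BLR
  expect_error(calibrate(rest[0, , drop = FALSE], stim), "at least one")
})

test_that("the Eq. 5 gate passes only in-band supra-threshold power", {
  cal <- fake_calib(TR = rep(3, 9), TS_min = rep(3, 9), TS_max = rep(5, 9))
  s <- extract_features(fake_est(c("7" = 4.5)), cal)
  expect_equal(unname(s["7"]), 1.5)        # P - TR inside the band
  expect_true(attr(s, "response_present"))
  s_hi <- extract_features(fake_est(c("7" = 6)), cal)
  expect_equal(unname(s_hi["7"]), 0)       # above TS_max
  s_lo <- extract_features(fake_est(c("7" = 2.5)), cal)
  expect_equal(unname(s_lo["7"]), 0)       # below TR
  expect_false(attr(s_lo, "response_present"))
  # min_only variant ignores the upper edge
  s_min <- extract_features(fake_est(c("7" = 6)), cal, eq5_mode = "min_only")
  expect_equal(unname(s_min["7"]), 3)

  # Sfi >= 0 and non-decreasing in P within the accepted band
  ps <- seq(3.05, 4.95, by = 0.1)
  vals <- vapply(ps, function(p) {
    unname(extract_features(fake_est(c("13" = p)), cal)["13"])
  }, 0)
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) > 0))
})

test_that("calibration and features are homogeneous under input gain", {
  set.seed(42)
  rest <- matrix(stats::rnorm(2 * 1024, sd = 0.5), nrow = 2)
  stim <- rbind(tone(7, 2, 4) + stats::rnorm(1024, sd = 0.5),
                tone(13, 2, 4) + stats::rnorm(1024, sd = 0.5))
  labs <- c("SFF1", "SFF2")
  c1 <- calibrate(rest, stim, labs)
  for (cc in c(0.3, 2, 10)) {
    c2 <- calibrate(cc * rest, cc * stim, labs)
    # PSD-domain quantities scale with the squared time-domain gain
    for (col in c("BLR", "BLS", "TR", "TS_min", "TS_max")) {
      expect_equal(c2[[col]], cc^2 * c1[[col]], tolerance = 1e-12)
    }
    est <- welch_psd(stim[1, ], 256)
    est_c <- welch_psd(cc * stim[1, ], 256)
    s1 <- as.numeric(extract_features(est, c1))
    s2 <- as.numeric(extract_features(est_c, c2))
    expect_equal(s2, cc^2 * s1, tolerance = 1e-12)
  }
  # the relative method is exactly scale-invariant
  r1 <- calibrate(rest, stim, labs, method = "relative")
  r2 <- calibrate(3 * rest, 3 * stim, labs, method = "relative")
  expect_equal(r2$BLS, r1$BLS, tolerance = 1e-12)
  expect_equal(r2$TR, r1$TR, tolerance = 1e-12)
})

test_that("feature matrices have trials x channels x frequencies layout", {
  p <- ssvep_profile()
  rec <- simulate_session(p, trial_protocol(trials_per_flicker = 1), seed = 8)
  ep <- segment_epochs(rec, 4, 0.5)
  fit <- ssvep_detector(ep)
  fm <- build_feature_matrix(ep, fit)
  expect_equal(dim(fm), c(18L, 2L, 9L))
  expect_equal(dimnames(fm)[[2]], c("O1", "O2"))
  expect_equal(attr(fm, "labels"), ep$labels)
  expect_true(all(fm >= 0))

  single <- make_epochs(list(O1 = matrix(ep$x[, 1, ], nrow = 18)), ep$labels)
  expect_error(build_feature_matrix(single, fit), "both occipital")
})
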