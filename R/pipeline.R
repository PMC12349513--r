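# End-to-end simulation experiments: offline multi-session analysis, the
# six-command recovery experiment, idle soundness, parameter recovery and
# the SNR-accuracy curve. These are the workhorses of the acceptance checks
# and of the worked examples.

#' Offline simulation run: simulate, filter, segment, calibrate, classify
#'
#' Simulates `sessions` recording sessions from a response profile, applies
#' the offline filter chain, cuts 4 s analysis epochs, fits an
#' [ssvep_detector()] (first trial of each stimulus + all rest epochs), and
#' classifies the remaining stimulation epochs with the label-appropriate
#' decision rule.
#'
#' @param profile An [ssvep_profile()].
#' @param sessions Number of sessions (default 3).
#' @param protocol A [trial_protocol()].
#' @param method Detector method, `"psd"` or `"relative"`.
#' @param seed Integer seed for the whole run.
#' @param window_s,offset_s Epoch window, see [segment_epochs()].
#' @param calibration_trials See [ssvep_detector()].
#' @param filter Apply the offline filter chain first (default TRUE).
#' @return Object of class `ssvep_offline_run`: list with `accuracy`
#'   (percent, over evaluation stimulation epochs), `by_condition` (named
#'   vector over SFF/MFH/MFF), `decisions` (prediction data frame),
#'   `detector`, `features` (trials x channels x frequencies array), and
#'   `n_eval`.
#' @export
run_offline_analysis <- function(profile = ssvep_profile(), sessions = 3,
                                 protocol = trial_protocol(),
                                 method = c("psd", "relative"), seed = NULL,
                                 window_s = 4, offset_s = 0.5,
                                 calibration_trials = 1, filter = TRUE) {
  method <- match.arg(method)
  with_seed(seed, {
    eps <- lapply(seq_len(sessions), function(s) {
      rec <- simulate_session(profile, protocol)
      if (filter) rec <- apply_filters(rec, filter_spec("offline"))
      segment_epochs(rec, window_s = window_s, offset_s = offset_s)
    })
    epochs <- do.call(epochs_bind, eps)
    fit <- ssvep_detector(epochs, method = method,
                          calibration_trials = calibration_trials)
    eval_idx <- setdiff(which(epochs$labels != "rest"), fit$calibration_index)
    eval_epochs <- epochs_subset(epochs, eval_idx)
    dec <- predict(fit, eval_epochs, mode = "auto")
    cond <- flicker_table()$condition[match(dec$label, flicker_table()$symbol)]
    by_cond <- vapply(split(dec$correct, cond), function(z) 100 * mean(z), 0)
    structure(list(accuracy = accuracy(dec$command, dec$truth),
                   by_condition = by_cond, decisions = dec, detector = fit,
                   features = build_feature_matrix(eval_epochs, fit),
                   n_eval = nrow(dec)),
              class = "ssvep_offline_run")
  })
}

#' @export
print.ssvep_offline_run <- function(x, ...) {
  cat(sprintf("Offline simulation run: %.1f%% accuracy over %d evaluation trials\n",
              x$accuracy, x$n_eval))
  cat("  by condition:",
      paste(sprintf("%s %.1f%%", names(x$by_condition), x$by_condition),
            collapse = ", "), "\n")
  invisible(x)
}

#' Six-command recovery experiment
#'
#' Simulates `trials_per_command` epochs attending each of the six command
#' stimuli of an assignment (MFH1-3 for commands 1-3, MFF1-3 for 4-6 by
#' default), calibrates on one extra trial per stimulus plus matched rest
#' epochs, and reports the command classification accuracy.
#'
#' @param profile An [ssvep_profile()].
#' @param trials_per_command Test trials per command (default 50).
#' @param seed Integer seed.
#' @param method Detector method.
#' @param cmd13_symbols,cmd46_symbols Stimuli encoding each command group.
#' @return List with `accuracy` (percent), `decisions`, `confusion`.
#' @export
six_command_experiment <- function(profile, trials_per_command = 50,
                                   seed = NULL, method = c("psd", "relative"),
                                   cmd13_symbols = c("MFH1", "MFH2", "MFH3"),
                                   cmd46_symbols = c("MFF1", "MFF2", "MFF3")) {
  method <- match.arg(method)
  symbols <- c(cmd13_symbols, cmd46_symbols)
  with_seed(seed, {
    epochs <- simulate_labeled_epochs(profile,
                                      c(rep("rest", 9L), symbols,
                                        rep(symbols, trials_per_command)))
    fit <- ssvep_detector(epochs, method = method, calibration_trials = 1)
    eval_idx <- setdiff(which(epochs$labels != "rest"), fit$calibration_index)
    dec <- predict(fit, epochs_subset(epochs, eval_idx), mode = "auto")
    list(accuracy = accuracy(dec$command, dec$truth), decisions = dec,
         confusion = confusion_matrix(dec$command, dec$truth))
  })
}

# Simulate one 4 s analysis epoch per label (both profile channels), without
# the session structure — the building block of the property experiments.
simulate_labeled_epochs <- function(profile, labels, duration_s = 4) {
  channels <- names(profile$gain)
  n <- round(duration_s * profile$fs)
  x <- array(NA_real_, dim = c(length(labels), length(channels), n),
             dimnames = list(NULL, channels, NULL))
  for (i in seq_along(labels)) {
    for (ch in channels) {
      x[i, ch, ] <- simulate_epoch(profile, labels[i], duration_s, channel = ch)
    }
  }
  structure(list(x = x, labels = labels, channels = channels,
                 fs = profile$fs),
            class = "ssvep_epochs")
}

#' Idle soundness experiment
#'
#' Calibrates a detector on a standard calibration set, then classifies
#' freshly simulated rest epochs; reports the false-command rate (decisions
#' other than idle), alternating the single- and dual-frequency decision
#' rules across epochs.
#'
#' @param profile An [ssvep_profile()].
#' @param n_epochs Number of rest epochs to classify (default 500).
#' @param seed Integer seed.
#' @param method Detector method.
#' @return List with `false_command_rate_pct`, `n`.
#' @export
idle_experiment <- function(profile, n_epochs = 500, seed = NULL,
                            method = c("psd", "relative")) {
  method <- match.arg(method)
  with_seed(seed, {
    cal <- simulate_labeled_epochs(profile,
                                   c(rep("rest", 9L), flicker_table()$symbol))
    fit <- ssvep_detector(cal, method = method, calibration_trials = 1)
    rest <- simulate_labeled_epochs(profile, rep("rest", n_epochs))
    modes <- rep(c("SFF_MFH", "MFF"), length.out = n_epochs)
    wrong <- vapply(seq_len(n_epochs), function(i) {
      dec <- predict(fit, epochs_subset(rest, i), mode = modes[i])
      dec$command != 0L
    }, logical(1))
    list(false_command_rate_pct = 100 * mean(wrong), n = n_epochs)
  })
}

#' Parameter recovery: dominant frequency family
#'
#' Simulates epochs attending randomly chosen single-family stimuli (SFF and
#' MFH) and checks how often the family of the largest raw PSD value among
#' the frequencies of interest matches the attended family — spectral
#' parameter recovery, independent of the threshold gates.
#'
#' @param profile An [ssvep_profile()].
#' @param n_epochs Number of epochs (default 1000).
#' @param seed Integer seed.
#' @param channel Profile channel to simulate.
#' @return List with `recovery_rate_pct`, `n`.
#' @export
family_recovery_experiment <- function(profile, n_epochs = 1000, seed = NULL,
                                       channel = "O1") {
  with_seed(seed, {
    symbols <- flicker_table()$symbol[flicker_table()$condition != "MFF"]
    labs <- sample(symbols, n_epochs, replace = TRUE)
    fam <- flicker_table()$f1[match(labs, flicker_table()$symbol)]
    hit <- vapply(seq_len(n_epochs), function(i) {
      x <- simulate_epoch(profile, labs[i], 4, channel = channel)
      dominant_family(welch_psd(x, fs = profile$fs)) == fam[i]
    }, logical(1))
    list(recovery_rate_pct = 100 * mean(hit), n = n_epochs)
  })
}

#' Accuracy as a function of synthetic SNR
#'
#' Runs a reduced offline analysis at each requested response gain (expressed
#' as a multiple of the background noise floor, see
#' [noise_floor_amplitude()]) and returns the accuracy curve.
#'
#' @param snr_values Amplitude/noise-floor ratios, high to low.
#' @param profile Base profile (gains are overridden per level).
#' @param trials_per_flicker Trials per stimulus per level (default 3: one
#'   calibration + two evaluation).
#' @param seed Integer seed.
#' @param method Detector method.
#' @return Data frame with `snr` and `accuracy` (percent).
#' @export
snr_accuracy_curve <- function(snr_values, profile = ssvep_profile(),
                               trials_per_flicker = 3, seed = NULL,
                               method = c("psd", "relative")) {
  method <- match.arg(method)
  with_seed(seed, {
    acc <- vapply(snr_values, function(k) {
      run <- run_offline_analysis(profile_with_snr(profile, k), sessions = 1,
                                  protocol = trial_protocol(
                                    trials_per_flicker = trials_per_flicker),
                                  method = method, filter = FALSE)
      run$accuracy
    }, 0)
    data.frame(snr = snr_values, accuracy = acc)
  })
}
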