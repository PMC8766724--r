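# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# A small full-pipeline cohort (16-channel montage, short rest) reused by
# several test files.
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    cfg <- smoke_profile(n_per_group = 4L, rest_duration = 20, seed = 202L)
    .fixtures$cohort <- simulate_cohort(cfg)
  }
  .fixtures$cohort
}

fixture_analysis <- function() {
  if (is.null(.fixtures$analysis)) {
    .fixtures$analysis <- suppressWarnings(run_analysis(
      fixture_cohort(), pipeline_config(lowpass = NULL, notch = NULL)
    ))
  }
  .fixtures$analysis
}

# Sine-wave recording helper.
sine_recording <- function(freqs, fs = 256, dur = 10, amp = 1) {
  t <- (0:(fs * dur - 1)) / fs
  data <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t), t))
  recording(data, fs, paste0("ch", seq_along(freqs)))
}

# Simulate a diagonal AR(2) process with resonance at f0 for each channel.
diag_ar2_coeffs <- function(k, f0, rho, fs) {
  labels <- paste0("ch", seq_len(k))
  coeffs <- array(0, dim = c(k, k, 2), dimnames = list(labels, labels, NULL))
  th <- 2 * pi * f0 / fs
  for (i in seq_len(k)) {
    coeffs[i, i, 1] <- 2 * rho * cos(th[min(i, length(th))])
    coeffs[i, i, 2] <- -rho^2
  }
  coeffs
}

# Wrap a channels x samples matrix as a single-phase event table + epochs.
matrix_epochs <- function(x, fs, n_epochs) {
  len <- ncol(x) %/% n_epochs
  arr <- array(x[, seq_len(len * n_epochs)], dim = c(nrow(x), len, n_epochs))
  thetadtf:::new_epoch_set(arr, fs, rownames(x) %||% paste0("ch", seq_len(nrow(x))),
                           "encoding", seq_len(n_epochs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
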