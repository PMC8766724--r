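#' @title Preprocessing chain
#' @description
#' The preprocessing operations mirror standard scalp-EEG practice: zero-phase
#' low-pass at 100 Hz, zero-phase notch at 49-51 Hz (50 Hz mains), common
#' average reference, and drift removal. All filters are 4th-order Butterworth
#' designs applied forward-backward (zero phase) with odd-reflection padding to
#' suppress edge transients.
#' @name preprocess
NULL

# Zero-phase filtering with odd-reflection (mirror) padding at both ends.
# The padding length is sized from the slowest filter pole so that edge
# transients decay below 1e-10 even for narrow (high-Q) band-stop designs.
zero_phase <- function(filt, x) {
  n <- length(x)
  pole_r <- max(Mod(polyroot(rev(filt$a))))
  settle <- if (pole_r < 1) ceiling(log(1e-10) / log(pole_r)) else 10000L
  np <- min(n - 1L, max(24L, min(settle, 10000L)))
  if (np < 1L) abort("signal too short to filter")
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(np + 1):(np + n)]
}

#' Zero-phase low-pass filter
#'
#' @param rec A [recording()].
#' @param cutoff Cutoff frequency in Hz; must lie below the Nyquist frequency.
#' @param order Butterworth order (default 4; the effective order doubles with
#'   forward-backward application).
#' @return The filtered recording.
#' @export
lowpass_filter <- function(rec, cutoff = 100, order = 4) {
  stopifnot(inherits(rec, "recording"))
  if (cutoff <= 0 || cutoff >= rec$fs / 2) {
    abort(sprintf("cutoff (%g Hz) must lie in (0, Nyquist = %g Hz)", cutoff, rec$fs / 2))
  }
  filt <- signal::butter(order, cutoff / (rec$fs / 2), type = "low")
  map_channels(rec, function(x) zero_phase(filt, x))
}

#' Zero-phase band-stop (notch) filter
#'
#' @param rec A [recording()].
#' @param band Two-element numeric `(low, high)` in Hz; the default `(49, 51)`
#'   removes 50 Hz mains interference.
#' @param order Butterworth order per pass (default 4).
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, band = c(49, 51), order = 4) {
  stopifnot(inherits(rec, "recording"))
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] || band[2] >= rec$fs / 2) {
    abort("band must satisfy 0 < low < high < Nyquist")
  }
  filt <- signal::butter(order, band / (rec$fs / 2), type = "stop")
  map_channels(rec, function(x) zero_phase(filt, x))
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels.
#'
#' @param rec A [recording()] with at least two channels.
#' @return The re-referenced recording; column means are zero to numerical
#'   precision.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$data) < 2) abort("common average reference needs at least 2 channels")
  centered <- sweep(rec$data, 2, colMeans(rec$data))
  recording_unsafe(centered, rec$fs, rec$channel_labels, rec$subject_id)
}

#' Remove slow baseline drift
#'
#' @param rec A [recording()].
#' @param method `"linear_detrend"` removes the per-channel least-squares line;
#'   `"highpass"` applies a zero-phase Butterworth high-pass.
#' @param cutoff High-pass cutoff in Hz (default 0.05, the lower delta edge);
#'   required when `method = "highpass"`.
#' @return The drift-corrected recording.
#' @export
remove_drift <- function(rec, method = c("linear_detrend", "highpass"),
                         cutoff = NULL) {
  stopifnot(inherits(rec, "recording"))
  method <- match.arg(method)
  if (method == "linear_detrend") {
    n <- ncol(rec$data)
    t_idx <- seq_len(n) - (n + 1) / 2           # centered regressor
    denom <- sum(t_idx^2)
    slope <- (rec$data %*% t_idx) / denom
    intercept <- rowMeans(rec$data)
    fitted <- outer(as.vector(slope), t_idx) + intercept
    recording_unsafe(rec$data - fitted, rec$fs, rec$channel_labels, rec$subject_id)
  } else {
    cutoff <- cutoff %||% 0.05
    if (cutoff <= 0 || cutoff >= rec$fs / 2) abort("invalid high-pass cutoff")
    filt <- signal::butter(2, cutoff / (rec$fs / 2), type = "high")
    map_channels(rec, function(x) zero_phase(filt, x))
  }
}

#' Hook for artifact removal on real recordings
#'
#' Synthetic cohorts carry no ocular or myogenic artifacts, so the default is
#' the identity. Users analysing real EEG can supply their own function
#' (e.g. an ICA-based cleaner) taking and returning a [recording()].
#'
#' @param rec A [recording()].
#' @param fun A function `recording -> recording`, or `NULL` for the identity.
#' @return The (possibly cleaned) recording.
#' @export
remove_artifacts <- function(rec, fun = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(fun)) return(rec)
  out <- fun(rec)
  stopifnot(inherits(out, "recording"))
  out
}

#' Segment epochs of one task phase
#'
#' Extracts, for every event row matching `phase`, the half-open sample window
#' `[onset_sample, onset_sample + duration_samples)` (0-based onsets). All
#' matching events must share one duration.
#'
#' @param rec A [recording()].
#' @param events Event tibble (see [read_events()]).
#' @param phase Phase label to extract (e.g. `"encoding"`).
#' @return An `epoch_set` (trials x channels x samples). An absent phase gives
#'   an empty epoch set with a warning.
#' @export
extract_epochs <- function(rec, events, phase) {
  stopifnot(inherits(rec, "recording"))
  ev <- events[events$phase == phase, , drop = FALSE]
  if (nrow(ev) == 0) {
    warn(sprintf("no events with phase '%s'; returning an empty epoch set", phase))
    return(new_epoch_set(
      array(numeric(0), dim = c(nrow(rec$data), 0, 0)),
      rec$fs, rec$channel_labels, phase, integer(0)
    ))
  }
  durs <- unique(ev$duration_samples)
  if (length(durs) != 1) abort("all epochs of one phase must share a duration")
  len <- durs[1]
  n <- ncol(rec$data)
  bad <- ev$trial[ev$onset_sample < 0 | ev$onset_sample + len > n]
  if (length(bad) > 0) {
    abort(sprintf("epochs exceed recording bounds for trials: %s",
                  paste(bad, collapse = ", ")))
  }
  idx <- as.vector(vapply(ev$onset_sample,
                          function(s0) (s0 + 1):(s0 + len), integer(len)))
  flat <- rec$data[, idx, drop = FALSE]       # k x (len * n_events)
  dim(flat) <- c(nrow(rec$data), len, nrow(ev))
  new_epoch_set(flat, rec$fs, rec$channel_labels, phase, ev$trial)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: low-pass, notch, common average reference and drift
#' removal. The order is configurable; each applied step is recorded in the
#' returned object's `"preprocess_log"` attribute.
#'
#' @param rec A [recording()].
#' @param lowpass Low-pass cutoff in Hz, or `NULL` to skip (skipped
#'   automatically when the cutoff would reach Nyquist).
#' @param notch Notch band `(low, high)` in Hz, or `NULL` to skip.
#' @param car Apply common average reference?
#' @param drift Drift-removal method (see [remove_drift()]), or `NULL` to skip.
#' @param artifact_fun Optional artifact-removal hook (see [remove_artifacts()]).
#' @return The preprocessed recording.
#' @export
preprocess_recording <- function(rec, lowpass = 100, notch = c(49, 51),
                                 car = TRUE, drift = "linear_detrend",
                                 artifact_fun = NULL) {
  log <- character(0)
  if (!is.null(lowpass) && lowpass < rec$fs / 2) {
    rec <- lowpass_filter(rec, lowpass)
    log <- c(log, sprintf("lowpass %g Hz", lowpass))
  }
  if (!is.null(notch) && notch[2] < rec$fs / 2) {
    rec <- notch_filter(rec, notch)
    log <- c(log, sprintf("notch %g-%g Hz", notch[1], notch[2]))
  }
  rec <- remove_artifacts(rec, artifact_fun)
  if (!is.null(artifact_fun)) log <- c(log, "artifact hook")
  if (isTRUE(car)) {
    rec <- common_average_reference(rec)
    log <- c(log, "common average reference")
  }
  if (!is.null(drift)) {
    rec <- remove_drift(rec, drift)
    log <- c(log, sprintf("drift removal (%s)", drift))
  }
  attr(rec, "preprocess_log") <- log
  rec
}
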