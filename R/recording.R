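#' Construct a continuous EEG recording
#'
#' A `recording` is the package's container for one subject's continuous
#' multichannel EEG: a channels x samples numeric matrix (microvolts), the
#' sampling rate and ordered channel labels.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param subject_id Optional subject identifier.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels, subject_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    abort("recording data must be a finite numeric matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("fs must be a positive scalar")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    abort(sprintf(
      "channel_labels length (%d) must equal the number of data rows (%d)",
      length(channel_labels), nrow(data)
    ))
  }
  if (anyDuplicated(channel_labels)) abort("channel labels must be unique")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = subject_id),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channels x %d samples @ %g Hz (%.1f s)%s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    if (is.na(x$subject_id)) "" else paste0(" [", x$subject_id, "]")
  ))
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

# Epochs are stored channels x samples x trials (column-major friendly).
new_epoch_set <- function(data, fs, channel_labels, phase, trial_ids) {
  stopifnot(length(dim(data)) == 3)
  if (anyDuplicated(trial_ids)) abort("trial_ids must be unique")
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         phase = phase, trial_ids = trial_ids),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> phase '%s': %d trials x %d channels x %d samples @ %g Hz\n",
    x$phase, d[3], d[1], d[2], x$fs
  ))
  invisible(x)
}

n_epochs <- function(epochs) dim(epochs$data)[3]

# Channels x samples matrix of one epoch.
epoch_matrix <- function(epochs, e) {
  m <- epochs$data[, , e]
  if (is.null(dim(m))) dim(m) <- dim(epochs$data)[1:2]
  m
}

# Internal fast path: skips validation for data produced by the package's
# own numeric operations (already finite, labels already consistent).
recording_unsafe <- function(data, fs, channel_labels, subject_id = NA_character_) {
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = subject_id),
    class = "recording"
  )
}

#' Subset channels of a recording or epoch set
#'
#' @param x A [recording()] or `epoch_set`.
#' @param channels Channel labels to keep, in the requested order.
#' @return The subsetted object.
#' @export
select_channels <- function(x, channels) {
  idx <- match(channels, x$channel_labels)
  if (anyNA(idx)) {
    abort(sprintf("unknown channels: %s",
                  paste(channels[is.na(idx)], collapse = ", ")))
  }
  if (inherits(x, "recording")) {
    recording(x$data[idx, , drop = FALSE], x$fs, channels, x$subject_id)
  } else if (inherits(x, "epoch_set")) {
    new_epoch_set(x$data[idx, , , drop = FALSE], x$fs, channels,
                  x$phase, x$trial_ids)
  } else {
    abort("select_channels expects a recording or epoch_set")
  }
}

# Apply a per-channel function over all samples of a recording, preserving shape.
map_channels <- function(rec, f) {
  out <- t(apply(rec$data, 1, f))
  recording_unsafe(out, rec$fs, rec$channel_labels, rec$subject_id)
}
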