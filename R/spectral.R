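#' Frequency-band scheme
#'
#' The default scheme follows the conventional EEG bands: delta [0.05, 4),
#' theta [4, 8), alpha [8, 13), beta [13, 30), gamma [30, 100) Hz. Band edges
#' are half-open `[low, high)` so adjacent bands sharing an endpoint never
#' double-count a frequency bin.
#'
#' @param bands A data frame with columns `band`, `low`, `high`; the default
#'   is the five-band clinical scheme.
#' @return A tibble of class `band_scheme`.
#' @export
band_scheme <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- tibble(
      band = c("delta", "theta", "alpha", "beta", "gamma"),
      low = c(0.05, 4, 8, 13, 30),
      high = c(4, 8, 13, 30, 100)
    )
  }
  bands <- as_tibble(bands)
  stopifnot(all(c("band", "low", "high") %in% names(bands)))
  if (any(bands$high <= bands$low)) abort("each band needs low < high")
  o <- order(bands$low)
  bands <- bands[o, ]
  if (nrow(bands) > 1 && any(bands$low[-1] < bands$high[-nrow(bands)])) {
    abort("bands must not overlap under the half-open [low, high) convention")
  }
  class(bands) <- c("band_scheme", class(bands))
  bands
}

#' Spectral estimation settings
#'
#' Controls the short-time Fourier transform used for power spectral density
#' estimation: 0.4 s Hamming windows with 50% overlap, zero-padded to a 0.5 Hz
#' frequency grid (Welch averaging over windows, and over epochs for epoched
#' input).
#'
#' @param window_length Window length in seconds (default 0.4).
#' @param window_type Taper, `"hamming"` or `"hann"`.
#' @param overlap Fractional overlap between consecutive windows in `[0, 1)`.
#' @param freq_resolution Grid spacing in Hz, obtained by zero-padding each
#'   windowed segment (default 0.5).
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(window_length = 0.4, window_type = c("hamming", "hann"),
                            overlap = 0.5, freq_resolution = 0.5) {
  window_type <- match.arg(window_type)
  if (overlap < 0 || overlap >= 1) abort("overlap must lie in [0, 1)")
  stopifnot(window_length > 0, freq_resolution > 0)
  structure(
    list(window_length = window_length, window_type = window_type,
         overlap = overlap, freq_resolution = freq_resolution),
    class = "spectral_config"
  )
}

taper_window <- function(type, L) {
  n <- 0:(L - 1)
  switch(type,
    hamming = 0.54 - 0.46 * cos(2 * pi * n / (L - 1)),
    hann = 0.5 - 0.5 * cos(2 * pi * n / (L - 1)),
    abort(sprintf("unknown window type '%s'", type))
  )
}

# Welch PSD of a channels x samples matrix -> channels x nfreq matrix.
# One-sided, window-power corrected: sum(psd) * df ~= mean signal power.
# A compiled radix-2 path handles the common power-of-two FFT length; any
# other length falls back to stats::mvfft (identical results).
welch_psd_matrix <- function(x, fs, cfg) {
  L <- round(cfg$window_length * fs)
  n <- ncol(x)
  if (L > n) abort("window longer than the data segment")
  nfft <- max(L, round(fs / cfg$freq_resolution))
  w <- taper_window(cfg$window_type, L)
  hop <- max(1L, round(L * (1 - cfg$overlap)))
  starts <- seq(1L, n - L + 1L, by = hop)
  k <- nrow(x)
  nf <- floor(nfft / 2) + 1L
  if (bitwAnd(nfft, nfft - 1L) == 0L) {
    acc <- welch_accum_cpp(x, w, as.integer(starts), as.integer(nfft))
  } else {
    segs <- matrix(0, nfft, length(starts) * k)
    for (j in seq_along(starts)) {
      idx <- starts[j]:(starts[j] + L - 1L)
      segs[1:L, ((j - 1L) * k + 1L):(j * k)] <- t(x[, idx, drop = FALSE] * rep(w, each = k))
    }
    spec <- Mod(stats::mvfft(segs))^2
    acc <- matrix(0, k, nf)
    for (j in seq_along(starts)) {
      acc <- acc + t(spec[1:nf, ((j - 1L) * k + 1L):(j * k), drop = FALSE])
    }
  }
  psd <- acc / (length(starts) * fs * sum(w^2))
  if (nf > 2) psd[, 2:(nf - 1L)] <- 2 * psd[, 2:(nf - 1L)]
  if (nfft %% 2 == 1) psd[, nf] <- 2 * psd[, nf]   # no Nyquist bin when odd
  list(freq = (seq_len(nf) - 1) * fs / nfft, psd = psd)
}

#' Short-time Fourier transform power spectral density
#'
#' Welch-style average of squared STFT magnitudes over tapered, overlapping,
#' zero-padded windows; for an `epoch_set` the per-epoch PSDs are additionally
#' averaged across epochs. The estimate is one-sided and normalized so that
#' `sum(psd) * freq_resolution` equals the windowed signal's mean power
#' (Parseval, up to taper correction).
#'
#' @param x A [recording()] or an `epoch_set`.
#' @param config A [spectral_config()].
#' @return A list of class `psd_estimate` with `freq` (Hz), `psd`
#'   (channels x frequencies, µV²/Hz), `channel_labels` and `fs`.
#' @export
stft_psd <- function(x, config = spectral_config()) {
  if (inherits(x, "recording")) {
    out <- welch_psd_matrix(x$data, x$fs, config)
    labels <- x$channel_labels; fs <- x$fs
  } else if (inherits(x, "epoch_set")) {
    ne <- n_epochs(x)
    if (ne == 0) abort("cannot estimate a PSD from an empty epoch set")
    acc <- NULL
    for (e in seq_len(ne)) {
      w <- welch_psd_matrix(epoch_matrix(x, e), x$fs, config)
      acc <- if (is.null(acc)) w$psd else acc + w$psd
      freq <- w$freq
    }
    out <- list(freq = freq, psd = acc / ne)
    labels <- x$channel_labels; fs <- x$fs
  } else {
    abort("stft_psd expects a recording or an epoch_set")
  }
  structure(
    list(freq = out$freq, psd = out$psd, channel_labels = labels, fs = fs),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d channels, %d frequencies (%g-%g Hz, df = %g)\n",
              nrow(x$psd), length(x$freq), min(x$freq), max(x$freq),
              x$freq[2] - x$freq[1]))
  invisible(x)
}

#' Band-average power
#'
#' Mean PSD over the frequency bins with `low <= f < high`, per channel and
#' band.
#'
#' @param psd A `psd_estimate` from [stft_psd()].
#' @param scheme A [band_scheme()].
#' @return A tibble with columns `channel`, `band`, `power` (µV²/Hz).
#' @export
band_power <- function(psd, scheme = band_scheme()) {
  stopifnot(inherits(psd, "psd_estimate"))
  rows <- purrr::pmap(scheme, function(band, low, high) {
    sel <- psd$freq >= low & psd$freq < high
    if (!any(sel)) {
      abort(sprintf("band '%s' [%g, %g) contains no frequency bins", band, low, high))
    }
    tibble(channel = psd$channel_labels,
           band = band,
           power = rowMeans(psd$psd[, sel, drop = FALSE]))
  })
  out <- bind_rows(rows)
  out$band <- factor(out$band, levels = scheme$band)
  out
}

#' Working-memory efficiency power
#'
#' Element-wise baseline normalization of task-phase band power against the
#' eyes-closed resting baseline: `p_wm = p_raw - p_rs`. Values may be negative
#' (task power below baseline).
#'
#' @param p_raw Band-power tibble from the task epochs (see [band_power()]).
#' @param p_rs Band-power tibble from the resting baseline, on the same
#'   channel/band grid.
#' @return A tibble with columns `channel`, `band`, `p_raw`, `p_rs`, `p_wm`.
#' @export
wm_efficiency <- function(p_raw, p_rs) {
  key_raw <- paste(p_raw$channel, p_raw$band)
  key_rs <- paste(p_rs$channel, p_rs$band)
  if (nrow(p_raw) != nrow(p_rs) || !setequal(key_raw, key_rs)) {
    abort("p_raw and p_rs must share one channel/band grid")
  }
  raw_vals <- p_raw$power
  rs_vals <- p_rs$power[match(key_raw, key_rs)]
  tibble(channel = p_raw$channel, band = p_raw$band,
         p_raw = raw_vals, p_rs = rs_vals, p_wm = raw_vals - rs_vals)
}

#' Prominent frequency band
#'
#' The band with maximum channel-averaged power. Exact ties break toward the
#' lower-frequency band and are reported via a message.
#'
#' @param band_powers Tibble with columns `band` and `power` (optionally
#'   `channel`; powers are averaged over channels per band first).
#' @param power_col Name of the power column to rank (default `"power"`).
#' @return The prominent band name (character scalar).
#' @export
prominent_band <- function(band_powers, power_col = "power") {
  stopifnot(power_col %in% names(band_powers))
  agg <- band_powers |>
    group_by(.data$band) |>
    summarise(power = mean(.data[[power_col]]), .groups = "drop")
  if (any(!is.finite(agg$power))) abort("band powers must be finite")
  # band is a factor ordered low -> high frequency; which.max takes the first
  # (lowest-frequency) band on exact ties.
  best <- which(agg$power == max(agg$power))
  if (length(best) > 1) {
    inform(sprintf("prominent_band tie between: %s; choosing the lowest band",
                   paste(agg$band[best], collapse = ", ")))
  }
  as.character(agg$band[best[1]])
}

#' Region-average power
#'
#' Unweighted mean of per-channel values over each scalp region; unassigned
#' channels are excluded.
#'
#' @param band_powers Tibble with columns `channel` and a value column.
#' @param regions Region map from [default_region_map()].
#' @param value_col Name of the value column to average (default `"power"`).
#' @return A tibble with columns `region` and `power`.
#' @export
region_power <- function(band_powers, regions = default_region_map(),
                         value_col = "power") {
  stopifnot(value_col %in% names(band_powers))
  joined <- left_join(band_powers, regions, by = "channel")
  if (any(is.na(joined$region))) {
    abort(sprintf("channels missing from the region map: %s",
                  paste(unique(joined$channel[is.na(joined$region)]), collapse = ", ")))
  }
  out <- joined |>
    filter(.data$region != "unassigned") |>
    group_by(.data$region) |>
    summarise(power = mean(.data[[value_col]]), .groups = "drop")
  present <- setdiff(unique(regions$region), "unassigned")
  if (!setequal(out$region, present)) {
    abort("a region in the map has no channels among the supplied values")
  }
  out
}
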