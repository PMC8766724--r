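#' Read a continuous EEG recording from disk
#'
#' Supports two on-disk dialects: a delimited numeric matrix (CSV/TSV, header
#' row of channel labels, one row per sample) and European Data Format (EDF,
#' 16-bit). Channel labels are normalized to the montage's canonical spelling
#' (T3/T4/T5/T6 -> T7/T8/P7/P8).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"delimited"` or `"edf"`.
#' @param fs Sampling rate in Hz; required for delimited files, read from the
#'   header for EDF.
#' @param expected_montage Optional character vector; when given, the file's
#'   labels must match it exactly (after normalization) or an error is raised.
#' @param subject_id Optional subject identifier attached to the result.
#' @return A [recording()].
#' @export
load_recording <- function(path, format = c("auto", "delimited", "edf"),
                           fs = NULL, expected_montage = NULL,
                           subject_id = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  if (format == "delimited") {
    if (is.null(fs)) abort("fs must be given for delimited recordings")
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, colClasses = "numeric")
    rec <- recording(t(as.matrix(tab)), fs,
                     normalize_channel_labels(colnames(tab)), subject_id)
  } else {
    edf <- read_edf(path)
    rec <- recording(edf$data, edf$fs,
                     normalize_channel_labels(edf$channel_labels), subject_id)
  }
  if (!is.null(expected_montage)) {
    expected <- normalize_channel_labels(expected_montage)
    if (!identical(rec$channel_labels, expected)) {
      abort(sprintf(
        "channel labels do not match the expected montage (got: %s; expected: %s)",
        paste(rec$channel_labels, collapse = ","), paste(expected, collapse = ",")
      ))
    }
  }
  rec
}

#' Write a recording to disk
#'
#' @param rec A [recording()].
#' @param path Output path; `.csv`/`.tsv` select the delimited dialect, `.edf`
#'   the 16-bit European Data Format (values are quantized to the 16-bit grid
#'   spanning the per-channel physical range).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    write_edf(rec, path)
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    # 17 significant digits round-trip IEEE doubles exactly
    tab <- as.data.frame(apply(t(rec$data), 2, sprintf, fmt = "%.17g"))
    colnames(tab) <- rec$channel_labels
    utils::write.table(tab, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  }
  invisible(path)
}

# --- minimal EDF (16-bit European Data Format) ---------------------------
# One data record holding the whole signal; ASCII header per the EDF layout.
# Written by hand because no installed R package reads or writes EDF.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

write_edf <- function(rec, path) {
  k <- nrow(rec$data); n <- ncol(rec$data)
  # physical range, expanded slightly and rounded to what fits the 8-char
  # header field, so writer and reader scale with identical values
  fit8 <- function(x) {
    for (d in 6:1) {
      s <- sprintf(paste0("%.", d, "g"), x)
      if (nchar(s) <= 8) return(s)
    }
    sprintf("%.0e", x)
  }
  data_min <- apply(rec$data, 1, min)
  data_max <- apply(rec$data, 1, max)
  span <- pmax(data_max - data_min, 1e-6)
  pm_str <- vapply(data_min - 1e-4 * span, fit8, "")
  px_str <- vapply(data_max + 1e-4 * span, fit8, "")
  phys_min <- as.numeric(pm_str)
  phys_max <- as.numeric(px_str)
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(ifelse(is.na(rec$subject_id), "X", rec$subject_id), 80),
    edf_pad("thetadtf synthetic EEG", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + k), 8),
    edf_pad("", 44),
    edf_pad(1, 8),                       # one data record
    edf_pad(fit8(n / rec$fs), 8),
    edf_pad(k, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$channel_labels, edf_pad, "", width = 16),
    rep(edf_pad("", 80), k),             # transducer
    rep(edf_pad("uV", 8), k),
    vapply(pm_str, edf_pad, "", width = 8),
    vapply(px_str, edf_pad, "", width = 8),
    rep(edf_pad(dig_min, 8), k),
    rep(edf_pad(dig_max, 8), k),
    rep(edf_pad("", 80), k),             # prefiltering
    rep(edf_pad(n, 8), k),
    rep(edf_pad("", 32), k)
  )
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  for (i in seq_len(k)) {
    scale <- (dig_max - dig_min) / (phys_max[i] - phys_min[i])
    dig <- round((rec$data[i, ] - phys_min[i]) * scale + dig_min)
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  k <- as.integer(rd(4))
  labels <- vapply(seq_len(k), function(i) rd(16), "")
  for (i in seq_len(k)) rd(80)
  for (i in seq_len(k)) rd(8)
  phys_min <- as.numeric(vapply(seq_len(k), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(k), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(k), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(k), function(i) rd(8), ""))
  for (i in seq_len(k)) rd(80)
  spr <- as.integer(vapply(seq_len(k), function(i) rd(8), ""))
  for (i in seq_len(k)) rd(32)
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec_mat <- matrix(NA_real_, k, max(spr))
    for (i in seq_len(k)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      rec_mat[i, seq_len(spr[i])] <-
        phys_min[i] + (dig - dig_min[i]) *
          (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    }
    chunks[[r]] <- rec_mat
  }
  data <- do.call(cbind, chunks)
  fs <- sum(spr[1]) / dur
  list(data = data, fs = fs, channel_labels = labels)
}

#' Read an event table
#'
#' Events are tab-separated with columns `trial`, `phase`, `onset_sample`,
#' `duration_samples`. Onsets are 0-based sample indices; an epoch covers the
#' half-open interval `[onset, onset + duration)`.
#'
#' @param path Path to an `events.tsv` file.
#' @return A tibble.
#' @export
read_events <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("trial", "phase", "onset_sample", "duration_samples")
  if (!all(need %in% names(tab))) {
    abort(sprintf("events table must have columns: %s", paste(need, collapse = ", ")))
  }
  as_tibble(tab)
}

#' Read a per-trial behavior table
#'
#' Tab-separated with columns `trial`, `correct` (0/1 or logical), `rt_ms`
#' (reaction time in milliseconds; NA for incorrect trials).
#'
#' @param path Path to a `behavior.tsv` file.
#' @return A tibble.
#' @export
read_behavior <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("trial", "correct", "rt_ms")
  if (!all(need %in% names(tab))) {
    abort(sprintf("behavior table must have columns: %s", paste(need, collapse = ", ")))
  }
  tab$correct <- as.logical(tab$correct)
  as_tibble(tab)
}

write_tsv_plain <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
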