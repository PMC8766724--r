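#' The 34-channel recording montage
#'
#' Channel labels of the extended 10-20 montage used throughout the package, in
#' recording order (channels 1-34): Fp1, Fp2, F7, F3, Fz, F4, F8, FT7, FC3,
#' FCz, FC4, FT8, T7, C3, Cz, C4, T8, TP7, CP3, CPz, CP4, TP8, P7, P3, Pz, P4,
#' P8, PO3, PO4, O1, Oz, O2, AF3, AF4.
#'
#' @param n_channels Number of leading channels to keep. The default (34) is
#'   the full montage; smaller values return a reduced montage that still
#'   covers all four scalp regions (used by the fast simulation profile).
#' @return Character vector of channel labels.
#' @export
#' @examples
#' default_montage()
default_montage <- function(n_channels = 34L) {
  full <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT7", "FC3", "FCz",
    "FC4", "FT8", "T7", "C3", "Cz", "C4", "T8", "TP7", "CP3", "CPz",
    "CP4", "TP8", "P7", "P3", "Pz", "P4", "P8", "PO3", "PO4", "O1",
    "Oz", "O2", "AF3", "AF4"
  )
  if (n_channels == 34L) return(full)
  # Reduced montages sample every region so region-level analyses stay defined.
  reduced16 <- c(
    "Fp1", "F7", "Fz", "F4", "FC3", "AF3", # frontal (+F7 unassigned)
    "C3", "Cz", "CP4", "Pz",               # central-parietal
    "PO3", "O1", "Oz",                     # occipital
    "T7", "T8", "TP7"                      # temporal
  )
  if (n_channels == 16L) return(reduced16)
  stopifnot(n_channels >= 1, n_channels <= 34)
  full[seq_len(n_channels)]
}

# Older temporal nomenclature used in printed region lists maps onto the
# recorded labels: T3->T7, T4->T8, T5->P7, T6->P8.
normalize_channel_labels <- function(labels) {
  eq <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")
  hit <- labels %in% names(eq)
  labels[hit] <- eq[labels[hit]]
  labels
}

#' Default scalp region map
#'
#' Groups the montage channels into four region clusters: frontal (F),
#' central-parietal (C), occipital (O) and temporal (T). F7 and F8 belong to
#' no cluster and are mapped to `"unassigned"`; they take part in whole-scalp
#' computations but are excluded from region aggregates.
#'
#' @param channel_labels Channels to map (default: the full 34-channel
#'   montage). Labels in the older temporal nomenclature (T3/T4/T5/T6) are
#'   accepted and normalized.
#' @return A tibble with columns `channel` and `region`
#'   (`F`, `C`, `O`, `T` or `unassigned`).
#' @export
#' @examples
#' table(default_region_map()$region)
default_region_map <- function(channel_labels = default_montage()) {
  channel_labels <- normalize_channel_labels(channel_labels)
  regions <- list(
    F = c("Fp1", "Fp2", "F3", "Fz", "F4", "FC3", "FCz", "FC4", "AF3", "AF4"),
    C = c("C3", "Cz", "C4", "CP3", "CPz", "CP4", "P3", "Pz", "P4"),
    O = c("PO3", "PO4", "O1", "Oz", "O2"),
    T = c("FT7", "FT8", "T7", "T8", "TP7", "TP8", "P7", "P8")
  )
  lookup <- unlist(lapply(names(regions), function(r) {
    setNames(rep(r, length(regions[[r]])), regions[[r]])
  }))
  region <- unname(lookup[channel_labels])
  region[is.na(region)] <- "unassigned"
  tibble(channel = channel_labels, region = region)
}

# Channels of one region from a region-map tibble; errors when empty.
region_channels <- function(regions, region, allow_empty = FALSE) {
  stopifnot(is.data.frame(regions), all(c("channel", "region") %in% names(regions)))
  ch <- regions$channel[regions$region == region]
  if (!allow_empty && length(ch) == 0) {
    abort(sprintf("region '%s' has no channels in the region map", region))
  }
  ch
}
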