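#' Fit a multivariate autoregressive (MVAR) model
#'
#' Multi-epoch ordinary least squares: each channel at time t is regressed on
#' the p previous samples of every channel, pooling regression rows across
#' epochs without ever spanning an epoch boundary. With `order = "auto"` the
#' order minimizing the chosen information criterion over 1..`max_order` is
#' selected (and reported via a message).
#'
#' @param epochs An `epoch_set` or a [recording()] (treated as one epoch).
#' @param order Integer lag order, or `"auto"`.
#' @param criterion `"BIC"` (default) or `"AIC"`, used when `order = "auto"`.
#' @param max_order Upper bound of the order search (default 20).
#' @return An object of class `mvar_model`: coefficient array `coeffs`
#'   (k x k x p, `coeffs[i, j, r]` = influence of channel j at lag r on
#'   channel i), innovation covariance `noise_cov`, `order`, `fs`,
#'   `channel_labels`, `n_obs`.
#' @export
fit_mvar <- function(epochs, order = "auto", criterion = c("BIC", "AIC"),
                     max_order = 20L) {
  criterion <- match.arg(criterion)
  if (inherits(epochs, "recording")) {
    dat <- array(epochs$data, dim = c(nrow(epochs$data), ncol(epochs$data), 1))
    epochs <- new_epoch_set(dat, epochs$fs, epochs$channel_labels,
                            "continuous", 1L)
  }
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  k <- d[1]
  if (identical(order, "auto")) {
    cand <- seq_len(min(max_order, (d[2] - 1L)))
    ics <- vapply(cand, function(p) mvar_ols(epochs, p)$ic[[criterion]], 0)
    order <- cand[which.min(ics)]
    inform(sprintf("fit_mvar: auto order selected p = %d by %s", order, criterion))
  }
  order <- as.integer(order)
  stopifnot(order >= 1)
  fit <- mvar_ols(epochs, order)
  if (fit$n_obs < 10 * k * order) {
    warn(sprintf(
      "fit_mvar: only %d regression rows for %d parameters per equation (< 10x); consider a lower order or more data",
      fit$n_obs, k * order
    ))
  }
  structure(
    list(order = order, coeffs = fit$coeffs, noise_cov = fit$noise_cov,
         fs = epochs$fs, channel_labels = epochs$channel_labels,
         n_obs = fit$n_obs, ic = fit$ic),
    class = "mvar_model"
  )
}

# Pooled OLS across epochs via the normal equations, accumulated in compiled
# code without materializing the design matrix (regressors never span epoch
# boundaries). Returns coeffs (k x k x p), noise_cov, n_obs, ICs.
mvar_ols <- function(epochs, p) {
  d <- dim(epochs$data)
  k <- d[1]; len <- d[2]; ne <- d[3]
  if (len <= p) abort("epochs shorter than the model order")
  nr <- mvar_xtxy_cpp(epochs$data, as.integer(p))
  n_obs <- nr$n_obs
  xty <- t(nr$YtX)
  B <- tryCatch(
    solve(nr$XtX, xty),
    error = function(e) abort(paste0(
      "rank-deficient MVAR regression; use fewer channels, a lower order or more data (",
      conditionMessage(e), ")"
    ))
  )
  rss <- nr$YtY - crossprod(B, xty)
  rss <- (rss + t(rss)) / 2
  sigma_ml <- rss / n_obs
  npar <- k * k * p
  logdet <- determinant(sigma_ml, logarithm = TRUE)$modulus[1]
  if (!is.finite(logdet)) logdet <- -Inf
  ic <- list(
    AIC = n_obs * logdet + 2 * npar,
    BIC = n_obs * logdet + log(n_obs) * npar
  )
  coeffs <- array(NA_real_, dim = c(k, k, p),
                  dimnames = list(epochs$channel_labels, epochs$channel_labels, NULL))
  for (r in seq_len(p)) {
    coeffs[, , r] <- t(B[((r - 1) * k + 1):(r * k), , drop = FALSE])
  }
  dof <- max(n_obs - k * p, 1)
  list(coeffs = coeffs, noise_cov = rss / dof, n_obs = n_obs, ic = ic)
}

# Companion-matrix spectral radius of a k x k x p coefficient array.
mvar_spectral_radius <- function(coeffs) {
  k <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  comp <- matrix(0, k * p, k * p)
  for (r in seq_len(p)) comp[1:k, ((r - 1) * k + 1):(r * k)] <- coeffs[, , r]
  if (p > 1) comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Is an MVAR coefficient array stable?
#'
#' @param coeffs k x k x p coefficient array (or an `mvar_model`).
#' @return Logical; `TRUE` when the companion-matrix spectral radius is < 1.
#' @export
is_stable <- function(coeffs) {
  if (inherits(coeffs, "mvar_model")) coeffs <- coeffs$coeffs
  mvar_spectral_radius(coeffs) < 1
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> k = %d channels, order p = %d, %d regression rows, spectral radius %.3f\n",
              dim(x$coeffs)[1], x$order, x$n_obs, mvar_spectral_radius(x$coeffs)))
  invisible(x)
}

#' @export
tidy.mvar_model <- function(x, ...) {
  k <- dim(x$coeffs)[1]; p <- x$order
  grid <- expand.grid(target = x$channel_labels, source = x$channel_labels,
                      lag = seq_len(p), stringsAsFactors = FALSE)
  tibble(target = grid$target, source = grid$source, lag = grid$lag,
         estimate = as.vector(x$coeffs))
}

#' @export
glance.mvar_model <- function(x, ...) {
  tibble(k = dim(x$coeffs)[1], order = x$order, n_obs = x$n_obs,
         spectral_radius = mvar_spectral_radius(x$coeffs),
         AIC = x$ic$AIC, BIC = x$ic$BIC)
}

#' Frequency-domain transfer matrix of an MVAR model
#'
#' `H(f) = [I - sum_r A_r exp(-i 2 pi f r / fs)]^{-1}`.
#'
#' @param model An `mvar_model`, or a k x k x p coefficient array (then `fs`
#'   must be given).
#' @param freq_grid Frequencies in Hz (below Nyquist).
#' @param fs Sampling rate, required when `model` is a bare array.
#' @return Complex array k x k x length(freq_grid).
#' @export
transfer_matrix <- function(model, freq_grid, fs = NULL) {
  if (inherits(model, "mvar_model")) {
    coeffs <- model$coeffs; fs <- model$fs
  } else {
    coeffs <- model
    if (is.null(fs)) abort("fs must be supplied with a bare coefficient array")
  }
  if (any(freq_grid < 0) || any(freq_grid > fs / 2)) {
    abort("frequencies must lie in [0, Nyquist]")
  }
  k <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  H <- array(NA_complex_, dim = c(k, k, length(freq_grid)))
  I <- diag(k)
  for (fi in seq_along(freq_grid)) {
    A <- matrix(0 + 0i, k, k)
    for (r in seq_len(p)) {
      A <- A + coeffs[, , r] * exp(-2i * pi * freq_grid[fi] * r / fs)
    }
    H[, , fi] <- tryCatch(
      solve(I - A),
      error = function(e) abort(sprintf(
        "transfer matrix singular at f = %g Hz", freq_grid[fi]
      ))
    )
  }
  dimnames(H) <- list(dimnames(coeffs)[[1]], dimnames(coeffs)[[2]], NULL)
  H
}

#' Directed transfer function
#'
#' Row-normalized squared transfer-matrix magnitude:
#' `gamma[i, j](f) = |H_ij(f)|^2 / sum_m |H_im(f)|^2`. Row i is the sink,
#' column j the source; every row sums to 1 at every frequency.
#'
#' @param model An `mvar_model` (or coefficient array with `fs`).
#' @param freq_grid Frequencies in Hz.
#' @param fs Sampling rate for bare coefficient arrays.
#' @return An object of class `dtf_result` with `gamma`
#'   (k x k x nfreq, in `[0, 1]`), `freq_grid` and `channel_labels`.
#' @export
dtf <- function(model, freq_grid, fs = NULL) {
  H <- transfer_matrix(model, freq_grid, fs)
  mag2 <- Mod(H)^2
  k <- dim(mag2)[1]
  gamma <- mag2
  for (fi in seq_along(freq_grid)) {
    denom <- rowSums(mag2[, , fi, drop = TRUE])
    if (any(denom == 0)) abort("all-zero transfer row; DTF undefined")
    gamma[, , fi] <- mag2[, , fi] / denom
  }
  labels <- dimnames(H)[[1]] %||%
    (if (inherits(model, "mvar_model")) model$channel_labels else NULL)
  structure(
    list(gamma = gamma, freq_grid = freq_grid, channel_labels = labels),
    class = "dtf_result"
  )
}

#' @export
print.dtf_result <- function(x, ...) {
  cat(sprintf("<dtf_result> %d channels, %d frequencies (%g-%g Hz)\n",
              dim(x$gamma)[1], length(x$freq_grid),
              min(x$freq_grid), max(x$freq_grid)))
  invisible(x)
}

#' Band-averaged DTF matrix
#'
#' Mean of the frequency-resolved DTF over the bins with `low <= f < high`.
#'
#' @param dtf_res A `dtf_result`, or a k x k x nfreq array with `freq_grid`.
#' @param band Two-element numeric `(low, high)` in Hz.
#' @param freq_grid Required when `dtf_res` is a bare array.
#' @return k x k matrix (rows = sink, columns = source).
#' @export
band_average_dtf <- function(dtf_res, band, freq_grid = NULL) {
  if (inherits(dtf_res, "dtf_result")) {
    gamma <- dtf_res$gamma; freq_grid <- dtf_res$freq_grid
    labels <- dtf_res$channel_labels
  } else {
    gamma <- dtf_res
    if (is.null(freq_grid)) abort("freq_grid must be supplied with a bare array")
    labels <- dimnames(gamma)[[1]]
  }
  sel <- freq_grid >= band[1] & freq_grid < band[2]
  if (!any(sel)) abort(sprintf("band [%g, %g) intersects no grid frequency", band[1], band[2]))
  out <- apply(gamma[, , sel, drop = FALSE], c(1, 2), mean)
  dimnames(out) <- list(labels, labels)
  out
}

#' Global connectivity strength
#'
#' Mean of the off-diagonal entries of a band-averaged DTF matrix,
#' `sum_{i} sum_{j != i} gamma_ij / (n (n - 1))`.
#'
#' @param band_gamma k x k band-averaged DTF matrix, k >= 2.
#' @return Scalar in `[0, 1]`.
#' @export
global_dtf <- function(band_gamma) {
  n <- nrow(band_gamma)
  if (is.null(n) || n < 2 || n != ncol(band_gamma)) {
    abort("band_gamma must be a square matrix with at least 2 channels")
  }
  (sum(band_gamma) - sum(diag(band_gamma))) / (n * (n - 1))
}

#' Per-channel (node) connectivity strength
#'
#' Average in+out connectivity of one channel:
#' `(1 / (2 (n - 1))) sum_{j != i} (gamma_ji + gamma_ij)`.
#'
#' @param band_gamma k x k band-averaged DTF matrix with channel dimnames.
#' @param channel Channel label or index.
#' @return Scalar.
#' @export
node_dtf <- function(band_gamma, channel) {
  n <- nrow(band_gamma)
  if (is.character(channel)) {
    i <- match(channel, rownames(band_gamma))
    if (is.na(i)) abort(sprintf("unknown channel '%s'", channel))
  } else {
    i <- as.integer(channel)
    if (i < 1 || i > n) abort("channel index out of range")
  }
  (sum(band_gamma[i, -i]) + sum(band_gamma[-i, i])) / (2 * (n - 1))
}

#' Region-pair connectivity strength
#'
#' Mean DTF over sink channels in region `sink` and source channels in region
#' `source`. For within-region pairs (`sink == source`) the diagonal entries
#' are excluded (self-connectivity is undefined for the DTF).
#'
#' @param band_gamma k x k band-averaged DTF matrix with channel dimnames.
#' @param regions Region map (see [default_region_map()]).
#' @param source Source region label (the sending cluster).
#' @param sink Sink region label (the receiving cluster).
#' @return Scalar.
#' @export
region_dtf <- function(band_gamma, regions, source, sink) {
  if (source == "unassigned" || sink == "unassigned") {
    abort("region connectivity is undefined for unassigned channels")
  }
  src <- intersect(region_channels(regions, source), colnames(band_gamma))
  snk <- intersect(region_channels(regions, sink), rownames(band_gamma))
  if (length(src) == 0 || length(snk) == 0) {
    abort("source/sink region has no channels in the DTF matrix")
  }
  sub <- band_gamma[snk, src, drop = FALSE]
  if (source == sink) {
    keep <- outer(snk, src, FUN = "!=")
    if (!any(keep)) abort("within-region pair has no off-diagonal entries")
    mean(sub[keep])
  } else {
    mean(sub)
  }
}

#' Hub-region outflow and inflow
#'
#' `dtf_out` is the mean over sink regions k != hub of the region-pair
#' connectivity with source = hub; `dtf_in` the mean over source regions
#' l != hub with sink = hub.
#'
#' @param band_gamma k x k band-averaged DTF matrix with channel dimnames.
#' @param regions Region map.
#' @param hub Hub region label (default `"F"`, the frontal cluster).
#' @return Named list with `dtf_out` and `dtf_in`.
#' @export
hub_flows <- function(band_gamma, regions, hub = "F") {
  present <- setdiff(unique(regions$region[regions$channel %in% rownames(band_gamma)]),
                     "unassigned")
  others <- setdiff(present, hub)
  if (!(hub %in% present) || length(others) == 0) {
    abort("hub_flows needs the hub region plus at least one other region")
  }
  list(
    dtf_out = mean(vapply(others, function(k) region_dtf(band_gamma, regions, hub, k), 0)),
    dtf_in = mean(vapply(others, function(l) region_dtf(band_gamma, regions, l, hub), 0))
  )
}

#' All connectivity aggregates of one band-averaged DTF matrix
#'
#' Convenience wrapper computing the global strength, every node strength,
#' the full region-pair matrix and the hub in/out flows.
#'
#' @inheritParams hub_flows
#' @return A list with `dtf_g`, `dtf_i` (tibble channel/value), `dtf_kl`
#'   (tibble sink/source/value) and `dtf_out`/`dtf_in` for the hub region.
#' @export
dtf_aggregates <- function(band_gamma, regions = default_region_map(rownames(band_gamma)),
                           hub = "F") {
  labels <- rownames(band_gamma)
  nodes <- tibble(
    channel = labels,
    value = vapply(labels, function(ch) node_dtf(band_gamma, ch), 0)
  )
  present <- setdiff(unique(regions$region[regions$channel %in% labels]), "unassigned")
  pairs <- expand.grid(sink = present, source = present, stringsAsFactors = FALSE)
  # a within-region pair needs at least two channels for its off-diagonal mean
  n_per_region <- vapply(present, function(r)
    sum(regions$channel[regions$region == r] %in% labels), 0L)
  pairs <- pairs[pairs$sink != pairs$source | n_per_region[pairs$sink] >= 2, ]
  pairs$value <- mapply(function(s, k) region_dtf(band_gamma, regions, s, k),
                        pairs$source, pairs$sink)
  flows <- hub_flows(band_gamma, regions, hub)
  list(dtf_g = global_dtf(band_gamma), dtf_i = nodes,
       dtf_kl = as_tibble(pairs), dtf_out = flows$dtf_out, dtf_in = flows$dtf_in)
}

#' @export
tidy.dtf_result <- function(x, band = NULL, ...) {
  if (is.null(band)) {
    gamma <- apply(x$gamma, c(1, 2), mean)
  } else {
    gamma <- band_average_dtf(x, band)
  }
  grid <- expand.grid(sink = x$channel_labels, source = x$channel_labels,
                      stringsAsFactors = FALSE)
  tibble(sink = grid$sink, source = grid$source, value = as.vector(gamma))
}

#' @export
glance.dtf_result <- function(x, band = c(4, 8),
                              regions = default_region_map(x$channel_labels),
                              hub = "F", ...) {
  bg <- band_average_dtf(x, band)
  agg <- dtf_aggregates(bg, regions, hub)
  tibble(dtf_g = agg$dtf_g, dtf_out = agg$dtf_out, dtf_in = agg$dtf_in,
         band_low = band[1], band_high = band[2], hub = hub)
}
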