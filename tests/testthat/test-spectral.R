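test_that("PSD of a pure sine satisfies Parseval and is concentrated", {
  fs <- 256
  rec <- sine_recording(6, fs = fs, dur = 10)
  psd <- stft_psd(rec)                       # default 0.4 s Hamming, 0.5 Hz grid
  df <- psd$freq[2] - psd$freq[1]
  expect_equal(df, 0.5)
  total <- sum(psd$psd) * df
  expect_lt(abs(total - 0.5) / 0.5, 0.05)    # mean power of a unit sine

  # concentration assessed at a 2 s window, where the Hamming main lobe is
  # narrower than the +-0.5 Hz target band
  psd2 <- stft_psd(rec, spectral_config(window_length = 2))
  sel <- psd2$freq >= 5.5 & psd2$freq <= 6.5
  expect_gt(sum(psd2$psd[, sel]) / sum(psd2$psd), 0.9)

  bp <- band_power(psd)
  theta <- bp$power[bp$band == "theta"]
  expect_true(all(theta > bp$power[bp$band != "theta"]))
})

test_that("PSD of zero input is zero and white noise is flat", {
  fs <- 256
  zero <- recording(matrix(0, 2, fs * 4), fs, c("a", "b"))
  expect_true(all(stft_psd(zero)$psd == 0))

  set.seed(11)
  epochs <- matrix_epochs(matrix(rnorm(fs * 100), 1), fs, 100)
  psd <- stft_psd(epochs)
  inner <- psd$psd[1, 2:(length(psd$freq) - 1)]
  expect_lt(abs(mean(inner) - 1 / (fs / 2)) / (1 / (fs / 2)), 0.1)
  expect_lt(max(abs(inner - mean(inner))) / mean(inner), 0.5)
})

test_that("fast and reference Welch paths agree", {
  set.seed(12)
  x <- matrix(rnorm(3 * 1000), 3)
  cfg <- spectral_config()
  fast <- thetadtf:::welch_psd_matrix(x, 256, cfg)
  # force the mvfft fallback with a non-power-of-two FFT length
  cfg2 <- spectral_config(freq_resolution = 0.5)
  fallback <- thetadtf:::welch_psd_matrix(x, 250, cfg2)  # nfft = 500
  expect_equal(dim(fast$psd), c(3L, 257L))
  expect_equal(dim(fallback$psd), c(3L, 251L))
  # direct cross-check on equal grids: nfft 512 via R path
  w <- thetadtf:::taper_window("hamming", round(0.4 * 256))
  L <- length(w); hop <- round(L * 0.5)
  starts <- seq(1, 1000 - L + 1, by = hop)
  ref <- matrix(0, 3, 257)
  for (s in starts) {
    seg <- x[, s:(s + L - 1), drop = FALSE] * rep(w, each = 3)
    sp <- Mod(t(stats::mvfft(t(cbind(seg, matrix(0, 3, 512 - L))))))^2
    ref <- ref + sp[, 1:257]
  }
  ref <- ref / (length(starts) * 256 * sum(w^2))
  ref[, 2:256] <- 2 * ref[, 2:256]
  expect_equal(fast$psd, ref, tolerance = 1e-10)
})

test_that("PSD scales quadratically with amplitude and is additive", {
  set.seed(13)
  fs <- 256
  x <- matrix(rnorm(fs * 20), 1)
  r1 <- recording(x, fs, "a")
  r3 <- recording(3 * x, fs, "a")
  expect_equal(stft_psd(r3)$psd, 9 * stft_psd(r1)$psd, tolerance = 1e-10)

  ep_a <- matrix_epochs(matrix(rnorm(fs * 100), 1), fs, 100)
  set.seed(14)
  b <- matrix(rnorm(fs * 100), 1)
  ep_b <- matrix_epochs(b, fs, 100)
  ep_ab <- matrix_epochs(ep_a$data[1, , ] |> as.vector() |> matrix(nrow = 1) + b,
                         fs, 100)
  pa <- stft_psd(ep_a)$psd + stft_psd(ep_b)$psd
  pab <- stft_psd(ep_ab)$psd
  inner <- 2:200
  expect_lt(mean(abs(pab[inner] - pa[inner]) / pa[inner]), 0.1)
})

test_that("band_power averages bins per half-open band", {
  psd <- structure(list(freq = seq(0, 127.5, by = 0.5),
                        psd = matrix(2, 1, 256),
                        channel_labels = "a", fs = 256),
                   class = "psd_estimate")
  bp <- band_power(psd)
  expect_true(all(bp$power == 2))
  narrow <- band_scheme(data.frame(band = "x", low = 200, high = 210))
  expect_error(band_power(psd, narrow), "no frequency bins")
  # 8 Hz belongs to alpha, not theta, under the half-open convention
  psd$psd[1, ] <- 0
  psd$psd[1, psd$freq == 8] <- 100
  bp2 <- band_power(psd)
  expect_equal(bp2$power[bp2$band == "theta"], 0)
  expect_gt(bp2$power[bp2$band == "alpha"], 0)
})

test_that("wm_efficiency is exact element-wise subtraction", {
  bp <- function(p) tibble::tibble(channel = c("a", "b"), band = "theta", power = p)
  eq <- wm_efficiency(bp(c(3, 4)), bp(c(3, 4)))
  expect_true(all(eq$p_wm == 0))
  out <- wm_efficiency(bp(c(10, 10)), bp(c(4, 12)))
  expect_equal(out$p_wm, c(6, -2))
  expect_error(wm_efficiency(bp(c(1, 2)),
                             tibble::tibble(channel = "c", band = "theta", power = 1)),
               "grid")
})

test_that("task and rest drawn from one process give near-zero mean p_wm", {
  set.seed(15)
  fs <- 128
  coeffs <- diag_ar2_coeffs(1, 6, 0.9, fs)
  p_wm <- vapply(1:40, function(i) {
    task <- simulate_mvar_eeg(coeffs, 1, fs * 10, fs, seed = 1000 + i)
    rest <- simulate_mvar_eeg(coeffs, 1, fs * 10, fs, seed = 5000 + i)
    out <- wm_efficiency(band_power(stft_psd(task)), band_power(stft_psd(rest)))
    out$p_wm[out$band == "theta"]
  }, 0)
  expect_lt(abs(mean(p_wm)), 2 * sd(p_wm) / sqrt(length(p_wm)))
})

test_that("prominent_band takes the argmax with a logged low-frequency tie-break", {
  tab <- tibble::tibble(band = factor(c("delta", "theta", "alpha", "beta", "gamma"),
                                      levels = c("delta", "theta", "alpha", "beta", "gamma")),
                        power = c(1, 5, 2, 1, 0.5))
  expect_equal(prominent_band(tab), "theta")
  expect_equal(prominent_band(dplyr::mutate(tab, power = power * 100)), "theta")
  tie <- dplyr::mutate(tab, power = c(1, 5, 5, 1, 0.5))
  expect_message(out <- prominent_band(tie), "tie")
  expect_equal(out, "theta")
  expect_error(prominent_band(dplyr::mutate(tab, power = c(1, NA, 2, 1, 1))),
               "finite")
})

test_that("the theta-resonant generator yields theta as the prominent band per subject", {
  res <- fixture_analysis()
  rate <- mean(res$prominent$per_subject$prominent_band == "theta")
  expect_gte(rate, 0.95)
})

test_that("region_power matches a brute-force loop and ignores unassigned channels", {
  set.seed(16)
  labels <- default_montage()
  vals <- tibble::tibble(channel = labels, power = rnorm(34))
  rm <- default_region_map()
  rp <- region_power(vals)
  for (r in c("F", "C", "O", "T")) {
    manual <- mean(vals$power[vals$channel %in% rm$channel[rm$region == r]])
    expect_equal(rp$power[rp$region == r], manual)
  }
  const <- dplyr::mutate(vals, power = 7)
  expect_true(all(region_power(const)$power == 7))
  bumped <- vals
  bumped$power[bumped$channel %in% c("F7", "F8")] <- 1e6
  expect_equal(region_power(bumped)$power, rp$power)
  expect_error(region_power(vals[1:3, ]), "no channels")
})
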