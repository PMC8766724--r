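test_that("white noise fits to a near-null MVAR model", {
  set.seed(21)
  coeffs <- array(0, dim = c(2, 2, 1), dimnames = list(c("a", "b"), c("a", "b"), NULL))
  rec <- simulate_mvar_eeg(coeffs, 1, 50000, 256, seed = 99)
  fit <- fit_mvar(rec, order = 1)
  se <- 1 / sqrt(fit$n_obs)          # asymptotic SE of an AR coefficient at 0
  expect_true(all(abs(fit$coeffs) < 3.5 * se))
  expect_true(all(abs(fit$coeffs) < 0.05))
})

test_that("a known 2-channel order-2 model is recovered from a long simulation", {
  truth <- array(0, dim = c(2, 2, 2), dimnames = list(c("a", "b"), c("a", "b"), NULL))
  truth[, , 1] <- matrix(c(0.6, 0.3, 0, 0.5), 2)   # a->b coupling at lag 1
  truth[, , 2] <- matrix(c(-0.2, 0, 0, -0.1), 2)
  expect_true(is_stable(truth))
  rec <- simulate_mvar_eeg(truth, c(1, 1), 50000, 256, seed = 7)
  fit <- fit_mvar(rec, order = 2)
  expect_lt(max(abs(fit$coeffs - truth)), 0.05)
  expect_equal(dim(fit$noise_cov), c(2L, 2L))
  expect_lt(max(abs(fit$noise_cov - diag(2))), 0.05)
})

test_that("BIC auto order recovers an order-3 generator in most seeds", {
  truth <- array(0, dim = c(2, 2, 3))
  truth[, , 1] <- matrix(c(0.4, 0.2, 0, 0.3), 2)
  truth[, , 2] <- matrix(c(-0.3, 0, 0.1, -0.2), 2)
  truth[, , 3] <- matrix(c(0.25, 0, 0, 0.3), 2)
  dimnames(truth) <- list(c("a", "b"), c("a", "b"), NULL)
  expect_true(is_stable(truth))
  hits <- vapply(1:50, function(s) {
    rec <- simulate_mvar_eeg(truth, 1, 5000, 100, seed = 3000 + s)
    fit <- suppressMessages(fit_mvar(rec, order = "auto", max_order = 8))
    fit$order == 3L
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("fit_mvar flags short data and rank deficiency", {
  set.seed(22)
  rec <- recording(matrix(rnorm(2 * 120), 2), 100, c("a", "b"))
  expect_warning(fit_mvar(rec, order = 6), "lower order")
  dup <- recording(rbind(rec$data, rec$data[1, , drop = FALSE]), 100,
                   c("a", "b", "c"))
  expect_error(suppressWarnings(fit_mvar(dup, order = 2)), "rank-deficient")
})

test_that("transfer matrix matches closed forms", {
  null2 <- array(0, dim = c(2, 2, 1), dimnames = list(c("a", "b"), c("a", "b"), NULL))
  H <- transfer_matrix(null2, c(0, 5, 20), fs = 100)
  for (i in 1:3) expect_equal(H[, , i], diag(2) + 0i, ignore_attr = TRUE)

  diag2 <- diag_ar2_coeffs(2, c(5, 9), 0.8, 100)
  Hd <- transfer_matrix(diag2, c(2, 8), fs = 100)
  expect_true(all(abs(Hd[1, 2, ]) == 0 & abs(Hd[2, 1, ]) == 0))

  # closed-form 2x2 inversion for a unidirectional system
  uni <- array(0, dim = c(2, 2, 1), dimnames = list(c("a", "b"), c("a", "b"), NULL))
  uni[1, 1, 1] <- 0.5; uni[2, 2, 1] <- 0.4; uni[2, 1, 1] <- 0.7
  freqs <- c(1, 7, 30)
  Hu <- transfer_matrix(uni, freqs, fs = 100)
  for (fi in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[fi] / 100)
    Amat <- matrix(c(1 - 0.5 * z, -0.7 * z, 0, 1 - 0.4 * z), 2)
    det <- Amat[1, 1] * Amat[2, 2] - Amat[1, 2] * Amat[2, 1]
    Hexp <- matrix(c(Amat[2, 2], -Amat[2, 1], -Amat[1, 2], Amat[1, 1]), 2) / det
    expect_lt(max(Mod(Hu[, , fi] - Hexp)), 1e-10)
  }
  expect_error(transfer_matrix(null2, 60, fs = 100), "Nyquist")
})

test_that("DTF rows are stochastic and reflect coupling direction", {
  diag2 <- diag_ar2_coeffs(3, c(4, 6, 8), 0.85, 100)
  g <- dtf(diag2, seq(0.5, 49.5, by = 0.5), fs = 100)
  for (fi in seq_along(g$freq_grid)) {
    expect_equal(g$gamma[, , fi], diag(3), ignore_attr = TRUE, tolerance = 1e-12)
  }

  uni <- array(0, dim = c(2, 2, 1), dimnames = list(c("a", "b"), c("a", "b"), NULL))
  uni[1, 1, 1] <- 0.5; uni[2, 2, 1] <- 0.4; uni[2, 1, 1] <- 0.7
  gu <- dtf(uni, seq(0.5, 49.5, by = 0.5), fs = 100)
  # no b -> a influence: zero up to squared double-precision rounding
  expect_lt(max(gu$gamma[1, 2, ]), 1e-30)
  expect_true(all(gu$gamma[2, 1, ] > 0))           # a -> b at every frequency
  sums <- apply(gu$gamma, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
})

test_that("band-averaged DTF equals the brute-force bin mean", {
  set.seed(23)
  freq <- seq(0, 49.5, by = 0.5)
  gamma <- array(runif(3 * 3 * length(freq)), dim = c(3, 3, length(freq)))
  res <- structure(list(gamma = gamma, freq_grid = freq,
                        channel_labels = c("a", "b", "c")),
                   class = "dtf_result")
  sel <- which(freq >= 4 & freq < 8)
  manual <- apply(gamma[, , sel], c(1, 2), mean)
  expect_equal(unname(band_average_dtf(res, c(4, 8))), manual)
  const <- res; const$gamma[] <- 0.25
  expect_true(all(band_average_dtf(const, c(4, 8)) == 0.25))
  expect_equal(unname(band_average_dtf(res, c(0, 50))),
               apply(gamma, c(1, 2), mean))
  expect_error(band_average_dtf(res, c(60, 70)), "intersects")
})

test_that("global, node and region aggregation match brute-force loops", {
  set.seed(24)
  labels <- default_montage(16L)
  k <- length(labels)
  bg <- matrix(runif(k * k), k, dimnames = list(labels, labels))

  manual_g <- 0
  for (i in 1:k) for (j in 1:k) if (i != j) manual_g <- manual_g + bg[i, j]
  expect_equal(global_dtf(bg), manual_g / (k * (k - 1)))
  expect_equal(global_dtf(diag(4)), 0)
  cmat <- matrix(0.3, 4, 4); diag(cmat) <- 1
  expect_equal(global_dtf(cmat), 0.3)

  for (i in c(1, 5, k)) {
    manual_i <- 0
    for (j in 1:k) if (j != i) manual_i <- manual_i + bg[j, i] + bg[i, j]
    expect_equal(node_dtf(bg, labels[i]), manual_i / (2 * (k - 1)))
  }
  expect_equal(node_dtf(cmat[1:2, 1:2], 1), (cmat[1, 2] + cmat[2, 1]) / 2)
  expect_error(node_dtf(bg, "nope"), "unknown channel")

  rm <- default_region_map(labels)
  for (pair in list(c("F", "O"), c("T", "C"), c("F", "F"))) {
    src <- rm$channel[rm$region == pair[1]]
    snk <- rm$channel[rm$region == pair[2]]
    manual <- c()
    for (i in snk) for (j in src) if (i != j) manual <- c(manual, bg[i, j])
    expect_equal(region_dtf(bg, rm, source = pair[1], sink = pair[2]),
                 mean(manual))
  }
  unif <- matrix(0.2, k, k, dimnames = list(labels, labels))
  expect_equal(region_dtf(unif, rm, "F", "O"), 0.2)
  expect_error(region_dtf(bg, rm, "unassigned", "F"), "unassigned")
})

test_that("hub flows reduce to known symmetric cases and brute force", {
  labels <- default_montage(16L)
  rm <- default_region_map(labels)
  k <- length(labels)
  unif <- matrix(0.4, k, k, dimnames = list(labels, labels))
  fl <- hub_flows(unif, rm, "F")
  expect_equal(fl$dtf_out, 0.4)
  expect_equal(fl$dtf_in, 0.4)

  set.seed(25)
  sym <- matrix(runif(k * k), k); sym <- (sym + t(sym)) / 2
  dimnames(sym) <- list(labels, labels)
  fs <- hub_flows(sym, rm, "F")
  expect_equal(fs$dtf_out, fs$dtf_in)

  bg <- matrix(runif(k * k), k, dimnames = list(labels, labels))
  manual_out <- mean(vapply(c("C", "O", "T"),
                            function(r) region_dtf(bg, rm, "F", r), 0))
  expect_equal(hub_flows(bg, rm, "F")$dtf_out, manual_out)
})

test_that("DTF is equivariant under channel permutation and amplitude scaling", {
  set.seed(26)
  k <- 4
  labels <- letters[1:k]
  coeffs <- diag_ar2_coeffs(k, c(4, 5, 6, 7), 0.8, 100)
  dimnames(coeffs) <- list(labels, labels, NULL)
  coeffs[2, 1, 1] <- 0.3
  rec <- simulate_mvar_eeg(coeffs, 1, 20000, 100, seed = 42)
  perm <- c(3, 1, 4, 2)
  rec_p <- recording(rec$data[perm, ], 100, labels[perm])
  grid <- seq(1, 48, by = 1)
  g1 <- band_average_dtf(dtf(fit_mvar(rec, 2), grid), c(4, 8))
  g2 <- band_average_dtf(dtf(fit_mvar(rec_p, 2), grid), c(4, 8))
  expect_equal(g2[labels, labels], g1, tolerance = 1e-10)

  rec_s <- recording(rec$data * 5, 100, labels)
  g3 <- band_average_dtf(dtf(fit_mvar(rec_s, 2), grid), c(4, 8))
  expect_equal(g3, g1, tolerance = 1e-8)
})

test_that("fitted DTF matches the generator DTF on small systems", {
  coeffs <- diag_ar2_coeffs(3, c(5, 6, 7), 0.85, 128)
  coeffs[2, 1, 1] <- 0.25
  coeffs[3, 2, 1] <- 0.2
  expect_true(is_stable(coeffs))
  grid <- seq(0.5, 63.5, by = 0.5)
  g_true <- band_average_dtf(dtf(coeffs, grid, fs = 128), c(4, 8))
  rec <- simulate_mvar_eeg(coeffs, 1, 50000, 128, seed = 91)
  g_fit <- band_average_dtf(dtf(fit_mvar(rec, 2), grid), c(4, 8))
  expect_lt(max(abs(g_fit - g_true)), 0.02)
})

test_that("tidy and glance summarize fitted objects", {
  rec <- simulate_mvar_eeg(diag_ar2_coeffs(2, c(5, 7), 0.8, 100), 1, 5000, 100,
                           seed = 17)
  fit <- fit_mvar(rec, 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 2 * 2)
  expect_named(td, c("target", "source", "lag", "estimate"))
  gl <- glance(fit)
  expect_equal(gl$order, 2L)
  expect_lt(gl$spectral_radius, 1)

  g <- dtf(fit, seq(1, 49, by = 1))
  tg <- tidy(g, band = c(4, 8))
  expect_equal(nrow(tg), 4)

  named <- diag_ar2_coeffs(2, c(5, 7), 0.8, 100)
  dimnames(named) <- list(c("Fz", "Oz"), c("Fz", "Oz"), NULL)
  rec2 <- simulate_mvar_eeg(named, 1, 5000, 100, seed = 18)
  g2 <- dtf(fit_mvar(rec2, 2), seq(1, 49, by = 1))
  gg <- glance(g2, band = c(4, 8))
  expect_named(gg, c("dtf_g", "dtf_out", "dtf_in", "band_low", "band_high", "hub"))
})
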