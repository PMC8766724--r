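test_that("the degenerate generator reproduces white noise", {
  coeffs <- array(0, dim = c(2, 2, 1), dimnames = list(c("a", "b"), c("a", "b"), NULL))
  rec <- simulate_mvar_eeg(coeffs, 1, 50000, 256, seed = 31)
  v <- apply(rec$data, 1, var)
  expect_true(all(abs(v - 1) < 0.05))
})

test_that("an AR(1) generator shows the closed-form lag-1 autocorrelation", {
  coeffs <- array(0, dim = c(2, 2, 1), dimnames = list(c("a", "b"), c("a", "b"), NULL))
  coeffs[1, 1, 1] <- 0.5; coeffs[2, 2, 1] <- 0.5
  rec <- simulate_mvar_eeg(coeffs, 1, 50000, 256, seed = 32)
  for (i in 1:2) {
    r1 <- cor(rec$data[i, -1], rec$data[i, -50000])
    expect_lt(abs(r1 - 0.5), 0.02)
  }
})

test_that("simulation is deterministic in the seed and validates inputs", {
  coeffs <- diag_ar2_coeffs(3, c(5, 6, 7), 0.9, 128)
  a <- simulate_mvar_eeg(coeffs, 1, 2000, 128, seed = 33)
  b <- simulate_mvar_eeg(coeffs, 1, 2000, 128, seed = 33)
  expect_identical(a$data, b$data)
  c2 <- simulate_mvar_eeg(coeffs, 1, 2000, 128, seed = 34)
  expect_false(identical(a$data, c2$data))

  unstable <- array(0, dim = c(1, 1, 1), dimnames = list("a", "a", NULL))
  unstable[1, 1, 1] <- 1.01
  expect_error(simulate_mvar_eeg(unstable, 1, 1000, 128, seed = 1), "unstable")
  bad <- coeffs; bad[1, 1, 1] <- NA
  expect_error(simulate_mvar_eeg(bad, 1, 1000, 128, seed = 1), "finite")
  expect_error(simulate_mvar_eeg(coeffs, 1, 15, 128, seed = 1), "10 x order")
})

test_that("cohort ground truth respects the construction rules", {
  cfg <- smoke_profile(n_per_group = 3L, seed = 41L)
  gt <- build_cohort_generator(cfg)
  expect_equal(nrow(gt$subjects), 9L)
  expect_false(anyDuplicated(gt$subjects$subject) > 0)
  expect_true(all(gt$subjects$impaired == (gt$subjects$group == "tle_wm")))

  rm <- default_region_map(cfg$channel_labels)
  targets <- setdiff(c(rm$channel[rm$region == "F"], rm$channel[rm$region == "O"]),
                     "Fz")
  non_targets <- setdiff(cfg$channel_labels, c(targets, "Fz"))
  for (s in seq_len(9)) {
    cc <- gt$coupling[[s]]$task
    expect_true(thetadtf:::mvar_spectral_radius(cc) < 1)
    expect_true(thetadtf:::mvar_spectral_radius(gt$coupling[[s]]$rest) < 1)
    # hub-column terms beyond the weak background only for target channels
    # (impaired subjects keep the scaled-down gains on the same rows)
    hub_col <- cc[, "Fz", 1]
    floor_gain <- if (gt$subjects$impaired[s]) 0.005 else 0.01
    expect_true(all(abs(hub_col[targets]) > floor_gain))
    expect_true(all(abs(hub_col[non_targets]) < 0.005))
  }
})

test_that("the impairment factor scales the hub-outflow block exactly", {
  # identical seeds consume the RNG identically, so a zero-gain run isolates
  # the shared background and the runs differ only in the hub-outflow gains
  gt_full <- build_cohort_generator(
    smoke_profile(n_per_group = 2L, seed = 42L, impairment_factor = 1))
  gt_half <- build_cohort_generator(
    smoke_profile(n_per_group = 2L, seed = 42L, impairment_factor = 0.5))
  gt_zero <- build_cohort_generator(
    smoke_profile(n_per_group = 2L, seed = 42L, coupling_gain = 0))
  rm <- default_region_map(default_montage(16L))
  targets <- setdiff(c(rm$channel[rm$region == "F"], rm$channel[rm$region == "O"]),
                     "Fz")
  for (s in which(gt_full$subjects$impaired)) {
    g_full <- gt_full$coupling[[s]]$task[targets, "Fz", 1] -
      gt_zero$coupling[[s]]$task[targets, "Fz", 1]
    g_half <- gt_half$coupling[[s]]$task[targets, "Fz", 1] -
      gt_zero$coupling[[s]]$task[targets, "Fz", 1]
    expect_equal(g_half, 0.5 * g_full, tolerance = 1e-12)
    expect_equal(sqrt(sum(g_half^2)), 0.5 * sqrt(sum(g_full^2)),
                 tolerance = 1e-12)
  }
  for (s in which(!gt_full$subjects$impaired)) {
    expect_identical(gt_full$coupling[[s]]$task, gt_half$coupling[[s]]$task)
  }
})

test_that("decreasing the impairment factor weakly decreases hub outflow", {
  rm <- default_region_map(default_montage(16L))
  targets <- setdiff(c(rm$channel[rm$region == "F"], rm$channel[rm$region == "O"]),
                     "Fz")
  gt_zero <- build_cohort_generator(
    smoke_profile(n_per_group = 2L, seed = 43L, coupling_gain = 0))
  norms <- vapply(c(1, 0.7, 0.4), function(f) {
    gt <- build_cohort_generator(smoke_profile(n_per_group = 2L, seed = 43L,
                                               impairment_factor = f))
    s <- which(gt$subjects$impaired)[1]
    gains <- gt$coupling[[s]]$task[targets, "Fz", 1] -
      gt_zero$coupling[[s]]$task[targets, "Fz", 1]
    sqrt(sum(gains^2))
  }, 0)
  expect_true(all(diff(norms) < 0))
})

test_that("simulated channels resonate in the configured band", {
  cfg <- smoke_profile(n_per_group = 1L, seed = 44L)
  gt <- build_cohort_generator(cfg)
  ses <- thetadtf:::simulate_subject_session(gt, "S001", 4242L)
  task_ev <- ses$events[ses$events$phase == "encoding", ]
  ep <- extract_epochs(ses$recording, ses$events, "encoding")
  psd <- stft_psd(ep)
  peak <- psd$freq[apply(psd$psd, 1, which.max)]
  expect_true(all(peak >= 4 & peak < 8))
})

test_that("behavior simulation links RT/ACC to the latent factor and group", {
  cfg <- smoke_profile(n_per_group = 15L, seed = 45L)
  gt <- build_cohort_generator(cfg)
  beh <- simulate_behavior(gt, cfg)
  expect_equal(nrow(beh), 45 * 60)
  expect_true(all(is.na(beh$rt_ms[!beh$correct])))
  expect_true(all(!is.na(beh$rt_ms[beh$correct])))
  expect_true(all(table(beh$subject) == 60))

  summ <- summarize_behavior(beh) |>
    dplyr::left_join(gt$subjects, by = "subject")
  imp <- summ$group == "tle_wm"
  expect_gt(mean(summ$mean_rt_correct[imp]), mean(summ$mean_rt_correct[!imp]))
  expect_lt(mean(summ$acc[imp]), mean(summ$acc[!imp]))
  # latent factor drives RT downwards among unimpaired subjects
  r <- cor(summ$latent_theta[!imp], summ$mean_rt_correct[!imp])
  expect_lt(r, 0)
})

test_that("null behavior (no link, no shift) gives uniform two-sample p-values", {
  pvals <- vapply(1:200, function(s) {
    cfg <- smoke_profile(n_per_group = 10L, seed = 70000 + s,
                         behavior_link = 0, rt_impair_shift_sd = 0,
                         acc_impair_drop = 0)
    gt <- build_cohort_generator(cfg)
    summ <- summarize_behavior(simulate_behavior(gt, cfg)) |>
      dplyr::left_join(gt$subjects, by = "subject")
    t.test(summ$mean_rt_correct[summ$group == "con"],
           summ$mean_rt_correct[summ$group == "tle_wm"],
           var.equal = TRUE)$p.value
  }, 0)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("accuracy clipping warns instead of producing invalid probabilities", {
  cfg <- smoke_profile(n_per_group = 2L, seed = 46L, acc_base = 0.9,
                       acc_impair_drop = 0.95)
  gt <- build_cohort_generator(cfg)
  expect_warning(beh <- simulate_behavior(gt, cfg), "clipped")
  summ <- summarize_behavior(beh)
  expect_true(all(summ$acc >= 0 & summ$acc <= 1))
})

test_that("cohorts are deterministic under a fixed configuration", {
  cfg <- smoke_profile(n_per_group = 2L, rest_duration = 5, n_trials = 4L,
                       seed = 47L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$recordings$S001$data, b$recordings$S001$data)
  expect_identical(a$behavior, b$behavior)
})

test_that("written cohorts round-trip and manifest bookkeeping holds", {
  cfg <- smoke_profile(n_per_group = 2L, rest_duration = 5, n_trials = 4L,
                       seed = 48L)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "cohort")
  write_cohort(co, out)
  expect_error(write_cohort(co, out), "not empty")
  expect_silent(write_cohort(co, out, overwrite = TRUE))

  manifest <- jsonlite::read_json(file.path(out, "cohort_manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(length(manifest$subjects), 3 * 2)

  back <- read_cohort(out)
  expect_identical(unname(back$recordings$S001$data),
                   unname(co$recordings$S001$data))
  expect_equal(back$behavior$rt_ms, co$behavior$rt_ms)

  # EDF layout round-trips within quantization
  out2 <- file.path(dir, "cohort_edf")
  write_cohort(co, out2, format = "edf")
  back2 <- read_cohort(out2)
  ref <- co$recordings$S002$data
  step <- max(apply(ref, 1, function(x) (max(x) - min(x)) / 65535))
  expect_lt(max(abs(back2$recordings$S002$data - ref)), step * 0.51)

  unlink(file.path(out, "S001"), recursive = TRUE)
  expect_error(read_cohort(out), "S001")
})
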