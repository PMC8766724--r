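#' Pipeline settings
#'
#' Bundles every knob of the analysis stage. The configuration is fully
#' serializable (YAML/JSON) and an echoed copy is written into every results
#' directory.
#'
#' @param spectral A [spectral_config()].
#' @param bands A [band_scheme()].
#' @param mvar_order MVAR lag order for connectivity, or `"auto"` (BIC over
#'   1..20). The default 2 matches the oscillatory-pair process class the
#'   synthetic generator emulates; real data should use `"auto"`.
#' @param dtf_band Frequency band (Hz) for DTF band-averaging (default theta,
#'   `c(4, 8)`).
#' @param hub_region Hub region for outflow/inflow aggregation (default
#'   `"F"`).
#' @param phenotype_threshold Z-score cutoff of the impairment rule
#'   (default 1.5 control SDs).
#' @param lowpass,notch,car,drift Preprocessing options passed to
#'   [preprocess_recording()]; set `lowpass`/`notch`/`drift` to `NULL` to
#'   skip a step. `car` applies to the spectral path.
#' @param car_connectivity Re-reference before the MVAR fit as well? Default
#'   `FALSE`: exact common average referencing leaves the channels linearly
#'   dependent, which makes the full-channel MVAR regression singular, so
#'   connectivity is estimated in the original reference.
#' @param alpha Significance level used in report annotations.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spectral = spectral_config(), bands = band_scheme(),
                            mvar_order = 2L, dtf_band = c(4, 8),
                            hub_region = "F", phenotype_threshold = 1.5,
                            lowpass = 100, notch = c(49, 51), car = TRUE,
                            car_connectivity = FALSE,
                            drift = "linear_detrend", alpha = 0.05) {
  structure(
    list(spectral = spectral, bands = bands, mvar_order = mvar_order,
         dtf_band = dtf_band, hub_region = hub_region,
         phenotype_threshold = phenotype_threshold, lowpass = lowpass,
         notch = notch, car = car, car_connectivity = car_connectivity,
         drift = drift, alpha = alpha),
    class = "pipeline_config"
  )
}

# Serializable echo of a pipeline config.
config_echo <- function(config) {
  list(
    spectral = unclass(config$spectral),
    bands = as.data.frame(config$bands[, c("band", "low", "high")]),
    mvar_order = config$mvar_order, dtf_band = config$dtf_band,
    hub_region = config$hub_region,
    phenotype_threshold = config$phenotype_threshold,
    lowpass = config$lowpass, notch = config$notch, car = config$car,
    car_connectivity = config$car_connectivity,
    drift = config$drift, alpha = config$alpha,
    version = as.character(utils::packageVersion("thetadtf"))
  )
}

#' Simulate a cohort and write it to disk
#'
#' @param sim_config A [simulation_config()].
#' @param out_dir Output directory for the cohort.
#' @param format `"csv"` or `"edf"`.
#' @param overwrite Passed to [write_cohort()].
#' @return The cohort directory, invisibly.
#' @export
run_simulate <- function(sim_config = simulation_config(), out_dir,
                         format = "csv", overwrite = FALSE) {
  cohort <- simulate_cohort(sim_config)
  write_cohort(cohort, out_dir, format = format, overwrite = overwrite)
  invisible(out_dir)
}

# Analyze one subject: preprocess -> encoding epochs + rest -> band power ->
# p_wm -> MVAR -> DTF aggregates. The common average reference is applied on
# the spectral path only: exact CAR leaves the channels linearly dependent
# (they sum to zero at every sample), which makes a full-channel MVAR
# regression singular, so directed connectivity is estimated in the original
# reference (set car_connectivity = TRUE to override).
analyze_subject <- function(rec, events, config, regions) {
  base <- preprocess_recording(rec, lowpass = config$lowpass,
                               notch = config$notch, car = FALSE,
                               drift = config$drift)
  rec_spec <- if (isTRUE(config$car)) common_average_reference(base) else base
  rec_conn <- if (isTRUE(config$car_connectivity))
    common_average_reference(base) else base
  epochs <- extract_epochs(rec_conn, events, "encoding")
  epochs_spec <- extract_epochs(rec_spec, events, "encoding")
  rest_ev <- events[events$phase == "rest", , drop = FALSE]
  if (nrow(rest_ev) != 1) abort("expected exactly one rest event")
  rest_idx <- (rest_ev$onset_sample + 1):(rest_ev$onset_sample + rest_ev$duration_samples)
  rest <- recording_unsafe(rec_spec$data[, rest_idx, drop = FALSE], rec_spec$fs,
                    rec_spec$channel_labels, rec_spec$subject_id)

  psd_task <- stft_psd(epochs_spec, config$spectral)
  psd_rest <- stft_psd(rest, config$spectral)
  bp <- wm_efficiency(band_power(psd_task, config$bands),
                      band_power(psd_rest, config$bands))
  subject_prominent <- prominent_band(bp, power_col = "p_raw")

  model <- fit_mvar(epochs, order = config$mvar_order)
  # gamma is row-normalized per frequency, so band-averaged DTF only needs
  # the grid frequencies inside the analysis band
  grid <- seq(0, rec$fs / 2, by = config$spectral$freq_resolution)
  grid <- grid[grid < rec$fs / 2]
  band_grid <- grid[grid >= config$dtf_band[1] & grid < config$dtf_band[2]]
  gamma <- dtf(model, band_grid)
  bg <- band_average_dtf(gamma, config$dtf_band)
  agg <- dtf_aggregates(bg, regions, config$hub_region)

  list(band_power = bp, prominent_band = subject_prominent,
       band_gamma = bg, dtf = agg)
}

#' Run the analysis stage over a cohort
#'
#' Per subject: preprocessing, encoding-epoch extraction, task and resting
#' PSD, band powers and baseline-normalized `p_wm`, prominent band, MVAR fit
#' and theta-band DTF aggregates. Cohort level: behavioral phenotyping
#' against the control group (1.5 SD rule) and the full statistical battery
#' over the groups control / performance-normal / performance-impaired.
#'
#' @param cohort A `cohort` from [simulate_cohort()], a `cohort_on_disk` from
#'   [read_cohort()], or a directory path.
#' @param config A [pipeline_config()].
#' @return A list of class `results_bundle`: `band_power`, `prominent`
#'   (per-subject and cohort-level prominent band), `dtf` (per-subject scalar
#'   aggregates), `dtf_i` and `dtf_kl` tibbles, `region_power` (per-subject
#'   region-level theta `p_wm`), `pheno`, `stats`, `manifest`.
#' @export
run_analysis <- function(cohort, config = pipeline_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (inherits(cohort, "cohort")) {
    subjects <- cohort$ground_truth$subjects[, c("subject", "group")]
    recordings <- cohort$recordings
    events <- cohort$events
    behavior <- cohort$behavior
    seed <- cohort$config$seed
  } else if (inherits(cohort, "cohort_on_disk")) {
    subjects <- tibble(subject = cohort$manifest$subjects,
                       group = unlist(cohort$manifest$groups))
    recordings <- cohort$recordings
    events <- cohort$events
    behavior <- cohort$behavior
    seed <- cohort$manifest$seed
  } else {
    abort("cohort must be a cohort, cohort_on_disk or directory path")
  }
  missing <- setdiff(subjects$subject, names(recordings))
  if (length(missing) > 0) {
    abort(sprintf("missing recordings for subjects: %s",
                  paste(missing, collapse = ", ")))
  }
  regions <- default_region_map(recordings[[1]]$channel_labels)

  per_subject <- vector("list", nrow(subjects))
  names(per_subject) <- subjects$subject
  for (s in subjects$subject) {
    per_subject[[s]] <- analyze_subject(recordings[[s]], events[[s]],
                                        config, regions)
  }

  band_power_tab <- purrr::imap_dfr(per_subject, function(res, s) {
    mutate(res$band_power, subject = s, .before = 1)
  })
  prominent_subject <- tibble(
    subject = subjects$subject,
    prominent_band = vapply(per_subject, function(r) r$prominent_band, "")
  )
  cohort_prominent <- prominent_band(
    band_power_tab |> group_by(.data$band) |>
      summarise(power = mean(.data$p_raw), .groups = "drop")
  )
  dtf_tab <- purrr::imap_dfr(per_subject, function(res, s) {
    tibble(subject = s, dtf_g = res$dtf$dtf_g,
           dtf_out = res$dtf$dtf_out, dtf_in = res$dtf$dtf_in)
  })
  dtf_i_tab <- purrr::imap_dfr(per_subject, function(res, s) {
    mutate(res$dtf$dtf_i, subject = s, .before = 1)
  })
  dtf_kl_tab <- purrr::imap_dfr(per_subject, function(res, s) {
    mutate(res$dtf$dtf_kl, subject = s, .before = 1)
  })
  region_tab <- purrr::imap_dfr(per_subject, function(res, s) {
    bp <- filter(res$band_power, .data$band == cohort_prominent)
    mutate(region_power(bp, regions, value_col = "p_wm"), subject = s,
           .before = 1)
  })

  summary_beh <- summarize_behavior(behavior) |>
    left_join(subjects, by = "subject")
  pheno <- phenotype_groups(
    phenotype(summary_beh, threshold = config$phenotype_threshold)
  )

  stats <- cohort_statistics(pheno, band_power_tab, region_tab, dtf_tab,
                             dtf_i_tab, regions, config)

  structure(
    list(band_power = band_power_tab,
         prominent = list(cohort = cohort_prominent,
                          per_subject = prominent_subject),
         dtf = dtf_tab, dtf_i = dtf_i_tab, dtf_kl = dtf_kl_tab,
         region_power = region_tab, pheno = pheno, stats = stats,
         manifest = list(subjects = subjects, seed = seed,
                         config = config_echo(config))),
    class = "results_bundle"
  )
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf(
    "<results_bundle> %d subjects; prominent band: %s; %d omnibus tests, %d correlations\n",
    nrow(x$manifest$subjects), x$prominent$cohort,
    nrow(x$stats$omnibus), nrow(x$stats$correlations)
  ))
  invisible(x)
}

# The cohort-level statistical battery over analysis groups.
cohort_statistics <- function(pheno, band_power_tab, region_tab, dtf_tab,
                              dtf_i_tab, regions, config) {
  joined <- pheno[, c("subject", "analysis_group", "mean_rt_correct", "acc")]
  grp <- function(tab) left_join(tab, joined, by = "subject")

  omnibus <- list(); pairwise <- list(); checks <- list()
  add_anova <- function(values, groups, measure) {
    res <- one_way_anova_lsd(values, groups, measure = measure)
    omnibus[[length(omnibus) + 1]] <<- res$omnibus
    pairwise[[length(pairwise) + 1]] <<- res$pairwise
    smp <- split(values, groups)
    if (all(lengths(smp) >= 3)) {
      ch <- suppressWarnings(assumption_checks(smp))
      checks[[length(checks) + 1]] <<- mutate(ch, measure = measure)
    }
  }

  # Behavior (group contrasts of RT and ACC)
  ok_groups <- length(unique(joined$analysis_group)) >= 2
  if (ok_groups) {
    add_anova(joined$mean_rt_correct, joined$analysis_group, "mean_rt")
    add_anova(joined$acc, joined$analysis_group, "acc")
  }

  # Band power: per-band group contrasts of channel-averaged p_raw,
  # and theta p_wm.
  bp_subj <- band_power_tab |>
    group_by(.data$subject, .data$band) |>
    summarise(p_raw = mean(.data$p_raw), p_wm = mean(.data$p_wm),
              .groups = "drop") |>
    grp()
  if (ok_groups) {
    for (b in levels(bp_subj$band)) {
      sub <- filter(bp_subj, .data$band == b)
      add_anova(sub$p_raw, sub$analysis_group, paste0("psd_", b))
    }
    th <- filter(bp_subj, .data$band == "theta")
    add_anova(th$p_wm, th$analysis_group, "p_wm_theta")
  }

  # Region-level p_wm of the prominent band: across regions within group,
  # and across groups within region.
  reg <- grp(region_tab)
  for (g in unique(reg$analysis_group)) {
    sub <- filter(reg, .data$analysis_group == g)
    if (length(unique(sub$subject)) >= 2) {
      add_anova(sub$power, sub$region, paste0("p_wm_regions_", g))
    }
  }
  if (ok_groups) {
    for (r in unique(reg$region)) {
      sub <- filter(reg, .data$region == r)
      add_anova(sub$power, sub$analysis_group, paste0("p_wm_", r))
    }
  }

  # Connectivity aggregates
  dtfj <- grp(dtf_tab)
  frontal_nodes <- dtf_i_tab |>
    left_join(regions, by = "channel") |>
    filter(.data$region == config$hub_region) |>
    group_by(.data$subject) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    grp()
  if (ok_groups) {
    add_anova(dtfj$dtf_g, dtfj$analysis_group, "dtf_g")
    add_anova(frontal_nodes$value, frontal_nodes$analysis_group, "dtf_node_frontal")
    add_anova(dtfj$dtf_out, dtfj$analysis_group, "dtf_out")
    add_anova(dtfj$dtf_in, dtfj$analysis_group, "dtf_in")
  }

  # Correlations between theta power / connectivity and behavior, per group
  corrs <- list()
  reg_wide <- reg |> tidyr::pivot_wider(names_from = "region",
                                        values_from = "power")
  corr_pair <- function(x, y, measure, group) {
    res <- tryCatch(pearson_corr(x, y, measure = measure),
                    error = function(e) NULL)
    if (!is.null(res)) corrs[[length(corrs) + 1]] <<- mutate(res, group = group)
  }
  for (g in unique(reg_wide$analysis_group)) {
    subp <- filter(reg_wide, .data$analysis_group == g)
    subd <- filter(dtfj, .data$analysis_group == g)
    if (nrow(subp) >= 3) {
      if ("F" %in% names(subp)) {
        corr_pair(subp$F, subp$mean_rt_correct, "p_wm_frontal~rt", g)
        corr_pair(subp$F, subp$acc, "p_wm_frontal~acc", g)
      }
      if ("O" %in% names(subp)) {
        corr_pair(subp$O, subp$mean_rt_correct, "p_wm_occipital~rt", g)
        corr_pair(subp$O, subp$acc, "p_wm_occipital~acc", g)
      }
      corr_pair(subd$dtf_out, subd$mean_rt_correct, "dtf_frontal~rt", g)
      corr_pair(subd$dtf_out, subd$acc, "dtf_frontal~acc", g)
    }
  }

  list(
    omnibus = if (length(omnibus)) bind_rows(omnibus) else stat_row(character(0), numeric(0), numeric(0), numeric(0))[0, ],
    pairwise = if (length(pairwise)) bind_rows(pairwise) else tibble(),
    correlations = if (length(corrs)) bind_rows(corrs) else tibble(),
    assumption_checks = if (length(checks)) bind_rows(checks) else tibble()
  )
}

#' Render a human-readable report
#'
#' Writes the results bundle as markdown plus TSV tables: cohort/phenotype
#' table, behavioral contrasts, band-power comparisons, region-level theta
#' power, DTF aggregates, and correlations.
#'
#' @param bundle A `results_bundle` from [run_analysis()].
#' @param out_dir Directory to write into (created if needed).
#' @return Path of the markdown report, invisibly.
#' @export
render_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(
    cohort = mutate(bundle$pheno, across(dplyr::where(is.numeric), round_report)),
    band_power = mutate(bundle$band_power, across(dplyr::where(is.numeric), round_report)),
    region_power = mutate(bundle$region_power, across(dplyr::where(is.numeric), round_report)),
    dtf = mutate(bundle$dtf, across(dplyr::where(is.numeric), round_report)),
    dtf_node = mutate(bundle$dtf_i, across(dplyr::where(is.numeric), round_report)),
    dtf_region_pairs = mutate(bundle$dtf_kl, across(dplyr::where(is.numeric), round_report)),
    tests_omnibus = mutate(bundle$stats$omnibus, across(dplyr::where(is.numeric), round_report)),
    tests_pairwise = mutate(bundle$stats$pairwise, across(dplyr::where(is.numeric), round_report)),
    correlations = mutate(bundle$stats$correlations, across(dplyr::where(is.numeric), round_report))
  )
  for (nm in names(tabs)) {
    write_tsv_plain(tabs[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(bundle$manifest$config,
                       file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  md <- c(
    "# Working-memory EEG analysis report", "",
    sprintf("Subjects: %d | prominent band: **%s**",
            nrow(bundle$manifest$subjects), bundle$prominent$cohort), "",
    "## Cohort and phenotyping", "",
    md_table(tabs$cohort[, c("subject", "group", "analysis_group",
                             "mean_rt_correct", "acc", "z_rt", "z_acc",
                             "phenotype")]),
    "", "## Group contrasts (one-way ANOVA)", "",
    if (nrow(tabs$tests_omnibus) > 0) md_table(tabs$tests_omnibus)
    else "_no tests run_",
    "", "## LSD pairwise comparisons", "",
    if (nrow(tabs$tests_pairwise) > 0) md_table(tabs$tests_pairwise)
    else "_no tests run_",
    "", "## Correlations with task performance", "",
    if (nrow(tabs$correlations) > 0) md_table(tabs$correlations)
    else "_no tests run_",
    "", "## Connectivity aggregates per subject", "",
    md_table(tabs$dtf), ""
  )
  path <- file.path(out_dir, "report.md")
  writeLines(md, path)
  invisible(path)
}

round_report <- function(x) round(x, 6)

md_table <- function(tab) {
  tab <- as.data.frame(tab)
  fmt <- vapply(seq_len(nrow(tab)), function(i) {
    paste0("| ", paste(vapply(tab[i, ], function(v)
      ifelse(is.na(v), "NA", format(v, trim = TRUE)), ""), collapse = " | "), " |")
  }, "")
  c(paste0("| ", paste(names(tab), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
    fmt)
}
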