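# thetadtf

Theta-band oscillations and directed connectivity during working-memory
encoding, from multichannel scalp EEG.

During the encoding phase of a delayed match-to-sample task, frontal
midline theta (4–8 Hz) dominates the scalp spectrum, and the frontal region
acts as the strongest *source* of directed influence on the rest of the
scalp. In temporal lobe epilepsy, patients whose task performance is
impaired show weaker theta networks even when their clinical features look
like those of unimpaired patients — which makes the theta network a
candidate marker of cognitive status. `thetadtf` implements the full
analysis chain behind that kind of finding, for researchers working with
task EEG and clinical cohorts:

* **Spectral analysis** — Welch/STFT power spectral density (0.4 s Hamming
  windows, 0.5 Hz grid), band powers over the clinical bands, and
  working-memory efficiency power `P_wm = P_raw − P_rs`, the task power
  minus the eyes-closed resting baseline.
* **Directed connectivity** — multivariate autoregressive (MVAR) models
  fitted to the encoding epochs by multi-epoch least squares, and the
  directed transfer function
  `γ_ij(f) = |H_ij(f)|² / Σ_m |H_im(f)|²`
  (row-normalized, sink `i`, source `j`), aggregated to the global strength
  `DTF_g`, per-channel node strengths `DTF_i`, region-pair strengths
  `DTF_kl`, and frontal outflow/inflow `DTF_out` / `DTF_in`.
* **Behavioral phenotyping** — reaction time and accuracy z-scored against
  the control group; performance impairment by the directional 1.5 SD rule.
* **Statistics** — Student t-tests, one-way ANOVA with Fisher's LSD
  post-hoc comparisons, Pearson chi-square, Pearson correlation, and
  Shapiro-Wilk / Levene assumption checks, reported as tidy tables.
* **A synthetic cohort generator** — stable MVAR processes with a
  theta-resonant frontal hub (Fz), a planted group effect that weakens hub
  outflow in an impaired subgroup, and behavior statistically linked to
  frontal theta power — so the entire pipeline is testable end to end with
  known ground truth.

Recordings come in as EDF or delimited matrices (channels in the header,
one row per sample), events and behavior as TSV; results come out as
tibbles, so everything chains with the pipe, and fitted objects have
`tidy()` / `glance()` / `autoplot()` methods.

## Worked example

Simulate a small cohort (controls plus patient-like groups, one of them
with hub outflow halved and behavior shifted), run the pipeline, and look
at the group-level connectivity:

```r
library(thetadtf)
library(dplyr)

cfg     <- smoke_profile(n_per_group = 5L, seed = 7L)   # 16-channel fast profile
cohort  <- simulate_cohort(cfg)
results <- run_analysis(cohort, pipeline_config(lowpass = NULL, notch = NULL))

results
#> <results_bundle> 15 subjects; prominent band: theta; 19 omnibus tests, 18 correlations

results$dtf |>
  left_join(results$pheno[, c("subject", "analysis_group")], by = "subject") |>
  group_by(analysis_group) |>
  summarise(dtf_g = mean(dtf_g), dtf_out = mean(dtf_out), dtf_in = mean(dtf_in))
#> # A tibble: 3 × 4
#>   analysis_group     dtf_g dtf_out  dtf_in
#>   <chr>              <dbl>   <dbl>   <dbl>
#> 1 con               0.0274  0.0595 0.00712
#> 2 impaired          0.0151  0.0261 0.00624
#> 3 normal_performing 0.0255  0.0530 0.00634

results$stats$omnibus |>
  filter(measure %in% c("mean_rt", "acc", "dtf_g", "dtf_out", "dtf_in")) |>
  select(measure, statistic, df_between, df_within, p_value)
#> # A tibble: 5 × 5
#>   measure statistic df_between df_within     p_value
#>   <chr>       <dbl>      <int>     <int>       <dbl>
#> 1 mean_rt    61.4            2        12 0.000000496
#> 2 acc         7.51           2        12 0.00767
#> 3 dtf_g      53.3            2        12 0.00000107
#> 4 dtf_out    39.5            2        12 0.00000528
#> 5 dtf_in      0.164          2        12 0.851
```

Read the tables the way the underlying science predicts: theta is the
prominent band during encoding; the performance-impaired group shows lower
global connectivity (`dtf_g` 0.015 vs 0.027) and lower frontal outflow
(`dtf_out` 0.026 vs 0.060) than controls, with large omnibus F statistics,
while frontal *inflow* does not differ between groups (p = 0.85) — the
planted effect is a weakening of the frontal source, and the pipeline
recovers exactly that. Behavioral contrasts (`mean_rt`, `acc`) separate the
groups because the impaired group carries the planted +3 SD reaction-time
shift and accuracy deficit. The patient split into `impaired` /
`normal_performing` comes from the 1.5 SD z-score rule against the control
group, not from the generator's hidden flags.

`render_report(results, "report/")` writes the markdown + TSV report;
`write_cohort()` / `read_cohort()` round-trip cohorts on disk, and
`inst/scripts/wm_pipeline.R` wraps simulate → analyze → report as a shell
command.

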