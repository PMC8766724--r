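#' Summarize per-trial behavior
#'
#' Accuracy is `n_correct / n_trials`; mean reaction time is computed over
#' correct trials only. Subjects with no correct trial get `NA` RT and are
#' flagged.
#'
#' @param trials Tibble with columns `subject`, `trial`, `correct`, `rt_ms`.
#' @return Tibble with `subject`, `mean_rt_correct`, `acc`, `n_trials`,
#'   `n_correct`, `rt_undefined`.
#' @export
summarize_behavior <- function(trials) {
  need <- c("subject", "correct", "rt_ms")
  if (!is.data.frame(trials) || !all(need %in% names(trials)) || nrow(trials) == 0) {
    abort("trials must be a non-empty table with columns subject, correct, rt_ms")
  }
  trials |>
    group_by(.data$subject) |>
    summarise(
      mean_rt_correct = if (any(.data$correct))
        mean(.data$rt_ms[.data$correct]) else NA_real_,
      acc = mean(.data$correct),
      n_trials = dplyr::n(),
      n_correct = sum(.data$correct),
      .groups = "drop"
    ) |>
    mutate(rt_undefined = is.na(.data$mean_rt_correct))
}

#' Phenotype behavioral performance by the 1.5 SD rule
#'
#' Z-scores every subject's mean RT and accuracy against the designated
#' control group's mean and sample SD (denominator n - 1). A subject is
#' classified `impaired` when the RT z-score exceeds `threshold` (slower than
#' normal) or the accuracy z-score falls below `-threshold` (less accurate
#' than normal); the rule is directional because faster-than-normal responses
#' are not an impairment (a two-sided variant is available). Control subjects
#' are scored like everyone else but retain their control label in the
#' `group` column.
#'
#' @param cohort Behavior summary tibble from [summarize_behavior()], with an
#'   added `group` column (or pass `control_ids`).
#' @param control_ids Subject ids of the reference (control) group; defaults
#'   to `cohort$group == "con"`.
#' @param threshold Cutoff in control SD units (default 1.5).
#' @param two_sided Flag any |z| beyond the threshold instead of the
#'   directional rule?
#' @return The input tibble plus `z_rt`, `z_acc`, `phenotype`
#'   (`"normal"`/`"impaired"`), with the control reference statistics in the
#'   `"reference"` attribute.
#' @export
phenotype <- function(cohort, control_ids = NULL, threshold = 1.5,
                      two_sided = FALSE) {
  stopifnot(is.data.frame(cohort),
            all(c("subject", "mean_rt_correct", "acc") %in% names(cohort)))
  if (is.null(control_ids)) {
    if (!("group" %in% names(cohort))) {
      abort("supply control_ids or a 'group' column containing 'con'")
    }
    control_ids <- cohort$subject[cohort$group == "con"]
  }
  ctrl <- cohort[cohort$subject %in% control_ids, ]
  if (nrow(ctrl) < 3) abort("at least 3 control subjects are required")
  ref <- list(
    rt_mean = mean(ctrl$mean_rt_correct), rt_sd = sd(ctrl$mean_rt_correct),
    acc_mean = mean(ctrl$acc), acc_sd = sd(ctrl$acc)
  )
  if (!all(is.finite(unlist(ref))) || ref$rt_sd == 0 || ref$acc_sd == 0) {
    abort("control group has zero or undefined variance")
  }
  out <- cohort |>
    mutate(
      z_rt = (.data$mean_rt_correct - ref$rt_mean) / ref$rt_sd,
      z_acc = (.data$acc - ref$acc_mean) / ref$acc_sd
    )
  flagged <- if (two_sided) {
    abs(out$z_rt) > threshold | abs(out$z_acc) > threshold
  } else {
    out$z_rt > threshold | out$z_acc < -threshold
  }
  out$phenotype <- ifelse(flagged, "impaired", "normal")
  attr(out, "reference") <- ref
  attr(out, "threshold") <- threshold
  out
}

#' Split patients into performance phenotype groups
#'
#' Mirrors the clinical grouping: controls keep the `con` label; patients are
#' split into performance-normal (`tle_n`-analog) and performance-impaired
#' (`tle_wm`-analog) by the 1.5 SD rule.
#'
#' @param pheno Output of [phenotype()] with a `group` column whose control
#'   rows are `"con"`.
#' @return The tibble with an `analysis_group` column
#'   (`con`/`normal_performing`/`impaired`).
#' @export
phenotype_groups <- function(pheno) {
  stopifnot(all(c("group", "phenotype") %in% names(pheno)))
  pheno$analysis_group <- ifelse(
    pheno$group == "con", "con",
    ifelse(pheno$phenotype == "impaired", "impaired", "normal_performing")
  )
  pheno
}
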