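#' @title Statistical battery
#' @description
#' The tests mirror a conventional SPSS-style workflow: Student (or Welch)
#' t-tests for two groups, one-way ANOVA with Fisher's LSD post-hoc
#' comparisons for three or more, Pearson chi-square for dichotomous
#' variables, Pearson correlation for continuous associations, and
#' Shapiro-Wilk / Levene assumption checks reported alongside. No
#' multiple-testing correction is applied anywhere (LSD by definition applies
#' none), matching the workflow the pipeline reproduces.
#' @name stat_battery
NULL

stat_row <- function(test, statistic, df, p_value, groups = NA_character_,
                     direction = NA_character_, measure = NA_character_) {
  tibble(measure = measure, test = test, groups = groups,
         statistic = statistic, df = df, p_value = p_value,
         direction = direction)
}

#' Two-sample t-test
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @param variant `"student"` (pooled variance, the default used after a
#'   passing Levene check) or `"welch"`.
#' @param measure Optional label carried into the result row.
#' @return A one-row tibble: `measure`, `test`, `groups`, `statistic`, `df`,
#'   `p_value`, `direction`.
#' @export
t_test <- function(x, y, variant = c("student", "welch"),
                   measure = NA_character_) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) abort("each sample needs n >= 2")
  if (variant == "student" && var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(stat_row("t (student)", 0, length(x) + length(y) - 2, 1,
                      direction = "none", measure = measure))
    }
    abort("zero pooled variance with unequal means; t-test undefined")
  }
  fit <- t.test(x, y, var.equal = variant == "student")
  stat_row(paste0("t (", variant, ")"), unname(fit$statistic),
           unname(fit$parameter), fit$p.value,
           direction = if (mean(x) > mean(y)) "x > y"
                       else if (mean(x) < mean(y)) "x < y" else "none",
           measure = measure)
}

#' One-way ANOVA with LSD post-hoc comparisons
#'
#' Standard between/within sum-of-squares decomposition, followed by Fisher's
#' least-significant-difference pairwise t-tests using the pooled within-group
#' mean square and its degrees of freedom. All pairwise results are returned;
#' no multiplicity correction is applied (that is what LSD means).
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation (>= 2 groups, n >= 2 each).
#' @param measure Optional label carried into the result rows.
#' @return A list with `omnibus` (one-row tibble with F, df pair, p) and
#'   `pairwise` (tibble of LSD t-tests: `group1`, `group2`, `statistic`,
#'   `df`, `p_value`, `direction`).
#' @export
one_way_anova_lsd <- function(values, groups, measure = NA_character_) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  lv <- unique(groups)
  if (length(lv) < 2) abort("at least two groups are required")
  ns <- table(groups)
  if (any(ns < 2)) abort("each group needs n >= 2")
  if (var(values) == 0) abort("all observations identical; F undefined")
  fit <- lm(values ~ factor(groups, levels = lv))
  av <- anova(fit)
  msw <- av$`Mean Sq`[2]
  df_w <- av$Df[2]
  omnibus <- stat_row("one-way ANOVA", av$`F value`[1], NA, av$`Pr(>F)`[1],
                      groups = paste(lv, collapse = "/"), measure = measure)
  omnibus$df_between <- av$Df[1]
  omnibus$df_within <- df_w
  means <- tapply(values, groups, mean)
  pairs <- utils::combn(lv, 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt(msw * (1 / ns[[g1]] + 1 / ns[[g2]]))
    tval <- (means[[g1]] - means[[g2]]) / se
    tibble(measure = measure, group1 = g1, group2 = g2,
           statistic = tval, df = df_w,
           p_value = 2 * pt(-abs(tval), df_w),
           direction = if (tval > 0) paste(g1, ">", g2)
                       else if (tval < 0) paste(g1, "<", g2) else "none")
  })
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Pearson chi-square test on a 2 x k count table
#'
#' Without continuity correction; `df = k - 1`.
#'
#' @param table_2xk Matrix of non-negative integer counts with 2 rows.
#' @param measure Optional label.
#' @return A one-row tibble.
#' @export
chi_square_2xk <- function(table_2xk, measure = NA_character_) {
  table_2xk <- as.matrix(table_2xk)
  if (nrow(table_2xk) != 2) abort("expected a 2 x k table")
  if (any(table_2xk < 0) || any(table_2xk != round(table_2xk))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(table_2xk) == 0) || any(colSums(table_2xk) == 0)) {
    abort("zero-sum row or column; chi-square undefined")
  }
  fit <- suppressWarnings(chisq.test(table_2xk, correct = FALSE))
  stat_row("chi-square", unname(fit$statistic), unname(fit$parameter),
           fit$p.value, measure = measure)
}

#' Pearson correlation
#'
#' Two-sided p-value via the t transform with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors, n >= 3, non-constant.
#' @param measure Optional label.
#' @return A one-row tibble with the correlation in `statistic` and an added
#'   `r` column.
#' @export
pearson_corr <- function(x, y, measure = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("n >= 3 complete pairs required")
  if (var(x) == 0 || var(y) == 0) abort("constant input; correlation undefined")
  fit <- cor.test(x, y, method = "pearson")
  out <- stat_row("pearson", unname(fit$statistic), unname(fit$parameter),
                  fit$p.value,
                  direction = if (fit$estimate > 0) "positive" else "negative",
                  measure = measure)
  out$r <- unname(fit$estimate)
  out
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per sample and Levene's test (mean-centered, the SPSS
#' default) across samples. Advisory only: the pipeline reports these next to
#' every t/ANOVA result and warns below alpha, but never switches tests
#' automatically.
#'
#' @param samples Named list of numeric vectors (n >= 3 each).
#' @param alpha Warning level (default 0.05).
#' @return A tibble with one Shapiro-Wilk row per sample and one Levene row.
#' @export
assumption_checks <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 1)
  if (is.null(names(samples))) names(samples) <- paste0("sample", seq_along(samples))
  if (any(lengths(samples) < 3)) abort("each sample needs n >= 3")
  sw <- purrr::imap_dfr(samples, function(x, nm) {
    fit <- shapiro.test(x)
    stat_row("shapiro-wilk", unname(fit$statistic), NA, fit$p.value, groups = nm)
  })
  out <- sw
  if (length(samples) >= 2) {
    values <- unlist(samples, use.names = FALSE)
    g <- factor(rep(names(samples), lengths(samples)))
    lev <- car::leveneTest(values, g, center = mean)
    out <- bind_rows(out, stat_row("levene", lev$`F value`[1], lev$Df[1],
                                   lev$`Pr(>F)`[1],
                                   groups = paste(names(samples), collapse = "/")))
  }
  low <- out$p_value < alpha
  if (any(low, na.rm = TRUE)) {
    warn(sprintf("assumption check(s) below alpha = %g: %s", alpha,
                 paste(unique(out$test[low]), collapse = ", ")))
  }
  out
}
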