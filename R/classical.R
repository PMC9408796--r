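#' One-way ANOVA of GHQ-12 sums across waves
#'
#' Complete-data linear-model F-test of wave mean differences on person-wave
#' Likert sums, treating person-waves as independent observations (the
#' denominator degrees of freedom are then the number of complete person-waves
#' minus the number of waves).
#'
#' @param scored Scored person-wave tibble from [score_ghq()].
#' @param use Which score to test: `"likert_sum"` (default) or
#'   `"interpreted_score"`.
#' @return A one-row tibble: `comparison`, `statistic` (F), `df1`, `df2`,
#'   `p_value`.
#' @export
wave_anova <- function(scored, use = c("likert_sum", "interpreted_score")) {
  use <- match.arg(use)
  d <- scored |> dplyr::filter(!is.na(.data[[use]]))
  counts <- table(d$wave)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("Need at least 2 waves with at least 2 complete observations each.",
          class = "ghqwave_error")
  }
  if (var(d[[use]]) == 0) {
    abort("All scores identical: zero residual variance, F undefined.",
          class = "ghqwave_degenerate")
  }
  fit <- stats::lm(d[[use]] ~ factor(d$wave))
  an <- stats::anova(fit)
  tibble::tibble(
    comparison = "wave_anova",
    statistic = an$`F value`[1],
    df1 = an$Df[1],
    df2 = an$Df[2],
    p_value = an$`Pr(>F)`[1]
  )
}

#' Paired t-test between two waves
#'
#' Two-sided paired t-test on within-person differences of the chosen score;
#' persons missing either wave are excluded.
#'
#' @param scored Scored person-wave tibble from [score_ghq()].
#' @param wave_a,wave_b The two waves to compare (`statistic` is for
#'   `wave_a - wave_b`).
#' @inheritParams wave_anova
#' @return A one-row tibble: `comparison`, `statistic` (t), `df1` (t df),
#'   `df2` (`NA`), `p_value`, `mean_diff`, `n_pairs`.
#' @export
paired_wave_test <- function(scored, wave_a, wave_b,
                             use = c("likert_sum", "interpreted_score")) {
  use <- match.arg(use)
  wide <- scored |>
    dplyr::filter(.data$wave %in% c(wave_a, wave_b), !is.na(.data[[use]])) |>
    dplyr::select("person_id", "wave", dplyr::all_of(use)) |>
    tidyr::pivot_wider(names_from = "wave", values_from = dplyr::all_of(use),
                       names_prefix = "w") |>
    stats::na.omit()
  a <- wide[[paste0("w", wave_a)]]
  b <- wide[[paste0("w", wave_b)]]
  if (is.null(a) || is.null(b) || length(a) < 2) {
    abort("Fewer than 2 complete pairs.", class = "ghqwave_error")
  }
  d <- a - b
  if (all(d == 0)) {
    # identical vectors: no evidence of a difference (t.test would refuse
    # constant data, but the answer is well defined)
    return(tibble::tibble(
      comparison = sprintf("wave%s_vs_wave%s", wave_a, wave_b),
      statistic = 0, df1 = length(d) - 1, df2 = NA_real_,
      p_value = 1, mean_diff = 0, n_pairs = length(d)
    ))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(
    comparison = sprintf("wave%s_vs_wave%s", wave_a, wave_b),
    statistic = unname(tt$statistic),
    df1 = unname(tt$parameter),
    df2 = NA_real_,
    p_value = tt$p.value,
    mean_diff = unname(tt$estimate),
    n_pairs = length(a)
  )
}

#' All classical wave comparisons
#'
#' Convenience wrapper: the across-wave ANOVA plus every pairwise paired
#' t-test, bound into one tidy results table. No multiplicity correction is
#' applied.
#'
#' @inheritParams wave_anova
#' @return Tibble of test results, one row per comparison.
#' @export
wave_tests <- function(scored, use = c("likert_sum", "interpreted_score")) {
  use <- match.arg(use)
  waves <- sort(unique(scored$wave[!is.na(scored[[use]])]))
  pairs <- utils::combn(waves, 2, simplify = FALSE)
  dplyr::bind_rows(
    wave_anova(scored, use = use),
    purrr::map_dfr(pairs, \(p) paired_wave_test(scored, p[2], p[1], use = use))
  )
}
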