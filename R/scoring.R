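#' GHQ-12 Likert sum score
#'
#' Sums the raw item categories (0--3) over a complete response vector, giving
#' the 0--36 Likert sum. Under the complete-case policy any missing item makes
#' the score missing (no proration is invented).
#'
#' @param responses Numeric vector of item categories in `{0, 1, 2, 3}` (or
#'   `NA`), one per item.
#' @param n_items Expected number of items (default 12).
#' @return Integer sum 0--36, or `NA` if any item is missing.
#' @examples
#' ghq_likert_sum(rep(3, 12))
#' @export
ghq_likert_sum <- function(responses, n_items = 12L) {
  check_categories(responses)
  if (length(responses) != n_items || anyNA(responses)) return(NA_integer_)
  as.integer(sum(responses))
}

#' GHQ-12 interpreted (0-0-1-1) score
#'
#' Recodes each item's category (0,1,2,3) to (0,0,1,1) -- "better" and "usual"
#' responses count 0, "worse" and "much worse" count 1 -- and sums, giving the
#' 0--12 interpreted score. Complete-case: any missing item yields `NA`.
#'
#' @inheritParams ghq_likert_sum
#' @return Integer score 0--12, or `NA` if any item is missing.
#' @examples
#' ghq_interpreted_score(rep(1, 12)) # all "usual" -> 0
#' @export
ghq_interpreted_score <- function(responses, n_items = 12L) {
  check_categories(responses)
  if (length(responses) != n_items || anyNA(responses)) return(NA_integer_)
  as.integer(sum(responses >= 2))
}

check_categories <- function(responses) {
  bad <- !is.na(responses) & !(responses %in% 0:3)
  if (any(bad)) {
    abort(sprintf("Item categories must be in {0,1,2,3}; got %s.",
                  paste(unique(responses[bad]), collapse = ", ")),
          class = "ghqwave_error")
  }
  invisible(responses)
}

#' Caseness classification from the interpreted score
#'
#' A person-wave is classified as a psychological-distress case when the
#' 0-0-1-1 interpreted score reaches the screening threshold (3 or more).
#'
#' @param interpreted_score Integer vector of 0--12 scores (NA allowed).
#' @param threshold Caseness cut-off (default 3).
#' @return Logical vector (`NA` where the score is missing).
#' @examples
#' ghq_caseness(c(0, 2, 3, 12))
#' @export
ghq_caseness <- function(interpreted_score, threshold = 3L) {
  bad <- !is.na(interpreted_score) &
    (interpreted_score < 0 | interpreted_score > 12)
  if (any(bad)) {
    abort("Interpreted scores must lie in 0..12.", class = "ghqwave_error")
  }
  interpreted_score >= threshold
}

#' Score person-waves on both GHQ-12 scoring systems
#'
#' Aggregates a long response table to one row per observed person-wave with
#' the 0--36 Likert sum, the 0--12 interpreted score and the caseness flag.
#' Complete-case policy: a person-wave missing any of the `n_items` items gets
#' missing scores (its `n_observed` still reports how many items were seen).
#'
#' @param responses Long response tibble (`person_id`, `wave`, `item`,
#'   `response`); rows with `NA` response count as unobserved.
#' @param n_items Number of items a complete person-wave must have.
#' @return Tibble: `person_id`, `wave`, `n_observed`, `likert_sum`,
#'   `interpreted_score`, `case`.
#' @export
score_ghq <- function(responses, n_items = 12L) {
  responses |>
    dplyr::filter(!is.na(.data$response)) |>
    dplyr::summarise(
      n_observed = dplyr::n(),
      likert_sum = if (dplyr::n() == n_items) as.integer(sum(.data$response))
                   else NA_integer_,
      interpreted_score = if (dplyr::n() == n_items)
        as.integer(sum(.data$response >= 2)) else NA_integer_,
      .by = c("person_id", "wave")
    ) |>
    dplyr::mutate(case = ghq_caseness(.data$interpreted_score)) |>
    dplyr::arrange(.data$person_id, .data$wave)
}

#' Descriptive summary of a cohort and its wave-level distress
#'
#' Builds the study's characteristics table: per wave the number of complete
#' respondents, case count and percentage, Likert-sum and interpreted-score
#' means/SDs, and item-response coverage; for the cohort the sex and diarrhoea
#' counts/percentages and the age distribution. Percentages are displayed
#' rounded half-up to the nearest integer; raw proportions are retained.
#'
#' @param responses Long response tibble (post-attrition).
#' @param persons Person covariate table.
#' @param n_items Number of items per wave.
#' @return A `ghq_summary` list with tibbles `waves` and `cohort`.
#' @export
descriptive_summary <- function(responses, persons, n_items = 12L) {
  if (nrow(responses) == 0 || nrow(persons) == 0) {
    abort("`responses` and `persons` must be non-empty.", class = "ghqwave_error")
  }
  scored <- score_ghq(responses, n_items = n_items)
  n_persons <- nrow(persons)
  obs <- responses |>
    dplyr::filter(!is.na(.data$response)) |>
    dplyr::summarise(n_item_responses = dplyr::n(), .by = "wave")
  waves <- scored |>
    dplyr::summarise(
      n_respondents = sum(!is.na(.data$likert_sum)),
      n_cases = sum(.data$case, na.rm = TRUE),
      likert_mean = mean(.data$likert_sum, na.rm = TRUE),
      likert_sd = sd(.data$likert_sum, na.rm = TRUE),
      interp_mean = mean(.data$interpreted_score, na.rm = TRUE),
      interp_sd = sd(.data$interpreted_score, na.rm = TRUE),
      .by = "wave"
    ) |>
    dplyr::left_join(obs, by = "wave") |>
    dplyr::mutate(
      case_prop = ifelse(.data$n_respondents > 0,
                         .data$n_cases / .data$n_respondents, NA_real_),
      case_pct = ghq_pct(.data$n_cases, .data$n_respondents),
      coverage_prop = .data$n_item_responses / (n_persons * n_items),
      coverage_pct = ghq_pct(.data$n_item_responses, n_persons * n_items)
    ) |>
    dplyr::arrange(.data$wave)
  cohort <- tibble::tibble(
    n_persons = n_persons,
    n_men = sum(persons$sex == 1),
    men_pct = ghq_pct(sum(persons$sex == 1), n_persons),
    n_diarrhoea_trip = sum(persons$diarrhoea_trip),
    diarrhoea_trip_pct = ghq_pct(sum(persons$diarrhoea_trip), n_persons),
    n_diarrhoea_after = sum(persons$diarrhoea_after),
    diarrhoea_after_pct = ghq_pct(sum(persons$diarrhoea_after), n_persons),
    age_mean = mean(persons$age),
    age_sd = sd(persons$age),
    age_min = min(persons$age),
    age_max = max(persons$age)
  )
  structure(list(waves = waves, cohort = cohort, n_items = n_items),
            class = "ghq_summary")
}

#' @export
print.ghq_summary <- function(x, ...) {
  co <- x$cohort
  cat("Cohort characteristics\n")
  cat(sprintf("  N (total)                 %4d\n", co$n_persons))
  cat(sprintf("  Men                       %4d  %3.0f%%\n", co$n_men, co$men_pct))
  cat(sprintf("  Diarrhoea during trip     %4d  %3.0f%%\n",
              co$n_diarrhoea_trip, co$diarrhoea_trip_pct))
  cat(sprintf("  Diarrhoea after trip      %4d  %3.0f%%\n",
              co$n_diarrhoea_after, co$diarrhoea_after_pct))
  cat(sprintf("  Age mean (sd) [range]     %.1f (%.1f) [%.0f-%.0f]\n",
              co$age_mean, co$age_sd, co$age_min, co$age_max))
  cat("Per wave\n")
  for (i in seq_len(nrow(x$waves))) {
    w <- x$waves[i, ]
    cat(sprintf("  wave %d: %4d item responses (%3.0f%%), cases %d/%d (%s), Likert sum %.2f (%.2f)\n",
                w$wave, w$n_item_responses, w$coverage_pct, w$n_cases,
                w$n_respondents,
                if (is.na(w$case_pct)) "NA" else sprintf("%.0f%%", w$case_pct),
                w$likert_mean, w$likert_sd))
  }
  invisible(x)
}

#' Write a descriptive summary to delimited files
#'
#' @param x A `ghq_summary`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_ghq_summary <- function(x, dir) {
  stopifnot(inherits(x, "ghq_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(file.path(dir, "summary_waves.csv"),
             file.path(dir, "summary_cohort.csv"))
  readr::write_csv(x$waves, paths[1])
  readr::write_csv(x$cohort, paths[2])
  invisible(paths)
}
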