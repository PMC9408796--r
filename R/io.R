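# CSV dialect is fixed, not sniffed: comma separator, "." decimal, ISO-8601
# dates, LF line endings, empty field for missing responses.

#' Read and validate a long response table
#'
#' @param path UTF-8 CSV with header `person_id, wave, item, response`; an
#'   empty response field is a missing (unobserved) record.
#' @param waves Allowed wave codes.
#' @param n_items Allowed item range `1..n_items`.
#' @return Validated response tibble (`response` integer or `NA`).
#' @export
read_response_table <- function(path, waves = 0:2, n_items = 12L) {
  x <- readr::read_csv(path, col_types = readr::cols(
    person_id = readr::col_integer(), wave = readr::col_integer(),
    item = readr::col_integer(), response = readr::col_integer()
  ), na = c("", "NA"))
  need <- c("person_id", "wave", "item", "response")
  if (!identical(names(x)[seq_along(need)], need)) {
    abort("Header must be person_id, wave, item, response.",
          class = "ghqwave_error")
  }
  bad <- which(!is.na(x$response) & !(x$response %in% 0:3))
  if (length(bad) > 0) {
    abort(sprintf("Response outside {0,1,2,3} at row(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")),
          class = "ghqwave_error")
  }
  bad_wave <- which(!x$wave %in% waves)
  if (length(bad_wave) > 0) {
    abort(sprintf("Unknown wave at row(s): %s",
                  paste(utils::head(bad_wave, 5), collapse = ", ")),
          class = "ghqwave_error")
  }
  bad_item <- which(!x$item %in% seq_len(n_items))
  if (length(bad_item) > 0) {
    abort(sprintf("Item outside 1..%d at row(s): %s", n_items,
                  paste(utils::head(bad_item, 5), collapse = ", ")),
          class = "ghqwave_error")
  }
  dup <- duplicated(x[, c("person_id", "wave", "item")])
  if (any(dup)) {
    abort(sprintf("Duplicate (person, wave, item) at row(s): %s",
                  paste(utils::head(which(dup), 5), collapse = ", ")),
          class = "ghqwave_error")
  }
  x
}

#' Write a response table (missing responses as empty fields)
#'
#' @param responses Response tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_response_table <- function(responses, path) {
  readr::write_csv(responses, path, na = "")
  invisible(path)
}

#' Read and validate a person covariate table
#'
#' @param path CSV with `person_id, sex, age, trip_return_date,
#'   diarrhoea_trip, diarrhoea_after` (ISO dates); `age_z` and `t_days` are
#'   recomputed.
#' @return Validated person tibble.
#' @export
read_person_table <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    person_id = readr::col_integer(), sex = readr::col_integer(),
    age = readr::col_double(), trip_return_date = readr::col_date(),
    diarrhoea_trip = readr::col_integer(), diarrhoea_after = readr::col_integer(),
    .default = readr::col_double()
  ))
  need <- c("person_id", "sex", "age", "trip_return_date",
            "diarrhoea_trip", "diarrhoea_after")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "ghqwave_error")
  }
  if (anyDuplicated(x$person_id)) {
    abort("Duplicate person_id.", class = "ghqwave_error")
  }
  if (any(!x$sex %in% 0:1) || any(!x$diarrhoea_trip %in% 0:1) ||
      any(!x$diarrhoea_after %in% 0:1)) {
    abort("sex and diarrhoea flags must be 0/1.", class = "ghqwave_error")
  }
  x$age_z <- as.numeric(scale(x$age))
  x$t_days <- as.integer(x$trip_return_date - ghq_epoch())
  x
}

#' Write a person covariate table
#'
#' @param persons Person tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_person_table <- function(persons, path) {
  readr::write_csv(persons, path, na = "")
  invisible(path)
}
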