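#' Claims-based case-ascertainment rule
#'
#' Parametrizes the family of administrative asthma definitions: a person is a
#' case when they have at least `min_claims` asthma physician claims falling
#' within `window_years` of each other inside the lookback period, or (when
#' `hospitalization_sufficient`) at least one asthma hospitalization in the
#' lookback. The study family uses `min_claims = 2` and
#' `window_years` of 1, 2, 3, 5 or 30 over a 1983--interview lookback; the
#' pre-1995 sampling definition is `window_years = Inf` with
#' `lookback_end = "1994-12-31"`.
#'
#' @param window_years Positive number of years (may be `Inf`, meaning any two
#'   claims inside the lookback qualify).
#' @param min_claims Minimum number of distinct-day claims (default 2).
#' @param lookback_start First eligible service date (default 1983-01-01, the
#'   start of the claims data).
#' @param lookback_end Last eligible service date, or `NULL` to use each
#'   person's interview date.
#' @param hospitalization_sufficient Does a single hospitalization suffice?
#' @return An object of class `algorithm_spec`.
#' @export
#' @examples
#' algorithm_spec(window_years = 2)
algorithm_spec <- function(window_years, min_claims = 2,
                           lookback_start = as.Date("1983-01-01"),
                           lookback_end = NULL,
                           hospitalization_sufficient = TRUE) {
  stopifnot(is.numeric(window_years), length(window_years) == 1,
            window_years > 0, min_claims >= 1)
  lookback_start <- as.Date(lookback_start)
  if (!is.null(lookback_end)) {
    lookback_end <- as.Date(lookback_end)
    if (lookback_start >= lookback_end) {
      stop("lookback_start must precede lookback_end", call. = FALSE)
    }
  }
  structure(list(window_years = window_years, min_claims = min_claims,
                 lookback_start = lookback_start, lookback_end = lookback_end,
                 hospitalization_sufficient = hospitalization_sufficient),
            class = "algorithm_spec")
}

#' @export
print.algorithm_spec <- function(x, ...) {
  end <- if (is.null(x$lookback_end)) "interview" else format(x$lookback_end)
  cat(sprintf(
    ">=%d physician claims within %s year(s)%s, lookback %s to %s\n",
    x$min_claims,
    if (is.infinite(x$window_years)) "any number of" else
      format(x$window_years),
    if (x$hospitalization_sufficient) " or >=1 hospitalization" else "",
    format(x$lookback_start), end))
  invisible(x)
}

#' Window length in days
#'
#' "Within k years" is interpreted as a day difference of at most
#' `floor(k * 365.25)` days, a leap-safe rule that is monotone in `k`.
#' @noRd
window_days <- function(k_years) {
  if (is.infinite(k_years)) Inf else floor(k_years * 365.25)
}

#' Do some two claim dates fall within a window?
#'
#' `TRUE` iff some pair of the given dates differs by at most
#' `floor(k_years * 365.25)` days. Because the closest pair among sorted dates
#' is always a consecutive pair, this is computed as the minimum consecutive
#' gap, which is linear after sorting and provably equivalent to checking all
#' pairs.
#'
#' @param dates A vector of claim `Date`s (need not be sorted or distinct).
#' @param k_years Window length in years (may be `Inf`).
#' @return Single logical; `FALSE` when fewer than 2 distinct dates.
#' @export
#' @examples
#' meets_pair_within(as.Date(c("1990-01-01", "1991-06-30")), 2)
meets_pair_within <- function(dates, k_years) {
  dates <- sort(unique(as.Date(dates)))
  if (length(dates) < 2) return(FALSE)
  min(diff(as.numeric(dates))) <= window_days(k_years)
}

#' Classify one person's asthma status from normalized events
#'
#' Applies an [algorithm_spec()] to one person's normalized asthma events.
#' Encounters after the lookback end (the interview, by default) or before the
#' lookback start are excluded. Status is `TRUE` when the person has at least
#' one in-lookback hospitalization (if sufficient) or their distinct claim
#' days contain a qualifying pair.
#'
#' @param events Normalized asthma events for a single person.
#' @param spec An [algorithm_spec()].
#' @param interview_date Person's interview date; used as lookback end when
#'   the spec leaves it `NULL`.
#' @return One-row tibble: `person_id`, `status`, `n_claims`,
#'   `n_hospitalizations`, `first_service_date`, `last_service_date`.
#' @export
classify_person <- function(events, spec, interview_date = NULL) {
  stopifnot(inherits(spec, "algorithm_spec"))
  pid <- if (nrow(events) > 0) events$person_id[1] else NA_character_
  if (nrow(events) > 0 && length(unique(events$person_id)) > 1) {
    stop("classify_person expects events for a single person", call. = FALSE)
  }
  end <- spec$lookback_end %||% as.Date(interview_date)
  if (is.null(end) || is.na(end)) {
    stop("no lookback end: spec$lookback_end and interview_date both absent",
         call. = FALSE)
  }
  keep <- events$date >= spec$lookback_start & events$date <= end
  ev <- events[keep, , drop = FALSE]
  claims <- ev$date[ev$kind == "physician_claim"]
  hosps <- ev$date[ev$kind == "hospitalization"]
  n_claims <- length(unique(claims))
  n_hosp <- length(unique(hosps))
  status <- (spec$hospitalization_sufficient && n_hosp >= 1) ||
    (n_claims >= spec$min_claims &&
       meets_pair_within(claims, spec$window_years))
  all_dates <- c(claims, hosps)
  tibble::tibble(
    person_id = pid, status = status, n_claims = n_claims,
    n_hospitalizations = n_hosp,
    first_service_date = if (length(all_dates)) min(all_dates) else
      as.Date(NA),
    last_service_date = if (length(all_dates)) max(all_dates) else as.Date(NA))
}

#' Classify a whole cohort under one ascertainment rule
#'
#' Vectorized equivalent of [classify_person()] over every person in
#' `persons`, including persons with no events (status `FALSE`). Events are
#' asthma-filtered with [is_asthma_event()] and normalized with
#' [normalize_events()] unless `normalized = TRUE`. The number of events
#' falling outside the lookback is recorded in the `n_excluded_events`
#' attribute of the result.
#'
#' @param events Event tibble for the cohort.
#' @param persons Person tibble with `person_id` and `interview_date`.
#' @param spec An [algorithm_spec()].
#' @param normalized Set `TRUE` when `events` are already asthma-filtered and
#'   normalized.
#' @return Tibble with one row per person in `persons` (same order):
#'   `person_id`, `status`, `n_claims`, `n_hospitalizations`,
#'   `first_service_date`, `last_service_date`.
#' @export
classify_cohort <- function(events, persons, spec, normalized = FALSE) {
  stopifnot(inherits(spec, "algorithm_spec"))
  if (!normalized) {
    events <- normalize_events(events[is_asthma_event(events), , drop = FALSE])
  }
  end_by_person <- if (is.null(spec$lookback_end)) {
    setNames(persons$interview_date, persons$person_id)
  } else {
    setNames(rep(spec$lookback_end, nrow(persons)), persons$person_id)
  }
  ev <- events[events$person_id %in% persons$person_id, , drop = FALSE]
  end <- end_by_person[ev$person_id]
  in_window <- !is.na(end) & ev$date >= spec$lookback_start & ev$date <= end
  n_excluded <- sum(!in_window)
  ev <- ev[in_window, , drop = FALSE]

  win <- window_days(spec$window_years)
  per <- ev |>
    dplyr::arrange(.data$person_id, .data$date) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      n_claims = sum(.data$kind == "physician_claim"),
      n_hospitalizations = sum(.data$kind == "hospitalization"),
      pair_ok = {
        cd <- as.numeric(.data$date[.data$kind == "physician_claim"])
        length(cd) >= 2 && min(diff(cd)) <= win
      },
      first_service_date = if (dplyr::n() == 0) as.Date(NA) else
        min(.data$date),
      last_service_date = if (dplyr::n() == 0) as.Date(NA) else
        max(.data$date),
      .groups = "drop")

  out <- tibble::tibble(person_id = persons$person_id) |>
    dplyr::left_join(per, by = "person_id") |>
    dplyr::mutate(
      n_claims = dplyr::coalesce(.data$n_claims, 0L),
      n_hospitalizations = dplyr::coalesce(.data$n_hospitalizations, 0L),
      pair_ok = dplyr::coalesce(.data$pair_ok, FALSE),
      status = (spec$hospitalization_sufficient &
                  .data$n_hospitalizations >= 1) |
        (.data$n_claims >= spec$min_claims & .data$pair_ok)) |>
    dplyr::select("person_id", "status", "n_claims", "n_hospitalizations",
                  "first_service_date", "last_service_date")
  attr(out, "n_excluded_events") <- n_excluded
  out
}

#' Crude and design-corrected prevalence
#'
#' @param status Logical vector of case status (may contain `NA`, e.g.
#'   missing self-report; such persons are dropped from both numerator and
#'   denominator).
#' @param weights Optional positive design weights aligned with `status`;
#'   `NULL` means unit weights, in which case corrected equals crude.
#' @return A tibble with `n_cases`, `n_valid`, `crude_pct` and
#'   `corrected_pct` (both on the 0--100 scale, full precision).
#' @export
#' @examples
#' prevalence(c(rep(TRUE, 801), rep(FALSE, 1643 - 801)))
prevalence <- function(status, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(status))
  stopifnot(length(weights) == length(status), all(weights > 0, na.rm = TRUE))
  ok <- !is.na(status)
  n_valid <- sum(ok)
  if (n_valid == 0) stop("prevalence undefined: no valid statuses",
                         call. = FALSE)
  s <- status[ok]
  w <- weights[ok]
  tibble::tibble(
    n_cases = sum(s), n_valid = n_valid,
    crude_pct = 100 * sum(s) / n_valid,
    corrected_pct = 100 * sum(w * s) / sum(w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
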