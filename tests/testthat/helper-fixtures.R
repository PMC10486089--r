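# Shared fixture builders; everything generated in code, nothing stored.

make_events <- function(person_id, dates, kind = "physician_claim",
                        code = "493", code_system = "ICD9") {
  n <- length(dates)
  tibble::tibble(
    person_id = rep_len(person_id, n), date = as.Date(dates),
    kind = rep_len(kind, n), code = rep_len(code, n),
    code_system = rep_len(code_system, n))
}

make_persons <- function(person_id, interview_date = "2012-06-30",
                         bcg = TRUE) {
  tibble::tibble(person_id = person_id, birth_year = 1974L,
                 interview_date = as.Date(rep_len(interview_date,
                                                  length(person_id))),
                 bcg = rep_len(bcg, length(person_id)))
}

write_lines_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

tiny_cohort <- function(n = 2000, seed = 42, ...) {
  generate_cohort(cohort_config(n_cohort = n, seed = seed, ...))
}

# Random event set for property tests: claims and hospitalizations scattered
# over the study period for one person.
random_event_set <- function(n_claims, n_hosp = 0,
                             from = as.Date("1983-01-01"),
                             to = as.Date("2012-06-30")) {
  span <- as.integer(to - from)
  ev <- dplyr::bind_rows(
    if (n_claims > 0) make_events("px", from + sample.int(span, n_claims,
                                                          replace = TRUE)),
    if (n_hosp > 0) make_events(
      "px", as.Date("1987-01-01") +
        sample.int(as.integer(to - as.Date("1987-01-01")), n_hosp,
                   replace = TRUE),
      kind = "hospitalization"))
  normalize_events(ev)
}

# All-pairs brute-force oracle for the claims-window rule.
pair_within_oracle <- function(dates, k_years) {
  dates <- sort(unique(as.Date(dates)))
  if (length(dates) < 2) return(FALSE)
  lim <- if (is.infinite(k_years)) Inf else floor(k_years * 365.25)
  for (i in seq_len(length(dates) - 1)) {
    for (j in seq(i + 1, length(dates))) {
      if (as.numeric(dates[j] - dates[i]) <= lim) return(TRUE)
    }
  }
  FALSE
}

# Direct textbook evaluation of the 2x2 agreement statistics from raw counts.
agreement_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  pa <- a / n; pb <- b / n; pc <- c / n; pd <- d / n
  p_o <- pa + pd
  p_e <- (pa + pb) * (pa + pc) + (pc + pd) * (pb + pd)
  list(p_o = p_o, p_e = p_e, kappa = (p_o - p_e) / (1 - p_e),
       ppos = 2 * pa / (2 * pa + pb + pc),
       pneg = 2 * pd / (2 * pd + pb + pc))
}

random_agreement_table <- function() {
  repeat {
    cells <- as.vector(stats::rmultinom(1, size = sample(50:500, 1),
                                        prob = stats::runif(4, 0.05, 1)))
    # need non-degenerate margins for kappa
    if ((cells[1] + cells[2]) > 0 && (cells[3] + cells[4]) > 0 &&
        (cells[1] + cells[3]) > 0 && (cells[2] + cells[4]) > 0) {
      return(table_from_counts(cells[1], cells[2], cells[3], cells[4]))
    }
  }
}
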