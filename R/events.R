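#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

EVENT_KINDS <- c("physician_claim", "hospitalization")
CODE_SYSTEMS <- c("ICD9", "ICD10")

# Era boundaries of the administrative databases: physician billing claims are
# observable from 1983, hospital discharge abstracts from 1987; ICD-10 replaced
# ICD-9 in the hospitalization stream at the start of 2006.
CLAIMS_ERA_START <- as.Date("1983-01-01")
HOSP_ERA_START <- as.Date("1987-01-01")
ICD10_HOSP_START <- as.Date("2006-01-01")

DATE_MIN <- as.Date("1900-01-01")
DATE_MAX <- as.Date("2100-01-01")

read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    stop("duplicate header column(s): ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                    stringsAsFactors = FALSE, na.strings = NULL,
                    quote = "\"", comment.char = "")
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("file '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

parse_iso_date <- function(x, path, what = "date") {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) | format(d, "%Y-%m-%d") != x)
  if (length(bad) > 0) {
    stop(sprintf("file '%s': malformed %s '%s' at data line %d", path, what,
                 x[bad[1]], bad[1] + 1L), call. = FALSE)
  }
  d
}

check_enum <- function(x, allowed, path, what) {
  bad <- which(!x %in% allowed)
  if (length(bad) > 0) {
    stop(sprintf(
      "file '%s': invalid %s '%s' at data line %d (allowed: %s)", path, what,
      x[bad[1]], bad[1] + 1L, paste(allowed, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Read a health-event table
#'
#' Reads one row per healthcare encounter (physician claim or hospitalization)
#' from a delimited text file. The delimiter is auto-detected from the file
#' extension (`.tsv` for tab, anything else comma). Required columns are
#' `person_id`, `date` (ISO 8601), `kind` (`physician_claim` or
#' `hospitalization`) and `code` plus `code_system` (`ICD9` or `ICD10`).
#'
#' Dates must fall in 1900--2100 and codes must be non-empty; a hospitalization
#' dated before 1987-01-01 (before the hospital discharge stream existed) is
#' accepted but flagged with a warning. Malformed rows raise an error naming
#' the offending line.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble of events sorted as read, with `date` as a `Date` column.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("person_id,date,kind,code,code_system",
#'              "p1,1990-05-01,physician_claim,493,ICD9"), f)
#' read_events(f)
read_events <- function(path) {
  df <- read_table_auto(path)
  require_columns(df, c("person_id", "date", "kind", "code", "code_system"),
                  path)
  if (nrow(df) == 0) {
    return(tibble::tibble(person_id = character(), date = as.Date(character()),
                          kind = character(), code = character(),
                          code_system = character()))
  }
  date <- parse_iso_date(df$date, path)
  check_enum(df$kind, EVENT_KINDS, path, "kind")
  check_enum(df$code_system, CODE_SYSTEMS, path, "code_system")
  if (any(df$code == "")) {
    stop(sprintf("file '%s': empty diagnosis code at data line %d", path,
                 which(df$code == "")[1] + 1L), call. = FALSE)
  }
  if (any(date < DATE_MIN | date > DATE_MAX)) {
    stop(sprintf("file '%s': date out of supported range at data line %d",
                 path, which(date < DATE_MIN | date > DATE_MAX)[1] + 1L),
         call. = FALSE)
  }
  early_hosp <- df$kind == "hospitalization" & date < HOSP_ERA_START
  if (any(early_hosp)) {
    warning(sprintf(
      "%d hospitalization(s) dated before %s, when no hospitalization data were collected",
      sum(early_hosp), format(HOSP_ERA_START)), call. = FALSE)
  }
  tibble::tibble(person_id = df$person_id, date = date, kind = df$kind,
                 code = df$code, code_system = df$code_system)
}

#' Read a person table
#'
#' Required columns: `person_id`, `birth_year`, `interview_date` (ISO 8601 or
#' empty for never interviewed) and `bcg` (`TRUE`/`FALSE`). Any further
#' columns are carried through as character covariates with empty fields
#' converted to `NA` (the missing marker for categorical covariates).
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble of persons.
#' @export
read_persons <- function(path) {
  df <- read_table_auto(path)
  require_columns(df, c("person_id", "birth_year", "interview_date", "bcg"),
                  path)
  birth_year <- suppressWarnings(as.integer(df$birth_year))
  if (anyNA(birth_year)) {
    stop(sprintf("file '%s': non-integer birth_year at data line %d", path,
                 which(is.na(birth_year))[1] + 1L), call. = FALSE)
  }
  has_itw <- df$interview_date != ""
  interview_date <- as.Date(rep(NA_character_, nrow(df)))
  if (any(has_itw)) {
    interview_date[has_itw] <- parse_iso_date(df$interview_date[has_itw],
                                              path, "interview_date")
  }
  check_enum(df$bcg, c("TRUE", "FALSE"), path, "bcg")
  out <- tibble::tibble(person_id = df$person_id, birth_year = birth_year,
                        interview_date = interview_date,
                        bcg = df$bcg == "TRUE")
  extra <- setdiff(names(df),
                   c("person_id", "birth_year", "interview_date", "bcg"))
  for (col in extra) out[[col]] <- ifelse(df[[col]] == "", NA, df[[col]])
  out
}

#' Read a self-report table
#'
#' Columns `person_id`, `ever_asthma`, `physician_diagnosed`; the latter two
#' are `TRUE`/`FALSE` or empty for missing. The questionnaire skip logic is
#' enforced: the physician-diagnosis item is only asked of respondents who
#' report ever having had asthma, so `physician_diagnosed` must be missing or
#' `FALSE` whenever `ever_asthma` is not `TRUE`.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble with logical `ever_asthma` and `physician_diagnosed`.
#' @export
read_self_reports <- function(path) {
  df <- read_table_auto(path)
  require_columns(df, c("person_id", "ever_asthma", "physician_diagnosed"),
                  path)
  to_lgl <- function(x, what) {
    check_enum(x, c("TRUE", "FALSE", ""), path, what)
    ifelse(x == "", NA, x == "TRUE")
  }
  ever <- to_lgl(df$ever_asthma, "ever_asthma")
  phys <- to_lgl(df$physician_diagnosed, "physician_diagnosed")
  bad <- which(phys %in% TRUE & !(ever %in% TRUE))
  if (length(bad) > 0) {
    stop(sprintf(
      "file '%s': physician_diagnosed TRUE without ever_asthma TRUE at data line %d (skip logic violated)",
      path, bad[1] + 1L), call. = FALSE)
  }
  tibble::tibble(person_id = df$person_id, ever_asthma = ever,
                 physician_diagnosed = phys)
}

strip_code <- function(code) toupper(gsub("[^A-Za-z0-9]", "", code))

#' Identify asthma diagnosis events
#'
#' Classifies events as asthma-related by 3-character rubric prefix after
#' stripping punctuation: ICD-9 `493` for all physician claims and for
#' hospitalizations up to the end of 2005, ICD-10 `J45` for hospitalizations
#' from 2006 onward. So `"4930"` and `"493.0"` match exactly when `"493"`
#' does.
#'
#' Events whose coding system disagrees with the era of their stream (an
#' ICD-10 hospitalization before 2006, or an ICD-9 hospitalization after
#' 2005) are a coding-dialect anomaly: with `on_era_mismatch = "warn"`
#' (default) they are still classified by their code prefix with a warning;
#' with `"reject"` they are classified `FALSE`. ICD-10 claims are matched on
#' `J45` (the claims stream is ICD-9 throughout the study period, so these are
#' also flagged).
#'
#' @param events Event tibble as returned by [read_events()].
#' @param on_era_mismatch `"warn"` or `"reject"`.
#' @return Logical vector, one element per event row.
#' @export
is_asthma_event <- function(events, on_era_mismatch = c("warn", "reject")) {
  on_era_mismatch <- match.arg(on_era_mismatch)
  code3 <- substr(strip_code(events$code), 1, 3)
  icd9_asthma <- events$code_system == "ICD9" & code3 == "493"
  icd10_asthma <- events$code_system == "ICD10" & code3 == "J45"
  hosp <- events$kind == "hospitalization"
  mismatch <- (hosp & events$code_system == "ICD10" &
                 events$date < ICD10_HOSP_START) |
    (hosp & events$code_system == "ICD9" & events$date >= ICD10_HOSP_START) |
    (!hosp & events$code_system == "ICD10")
  flagged <- mismatch & (icd9_asthma | icd10_asthma)
  if (any(flagged)) {
    warning(sprintf(
      "%d asthma-coded event(s) use an ICD revision outside its era%s",
      sum(flagged),
      if (on_era_mismatch == "reject") "; rejected" else ""), call. = FALSE)
  }
  out <- icd9_asthma | icd10_asthma
  if (on_era_mismatch == "reject") out <- out & !mismatch
  out
}

#' Normalize encounters to one event per person-day
#'
#' Administrative extracts can bill several claims on the same day; only one
#' encounter per person per calendar day is counted. When a claim and a
#' hospitalization coincide on a day, the hospitalization is the one retained.
#' Output is sorted by person then date. The operation is idempotent.
#'
#' @param events Event tibble (typically already asthma-filtered).
#' @return Event tibble with at most one row per (person, date).
#' @export
normalize_events <- function(events) {
  if (nrow(events) == 0) return(events)
  events |>
    dplyr::mutate(.hosp = .data$kind == "hospitalization") |>
    dplyr::arrange(.data$person_id, .data$date, dplyr::desc(.data$.hosp)) |>
    dplyr::distinct(.data$person_id, .data$date, .keep_all = TRUE) |>
    dplyr::select(-".hosp")
}
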