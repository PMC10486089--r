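test_that("event files parse, with line-addressed errors for bad rows", {
  f <- write_lines_tmp(c("person_id,date,kind,code,code_system",
                         "p1,1990-05-01,physician_claim,493,ICD9"))
  ev <- read_events(f)
  expect_equal(nrow(ev), 1)
  expect_s3_class(ev$date, "Date")
  expect_identical(ev$kind, "physician_claim")

  empty <- read_events(write_lines_tmp(
    "person_id,date,kind,code,code_system"))
  expect_equal(nrow(empty), 0)

  bad_kind <- write_lines_tmp(c("person_id,date,kind,code,code_system",
                                "p1,1990-05-01,visit,493,ICD9"))
  expect_error(read_events(bad_kind), "visit.*line 2")

  bad_date <- write_lines_tmp(c("person_id,date,kind,code,code_system",
                                "p1,1990-05-01,physician_claim,493,ICD9",
                                "p1,1990-13-40,physician_claim,493,ICD9"))
  expect_error(read_events(bad_date), "malformed date.*line 3")

  dup_header <- write_lines_tmp(c("person_id,date,date,code,code_system",
                                  "p1,1990-05-01,x,493,ICD9"))
  expect_error(read_events(dup_header), "duplicate header")

  tsv <- write_lines_tmp(c("person_id\tdate\tkind\tcode\tcode_system",
                           "p1\t1990-05-01\tphysician_claim\t493\tICD9"),
                         ext = ".tsv")
  expect_equal(nrow(read_events(tsv)), 1)
})

test_that("hospitalizations before the 1987 data era are flagged", {
  f <- write_lines_tmp(c("person_id,date,kind,code,code_system",
                         "p1,1985-05-01,hospitalization,493,ICD9"))
  expect_warning(read_events(f), "before 1987")
})

test_that("asthma codes are matched by rubric prefix and stream era", {
  ev <- tibble::tibble(
    person_id = "p1",
    date = as.Date(c("1990-05-01", "2007-03-10", "1990-05-01", "1995-01-01",
                     "2000-06-15", "2010-01-01")),
    kind = c("physician_claim", "hospitalization", "physician_claim",
             "hospitalization", "physician_claim", "physician_claim"),
    code = c("493", "J45", "486", "4930", "493.0", "49390"),
    code_system = c("ICD9", "ICD10", "ICD9", "ICD9", "ICD9", "ICD9"))
  expect_identical(is_asthma_event(ev),
                   c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
})

test_that("code suffixes and punctuation do not change the match", {
  for (code in c("493", "4930", "493.0", "49390")) {
    ev <- make_events("p1", "1990-01-01", code = code)
    expect_true(is_asthma_event(ev), label = code)
  }
  for (code in c("J45", "J450", "J45.0")) {
    ev <- make_events("p1", "2008-01-01", kind = "hospitalization",
                      code = code, code_system = "ICD10")
    expect_true(is_asthma_event(ev), label = code)
  }
  expect_false(is_asthma_event(make_events("p1", "1990-01-01",
                                           code = "449")))
  # suffix rule: "4931" shares the "493" rubric, so it matches too
  expect_true(is_asthma_event(make_events("p1", "1990-01-01",
                                          code = "4931")))
})

test_that("era-mismatched coding is warned about or rejected", {
  # ICD-10 hospitalization before 2006
  early10 <- make_events("p1", "2004-02-02", kind = "hospitalization",
                         code = "J45", code_system = "ICD10")
  expect_warning(r <- is_asthma_event(early10), "era")
  expect_true(r)
  expect_warning(r2 <- is_asthma_event(early10, on_era_mismatch = "reject"),
                 "rejected")
  expect_false(r2)
  # ICD-9 hospitalization after 2005
  late9 <- make_events("p1", "2008-02-02", kind = "hospitalization",
                       code = "493", code_system = "ICD9")
  expect_warning(is_asthma_event(late9), "era")
})

test_that("normalization keeps one encounter per day, hospitalization first", {
  trip <- make_events("p1", rep("1991-02-02", 3))
  expect_equal(nrow(normalize_events(trip)), 1)
  expect_identical(normalize_events(trip)$kind, "physician_claim")

  both <- dplyr::bind_rows(
    make_events("p1", "1992-07-01"),
    make_events("p1", "1992-07-01", kind = "hospitalization"))
  kept <- normalize_events(both)
  expect_equal(nrow(kept), 1)
  expect_identical(kept$kind, "hospitalization")

  expect_equal(nrow(normalize_events(make_events("p1", character(0)))), 0)
})

test_that("normalization is idempotent and counts distinct person-days", {
  set.seed(101)
  for (i in 1:25) {
    ev <- dplyr::bind_rows(
      make_events("a", as.Date("1990-01-01") + sample(0:30, 12, TRUE)),
      make_events("b", as.Date("1990-01-01") + sample(0:10, 6, TRUE),
                  kind = "hospitalization"))
    once <- normalize_events(ev)
    expect_identical(normalize_events(once), once)
    expect_equal(nrow(once),
                 nrow(dplyr::distinct(ev, person_id, date)))
  }
})

test_that("person and self-report readers enforce their contracts", {
  pf <- write_lines_tmp(c("person_id,birth_year,interview_date,bcg,sex",
                          "p1,1974,2012-06-30,TRUE,female",
                          "p2,1974,,FALSE,"))
  pp <- read_persons(pf)
  expect_equal(nrow(pp), 2)
  expect_true(is.na(pp$interview_date[2]))
  expect_true(is.na(pp$sex[2]))

  sf <- write_lines_tmp(c("person_id,ever_asthma,physician_diagnosed",
                          "p1,TRUE,TRUE", "p2,FALSE,", "p3,,"))
  sr <- read_self_reports(sf)
  expect_identical(sr$ever_asthma, c(TRUE, FALSE, NA))

  bad <- write_lines_tmp(c("person_id,ever_asthma,physician_diagnosed",
                           "p1,FALSE,TRUE"))
  expect_error(read_self_reports(bad), "skip logic")
})
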