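spec_lurbi <- cohort_spec(c("lurbinectedin", "PM-01183", "ZEPZELCA"))

test_that("the descriptive fixture reproduces its published percentages", {
  snap <- fixture_table6()
  cs <- summarize_clinical(snap, snap$demo$primaryid,
                           countries = c("US", "CA", "FR", "CN"))
  expect_equal(cs$n_reports, 511L)
  get <- function(tab, cat, col = "pct") tab[[col]][tab$category == cat]
  expect_equal(get(cs$sex, "Male"), 37.6)
  expect_equal(get(cs$sex, "Female"), 30.9)
  expect_equal(get(cs$age, "18-64"), 19.6)
  expect_equal(get(cs$age, "65-85"), 22.3)
  expect_equal(get(cs$year, "2021"), 40.9)
  expect_equal(get(cs$country, "US"), 48.7)
  expect_equal(get(cs$occupation, "Physician"), 38.4)
  # outcome percentages use the outcome-entry denominator (729 entries)
  expect_equal(cs$n_outcome_entries, 729L)
  expect_equal(get(cs$outcome, "Death", "n"), 145L)
  expect_equal(get(cs$outcome, "Death"), 19.9)
})

test_that("each characteristic's percentages sum to 100 within rounding", {
  snap <- fixture_table6()
  cs <- summarize_clinical(snap, snap$demo$primaryid)
  for (nm in c("sex", "age", "year", "country", "occupation", "outcome")) {
    expect_equal(sum(cs[[nm]]$pct), 100, tolerance = 0.2)
    # counts of report-level characteristics partition the cohort
    if (nm != "outcome") expect_equal(sum(cs[[nm]]$n), cs$n_reports)
  }
})

test_that("fully missing fields all land in Unknown", {
  demo <- data.frame(primaryid = c("1", "2"), caseid = c("1", "2"),
                     fda_dt = NA_integer_, event_dt = "", age = NA_real_,
                     age_cod = "", sex = "UNK", occr_country = "",
                     occp_cod = "", stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = c("1", "2"), drug_seq = 1L,
                     role_cod = "PS", drugname = "X",
                     stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = c("1", "2"), pt = "EV",
                     stringsAsFactors = FALSE)
  cs <- summarize_clinical(make_snapshot(demo, drug, reac), c("1", "2"))
  expect_equal(cs$sex$pct[cs$sex$category == "Unknown"], 100)
  expect_equal(cs$age$pct[cs$age$category == "Unknown"], 100)
  expect_equal(cs$outcome$pct[cs$outcome$category == "Unknown"], 100)
  for (nm in c("sex", "age", "year", "country", "occupation", "outcome")) {
    expect_equal(sum(cs[[nm]]$pct), 100, tolerance = 0.2)
  }
})

test_that("top-k tables rank indications and concomitants with ties broken alphabetically", {
  snap <- fixture_table6()
  ind <- top_k(snap, spec_lurbi, "indications", k = 5)
  expect_equal(ind$name,
               c("Small cell lung cancer", "Prophylaxis", "Metastatic SCLC",
                 "Extensive stage SCLC", "Hypertension"))
  expect_equal(ind$count, c(220L, 75L, 56L, 51L, 32L))
  # the unknown-indication term is excluded from the ranking
  expect_false(any(grepl("unknown", ind$name, ignore.case = TRUE)))
  co <- top_k(snap, spec_lurbi, "concomitants", k = 5)
  expect_equal(co$count, c(63L, 52L, 47L, 47L, 44L))
  # tie at 47 broken alphabetically
  expect_equal(co$name[3:4], c("ATEZOLIZUMAB", "IRINOTECAN"))
})

test_that("a concomitant repeated within one report counts once", {
  demo <- data.frame(primaryid = "1", caseid = "1", fda_dt = 20210101L,
                     event_dt = "", age = NA_real_, age_cod = "",
                     sex = "UNK", occr_country = "", occp_cod = "",
                     stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = "1", drug_seq = 1:3,
    role_cod = c("PS", "C", "C"),
    drugname = c("TARGETDRUG", "DEXAMETHASONE 4MG", "Dexamethasone"),
    stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = "1", pt = "EV", stringsAsFactors = FALSE)
  snap <- make_snapshot(demo, drug, reac)
  co <- top_k(snap, cohort_spec("TARGETDRUG"), "concomitants", k = 5)
  expect_equal(nrow(co), 2L)  # two distinct normalized names
  expect_true(all(co$count == 1L))
})

test_that("onset arithmetic uses day-resolution dates of the target drug", {
  demo <- data.frame(
    primaryid = c("1", "2", "3", "4"), caseid = c("1", "2", "3", "4"),
    fda_dt = 20210601L,
    event_dt = c("20210126", "20201201", "202101", "20210110"),
    age = NA_real_, age_cod = "", sex = "UNK", occr_country = "",
    occp_cod = "", stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = c("1", "2", "3", "4", "4"),
                     drug_seq = c(1L, 1L, 1L, 1L, 2L),
                     role_cod = "PS", drugname = "TARGETDRUG",
                     stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = c("1", "2", "3", "4"), pt = "EV",
                     stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = c("1", "2", "3", "4", "4"),
                     drug_seq = c(1L, 1L, 1L, 1L, 2L),
                     start_dt = c("20210101", "20210101", "20210101",
                                  "20210105", "20210101"),
                     stringsAsFactors = FALSE)
  snap <- make_snapshot(demo, drug, reac, ther = ther)
  days <- onset_days(snap, cohort_spec("TARGETDRUG"))
  # report 1: 25 days; report 2: negative, dropped and counted;
  # report 3: partial event date, excluded; report 4: earliest of the two
  # therapy starts (Jan 1) -> 9 days
  expect_setequal(days, c(25L, 9L))
  expect_equal(attr(days, "n_excluded"), 1L)
})

test_that("onset summary reports quartiles and inclusive bins", {
  s <- summarize_onset(c(8, 25, 64))
  expect_equal(s$median_days, 25)
  expect_equal(s$q1_days, 8)
  expect_equal(s$q3_days, 64)
  expect_true(s$q1_days <= s$median_days && s$median_days <= s$q3_days)
  # upper bin edges are inclusive
  s30 <- summarize_onset(30)
  expect_equal(s30$bins$n[s30$bins$bin == "0-30"], 1L)
  s0 <- summarize_onset(integer(0))
  expect_equal(s0$n_with_onset, 0L)
  # bins partition the sample
  sm <- summarize_onset(c(0, 15, 30, 31, 60, 61, 90, 91, 180, 181, 400))
  expect_equal(sum(sm$bins$n), sm$n_with_onset)
  expect_equal(sm$bins$n, c(3L, 2L, 2L, 2L, 2L))
})

test_that("a seeded generator cohort recovers the onset-model median", {
  cfg <- synth_config(
    seed = 160, n_reports = 16000,
    event_catalog = default_event_catalog(n_pt = 30),
    missing_rates = list(sex = 0, age = 0, country = 0, occupation = 0,
                         event_dt = 0, start_dt = 0))
  sim <- synth_generate(cfg)
  snap <- dedup_snapshot(sim$snapshot)
  spec <- cohort_spec("LURBINECTEDIN")
  days <- onset_days(snap, spec)
  expect_gt(length(days), 100)
  s <- summarize_onset(days)
  # median parameter 25 d, recovery within 20%
  expect_lt(abs(s$median_days - 25) / 25, 0.2)
  # with no missingness, the recovered day counts are exactly the
  # generator's realized onset draws for the target reports
  draws <- unlist(sim$manifest$onset_draws_target)
  expect_equal(sort(as.integer(unname(days))), sort(as.integer(draws)))
})
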