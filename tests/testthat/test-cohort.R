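test_that("cohort matching honours role filter and name normalization", {
  demo <- data.frame(primaryid = c("1", "2", "3"), caseid = c("1", "2", "3"),
                     fda_dt = 20210101L, event_dt = "", age = NA_real_,
                     age_cod = "", sex = "UNK", occr_country = "",
                     occp_cod = "", stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = c("1", "2", "3"), drug_seq = 1L,
    role_cod = c("PS", "C", "PS"),
    drugname = c("ZEPZELCA", "zepzelca 4mg vial", "Pm-01183"),
    stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = c("1", "2", "3"), pt = "Nausea",
                     stringsAsFactors = FALSE)
  snap <- make_snapshot(demo, drug, reac)
  spec <- cohort_spec(c("lurbinectedin", "PM-01183", "ZEPZELCA"),
                      role_filter = "PS")
  # report 2 matches by name (substring, case-folded) but fails the PS role;
  # report 3 matches the former development name case-insensitively
  expect_setequal(match_target_reports(snap, spec), c("1", "3"))
  # widening the role filter picks up the concomitant entry too
  spec_all <- cohort_spec("zepzelca", role_filter = c("PS", "SS", "C", "I"))
  expect_setequal(match_target_reports(snap, spec_all), c("1", "2"))
  # exact-match mode rejects the suffixed form
  spec_exact <- cohort_spec("ZEPZELCA", role_filter = c("PS", "C"),
                            exact = TRUE)
  expect_setequal(match_target_reports(snap, spec_exact), "1")
})

test_that("an indication filter requires the matching entry to carry it", {
  demo <- data.frame(primaryid = "1", caseid = "1", fda_dt = 20210101L,
                     event_dt = "", age = NA_real_, age_cod = "",
                     sex = "UNK", occr_country = "", occp_cod = "",
                     stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = "1", drug_seq = 1L, role_cod = "PS",
                     drugname = "ZEPZELCA", stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = "1", pt = "Nausea",
                     stringsAsFactors = FALSE)
  indi <- data.frame(primaryid = "1", drug_seq = 1L,
                     indi_pt = "Hypertension", stringsAsFactors = FALSE)
  snap <- make_snapshot(demo, drug, reac, indi = indi)
  spec <- cohort_spec("ZEPZELCA", indication_filter =
                        c("Metastatic SCLC", "Extensive stage SCLC"))
  expect_warning(ids <- match_target_reports(snap, spec), "no reports")
  expect_length(ids, 0)
  spec2 <- cohort_spec("ZEPZELCA", indication_filter = "Hypertension")
  expect_equal(match_target_reports(snap, spec2), "1")
})

test_that("event counting is report-level: one contribution per report", {
  demo <- data.frame(primaryid = c("1", "2"), caseid = c("1", "2"),
                     fda_dt = 20210101L, event_dt = "", age = NA_real_,
                     age_cod = "", sex = "UNK", occr_country = "",
                     occp_cod = "", stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = c("1", "2"), drug_seq = 1L,
                     role_cod = "PS", drugname = "TARGETDRUG",
                     stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = c("1", "1", "2"),
                     pt = c("Nausea", "Vomiting", "Nausea"),
                     stringsAsFactors = FALSE)
  dict <- data.frame(pt = c("Nausea", "Vomiting"),
                     soc = "Gastrointestinal disorders",
                     stringsAsFactors = FALSE)
  snap <- make_snapshot(demo, drug, reac, dict = dict)
  pt <- event_counts(snap, c("1", "2"), level = "PT")
  expect_equal(pt$a[pt$event == "Nausea"], 2L)
  expect_equal(pt$a[pt$event == "Vomiting"], 1L)
  soc <- event_counts(snap, c("1", "2"), level = "SOC")
  # report 1 carries two PTs of the same SOC but counts once
  expect_equal(soc$a[soc$event == "Gastrointestinal disorders"], 2L)
  soc_pair <- event_counts(snap, c("1", "2"), level = "SOC", unit = "pair")
  expect_equal(soc_pair$a[soc_pair$event == "Gastrointestinal disorders"], 3L)
})

test_that("contingency cells derive from margins by subtraction", {
  t1 <- build_contingency(10, 110, 100, 1100)
  expect_equal(unlist(t1), c(a = 10L, b = 90L, c = 100L, d = 900L))
  t0 <- build_contingency(0, 25, 100, 1100)
  expect_equal(unlist(t0), c(a = 0L, b = 100L, c = 25L, d = 975L))
  expect_error(build_contingency(10, 5, 100, 1100), "negative")
  expect_error(build_contingency(10, 1050, 100, 1100), "negative")
})

test_that("margin-derived tables equal brute-force per-report classification", {
  snap <- make_oracle_snapshot()
  spec <- cohort_spec("TARGETDRUG")
  ids <- match_target_reports(snap, spec)
  for (level in c("PT", "SOC")) {
    counts <- event_counts(snap, ids, level = level)
    mg <- faersignal:::.margins(snap, ids, "report")
    cells <- build_contingency(counts$a, counts$a_c, mg$margin, mg$n_total)
    # brute force: classify every report for every event
    reac <- snap$reac
    if (level == "SOC") {
      reac$event <- snap$dict$soc[match(reac$pt, snap$dict$pt)]
    } else reac$event <- reac$pt
    for (i in seq_len(nrow(counts))) {
      ev <- counts$event[i]
      with_ev <- unique(reac$primaryid[reac$event == ev])
      all_ids <- snap$demo$primaryid
      a <- sum(all_ids %in% ids & all_ids %in% with_ev)
      b <- sum(all_ids %in% ids & !(all_ids %in% with_ev))
      cc <- sum(!(all_ids %in% ids) & all_ids %in% with_ev)
      d <- sum(!(all_ids %in% ids) & !(all_ids %in% with_ev))
      expect_equal(unlist(cells[i, ]), c(a = a, b = b, c = cc, d = d),
                   info = paste(level, ev))
    }
    # a+b is the same for every event at a given level
    expect_true(all(cells$a + cells$b == mg$margin))
    expect_equal(counts$a_c, cells$a + cells$c)
  }
})
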