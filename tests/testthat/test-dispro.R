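# Direct-arithmetic oracles for the four statistics, written out
# independently of the implementation.
oracle_ror <- function(a, b, c, d) a * d / (b * c)
oracle_prr <- function(a, b, c, d) (a / (a + b)) / (c / (c + d))
oracle_ebgm <- function(a, b, c, d) a * (a + b + c + d) / ((a + b) * (a + c))
oracle_chi2 <- function(a, b, c, d) {
  # Pearson's sum over observed and expected cells, no correction
  suppressWarnings(
    stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                      correct = FALSE)$statistic[[1]])
}

test_that("point statistics match direct-arithmetic oracles", {
  cases <- list(c(25, 75, 100, 900), c(20, 80, 100, 9800),
                c(3, 47, 11, 939), c(150, 850, 1500, 17500))
  for (t in cases) {
    a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
    expect_equal(ror_stat(a, b, c, d)$ror, oracle_ror(a, b, c, d))
    expect_equal(prr_stat(a, b, c, d), oracle_prr(a, b, c, d))
    expect_equal(ebgm_stat(a, b, c, d)$ebgm, oracle_ebgm(a, b, c, d))
    expect_equal(chi_square(a, b, c, d), oracle_chi2(a, b, c, d),
                 tolerance = 1e-12)
    expect_equal(ic_stat(a, b, c, d)$ic, log2(oracle_ebgm(a, b, c, d)))
  }
  # frozen spot values
  expect_equal(ror_stat(25, 75, 100, 900)$ror, 3.0)
  expect_equal(ror_stat(20, 80, 100, 9800)$ror, 24.5)
  expect_equal(prr_stat(25, 75, 100, 900), 2.5)
  expect_equal(prr_stat(20, 80, 100, 9800), 19.8)
  expect_equal(chi_square(25, 75, 100, 900), 20.3077, tolerance = 1e-4)
  expect_equal(chi_square(20, 80, 100, 9800), 301.13, tolerance = 1e-4)
  expect_equal(ebgm_stat(25, 75, 100, 900)$ebgm, 2.2)
  expect_equal(ebgm_stat(20, 80, 100, 9800)$ebgm, 16.6667, tolerance = 1e-4)
  expect_equal(ic_stat(25, 75, 100, 900)$ic, 1.1375, tolerance = 1e-4)
})

test_that("an independent table is the exact null of all four algorithms", {
  s <- signal_stats(10, 90, 100, 900)
  expect_equal(s$ror, 1)
  expect_equal(s$prr, 1)
  expect_equal(s$ebgm, 1)
  expect_equal(s$ic, 0)
  expect_equal(s$chi2, 0)
  flags <- evaluate_criteria(s)
  expect_false(any(unlist(flags)))
})

test_that("interval bounds bracket the point estimates", {
  tabs <- random_tables(200, seed = 3)
  s <- signal_stats(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_true(all(s$ror_lo95 <= s$ror & s$ror <= s$ror_hi95))
  expect_true(all(s$ebgm05 <= s$ebgm))
  expect_true(all(s$ic025 < s$ic))
})

test_that("IC equals log2(EBGM), including on published value pairs", {
  tabs <- random_tables(500, seed = 5)
  s <- signal_stats(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(s$ic, log2(s$ebgm), tolerance = 1e-15)
  # relative-reporting-ratio values with their published 2-decimal ICs
  expect_equal(round(log2(c(6.11, 62.37, 316.02)), 2), c(2.61, 5.96, 8.30))
})

test_that("closed-form chi-square equals the sum over cells", {
  tabs <- random_tables(1000, lo = 1, hi = 1e4, seed = 9)
  ours <- chi_square(tabs$a, tabs$b, tabs$c, tabs$d)
  direct <- mapply(function(a, b, c, d) {
    n <- a + b + c + d
    o <- c(a, b, c, d)
    e <- c((a + b) * (a + c), (a + b) * (b + d),
           (c + d) * (a + c), (c + d) * (b + d)) / n
    sum((o - e)^2 / e)
  }, tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(ours, direct, tolerance = 1e-9)
})

test_that("ratios are scale-invariant while chi-square scales with N", {
  base <- c(12, 88, 140, 1760)
  for (k in c(2, 5, 10)) {
    s1 <- signal_stats(base[1], base[2], base[3], base[4])
    s2 <- signal_stats(k * base[1], k * base[2], k * base[3], k * base[4])
    expect_equal(s2$ror, s1$ror)
    expect_equal(s2$prr, s1$prr)
    expect_equal(s2$ebgm, s1$ebgm)
    expect_equal(s2$ic, s1$ic)
    expect_equal(s2$chi2, k * s1$chi2)
  }
})

test_that("all four point statistics are non-decreasing in a", {
  b <- 200; c <- 500; d <- 12000
  a <- 1:60
  s <- signal_stats(a, rep(b, 60), rep(c, 60), rep(d, 60))
  expect_true(all(diff(s$ror) >= 0))
  expect_true(all(diff(s$prr) >= 0))
  expect_true(all(diff(s$ebgm) >= 0))
  expect_true(all(diff(s$ic) >= 0))
})

test_that("zero cells flag statistics undefined unless Haldane-corrected", {
  s <- signal_stats(5, 95, 0, 1000)
  expect_true(is.na(s$ror))
  expect_true(is.na(s$prr))
  flags <- evaluate_criteria(s)
  expect_false(flags$ror_flag)
  expect_false(flags$prr_flag)
  expect_false(flags$consensus)
  # a = 0: EBGM is 0, its bound undefined, never silently dropped
  s0 <- signal_stats(0, 100, 50, 1000)
  expect_equal(s0$ebgm, 0)
  expect_true(is.na(s0$ebgm05))
  expect_true(is.na(s0$ic))
  ch <- dispro_config(zero_cell = "haldane")
  sh <- signal_stats(5, 95, 0, 1000, config = ch)
  expect_false(anyNA(sh[c("ror", "prr", "ebgm", "ic")]))
})

test_that("signal criteria respect their report-count minima", {
  # strong disproportionality at n = 2 cannot reach consensus (PRR needs 3)
  s2 <- signal_stats(2, 98, 2, 9898)
  f2 <- evaluate_criteria(s2)
  expect_true(f2$ror_flag)
  expect_false(f2$prr_flag)
  expect_false(f2$consensus)
  # the worked strong-signal table passes all four
  s <- signal_stats(20, 80, 100, 9800)
  f <- evaluate_criteria(s)
  expect_true(all(unlist(f)))
})

test_that("screening finds an injected association as the unique signal", {
  cfg <- synth_config(
    seed = 303, n_reports = 20000,
    event_catalog = default_event_catalog(n_pt = 50),
    signals = list(list(drug = "LURBINECTEDIN", pt = "PT 040",
                        lambda = 15)))
  snap <- dedup_snapshot(synth_generate(cfg)$snapshot)
  scr <- dispro_screen(snap, cohort_spec("LURBINECTEDIN"))
  sig <- signals(scr)
  expect_equal(sig$event, "PT 040")
  expect_true(sig$ror > 5)
  # the screen table is sorted by report count and keeps non-signal rows
  expect_true(all(diff(scr$table$n) <= 0))
  expect_gt(nrow(scr$table), nrow(sig))
})

test_that("screening is invariant to input row order", {
  cfg <- synth_config(seed = 7, n_reports = 2000,
                      event_catalog = default_event_catalog(n_pt = 30))
  snap <- dedup_snapshot(synth_generate(cfg)$snapshot)
  scr1 <- dispro_screen(snap, cohort_spec("LURBINECTEDIN"))
  set.seed(1)
  snap2 <- snap
  for (tb in c("demo", "drug", "reac")) {
    snap2[[tb]] <- snap2[[tb]][sample(nrow(snap2[[tb]])), ]
  }
  scr2 <- dispro_screen(snap2, cohort_spec("LURBINECTEDIN"))
  expect_identical(scr1$table, scr2$table)
})

test_that("a cohort with no reports yields an empty table and a warning", {
  snap <- dedup_snapshot(synth_generate(
    synth_config(seed = 2, n_reports = 500,
                 event_catalog = default_event_catalog(n_pt = 20)))$snapshot)
  expect_warning(scr <- dispro_screen(snap, cohort_spec("NOSUCHDRUG")),
                 "no target reports")
  expect_equal(nrow(scr$table), 0L)
})
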