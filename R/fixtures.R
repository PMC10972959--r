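# Deterministic golden-value fixture.

#' Golden descriptive fixture: a 511-report cohort snapshot
#'
#' Builds, in code, a deduplicated snapshot of 511 reports of one target
#' drug whose marginal category counts reproduce a published descriptive
#' table of a post-marketing cohort: sex 192 M / 158 F / 161 unknown; age
#' bins 100 / 114 / 3 / 294 (with a few ages coded in months and days to
#' exercise unit conversion); report years 21 / 209 / 126 / 155 across
#' 2020-2023; countries US 249, CA 88, FR 39, CN 4, others 131; reporter
#' occupations 104 consumers, 123 pharmacists, 196 physicians, 88 unknown;
#' and 601 outcome entries (145 death, 2 disability, 137 hospitalization,
#' 12 life-threatening, 305 other serious) over 383 reports, the other 128
#' reports carrying no outcome. Indications and concomitant drugs follow
#' the same cohort's top-5 tables, and three reports carry day-resolution
#' onset data of 8, 25 and 64 days.
#'
#' @return a deduplicated \code{faers_snapshot}.
#' @export
fixture_table6 <- function() {
  n <- 511L
  caseid <- as.character(2000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  years <- c(rep(2021L, 209), rep(2020L, 21), rep(2022L, 126),
             rep(2023L, 155))
  fda_dt <- as.integer(paste0(years, "0915"))

  sex <- c(rep("M", 192), rep("F", 158), rep("UNK", 161))

  age <- rep(NA_real_, n); age_cod <- rep("", n)
  age[1:97] <- 50; age_cod[1:97] <- "YR"
  age[98:99] <- 480; age_cod[98:99] <- "MON"      # 40 years
  age[100] <- 14610; age_cod[100] <- "DY"          # 40 years
  age[101:214] <- 70; age_cod[101:214] <- "YR"
  age[215:217] <- 90; age_cod[215:217] <- "YR"

  country <- c(rep("US", 249), rep("CA", 88), rep("FR", 39), rep("CN", 4),
               rep("GB", 40), rep("JP", 30), rep("DE", 30), rep("IT", 31))

  occp <- c(rep("CN", 104), rep("PH", 123), rep("MD", 196), rep("", 60),
            rep("OT", 28))

  event_dt <- rep("", n)
  event_dt[1:3] <- c("20210109", "20210126", "20210306")  # 8, 25, 64 days

  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     fda_dt = fda_dt, event_dt = event_dt, age = age,
                     age_cod = age_cod, sex = sex, occr_country = country,
                     occp_cod = occp, stringsAsFactors = FALSE)

  # outcome entries: 601 coded rows over reports 1..383; a report never
  # repeats a code (second entries are all OT, first entries of those
  # reports are DE/DS/HO)
  codes <- c(rep("DE", 145), rep("DS", 2), rep("HO", 137), rep("LT", 12),
             rep("OT", 305))
  outc <- data.frame(
    primaryid = c(primaryid[1:383], primaryid[1:218]),
    outc_cod = c(codes[1:383], codes[384:601]),
    stringsAsFactors = FALSE)

  target <- "LURBINECTEDIN"
  co <- list(c("DEXAMETHASONE", 63), c("ONDANSETRON", 52),
             c("IRINOTECAN", 47), c("ATEZOLIZUMAB", 47),
             c("CARBOPLATIN", 44))
  drug <- data.frame(primaryid = primaryid, drug_seq = 1L, role_cod = "PS",
                     drugname = target, stringsAsFactors = FALSE)
  for (k in seq_along(co)) {
    m <- as.integer(co[[k]][2])
    drug <- rbind(drug, data.frame(
      primaryid = primaryid[seq_len(m)], drug_seq = k + 1L,
      role_cod = "C", drugname = co[[k]][1], stringsAsFactors = FALSE))
  }

  ind <- c(rep("Small cell lung cancer", 220), rep("Prophylaxis", 75),
           rep("Metastatic SCLC", 56), rep("Extensive stage SCLC", 51),
           rep("Hypertension", 32),
           rep("Product used for unknown indication", 77))
  indi <- data.frame(primaryid = primaryid, drug_seq = 1L, indi_pt = ind,
                     stringsAsFactors = FALSE)

  reac <- rbind(
    data.frame(primaryid = primaryid, pt = "Fatigue",
               stringsAsFactors = FALSE),
    data.frame(primaryid = primaryid[1:10], pt = "Tumour lysis syndrome",
               stringsAsFactors = FALSE),
    data.frame(primaryid = primaryid[6:7], pt = "Pneumonia",
               stringsAsFactors = FALSE),
    data.frame(primaryid = primaryid[11:21], pt = "Acute kidney injury",
               stringsAsFactors = FALSE))

  ther <- data.frame(primaryid = primaryid[1:3], drug_seq = 1L,
                     start_dt = "20210101", stringsAsFactors = FALSE)

  dict <- data.frame(
    pt = c("Fatigue", "Tumour lysis syndrome", "Pneumonia",
           "Acute kidney injury"),
    soc = c("General disorders and administration site conditions",
            "Metabolism and nutrition disorders",
            "Infections and infestations",
            "Renal and urinary disorders"),
    stringsAsFactors = FALSE)

  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 indi = indi, ther = ther, dict = dict, load_log = NULL,
                 orphans = integer(0), deduplicated = TRUE),
            class = "faers_snapshot")
}
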