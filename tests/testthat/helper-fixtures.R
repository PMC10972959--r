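# Fixtures are built in code at test time; nothing is stored on disk.

# Write a "$"-delimited FAERS-dialect file from a data frame.
write_faers_file <- function(df, path) {
  con <- file(path, open = "wb")
  utils::write.table(df, con, sep = "$", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  close(con)
  path
}

# A minimal valid snapshot directory with n reports of one target drug
# plus background reports; returns the directory.
write_mini_snapshot_dir <- function(dir = tempfile("snap")) {
  dir.create(dir)
  demo <- data.frame(
    primaryid = c("101", "201", "301", "401"),
    caseid = c("10", "20", "30", "40"),
    fda_dt = c("20210101", "20210202", "20210303", "20210404"),
    event_dt = "", age = c("60", "70", "", "55"),
    age_cod = c("YR", "YR", "", "YR"),
    sex = c("M", "F", "", "M"),
    occr_country = c("US", "US", "FR", "CA"),
    occp_cod = c("MD", "PH", "", "CN"))
  drug <- data.frame(
    primaryid = c("101", "201", "301", "401"),
    drug_seq = "1",
    role_cod = c("PS", "PS", "PS", "PS"),
    drugname = c("TARGETDRUG", "TARGETDRUG", "OTHERDRUG", "OTHERDRUG"))
  reac <- data.frame(
    primaryid = c("101", "201", "301", "401"),
    pt = c("Nausea", "Vomiting", "Nausea", "Headache"))
  write_faers_file(demo, file.path(dir, "DEMO.txt"))
  write_faers_file(drug, file.path(dir, "DRUG.txt"))
  write_faers_file(reac, file.path(dir, "REAC.txt"))
  dict <- data.frame(pt = c("Nausea", "Vomiting", "Headache"),
                     soc = c("Gastrointestinal disorders",
                             "Gastrointestinal disorders",
                             "Nervous system disorders"))
  con <- file(file.path(dir, "event_dict.tsv"), open = "wb")
  utils::write.table(dict, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  close(con)
  dir
}

# In-memory snapshot builder from compact per-report specifications.
# reports: list of list(id, caseid, fda, drugs = data.frame(name, role,
# seq), pts = character, inds = data.frame(seq, pt), ...)
make_snapshot <- function(demo, drug, reac,
                          outc = NULL, indi = NULL, ther = NULL,
                          dict = NULL, deduplicated = TRUE) {
  empty <- function(cols) as.data.frame(setNames(
    rep(list(character(0)), length(cols)), cols))
  if (is.null(outc)) outc <- empty(c("primaryid", "outc_cod"))
  if (is.null(indi)) {
    indi <- empty(c("primaryid", "drug_seq", "indi_pt"))
    indi$drug_seq <- integer(0)
  }
  if (is.null(ther)) {
    ther <- empty(c("primaryid", "drug_seq", "start_dt"))
    ther$drug_seq <- integer(0)
  }
  if (is.null(dict)) {
    dict <- data.frame(pt = unique(reac$pt), soc = "SOC A",
                       stringsAsFactors = FALSE)
  }
  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 indi = indi, ther = ther, dict = dict, load_log = NULL,
                 orphans = integer(0), deduplicated = deduplicated),
            class = "faers_snapshot")
}

# A deterministic 50-report snapshot with two drugs and four events,
# used for brute-force contingency oracles.
make_oracle_snapshot <- function(seed = 7) {
  set.seed(seed)
  n <- 50
  ids <- sprintf("%03d", seq_len(n))
  target <- seq_len(n) <= 15
  demo <- data.frame(primaryid = ids, caseid = ids,
                     fda_dt = 20210101L, event_dt = "", age = NA_real_,
                     age_cod = "", sex = "UNK", occr_country = "US",
                     occp_cod = "", stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = ids, drug_seq = 1L,
                     role_cod = "PS",
                     drugname = ifelse(target, "TARGETDRUG", "OTHERDRUG"),
                     stringsAsFactors = FALSE)
  pts <- c("EV1", "EV2", "EV3", "EV4")
  socs <- c(EV1 = "SOC A", EV2 = "SOC A", EV3 = "SOC B", EV4 = "SOC B")
  reac <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    data.frame(primaryid = ids[i],
               pt = sample(pts, k, prob = c(0.4, 0.3, 0.2, 0.1)),
               stringsAsFactors = FALSE)
  }))
  reac <- reac[!duplicated(reac), ]
  dict <- data.frame(pt = pts, soc = unname(socs[pts]),
                     stringsAsFactors = FALSE)
  make_snapshot(demo, drug, reac, dict = dict)
}

# Two-stratum snapshot for subgroup validation: EV1 is strongly
# associated with the target drug in both indication strata, EV2 only in
# stratum A (2 target reports in stratum B fail the n >= 3 criterion).
make_strata_snapshot <- function() {
  mk_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  rows <- list(); drugs <- list(); reacs <- list(); inds <- list()
  add <- function(ids, drugname, ind, pts_per_report) {
    rows[[length(rows) + 1]] <<- data.frame(
      primaryid = ids, caseid = ids, fda_dt = 20220101L, event_dt = "",
      age = NA_real_, age_cod = "", sex = "UNK", occr_country = "US",
      occp_cod = "", stringsAsFactors = FALSE)
    drugs[[length(drugs) + 1]] <<- data.frame(
      primaryid = ids, drug_seq = 1L, role_cod = "PS",
      drugname = drugname, stringsAsFactors = FALSE)
    inds[[length(inds) + 1]] <<- data.frame(
      primaryid = ids, drug_seq = 1L, indi_pt = ind,
      stringsAsFactors = FALSE)
    for (i in seq_along(ids)) {
      reacs[[length(reacs) + 1]] <<- data.frame(
        primaryid = ids[i], pt = pts_per_report[[i]],
        stringsAsFactors = FALSE)
    }
  }
  # stratum A: 40 target (30 EV1, 25 EV2), 400 background (5 EV1, 5 EV2)
  idsA <- mk_ids("A", 40)
  ptsA <- lapply(seq_len(40), function(i)
    c("Background event", if (i <= 30) "EV1", if (i <= 25) "EV2"))
  add(idsA, "TARGETDRUG", "IndA", ptsA)
  idsAb <- mk_ids("B", 400)
  ptsAb <- lapply(seq_len(400), function(i)
    c("Background event", if (i <= 5) "EV1", if (i > 5 && i <= 10) "EV2"))
  add(idsAb, "OTHERDRUG", "IndA", ptsAb)
  # stratum B: 40 target (28 EV1, 2 EV2), 400 background (5 EV1, 5 EV2)
  idsB <- mk_ids("C", 40)
  ptsB <- lapply(seq_len(40), function(i)
    c("Background event", if (i <= 28) "EV1", if (i <= 2) "EV2"))
  add(idsB, "TARGETDRUG", "IndB", ptsB)
  idsBb <- mk_ids("D", 400)
  ptsBb <- lapply(seq_len(400), function(i)
    c("Background event", if (i <= 5) "EV1", if (i > 5 && i <= 10) "EV2"))
  add(idsBb, "OTHERDRUG", "IndB", ptsBb)
  dict <- data.frame(pt = c("EV1", "EV2", "Background event"),
                     soc = c("SOC A", "SOC A", "SOC B"),
                     stringsAsFactors = FALSE)
  make_snapshot(do.call(rbind, rows), do.call(rbind, drugs),
                do.call(rbind, reacs), indi = do.call(rbind, inds),
                dict = dict)
}

# Random 2x2 tables with cells in [lo, hi] for oracle-equivalence loops.
random_tables <- function(n, lo = 1, hi = 1e4, seed = 1) {
  set.seed(seed)
  data.frame(a = sample(lo:hi, n, replace = TRUE),
             b = sample(lo:hi, n, replace = TRUE),
             c = sample(lo:hi, n, replace = TRUE),
             d = sample(lo:hi, n, replace = TRUE))
}
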