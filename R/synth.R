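# Seeded synthetic spontaneous-report generator.
#
# Emits FAERS-dialect snapshots with a ground-truth manifest so every
# pipeline stage can be tested without downloading data. Event occurrence
# for (drug d, event e) on a report follows probability min(1, lambda * p_e)
# when d is present and p_e otherwise; duplicate case versions share a
# CASEID with a distinct PRIMARYID and an earlier FDA_DT, so deduplication
# recovers exactly the current versions.
#
# All randomness comes from one seeded generator with a fixed stream
# order: drug presence, roles, therapy starts, onset draws, reporting
# delays, demographics, event draws, empty-report redraws, outcomes,
# indications, duplicate selection, missingness masks. Generation is
# byte-deterministic given the seed.

#' Default synthetic drug catalog
#'
#' One target oncology drug (always primary suspect, 1\% of reports) and a
#' background of common oncology and general-medicine products with mixed
#' role codes.
#'
#' @param target_marginal marginal probability of the target drug.
#' @return data frame with columns \code{name}, \code{marginal},
#'   \code{p_ps}, \code{p_ss}, \code{p_c}, \code{p_i}.
#' @export
default_drug_catalog <- function(target_marginal = 0.01) {
  bg <- c("DEXAMETHASONE", "ONDANSETRON", "IRINOTECAN", "ATEZOLIZUMAB",
          "CARBOPLATIN", "TOPOTECAN", "CISPLATIN", "ETOPOSIDE",
          "PACLITAXEL", "METFORMIN", "LISINOPRIL", "ATORVASTATIN",
          "OMEPRAZOLE", "ASPIRIN", "FUROSEMIDE")
  data.frame(
    name = c("LURBINECTEDIN", bg),
    marginal = c(target_marginal,
                 round(seq(0.18, 0.03, length.out = length(bg)), 4)),
    p_ps = c(1, rep(0.5, length(bg))),
    p_ss = c(0, rep(0.1, length(bg))),
    p_c = c(0, rep(0.35, length(bg))),
    p_i = c(0, rep(0.05, length(bg))),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic event catalog
#'
#' \code{n_pt} preferred terms assigned round-robin to \code{n_soc} system
#' organ classes, with geometrically decaying background report
#' probabilities (about 1.7 events per report in expectation).
#'
#' @param n_pt number of preferred terms.
#' @param n_soc number of system organ classes.
#' @param p_max background probability of the most common term.
#' @param decay geometric decay of the probability across terms.
#' @return data frame with columns \code{pt}, \code{soc}, \code{p}.
#' @export
default_event_catalog <- function(n_pt = 200, n_soc = 20, p_max = 0.05,
                                  decay = 0.97) {
  data.frame(
    pt = sprintf("PT %03d", seq_len(n_pt)),
    soc = sprintf("SOC %02d", (seq_len(n_pt) - 1L) %% n_soc + 1L),
    p = p_max * decay^(seq_len(n_pt) - 1L),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic-report generator
#'
#' @param seed RNG seed; generation is byte-deterministic given the seed.
#' @param n_reports number of cases (before duplicate versions).
#' @param drug_catalog see \code{\link{default_drug_catalog}}.
#' @param event_catalog see \code{\link{default_event_catalog}}.
#' @param signals list of injected drug-event associations, each a list
#'   \code{(drug, pt, lambda)}; the event probability is multiplied by
#'   \code{lambda} (capped at 1, with a warning recorded in the manifest)
#'   on reports carrying the drug.
#' @param duplicate_rate fraction of cases emitted with a stale extra
#'   version (same CASEID, earlier FDA_DT, identical content).
#' @param missing_rates per-field missingness fractions: \code{sex},
#'   \code{age}, \code{country}, \code{occupation}, \code{event_dt},
#'   \code{start_dt}.
#' @param onset_model log-normal time-to-onset: \code{median_days} and
#'   \code{sdlog} (log-scale standard deviation; 1.54 puts the quartiles
#'   at about 25/2.8 and 25*2.8 days).
#' @param outcome_model named per-outcome probabilities (codes DE, DS, HO,
#'   LT, CA, RI, OT); a report may carry several outcomes, or none.
#' @param indication_rate probability that a drug entry carries an
#'   indication row.
#' @param target_indications named probability vector of indication terms
#'   for the target (first) drug.
#' @param background_indications same for all other drugs.
#' @param date_window character vector \code{c(from, to)} of YYYYMMDD
#'   bounds for therapy start dates.
#' @return an object of class \code{synth_config}.
#' @export
synth_config <- function(seed = 20200615,
                         n_reports = 20000,
                         drug_catalog = default_drug_catalog(),
                         event_catalog = default_event_catalog(),
                         signals = list(),
                         duplicate_rate = 0.05,
                         missing_rates = list(sex = 0.25, age = 0.5,
                                              country = 0.05,
                                              occupation = 0.15,
                                              event_dt = 0.4,
                                              start_dt = 0.35),
                         onset_model = list(median_days = 25, sdlog = 1.54),
                         outcome_model = c(DE = 0.12, DS = 0.005, HO = 0.15,
                                           LT = 0.012, OT = 0.30),
                         indication_rate = 0.8,
                         target_indications = c(
                           "Small cell lung cancer" = 0.45,
                           "Metastatic SCLC" = 0.12,
                           "Extensive stage SCLC" = 0.10,
                           "Prophylaxis" = 0.13,
                           "Hypertension" = 0.05,
                           "Product used for unknown indication" = 0.15),
                         background_indications = c(
                           "Hypertension" = 0.2,
                           "Small cell lung cancer" = 0.12,
                           "Prophylaxis" = 0.18,
                           "Diabetes mellitus" = 0.15,
                           "Pain" = 0.15,
                           "Product used for unknown indication" = 0.2),
                         date_window = c("20200615", "20230930")) {
  stopifnot(n_reports >= 1,
            all(drug_catalog$marginal >= 0 & drug_catalog$marginal <= 1),
            all(event_catalog$p >= 0 & event_catalog$p <= 1),
            duplicate_rate >= 0 && duplicate_rate < 1)
  for (s in signals) {
    stopifnot(s$lambda > 0,
              s$drug %in% drug_catalog$name,
              s$pt %in% event_catalog$pt)
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic snapshot with ground truth
#'
#' @param config a \code{\link{synth_config}}.
#' @return list with \code{snapshot} (a deduplicatable
#'   \code{faers_snapshot} including the stale duplicate versions) and
#'   \code{manifest} (realized per-event counts for the signal drugs,
#'   injected-signal truth, duplicate map, onset draws for target
#'   reports, and any probability-capping warnings).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_reports
  drugs <- config$drug_catalog
  events <- config$event_catalog
  n_drug <- nrow(drugs)
  n_pt <- nrow(events)

  caseid <- as.character(1000000L + seq_len(n))
  primaryid <- paste0(caseid, "2")

  # --- drug presence (stream 1) and roles (stream 2)
  present <- matrix(stats::runif(n * n_drug), n, n_drug) <
    matrix(drugs$marginal, n, n_drug, byrow = TRUE)
  none <- which(rowSums(present) == 0L)
  if (length(none)) {
    forced <- sample.int(n_drug, length(none), replace = TRUE,
                         prob = drugs$marginal)
    present[cbind(none, forced)] <- TRUE
  }
  roles <- matrix(NA_character_, n, n_drug)
  for (j in seq_len(n_drug)) {
    idx <- which(present[, j])
    if (length(idx)) {
      roles[idx, j] <- sample(ROLE_CODES, length(idx), replace = TRUE,
                              prob = c(drugs$p_ps[j], drugs$p_ss[j],
                                       drugs$p_c[j], drugs$p_i[j]))
    }
  }

  # --- therapy starts (stream 3), onset (4), reporting delay (5)
  d0 <- as.integer(parse_ymd(config$date_window[1]))
  d1 <- as.integer(parse_ymd(config$date_window[2]))
  starts <- matrix(NA_integer_, n, n_drug)
  for (j in seq_len(n_drug)) {
    idx <- which(present[, j])
    if (length(idx)) {
      starts[idx, j] <- d0 + sample.int(d1 - d0 + 1L, length(idx),
                                        replace = TRUE) - 1L
    }
  }
  onset <- pmax(0L, as.integer(round(stats::rlnorm(
    n, meanlog = log(config$onset_model$median_days),
    sdlog = config$onset_model$sdlog))))
  delay <- sample.int(90L, n, replace = TRUE)

  # anchor drug: the first injected-signal drug when present, else the
  # first drug on the report
  sig_drugs <- unique(vapply(config$signals, `[[`, "", "drug"))
  first_j <- max.col(present, ties.method = "first")
  anchor_j <- first_j
  for (sd in sig_drugs) {
    j <- match(sd, drugs$name)
    anchor_j[present[, j]] <- j
  }
  anchor_start <- starts[cbind(seq_len(n), anchor_j)]
  event_day <- anchor_start + onset
  fda_day <- event_day + delay

  # --- demographics (stream 6)
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.55, 0.45))
  age <- round(pmin(95, pmax(18, stats::rnorm(n, 66, 12))))
  country <- sample(c("US", "CA", "FR", "CN", "GB", "JP", "DE", "IT"), n,
                    replace = TRUE,
                    prob = c(0.45, 0.15, 0.08, 0.02, 0.1, 0.08, 0.07, 0.05))
  occp <- sample(c("MD", "PH", "CN", "HP", "OT"), n, replace = TRUE,
                 prob = c(0.35, 0.2, 0.25, 0.15, 0.05))

  # --- event draws (stream 7) and empty-report redraws (stream 8)
  capped <- logical(length(config$signals))
  prob_for <- function(rows) {
    # rows x n_pt probability matrix under the injected signals
    p <- matrix(events$p, length(rows), n_pt, byrow = TRUE)
    for (k in seq_along(config$signals)) {
      s <- config$signals[[k]]
      j <- match(s$drug, drugs$name)
      e <- match(s$pt, events$pt)
      hit <- present[rows, j]
      pe <- s$lambda * events$p[e]
      if (pe > 1) capped[k] <<- TRUE
      p[hit, e] <- min(1, pe)
    }
    p
  }
  draw_rows <- function(rows) {
    p <- prob_for(rows)
    matrix(stats::runif(length(rows) * n_pt), length(rows), n_pt) < p
  }
  ev <- draw_rows(seq_len(n))
  empty <- which(rowSums(ev) == 0L)
  while (length(empty)) {  # every report carries at least one reaction
    redraw <- draw_rows(empty)
    ev[empty, ] <- redraw
    empty <- empty[rowSums(redraw) == 0L]
  }

  # --- outcomes (stream 9)
  om <- config$outcome_model
  outc_rows <- list()
  for (code in names(om)) {
    hit <- which(stats::runif(n) < om[[code]])
    if (length(hit)) {
      outc_rows[[code]] <- data.frame(primaryid = primaryid[hit],
                                      outc_cod = code,
                                      stringsAsFactors = FALSE)
    }
  }

  # --- indications (stream 10)
  indi_rows <- list()
  for (j in seq_len(n_drug)) {
    idx <- which(present[, j])
    if (!length(idx)) next
    has_ind <- stats::runif(length(idx)) < config$indication_rate
    idx <- idx[has_ind]
    if (!length(idx)) next
    dist <- if (j == 1L) config$target_indications else
      config$background_indications
    indi_rows[[j]] <- data.frame(
      primaryid = primaryid[idx], drug_seq = j,
      indi_pt = sample(names(dist), length(idx), replace = TRUE,
                       prob = dist),
      stringsAsFactors = FALSE)
  }

  # --- duplicate versions (stream 11) and missingness (stream 12)
  dup <- which(stats::runif(n) < config$duplicate_rate)
  dup_delta <- if (length(dup)) sample.int(120L, length(dup),
                                           replace = TRUE) else integer(0)
  mr <- config$missing_rates
  miss <- function(rate) stats::runif(n) < rate
  m_sex <- miss(mr$sex %||% 0)
  m_age <- miss(mr$age %||% 0)
  m_ctry <- miss(mr$country %||% 0)
  m_occ <- miss(mr$occupation %||% 0)
  m_ev <- miss(mr$event_dt %||% 0)
  m_st <- miss(mr$start_dt %||% 0)

  fmt_day <- function(day) {
    out <- rep("", length(day))
    ok <- !is.na(day)
    out[ok] <- format(as.Date(day[ok], origin = "1970-01-01"), "%Y%m%d")
    out
  }

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid,
    fda_dt = as.integer(fmt_day(fda_day)),
    event_dt = ifelse(m_ev, "", fmt_day(event_day)),
    age = ifelse(m_age, NA_real_, age),
    age_cod = ifelse(m_age, "", "YR"),
    sex = ifelse(m_sex, "UNK", sex),
    occr_country = ifelse(m_ctry, "", country),
    occp_cod = ifelse(m_occ, "", occp),
    stringsAsFactors = FALSE
  )

  pres_idx <- which(present, arr.ind = TRUE)
  pres_idx <- pres_idx[order(pres_idx[, 1], pres_idx[, 2]), , drop = FALSE]
  drug_tab <- data.frame(
    primaryid = primaryid[pres_idx[, 1]],
    drug_seq = pres_idx[, 2],
    role_cod = roles[pres_idx],
    drugname = drugs$name[pres_idx[, 2]],
    stringsAsFactors = FALSE
  )

  ther <- data.frame(
    primaryid = primaryid[pres_idx[, 1]],
    drug_seq = pres_idx[, 2],
    start_dt = ifelse(m_st[pres_idx[, 1]], "", fmt_day(starts[pres_idx])),
    stringsAsFactors = FALSE
  )
  ther <- ther[nzchar(ther$start_dt), , drop = FALSE]

  ev_idx <- which(ev, arr.ind = TRUE)
  ev_idx <- ev_idx[order(ev_idx[, 1], ev_idx[, 2]), , drop = FALSE]
  reac <- data.frame(
    primaryid = primaryid[ev_idx[, 1]],
    pt = events$pt[ev_idx[, 2]],
    stringsAsFactors = FALSE
  )

  outc <- if (length(outc_rows)) do.call(rbind, outc_rows) else
    .empty_table("OUTC")
  indi <- if (length(indi_rows)) do.call(rbind, indi_rows) else
    .empty_table("INDI")

  # stale duplicate versions: same caseid and content, version 1,
  # earlier fda_dt
  if (length(dup)) {
    stale_id <- paste0(caseid[dup], "1")
    map <- stats::setNames(stale_id, primaryid[dup])
    clone <- function(df, idx_col = "primaryid") {
      sel <- df[[idx_col]] %in% names(map)
      cl <- df[sel, , drop = FALSE]
      cl[[idx_col]] <- unname(map[cl[[idx_col]]])
      cl
    }
    demo_stale <- clone(demo)
    demo_stale$fda_dt <- as.integer(fmt_day(
      as.integer(parse_ymd(demo_stale$fda_dt)) -
        dup_delta[match(demo_stale$caseid, caseid[dup])]))
    demo <- rbind(demo, demo_stale)
    drug_tab <- rbind(drug_tab, clone(drug_tab))
    reac <- rbind(reac, clone(reac))
    outc <- rbind(outc, clone(outc))
    indi <- rbind(indi, clone(indi))
    ther <- rbind(ther, clone(ther))
  }

  ord <- function(df) {
    df <- df[order(.primaryid_rank(df$primaryid)), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  snap <- structure(list(
    demo = ord(demo), drug = ord(drug_tab), reac = ord(reac),
    outc = ord(outc), indi = ord(indi), ther = ord(ther),
    dict = events[, c("pt", "soc")],
    load_log = NULL, orphans = integer(0), deduplicated = FALSE
  ), class = "faers_snapshot")

  # --- ground-truth manifest (current versions only)
  pt_counts <- as.integer(colSums(ev))
  names(pt_counts) <- events$pt
  signal_truth <- lapply(seq_along(config$signals), function(k) {
    s <- config$signals[[k]]
    j <- match(s$drug, drugs$name)
    e <- match(s$pt, events$pt)
    list(drug = s$drug, pt = s$pt, lambda = s$lambda,
         expected_a = sum(present[, j]) * min(1, s$lambda * events$p[e]),
         realized_a = sum(present[, j] & ev[, e]),
         realized_a_ps = sum(present[, j] & roles[, j] == "PS" & ev[, e]),
         capped = capped[k])
  })
  drug_pt_counts <- lapply(stats::setNames(sig_drugs, sig_drugs),
                           function(sd) {
    j <- match(sd, drugs$name)
    cnt <- as.integer(colSums(ev[present[, j], , drop = FALSE]))
    stats::setNames(cnt, events$pt)
  })
  tgt <- present[, 1L]
  manifest <- list(
    seed = config$seed, n_cases = n,
    n_versions = nrow(demo),
    n_duplicate_cases = length(dup),
    duplicate_caseids = caseid[dup],
    pt_counts = as.list(pt_counts),
    n_drug_reports = stats::setNames(as.list(as.integer(colSums(present))),
                                     drugs$name),
    signals = signal_truth,
    drug_pt_counts = drug_pt_counts,
    onset_draws_target = stats::setNames(as.list(onset[tgt]),
                                         primaryid[tgt])
  )
  list(snapshot = snap, manifest = manifest)
}

#' Write a synthetic snapshot as FAERS-dialect files
#'
#' Emits \code{DEMO.txt}, \code{DRUG.txt}, \code{REAC.txt},
#' \code{OUTC.txt}, \code{INDI.txt}, \code{THER.txt} ("$"-delimited, one
#' header row, blank = missing), the \code{event_dict.tsv} PT-to-SOC
#' dictionary, and \code{manifest.json}. Output is byte-deterministic for
#' a fixed generation.
#'
#' @param sim result of \code{\link{synth_generate}} (or a bare
#'   \code{faers_snapshot}).
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_snapshot <- function(sim, dir) {
  snap <- if (inherits(sim, "faers_snapshot")) sim else sim$snapshot
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  put <- function(df, name) {
    df2 <- df
    for (j in seq_along(df2)) {
      x <- df2[[j]]
      df2[[j]] <- ifelse(is.na(x), "", as.character(x))
    }
    con <- file(file.path(dir, name), open = "wb")
    utils::write.table(df2, con, sep = "$", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n",
                       fileEncoding = "UTF-8")
    close(con)
  }
  put(snap$demo, "DEMO.txt")
  put(snap$drug, "DRUG.txt")
  put(snap$reac, "REAC.txt")
  put(snap$outc, "OUTC.txt")
  put(snap$indi, "INDI.txt")
  put(snap$ther, "THER.txt")
  con <- file(file.path(dir, "event_dict.tsv"), open = "wb")
  utils::write.table(snap$dict, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  close(con)
  if (!inherits(sim, "faers_snapshot") && !is.null(sim$manifest)) {
    json <- jsonlite::toJSON(sim$manifest, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    writeLines(json, file.path(dir, "manifest.json"), useBytes = TRUE)
  }
  invisible(dir)
}
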