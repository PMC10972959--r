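# Descriptive profiling of a drug cohort: clinical characteristics,
# top-k indications / concomitant drugs, and time-to-onset analysis.

.OCCUPATION_LABELS <- c(CN = "Consumer", PH = "Pharmacist", MD = "Physician")
.OUTCOME_LABELS <- c(DE = "Death", DS = "Disability", HO = "Hospitalization",
                     LT = "Life-threatening",
                     OT = "Other serious medical event",
                     CA = "Other serious medical event",
                     RI = "Other serious medical event")

.count_pct <- function(labels, values, denom) {
  n <- vapply(labels, function(l) sum(values == l), integer(1))
  data.frame(category = labels, n = as.integer(n),
             pct = round_half_up(100 * n / denom, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Clinical characteristics of a report cohort
#'
#' Tabulates counts and percentages for sex, age bins (in years, after
#' unit conversion), report year (from \code{fda_dt}), reporting country
#' (listed countries plus an "Others" bucket), reporter occupation, and
#' report outcomes. All report-level characteristics use the number of
#' target reports as denominator; outcome percentages use the total number
#' of outcome *entries*, since one report may carry several outcomes (a
#' report without any outcome row contributes one "Unknown" entry).
#'
#' Age bins are 18-64, 65-85 and >85 years inclusive of their edges; ages
#' below 18 or missing fall in "Unknown". Percentages are rounded to one
#' decimal (half-up).
#'
#' @param snapshot a deduplicated \code{faers_snapshot}.
#' @param target_ids primaryids of the cohort.
#' @param countries country codes listed individually; everything else is
#'   aggregated as "Others". \code{NULL} (default) lists the top 4 by
#'   count.
#' @return an object of class \code{clinical_summary}: a list of data
#'   frames \code{sex}, \code{age}, \code{year}, \code{country},
#'   \code{occupation}, \code{outcome}, each with columns
#'   \code{category}, \code{n}, \code{pct}, plus \code{n_reports} and
#'   \code{n_outcome_entries}.
#' @export
summarize_clinical <- function(snapshot, target_ids, countries = NULL) {
  demo <- snapshot$demo[snapshot$demo$primaryid %in% target_ids, ,
                        drop = FALSE]
  n_rep <- nrow(demo)
  denom <- max(n_rep, 1L)

  sex <- ifelse(demo$sex == "M", "Male",
                ifelse(demo$sex == "F", "Female", "Unknown"))
  sex_tab <- .count_pct(c("Male", "Female", "Unknown"), sex, denom)

  age <- age_in_years(demo$age, demo$age_cod)
  age_bin <- rep("Unknown", n_rep)
  age_bin[!is.na(age) & age >= 18 & age <= 64] <- "18-64"
  age_bin[!is.na(age) & age >= 65 & age <= 85] <- "65-85"
  age_bin[!is.na(age) & age > 85] <- ">85"
  age_tab <- .count_pct(c("18-64", "65-85", ">85", "Unknown"), age_bin, denom)

  yr <- date_year(demo$fda_dt)
  yr_chr <- ifelse(is.na(yr), "Unknown", as.character(yr))
  yr_levels <- sort(unique(yr_chr[yr_chr != "Unknown"]))
  if (any(yr_chr == "Unknown")) yr_levels <- c(yr_levels, "Unknown")
  year_tab <- .count_pct(yr_levels, yr_chr, denom)

  ctry <- toupper(trimws(demo$occr_country))
  if (is.null(countries)) {
    tt <- sort(table(ctry[nzchar(ctry)]), decreasing = TRUE)
    countries <- utils::head(names(tt), 4)
  }
  ctry_grp <- ifelse(ctry %in% toupper(countries), ctry,
                     ifelse(nzchar(ctry), "Others", "Others"))
  country_tab <- .count_pct(c(toupper(countries), "Others"), ctry_grp, denom)

  occ <- .OCCUPATION_LABELS[demo$occp_cod]
  occ[is.na(occ)] <- "Unknown"
  occ_tab <- .count_pct(c("Consumer", "Pharmacist", "Physician", "Unknown"),
                        occ, denom)

  outc <- snapshot$outc[snapshot$outc$primaryid %in% target_ids, ,
                        drop = FALSE]
  out_lab <- .OUTCOME_LABELS[outc$outc_cod]
  n_unknown <- sum(!(demo$primaryid %in% outc$primaryid))
  out_lab <- c(out_lab, rep("Unknown", n_unknown))
  n_entries <- length(out_lab)
  outcome_tab <- .count_pct(
    c("Death", "Disability", "Hospitalization", "Life-threatening",
      "Other serious medical event", "Unknown"),
    out_lab, max(n_entries, 1L))

  structure(list(sex = sex_tab, age = age_tab, year = year_tab,
                 country = country_tab, occupation = occ_tab,
                 outcome = outcome_tab, n_reports = n_rep,
                 n_outcome_entries = n_entries),
            class = "clinical_summary")
}

#' @export
print.clinical_summary <- function(x, ...) {
  cat("Clinical characteristics of", x$n_reports, "reports\n")
  for (nm in c("sex", "age", "year", "country", "occupation", "outcome")) {
    cat("\n", toupper(substring(nm, 1, 1)), substring(nm, 2),
        if (nm == "outcome")
          paste0(" (", x$n_outcome_entries, " outcome entries)"),
        ":\n", sep = "")
    print(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}

#' Top-k indications or concomitant drugs of a cohort
#'
#' Indications are counted over indication rows attached to the matched
#' target drug entries, excluding the FAERS "unknown indication" terms.
#' Concomitant drugs are the distinct normalized non-target drug names
#' co-reported on target reports, counted once per report. Ties are
#' broken alphabetically.
#'
#' @param snapshot a deduplicated \code{faers_snapshot}.
#' @param spec the target \code{\link{cohort_spec}}.
#' @param kind \code{"indications"} or \code{"concomitants"}.
#' @param k number of rows returned.
#' @return data frame with columns \code{name}, \code{count}.
#' @export
top_k <- function(snapshot, spec, kind = c("indications", "concomitants"),
                  k = 5) {
  kind <- match.arg(kind)
  stopifnot(k >= 1)
  entries <- match_target_entries(snapshot, spec)
  if (kind == "indications") {
    keys <- paste(entries$primaryid, entries$drug_seq)
    indi <- snapshot$indi
    indi <- indi[paste(indi$primaryid, indi$drug_seq) %in% keys, ,
                 drop = FALSE]
    vals <- indi$indi_pt
    unknown <- grepl("unknown indication", vals, ignore.case = TRUE) |
      tolower(trimws(vals)) == "unknown"
    vals <- vals[!unknown]
    # one count per report and indication term
    vals <- vals[!duplicated(paste(indi$primaryid[!unknown], vals))]
  } else {
    ids <- unique(entries$primaryid)
    drug <- snapshot$drug
    co <- drug[drug$primaryid %in% ids &
                 drug$role_cod %in% c("SS", "C", "I"), , drop = FALSE]
    co$name <- normalize_name(co$drugname)
    co <- co[!.name_matches(co$name, spec), , drop = FALSE]
    co <- co[!duplicated(paste(co$primaryid, co$name)), , drop = FALSE]
    vals <- co$name
  }
  if (!length(vals)) {
    return(data.frame(name = character(0), count = integer(0)))
  }
  tt <- table(vals)
  out <- data.frame(name = names(tt), count = as.integer(tt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$name), , drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Per-report time to onset in days
#'
#' Onset is the difference between the event date and the earliest
#' day-resolution therapy start date of the matched target drug on the
#' same report. Reports with partial or missing dates, or with the event
#' preceding therapy start, are excluded and counted.
#'
#' @param snapshot a deduplicated \code{faers_snapshot}.
#' @param spec the target \code{\link{cohort_spec}}.
#' @return integer vector of day counts with attribute
#'   \code{"n_excluded"} (reports with both dates present but a negative
#'   difference).
#' @export
onset_days <- function(snapshot, spec) {
  entries <- match_target_entries(snapshot, spec)
  keys <- paste(entries$primaryid, entries$drug_seq)
  ther <- snapshot$ther
  ther <- ther[paste(ther$primaryid, ther$drug_seq) %in% keys, , drop = FALSE]
  ther$start <- parse_ymd(ther$start_dt)
  ther <- ther[!is.na(ther$start), , drop = FALSE]
  if (!nrow(ther)) {
    out <- integer(0)
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  # earliest start per report
  start <- tapply(as.integer(ther$start), ther$primaryid, min)
  demo <- snapshot$demo
  ev <- parse_ymd(demo$event_dt[match(names(start), demo$primaryid)])
  diffs <- as.integer(ev) - as.integer(start)
  ok <- !is.na(diffs)
  neg <- ok & diffs < 0
  out <- as.integer(diffs[ok & !neg])
  attr(out, "n_excluded") <- sum(neg)
  out
}

#' Summarize time-to-onset day counts
#'
#' Mean, median, quartiles (linear interpolation between order statistics
#' at the (n+1)p plotting positions) and a binned distribution over 0-30,
#' 31-60, 61-90, 91-180 and >180 days (upper edges inclusive).
#'
#' @param days integer vector of nonnegative day counts.
#' @param quantile_type quartile rule passed to
#'   \code{\link[stats]{quantile}}; the default (type 6) returns the
#'   sample extremes of a 3-point sample as its quartiles, which is how
#'   small-sample interquartile ranges are conventionally reported.
#' @return an object of class \code{onset_summary}: list with
#'   \code{n_with_onset}, \code{mean_days}, \code{median_days},
#'   \code{q1_days}, \code{q3_days}, \code{bins} (data frame
#'   \code{bin}, \code{n}, \code{pct}).
#' @export
summarize_onset <- function(days, quantile_type = 6) {
  labs <- c("0-30", "31-60", "61-90", "91-180", ">180")
  if (!length(days)) {
    return(structure(list(n_with_onset = 0L, mean_days = NA_real_,
                          median_days = NA_real_, q1_days = NA_real_,
                          q3_days = NA_real_,
                          bins = data.frame(bin = labs, n = 0L, pct = 0)),
                     class = "onset_summary"))
  }
  q <- stats::quantile(days, c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  cut_bins <- cut(days, breaks = c(-0.5, 30, 60, 90, 180, Inf), labels = labs)
  tab <- table(cut_bins)
  structure(list(
    n_with_onset = length(days),
    mean_days = mean(days),
    median_days = q[2], q1_days = q[1], q3_days = q[3],
    bins = data.frame(bin = labs, n = as.integer(tab),
                      pct = round_half_up(100 * as.integer(tab) /
                                            length(days), 1),
                      stringsAsFactors = FALSE)
  ), class = "onset_summary")
}

#' @export
print.onset_summary <- function(x, ...) {
  cat("Time to onset over", x$n_with_onset, "reports\n")
  if (x$n_with_onset > 0) {
    cat(sprintf("  mean %.1f d, median %.1f d (IQR %.1f-%.1f d)\n",
                x$mean_days, x$median_days, x$q1_days, x$q3_days))
    print(x$bins, row.names = FALSE)
  }
  invisible(x)
}
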