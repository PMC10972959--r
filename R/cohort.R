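# Target-drug cohorts and 2x2 contingency construction.
#
# The disproportionality unit defaults to the REPORT: a report contributes
# at most once to any event regardless of duplicated PT rows, and the
# target-drug margin a+b is the number of target reports. An alternative
# "pair" unit (report x PT rows) is available because spontaneous-report
# analyses differ on this; see cohort_spec().

#' Specify a drug cohort
#'
#' @param name_patterns character vector of search strings matched
#'   case-insensitively as substrings of the normalized drug name (generic
#'   name, former development code, brand name, ...).
#' @param role_filter drug role codes that qualify a report;
#'   default \code{"PS"} (primary suspect criterion).
#' @param indication_filter optional character vector of indication
#'   preferred terms; when set, the matching drug entry must also carry one
#'   of these indications.
#' @param level \code{"PT"} or \code{"SOC"}: aggregation level for
#'   screening.
#' @param unit \code{"report"} (default: distinct reports) or \code{"pair"}
#'   (report-PT rows) as the counting unit of the 2x2 table.
#' @param exact if \code{TRUE}, drug names must equal a pattern after
#'   normalization instead of containing it.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(name_patterns,
                        role_filter = "PS",
                        indication_filter = NULL,
                        level = c("PT", "SOC"),
                        unit = c("report", "pair"),
                        exact = FALSE) {
  stopifnot(length(name_patterns) >= 1, all(nzchar(name_patterns)))
  level <- match.arg(level)
  unit <- match.arg(unit)
  stopifnot(all(role_filter %in% ROLE_CODES))
  structure(list(
    name_patterns = normalize_name(name_patterns),
    role_filter = role_filter,
    indication_filter = if (!is.null(indication_filter))
      normalize_name(indication_filter),
    level = level, unit = unit, exact = exact
  ), class = "cohort_spec")
}

# TRUE for drug rows whose normalized name matches the spec patterns.
.name_matches <- function(names_norm, spec) {
  hit <- rep(FALSE, length(names_norm))
  for (p in spec$name_patterns) {
    hit <- hit | if (spec$exact) names_norm == p else
      grepl(p, names_norm, fixed = TRUE)
  }
  hit
}

#' Drug rows matching a cohort specification
#'
#' Returns the DRUG rows whose normalized name contains one of the spec's
#' patterns and whose role code is in the role filter; with an indication
#' filter, the same \code{(primaryid, drug_seq)} entry must carry one of
#' the listed indications.
#'
#' @param snapshot a deduplicated \code{faers_snapshot}.
#' @param spec a \code{\link{cohort_spec}}.
#' @return the matching DRUG rows.
#' @export
match_target_entries <- function(snapshot, spec) {
  drug <- snapshot$drug
  hit <- .name_matches(normalize_name(drug$drugname), spec) &
    drug$role_cod %in% spec$role_filter
  out <- drug[hit, , drop = FALSE]
  if (!is.null(spec$indication_filter) && nrow(out)) {
    indi <- snapshot$indi
    ind_ok <- normalize_indication(indi$indi_pt) %in%
      normalize_indication(spec$indication_filter)
    good_keys <- paste(indi$primaryid[ind_ok], indi$drug_seq[ind_ok])
    out <- out[paste(out$primaryid, out$drug_seq) %in% good_keys, ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Reports matching a cohort specification
#'
#' @inheritParams match_target_entries
#' @return character vector of matching \code{primaryid}s (warns when
#'   empty).
#' @export
match_target_reports <- function(snapshot, spec) {
  ids <- unique(match_target_entries(snapshot, spec)$primaryid)
  if (!length(ids)) warning("cohort specification matched no reports")
  ids
}

# Reaction rows annotated with the event label at the requested level.
.event_rows <- function(snapshot, level) {
  reac <- snapshot$reac
  if (level == "SOC") {
    soc <- snapshot$dict$soc[match(reac$pt, snapshot$dict$pt)]
    if (anyNA(soc)) {
      warning(sum(is.na(soc)), " PT(s) missing from dictionary; routed to '",
              SENTINEL_SOC, "'")
      soc[is.na(soc)] <- SENTINEL_SOC
    }
    reac$event <- soc
  } else {
    reac$event <- reac$pt
  }
  reac
}

#' Per-event target and database-wide counts
#'
#' Counts, for every event at the requested level, the number of target
#' units carrying the event (\code{a}) and the database-wide number
#' (\code{a_c}, the \code{a + c} margin). With \code{unit = "report"} a
#' report contributes at most one unit to an event even when several of
#' its PTs map to the same SOC; with \code{unit = "pair"} PT rows are
#' summed.
#'
#' @param snapshot a deduplicated \code{faers_snapshot}.
#' @param target_ids primaryids of the target cohort.
#' @param level \code{"PT"} or \code{"SOC"}.
#' @param unit \code{"report"} or \code{"pair"}.
#' @return data frame with columns \code{event}, \code{a}, \code{a_c},
#'   sorted by \code{a} descending.
#' @export
event_counts <- function(snapshot, target_ids, level = c("PT", "SOC"),
                         unit = c("report", "pair")) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  reac <- .event_rows(snapshot, level)
  if (unit == "report") {
    reac <- reac[!duplicated(reac[, c("primaryid", "event")]), , drop = FALSE]
  }
  if (!nrow(reac)) {
    return(data.frame(event = character(0), a = integer(0),
                      a_c = integer(0), stringsAsFactors = FALSE))
  }
  all_tab <- table(reac$event)
  tgt_tab <- table(reac$event[reac$primaryid %in% target_ids])
  events <- names(all_tab)
  out <- data.frame(
    event = events,
    a = as.integer(tgt_tab[events]),
    a_c = as.integer(all_tab[events]),
    stringsAsFactors = FALSE
  )
  out$a[is.na(out$a)] <- 0L
  out <- out[order(-out$a, out$event), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the four-grid contingency table from margins
#'
#' Given \code{a} (target units with the event), the event margin
#' \code{a + c}, the target margin \code{a + b}, and the grand total
#' \code{N}, derives \code{b}, \code{c}, \code{d} by subtraction.
#' Vectorized over events.
#'
#' @param a counts of target units with the event.
#' @param a_c database-wide event counts (\code{a + c}).
#' @param margin target margin (\code{a + b}), a scalar.
#' @param n_total grand total \code{N}, a scalar.
#' @return data frame with integer columns \code{a}, \code{b}, \code{c},
#'   \code{d}.
#' @export
build_contingency <- function(a, a_c, margin, n_total) {
  a <- as.integer(a); a_c <- as.integer(a_c)
  margin <- as.integer(margin); n_total <- as.integer(n_total)
  b <- margin - a
  cc <- a_c - a
  d <- n_total - margin - cc
  if (any(a < 0 | b < 0 | cc < 0 | d < 0)) {
    stop("inconsistent margins: negative contingency cell derived")
  }
  data.frame(a = a, b = b, c = cc, d = d)
}

# Margins of the 2x2 universe for a snapshot under a spec unit.
.margins <- function(snapshot, target_ids, unit) {
  if (unit == "report") {
    list(margin = sum(snapshot$demo$primaryid %in% target_ids),
         n_total = nrow(snapshot$demo))
  } else {
    reac <- snapshot$reac
    list(margin = sum(reac$primaryid %in% target_ids),
         n_total = nrow(reac))
  }
}
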