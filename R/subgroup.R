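# Indication-restricted re-screening and confounding checks.
#
# The restricted screen narrows the 2x2 universe to reports (any drug)
# whose indications fall in a given set, then re-runs the disproportionality
# screen inside that universe. Confounding checks are counting audits:
# event co-occurrence within the cohort, and the concomitant medications
# present on reports carrying a given event.

# FAERS indication text is free-form; a small synonym map folds common
# phrasings onto one canonical normalized form.
.INDICATION_SYNONYMS <- c(
  "SMALL CELL LUNG CANCER SCLC" = "SMALL CELL LUNG CANCER",
  "SCLC" = "SMALL CELL LUNG CANCER",
  "METASTATIC SMALL CELL LUNG CANCER" = "METASTATIC SCLC",
  "EXTENSIVE STAGE SMALL CELL LUNG CANCER" = "EXTENSIVE STAGE SCLC",
  "ES SCLC" = "EXTENSIVE STAGE SCLC"
)

#' Normalize an indication term
#'
#' Case-insensitive, punctuation-folded normalization with a small synonym
#' map for common small-cell lung cancer phrasings.
#'
#' @param x character vector of indication terms.
#' @return normalized character vector.
#' @export
normalize_indication <- function(x) {
  x <- normalize_name(x)
  hit <- x %in% names(.INDICATION_SYNONYMS)
  x[hit] <- .INDICATION_SYNONYMS[x[hit]]
  x
}

# primaryids of reports carrying at least one of the given indications
# (on any drug entry).
.reports_with_indication <- function(snapshot, indications) {
  want <- normalize_indication(indications)
  indi <- snapshot$indi
  unique(indi$primaryid[normalize_indication(indi$indi_pt) %in% want])
}

#' Indication-restricted disproportionality screen
#'
#' Restricts the comparison universe to reports (any drug) carrying one of
#' the listed indications, then screens target vs other drugs within it.
#' With \code{comparator = "named"}, the universe is further restricted to
#' reports carrying either the target drug or one of
#' \code{comparator_patterns} (e.g. a same-indication comparator drug).
#'
#' @param snapshot a deduplicated \code{faers_snapshot}.
#' @param spec the target \code{\link{cohort_spec}}.
#' @param indications character vector of indication terms defining the
#'   universe.
#' @param config a \code{\link{dispro_config}}.
#' @param comparator \code{"all"} (default: target vs all other drugs) or
#'   \code{"named"}.
#' @param comparator_patterns drug-name patterns for
#'   \code{comparator = "named"}.
#' @return a \code{faers_screen} (empty, with a warning, when the
#'   restricted universe is empty).
#' @export
restricted_screen <- function(snapshot, spec, indications,
                              config = dispro_config(),
                              comparator = c("all", "named"),
                              comparator_patterns = NULL) {
  stopifnot(length(indications) >= 1)
  comparator <- match.arg(comparator)
  ids <- .reports_with_indication(snapshot, indications)
  if (comparator == "named") {
    stopifnot(!is.null(comparator_patterns))
    comp_spec <- cohort_spec(comparator_patterns,
                             role_filter = spec$role_filter,
                             level = spec$level, unit = spec$unit)
    keep <- unique(c(
      suppressWarnings(match_target_reports(snapshot, spec)),
      suppressWarnings(match_target_reports(snapshot, comp_spec))
    ))
    ids <- intersect(ids, keep)
  }
  if (!length(ids)) {
    warning("restricted universe is empty for the given indications")
  }
  sub <- subset_snapshot(snapshot, ids)
  suppressWarnings(dispro_screen(sub, spec, config))
}

#' Count reports carrying two events simultaneously
#'
#' Exact report-level intersection count of two preferred terms within a
#' cohort. Symmetric in its two PT arguments and bounded by the smaller
#' single-PT count; \code{pt_x == pt_y} degenerates to that PT's report
#' count.
#'
#' @param snapshot a deduplicated \code{faers_snapshot}.
#' @param target_ids primaryids of the cohort.
#' @param pt_x,pt_y preferred terms.
#' @return integer count.
#' @export
cooccurrence <- function(snapshot, target_ids, pt_x, pt_y) {
  reac <- snapshot$reac
  reac <- reac[reac$primaryid %in% target_ids, , drop = FALSE]
  ids_x <- unique(reac$primaryid[reac$pt == pt_x])
  ids_y <- unique(reac$primaryid[reac$pt == pt_y])
  length(intersect(ids_x, ids_y))
}

#' Concomitant medications on reports carrying given events
#'
#' For each preferred term, lists the distinct co-reported non-target
#' drugs on cohort reports carrying that PT, with report counts. An empty
#' listing means concomitant medication is absent for that event.
#'
#' @param snapshot a deduplicated \code{faers_snapshot}.
#' @param spec the target \code{\link{cohort_spec}}.
#' @param pts character vector of preferred terms to audit.
#' @return data frame with columns \code{pt}, \code{n_reports} (reports
#'   carrying the PT), \code{drug}, \code{count}; PTs with no concomitant
#'   drugs appear with \code{drug = NA} and \code{count = 0}.
#' @export
concomitant_audit <- function(snapshot, spec, pts) {
  target_ids <- suppressWarnings(match_target_reports(snapshot, spec))
  reac <- snapshot$reac[snapshot$reac$primaryid %in% target_ids, ,
                        drop = FALSE]
  drug <- snapshot$drug
  out <- list()
  for (pt in pts) {
    ids <- unique(reac$primaryid[reac$pt == pt])
    co <- drug[drug$primaryid %in% ids &
                 drug$role_cod %in% c("SS", "C", "I"), , drop = FALSE]
    if (nrow(co)) {
      co$name <- normalize_name(co$drugname)
      co <- co[!.name_matches(co$name, spec), , drop = FALSE]
      co <- co[!duplicated(paste(co$primaryid, co$name)), , drop = FALSE]
    }
    if (nrow(co)) {
      tt <- sort(table(co$name), decreasing = TRUE)
      out[[pt]] <- data.frame(pt = pt, n_reports = length(ids),
                              drug = names(tt), count = as.integer(tt),
                              stringsAsFactors = FALSE)
    } else {
      out[[pt]] <- data.frame(pt = pt, n_reports = length(ids),
                              drug = NA_character_, count = 0L,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Validate a candidate signal across indication strata
#'
#' Re-screens the snapshot restricted to each indication separately and
#' extracts the decision row for the candidate preferred term. The PT is
#' confirmed as a new signal only when the consensus criterion holds in
#' the pooled screen and in every stratum; a stratum where the PT is
#' absent or the cohort is empty is "not evaluable" and blocks
#' confirmation.
#'
#' @param snapshot a deduplicated \code{faers_snapshot}.
#' @param spec the target \code{\link{cohort_spec}} (PT level).
#' @param pt the candidate preferred term.
#' @param indications character vector; one stratum per element.
#' @param config a \code{\link{dispro_config}}.
#' @return list with \code{per_stratum} (data frame \code{indication},
#'   \code{n}, \code{consensus}, \code{status}) and \code{confirmed}
#'   (logical).
#' @export
per_indication_validation <- function(snapshot, spec, pt, indications,
                                      config = dispro_config()) {
  rows <- lapply(indications, function(ind) {
    scr <- suppressWarnings(
      restricted_screen(snapshot, spec, ind, config = config))
    tab <- scr$table
    hit <- if (nrow(tab)) which(tab$event == pt) else integer(0)
    if (scr$margin == 0L) {
      data.frame(indication = ind, n = 0L, consensus = FALSE,
                 status = "not evaluable", stringsAsFactors = FALSE)
    } else if (!length(hit)) {
      data.frame(indication = ind, n = 0L, consensus = FALSE,
                 status = "not observed", stringsAsFactors = FALSE)
    } else {
      data.frame(indication = ind, n = tab$n[hit[1]],
                 consensus = tab$consensus[hit[1]],
                 status = if (tab$consensus[hit[1]]) "signal" else
                   "no signal", stringsAsFactors = FALSE)
    }
  })
  per <- do.call(rbind, rows)
  list(per_stratum = per, confirmed = all(per$consensus))
}
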