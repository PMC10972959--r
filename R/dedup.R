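# Case deduplication.
#
# FAERS stores one row per report *version*; several versions of the same
# case (shared CASEID) accumulate across quarterly files as manufacturers
# and the FDA update a report. The FDA-recommended recipe keeps, within
# each CASEID, the version with the most recent FDA_DT; ties are broken by
# the highest PRIMARYID (the report version identifier). A version with a
# missing FDA_DT loses to any version with one.

# Order primaryids as zero-padded numeric strings where possible so "999"
# sorts below "1002"; non-numeric ids fall back to plain lexicographic.
.primaryid_rank <- function(x) {
  num <- grepl("^[0-9]+$", x)
  key <- x
  if (any(num)) {
    width <- max(nchar(x[num]))
    key[num] <- formatC(x[num], width = width, flag = "0")
  }
  key
}

#' Collapse case versions to one report per CASEID
#'
#' Within each \code{caseid} group the surviving row is the one with the
#' maximal \code{fda_dt} (missing loses to present); remaining ties are
#' broken by the rule in \code{tie_break}. The default, and the standard
#' FDA recipe, keeps the highest \code{primaryid}; \code{"lowest_primaryid"}
#' is provided so an alternative reading of the recipe can be swapped in.
#'
#' The result is independent of input row order and idempotent.
#'
#' @param demo a DEMO data frame (one row per report version).
#' @param tie_break \code{"highest_primaryid"} (default) or
#'   \code{"lowest_primaryid"}.
#' @return the surviving DEMO rows, one per \code{caseid}, with attribute
#'   \code{"n_dropped"}.
#' @export
dedup_cases <- function(demo, tie_break = c("highest_primaryid",
                                            "lowest_primaryid")) {
  tie_break <- match.arg(tie_break)
  if (nrow(demo) == 0L) {
    attr(demo, "n_dropped") <- 0L
    return(demo)
  }
  fda <- demo$fda_dt
  fda[is.na(fda)] <- -1L  # missing date loses to any present date
  rank2 <- .primaryid_rank(demo$primaryid)
  if (tie_break == "lowest_primaryid") {
    ord <- order(demo$caseid, -fda, rank2, method = "radix")
  } else {
    ord <- order(demo$caseid, -fda, rank2, method = "radix",
                 decreasing = c(FALSE, FALSE, TRUE))
  }
  sorted <- demo[ord, , drop = FALSE]
  keep <- !duplicated(sorted$caseid)
  out <- sorted[keep, , drop = FALSE]
  out <- out[order(.primaryid_rank(out$primaryid), method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- nrow(demo) - nrow(out)
  out
}

#' Deduplicate a snapshot
#'
#' Applies \code{\link{dedup_cases}} to the DEMO table and restricts every
#' child table to the surviving report versions.
#'
#' @param snapshot a \code{faers_snapshot}.
#' @inheritParams dedup_cases
#' @return the deduplicated snapshot; \code{$dedup_dropped} records how
#'   many versions were discarded.
#' @export
dedup_snapshot <- function(snapshot, tie_break = "highest_primaryid") {
  demo <- dedup_cases(snapshot$demo, tie_break = tie_break)
  n_dropped <- attr(demo, "n_dropped")
  attr(demo, "n_dropped") <- NULL
  snap <- subset_snapshot(snapshot, demo$primaryid)
  snap$demo <- demo
  snap$deduplicated <- TRUE
  snap$dedup_dropped <- n_dropped
  snap
}
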