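# Reading and writing FAERS-dialect quarterly ASCII tables.
#
# Dialect: "$"-delimited, one header row, no quoting; a blank field is
# missing. This matches the public FAERS ASCII distribution (post-2012
# layouts). Loading is strict-but-forgiving: rows that fail type coercion
# are dropped and counted, never silently kept, so
# rows_read = rows_kept + rows_dropped always holds.

# Required columns per table kind; aliases map the FAERS physical column
# names onto the canonical names used throughout the package.
.table_spec <- list(
  DEMO = list(
    required = c("primaryid", "caseid"),
    keep = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
             "sex", "occr_country", "occp_cod"),
    aliases = c(gndr_cod = "sex", reporter_country = "occr_country")
  ),
  DRUG = list(
    required = c("primaryid", "drug_seq", "role_cod", "drugname"),
    keep = c("primaryid", "drug_seq", "role_cod", "drugname"),
    aliases = c(drug_name = "drugname", role_code = "role_cod")
  ),
  REAC = list(
    required = c("primaryid", "pt"),
    keep = c("primaryid", "pt"),
    aliases = c(drug_rec_act = "pt_unused")
  ),
  OUTC = list(
    required = c("primaryid", "outc_cod"),
    keep = c("primaryid", "outc_cod"),
    aliases = c(outc_code = "outc_cod")
  ),
  INDI = list(
    required = c("primaryid", "drug_seq", "indi_pt"),
    keep = c("primaryid", "drug_seq", "indi_pt"),
    aliases = c(indi_drug_seq = "drug_seq")
  ),
  THER = list(
    required = c("primaryid", "drug_seq", "start_dt"),
    keep = c("primaryid", "drug_seq", "start_dt"),
    aliases = c(dsg_drug_seq = "drug_seq")
  )
)

ROLE_CODES <- c("PS", "SS", "C", "I")
OUTCOME_CODES <- c("DE", "DS", "HO", "LT", "CA", "RI", "OT")

#' Read one FAERS-dialect ASCII table
#'
#' Reads a "$"-delimited file with a header row and returns a typed data
#' frame for the requested table kind. Rows that fail type coercion (blank
#' key fields, malformed dates, unknown role or outcome codes) are dropped
#' and counted in the load report attached as attribute
#' \code{"load_report"} (\code{read}, \code{kept}, \code{dropped}).
#'
#' Duplicate \code{(primaryid, pt)} reaction rows and duplicate
#' \code{(primaryid, outc_cod)} outcome rows are collapsed on load, so each
#' table stores sets at the report level.
#'
#' @param path path to the ASCII file.
#' @param table_kind one of \code{"DEMO"}, \code{"DRUG"}, \code{"REAC"},
#'   \code{"OUTC"}, \code{"INDI"}, \code{"THER"}.
#' @return a data frame of kept rows with a \code{"load_report"} attribute.
#' @export
load_table <- function(path, table_kind = c("DEMO", "DRUG", "REAC", "OUTC",
                                            "INDI", "THER")) {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) {
    stop("cannot read FAERS table: file not found: ", path)
  }
  spec <- .table_spec[[table_kind]]
  header <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  cols <- tolower(trimws(strsplit(header, "$", fixed = TRUE)[[1]]))
  for (al in names(spec$aliases)) {
    cols[cols == al] <- spec$aliases[[al]]
  }
  missing_cols <- setdiff(spec$required, cols)
  if (length(missing_cols)) {
    stop("unknown ", table_kind, " header layout (missing ",
         paste(missing_cols, collapse = ", "), "): ", header)
  }
  raw <- utils::read.table(path, sep = "$", header = FALSE, skip = 1L,
                           colClasses = "character", quote = "",
                           comment.char = "", fill = TRUE,
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           col.names = paste0("V", seq_along(cols)))
  names(raw) <- cols
  n_read <- nrow(raw)
  for (col in setdiff(spec$keep, cols)) raw[[col]] <- ""
  df <- raw[, spec$keep, drop = FALSE]
  for (j in seq_along(df)) df[[j]] <- trimws(df[[j]])

  keep <- rep(TRUE, nrow(df))
  keep <- keep & nzchar(df$primaryid)
  if (table_kind == "DEMO") {
    keep <- keep & nzchar(df$caseid)
    # fda_dt: blank is missing; a non-blank value must be a valid date
    keep <- keep & (!nzchar(df$fda_dt) | is_full_date(df$fda_dt))
    df <- df[keep, , drop = FALSE]
    df$fda_dt <- ifelse(nzchar(df$fda_dt),
                        suppressWarnings(as.integer(df$fda_dt)), NA_integer_)
    df$fda_dt <- as.integer(df$fda_dt)
    df$age <- suppressWarnings(as.numeric(ifelse(nzchar(df$age), df$age, NA)))
    df$sex <- toupper(df$sex)
    df$sex[!(df$sex %in% c("M", "F"))] <- "UNK"
    df$occp_cod <- toupper(df$occp_cod)
    # one row per primaryid
    dup <- duplicated(df$primaryid)
    df <- df[!dup, , drop = FALSE]
  } else if (table_kind == "DRUG") {
    seq_ok <- grepl("^[0-9]+$", df$drug_seq)
    keep <- keep & seq_ok & toupper(df$role_cod) %in% ROLE_CODES &
      nzchar(df$drugname)
    df <- df[keep, , drop = FALSE]
    df$drug_seq <- as.integer(df$drug_seq)
    df$role_cod <- toupper(df$role_cod)
    dup <- duplicated(df[, c("primaryid", "drug_seq")])
    df <- df[!dup, , drop = FALSE]
  } else if (table_kind == "REAC") {
    keep <- keep & nzchar(df$pt)
    df <- df[keep, , drop = FALSE]
    dup <- duplicated(df[, c("primaryid", "pt")])
    df <- df[!dup, , drop = FALSE]
  } else if (table_kind == "OUTC") {
    df$outc_cod <- toupper(df$outc_cod)
    keep <- keep & df$outc_cod %in% OUTCOME_CODES
    df <- df[keep, , drop = FALSE]
    dup <- duplicated(df[, c("primaryid", "outc_cod")])
    df <- df[!dup, , drop = FALSE]
  } else { # INDI, THER
    seq_ok <- grepl("^[0-9]+$", df$drug_seq)
    keep <- keep & seq_ok
    if (table_kind == "INDI") keep <- keep & nzchar(df$indi_pt)
    df <- df[keep, , drop = FALSE]
    df$drug_seq <- as.integer(df$drug_seq)
  }
  rownames(df) <- NULL
  attr(df, "load_report") <- data.frame(
    table = table_kind, read = n_read, kept = nrow(df),
    dropped = n_read - nrow(df), stringsAsFactors = FALSE
  )
  df
}

.empty_table <- function(table_kind) {
  spec <- .table_spec[[table_kind]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(spec$keep)),
                               spec$keep), stringsAsFactors = FALSE)
  if (table_kind == "DEMO") {
    df$fda_dt <- integer(0)
    df$age <- numeric(0)
  }
  if (table_kind %in% c("DRUG", "INDI", "THER")) df$drug_seq <- integer(0)
  attr(df, "load_report") <- data.frame(table = table_kind, read = 0L,
                                        kept = 0L, dropped = 0L,
                                        stringsAsFactors = FALSE)
  df
}

#' Read a PT-to-SOC event dictionary
#'
#' Two-column tab-separated file mapping each MedDRA preferred term to its
#' system organ class. A simplified two-level dictionary stands in for the
#' licensed MedDRA hierarchy.
#'
#' @param path TSV file with columns \code{pt} and \code{soc}.
#' @return data frame with columns \code{pt}, \code{soc}.
#' @export
load_event_dictionary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  names(df) <- tolower(names(df))
  if (!all(c("pt", "soc") %in% names(df))) {
    stop("event dictionary must have columns 'pt' and 'soc'")
  }
  df <- df[, c("pt", "soc")]
  df[!duplicated(df$pt), , drop = FALSE]
}

#' Load a directory of FAERS-dialect quarterly files into a snapshot
#'
#' Globs \code{DEMO*.txt}, \code{DRUG*.txt}, \code{REAC*.txt},
#' \code{OUTC*.txt}, \code{INDI*.txt}, \code{THER*.txt} (case-insensitive;
#' several quarterly files per table are concatenated), loads each through
#' \code{\link{load_table}}, and enforces referential integrity: child rows
#' whose \code{primaryid} (or \code{(primaryid, drug_seq)} for indications
#' and therapy dates) has no parent are dropped and counted as orphans.
#'
#' The event dictionary is read from \code{dict_path}, or from
#' \code{event_dict.tsv} in \code{dir} when present. Preferred terms
#' observed in the reaction table but absent from the dictionary are routed
#' to a sentinel SOC and a warning is raised, so the PT-to-SOC mapping is
#' total over observed PTs.
#'
#' @param dir directory containing the quarterly files.
#' @param dict_path optional path to the PT-to-SOC dictionary TSV.
#' @return an object of class \code{faers_snapshot}: a list with elements
#'   \code{demo}, \code{drug}, \code{reac}, \code{outc}, \code{indi},
#'   \code{ther}, \code{dict}, \code{load_log}, \code{orphans},
#'   \code{deduplicated}.
#' @export
load_snapshot <- function(dir, dict_path = NULL) {
  if (!dir.exists(dir)) stop("snapshot directory not found: ", dir)
  kinds <- names(.table_spec)
  tabs <- list()
  logs <- list()
  for (kind in kinds) {
    files <- list.files(dir, pattern = paste0("^", kind, ".*\\.txt$"),
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(files)) {
      if (kind %in% c("DEMO", "DRUG", "REAC")) {
        stop("mandatory table missing from snapshot directory: ", kind)
      }
      tabs[[kind]] <- .empty_table(kind)
      logs[[kind]] <- attr(tabs[[kind]], "load_report")
      next
    }
    parts <- lapply(sort(files), load_table, table_kind = kind)
    tabs[[kind]] <- do.call(rbind, parts)
    rep_df <- do.call(rbind, lapply(parts, attr, "load_report"))
    logs[[kind]] <- data.frame(table = kind, read = sum(rep_df$read),
                               kept = sum(rep_df$kept),
                               dropped = sum(rep_df$dropped),
                               stringsAsFactors = FALSE)
  }

  ids <- tabs$DEMO$primaryid
  orphans <- integer(0)
  drop_orphans <- function(df, kind) {
    ok <- df$primaryid %in% ids
    if (kind %in% c("INDI", "THER")) {
      key <- paste(df$primaryid, df$drug_seq)
      ok <- ok & key %in% paste(tabs$DRUG$primaryid, tabs$DRUG$drug_seq)
    }
    orphans[[kind]] <<- sum(!ok)
    df[ok, , drop = FALSE]
  }
  for (kind in c("DRUG", "REAC", "OUTC")) {
    tabs[[kind]] <- drop_orphans(tabs[[kind]], kind)
  }
  for (kind in c("INDI", "THER")) {
    tabs[[kind]] <- drop_orphans(tabs[[kind]], kind)
  }

  if (is.null(dict_path)) {
    cand <- file.path(dir, "event_dict.tsv")
    if (file.exists(cand)) dict_path <- cand
  }
  dict <- if (!is.null(dict_path)) load_event_dictionary(dict_path) else
    data.frame(pt = character(0), soc = character(0),
               stringsAsFactors = FALSE)
  observed <- unique(tabs$REAC$pt)
  unmapped <- setdiff(observed, dict$pt)
  if (length(unmapped)) {
    warning(length(unmapped),
            " preferred term(s) not in the event dictionary; routed to '",
            SENTINEL_SOC, "'")
    dict <- rbind(dict, data.frame(pt = unmapped, soc = SENTINEL_SOC,
                                   stringsAsFactors = FALSE))
  }

  snap <- structure(list(
    demo = tabs$DEMO, drug = tabs$DRUG, reac = tabs$REAC, outc = tabs$OUTC,
    indi = tabs$INDI, ther = tabs$THER, dict = dict,
    load_log = do.call(rbind, logs),
    orphans = unlist(orphans),
    deduplicated = FALSE
  ), class = "faers_snapshot")
  rownames(snap$load_log) <- NULL
  snap
}

#' @export
print.faers_snapshot <- function(x, ...) {
  cat("FAERS snapshot:", nrow(x$demo), "reports",
      if (x$deduplicated) "(deduplicated)" else "(raw case versions)", "\n")
  cat("  drug rows:     ", nrow(x$drug), "\n")
  cat("  reaction rows: ", nrow(x$reac), " (", length(unique(x$reac$pt)),
      " distinct PTs)\n", sep = "")
  cat("  outcome rows:  ", nrow(x$outc), "\n")
  cat("  indications:   ", nrow(x$indi), "\n")
  cat("  therapy rows:  ", nrow(x$ther), "\n")
  if (length(x$orphans) && sum(x$orphans) > 0) {
    cat("  orphan child rows dropped:", sum(x$orphans), "\n")
  }
  invisible(x)
}

# Restrict every table of a snapshot to the given primaryids.
subset_snapshot <- function(snapshot, primaryids) {
  snap <- snapshot
  for (tb in c("demo", "drug", "reac", "outc", "indi", "ther")) {
    snap[[tb]] <- snap[[tb]][snap[[tb]]$primaryid %in% primaryids, ,
                             drop = FALSE]
    rownames(snap[[tb]]) <- NULL
  }
  snap
}

#' Write result tables as UTF-8 CSV
#'
#' Writes each table in a named list to \code{<name>.csv} under \code{dir}
#' with a stable column order. Numeric columns round-trip bit-exactly for
#' integers and to at least 12 significant digits for reals via
#' \code{\link{read_results}}.
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) {
        df[[j]] <- ifelse(is.na(df[[j]]), NA,
                          formatC(df[[j]], digits = 15, format = "g"))
      }
    }
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, open = "wb")
    utils::write.csv(df, con, row.names = FALSE, na = "", fileEncoding = "UTF-8")
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back a CSV written by \code{write_results}
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
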