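# Disproportionality statistics and consensus signal calling.
#
# Four algorithms are computed on each (drug, event) four-grid:
#   ROR  = ad/(bc), Woolf log-normal 95% CI
#   PRR  = (a/(a+b)) / (c/(c+d)), paired with the Pearson chi-square
#   EBGM = aN/((a+b)(a+c)), the relative reporting ratio, with a
#          log-normal 5th-percentile lower bound EBGM05
#   IC   = log2(EBGM), with a lower credibility bound IC025
# A consensus signal requires all four algorithms' criteria simultaneously.
#
# The "EBGM" here is the unshrunk relative reporting ratio; no empirical-
# Bayes gamma-mixture shrinkage is applied (out of scope by design, and at
# the report counts this package screens the two agree closely, as the
# near-equality EBGM ~ PRR shows).

#' Configuration of the disproportionality algorithms
#'
#' @param z_ror normal quantile for the ROR 95\% interval (1.96).
#' @param z_ebgm normal quantile for the one-sided EBGM05 bound (1.645).
#' @param ic025_mode \code{"noren"} (default): the Noren closed-form
#'   approximation \code{IC - 3.3 (a+0.5)^-1/2 - 2 (a+0.5)^-3/4};
#'   \code{"fixed_offset"}: \code{IC - ic025_delta}, for replicating
#'   reports whose printed IC - IC025 gap is a constant.
#' @param ic025_delta offset used by \code{"fixed_offset"} (default 1.67).
#' @param zero_cell \code{"undefined"} (default): a zero cell leaves the
#'   affected statistics flagged undefined (\code{NA}) and their criteria
#'   false; \code{"haldane"}: add 0.5 to all four cells first.
#' @param ror_lo_thresh,ror_n_min,chi2_thresh,prr_thresh,prr_n_min,
#'   ebgm05_thresh,ic025_thresh,bcpnn_n_min signal-criterion thresholds;
#'   defaults are the conventional standards (ROR lower 95\% bound > 1 with
#'   n >= 2; chi-square >= 4 and PRR >= 2 with n >= 3; EBGM05 > 2;
#'   IC025 > 0 with n > 0).
#' @return an object of class \code{dispro_config}.
#' @export
dispro_config <- function(z_ror = 1.96,
                          z_ebgm = 1.645,
                          ic025_mode = c("noren", "fixed_offset"),
                          ic025_delta = 1.67,
                          zero_cell = c("undefined", "haldane"),
                          ror_lo_thresh = 1, ror_n_min = 2,
                          chi2_thresh = 4, prr_thresh = 2, prr_n_min = 3,
                          ebgm05_thresh = 2,
                          ic025_thresh = 0, bcpnn_n_min = 0) {
  structure(list(
    z_ror = z_ror, z_ebgm = z_ebgm,
    ic025_mode = match.arg(ic025_mode), ic025_delta = ic025_delta,
    zero_cell = match.arg(zero_cell),
    ror_lo_thresh = ror_lo_thresh, ror_n_min = ror_n_min,
    chi2_thresh = chi2_thresh, prr_thresh = prr_thresh,
    prr_n_min = prr_n_min, ebgm05_thresh = ebgm05_thresh,
    ic025_thresh = ic025_thresh, bcpnn_n_min = bcpnn_n_min
  ), class = "dispro_config")
}

.cells <- function(a, b, c, d, config) {
  if (config$zero_cell == "haldane" && any(a == 0 | b == 0 | c == 0 | d == 0)) {
    z <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * z; b <- b + 0.5 * z; c <- c + 0.5 * z; d <- d + 0.5 * z
  }
  list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
       d = as.numeric(d))
}

#' Reporting odds ratio with Woolf 95\% interval
#'
#' \code{ROR = ad/(bc)}; interval
#' \code{exp(log ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))}. Undefined
#' (\code{NA}) when any cell is zero under the default zero-cell policy.
#'
#' @param a,b,c,d contingency cells (vectorized).
#' @param config a \code{\link{dispro_config}}.
#' @return data frame with columns \code{ror}, \code{ror_lo95},
#'   \code{ror_hi95}.
#' @export
ror_stat <- function(a, b, c, d, config = dispro_config()) {
  cl <- .cells(a, b, c, d, config)
  bad <- cl$a <= 0 | cl$b <= 0 | cl$c <= 0 | cl$d <= 0
  ror <- (cl$a * cl$d) / (cl$b * cl$c)
  se <- sqrt(1 / cl$a + 1 / cl$b + 1 / cl$c + 1 / cl$d)
  lo <- exp(log(ror) - config$z_ror * se)
  hi <- exp(log(ror) + config$z_ror * se)
  ror[bad] <- NA_real_; lo[bad] <- NA_real_; hi[bad] <- NA_real_
  data.frame(ror = ror, ror_lo95 = lo, ror_hi95 = hi)
}

#' Proportional reporting ratio
#'
#' \code{PRR = (a/(a+b)) / (c/(c+d))}; undefined when \code{c = 0} or a
#' margin is empty.
#'
#' @inheritParams ror_stat
#' @return numeric vector.
#' @export
prr_stat <- function(a, b, c, d, config = dispro_config()) {
  cl <- .cells(a, b, c, d, config)
  bad <- cl$a + cl$b <= 0 | cl$c <= 0
  prr <- (cl$a / (cl$a + cl$b)) / (cl$c / (cl$c + cl$d))
  prr[bad] <- NA_real_
  prr
}

#' Pearson chi-square of the four-grid
#'
#' \code{sum (O - E)^2 / E} with \code{E} the product of margins over
#' \code{N}; computed in the algebraically equal closed form
#' \code{N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, without continuity
#' correction. Undefined when any margin is zero.
#'
#' @inheritParams ror_stat
#' @return numeric vector.
#' @export
chi_square <- function(a, b, c, d, config = dispro_config()) {
  cl <- .cells(a, b, c, d, config)
  n <- cl$a + cl$b + cl$c + cl$d
  m1 <- cl$a + cl$b; m2 <- cl$c + cl$d; m3 <- cl$a + cl$c; m4 <- cl$b + cl$d
  bad <- m1 <= 0 | m2 <= 0 | m3 <= 0 | m4 <= 0
  chi2 <- n * (cl$a * cl$d - cl$b * cl$c)^2 / (m1 * m2 * m3 * m4)
  chi2[bad] <- NA_real_
  chi2
}

#' Relative reporting ratio (EBGM as printed) with lower bound
#'
#' \code{EBGM = aN/((a+b)(a+c))}; \code{EBGM05 =
#' exp(log EBGM - z sqrt(1/a + 1/b + 1/c + 1/d))} (log-normal lower bound,
#' one-sided z = 1.645 by default). \code{a = 0} gives EBGM 0 with the
#' bound undefined.
#'
#' @inheritParams ror_stat
#' @return data frame with columns \code{ebgm}, \code{ebgm05}.
#' @export
ebgm_stat <- function(a, b, c, d, config = dispro_config()) {
  cl <- .cells(a, b, c, d, config)
  n <- cl$a + cl$b + cl$c + cl$d
  m1 <- cl$a + cl$b; m3 <- cl$a + cl$c
  bad_margin <- m1 <= 0 | m3 <= 0
  ebgm <- cl$a * n / (m1 * m3)
  se <- sqrt(1 / cl$a + 1 / cl$b + 1 / cl$c + 1 / cl$d)
  ebgm05 <- exp(log(ebgm) - config$z_ebgm * se)
  zero_a <- cl$a <= 0
  ebgm[zero_a & !bad_margin] <- 0
  ebgm05[zero_a | cl$b <= 0 | cl$c <= 0 | cl$d <= 0] <- NA_real_
  ebgm[bad_margin] <- NA_real_
  data.frame(ebgm = ebgm, ebgm05 = ebgm05)
}

#' Information component with lower credibility bound
#'
#' \code{IC = log2(aN/((a+b)(a+c)))}, i.e. \code{log2(EBGM)} exactly.
#' The lower bound \code{IC025} follows the configured mode: the Noren
#' closed-form approximation (default) or a fixed offset below IC.
#'
#' @inheritParams ror_stat
#' @return data frame with columns \code{ic}, \code{ic025}.
#' @export
ic_stat <- function(a, b, c, d, config = dispro_config()) {
  eb <- ebgm_stat(a, b, c, d, config)
  cl <- .cells(a, b, c, d, config)
  ic <- log2(eb$ebgm)
  ic[!is.na(eb$ebgm) & eb$ebgm <= 0] <- NA_real_
  ic025 <- if (config$ic025_mode == "noren") {
    ic - 3.3 * (cl$a + 0.5)^(-0.5) - 2 * (cl$a + 0.5)^(-0.75)
  } else {
    ic - config$ic025_delta
  }
  ic025[is.na(ic)] <- NA_real_
  data.frame(ic = ic, ic025 = ic025)
}

#' All four statistics for a set of four-grids
#'
#' @inheritParams ror_stat
#' @return data frame with \code{n} (= \code{a}) and the statistic columns
#'   \code{ror}, \code{ror_lo95}, \code{ror_hi95}, \code{prr}, \code{chi2},
#'   \code{ebgm}, \code{ebgm05}, \code{ic}, \code{ic025}.
#' @export
signal_stats <- function(a, b, c, d, config = dispro_config()) {
  out <- cbind(
    data.frame(n = as.integer(a)),
    ror_stat(a, b, c, d, config),
    data.frame(prr = prr_stat(a, b, c, d, config),
               chi2 = chi_square(a, b, c, d, config)),
    ebgm_stat(a, b, c, d, config),
    ic_stat(a, b, c, d, config)
  )
  out
}

#' Per-algorithm signal criteria and the consensus call
#'
#' Evaluates the four signal standards on computed statistics; an
#' undefined (\code{NA}) statistic fails its criterion. The consensus flag
#' is the conjunction of all four.
#'
#' @param stats a data frame from \code{\link{signal_stats}}.
#' @param config a \code{\link{dispro_config}}.
#' @return data frame with logical columns \code{ror_flag},
#'   \code{prr_flag}, \code{mgps_flag}, \code{bcpnn_flag},
#'   \code{consensus}.
#' @export
evaluate_criteria <- function(stats, config = dispro_config()) {
  f <- function(x) !is.na(x) & x
  ror_flag <- f(stats$ror_lo95 > config$ror_lo_thresh) &
    stats$n >= config$ror_n_min
  prr_flag <- f(stats$chi2 >= config$chi2_thresh) &
    f(stats$prr >= config$prr_thresh) & stats$n >= config$prr_n_min
  mgps_flag <- f(stats$ebgm05 > config$ebgm05_thresh)
  bcpnn_flag <- f(stats$ic025 > config$ic025_thresh) &
    stats$n > config$bcpnn_n_min
  data.frame(ror_flag = ror_flag, prr_flag = prr_flag,
             mgps_flag = mgps_flag, bcpnn_flag = bcpnn_flag,
             consensus = ror_flag & prr_flag & mgps_flag & bcpnn_flag)
}

#' Screen every event of a snapshot for disproportionality signals
#'
#' The central fitting function: builds the target cohort, forms the
#' four-grid for every event at the requested level, computes the four
#' statistics with their interval bounds, evaluates each algorithm's
#' signal standard, and calls consensus signals (all four simultaneously).
#' Non-qualifying events are retained in the table.
#'
#' @param snapshot a deduplicated \code{faers_snapshot}.
#' @param spec a \code{\link{cohort_spec}} naming the target drug.
#' @param config a \code{\link{dispro_config}}.
#' @return an object of class \code{faers_screen}: list with \code{table}
#'   (one row per event, sorted by \code{n} descending), \code{level},
#'   \code{unit}, \code{margin} (a+b), \code{n_total}, \code{n_target},
#'   \code{spec}, \code{config}.
#' @seealso \code{\link{signals}}, \code{\link{summary.faers_screen}}
#' @export
dispro_screen <- function(snapshot, spec, config = dispro_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!isTRUE(snapshot$deduplicated)) {
    warning("screening a snapshot that has not been deduplicated")
  }
  target_ids <- suppressWarnings(match_target_reports(snapshot, spec))
  empty <- length(target_ids) == 0L
  if (empty) warning("no target reports matched; empty screening table")
  counts <- event_counts(snapshot, target_ids, level = spec$level,
                         unit = spec$unit)
  counts <- counts[counts$a > 0L, , drop = FALSE]
  mg <- .margins(snapshot, target_ids, spec$unit)
  if (nrow(counts)) {
    cells <- build_contingency(counts$a, counts$a_c, mg$margin, mg$n_total)
    stats <- signal_stats(cells$a, cells$b, cells$c, cells$d, config)
    flags <- evaluate_criteria(stats, config)
    tab <- cbind(data.frame(event = counts$event, stringsAsFactors = FALSE),
                 cells, stats[, -1, drop = FALSE],
                 data.frame(n = stats$n), flags)
    tab <- tab[, c("event", "n", "a", "b", "c", "d",
                   "ror", "ror_lo95", "ror_hi95", "prr", "chi2",
                   "ebgm", "ebgm05", "ic", "ic025",
                   "ror_flag", "prr_flag", "mgps_flag", "bcpnn_flag",
                   "consensus")]
    if (spec$level == "PT") {
      tab$soc <- snapshot$dict$soc[match(tab$event, snapshot$dict$pt)]
      tab$soc[is.na(tab$soc)] <- SENTINEL_SOC
      tab <- tab[, c("event", "soc", setdiff(names(tab),
                                             c("event", "soc")))]
    }
    tab <- tab[order(-tab$n, tab$event), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(event = character(0), n = integer(0))
  }
  structure(list(
    table = tab, level = spec$level, unit = spec$unit,
    margin = mg$margin, n_total = mg$n_total,
    n_target = length(target_ids), spec = spec, config = config
  ), class = "faers_screen")
}

#' Consensus signals of a screen
#'
#' @param object a \code{faers_screen}.
#' @param ... unused.
#' @return the rows of the screening table with \code{consensus = TRUE}.
#' @export
signals <- function(object, ...) UseMethod("signals")

#' @rdname signals
#' @export
signals.faers_screen <- function(object, ...) {
  tab <- object$table
  if (!nrow(tab)) return(tab)
  out <- tab[tab$consensus, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.faers_screen <- function(x, ...) {
  cat("Disproportionality screen (", x$level, " level, unit = ", x$unit,
      ")\n", sep = "")
  cat("  target units (a+b):", x$margin, " of N =", x$n_total, "\n")
  cat("  events screened:   ", nrow(x$table), "\n")
  n_sig <- if (nrow(x$table)) sum(x$table$consensus) else 0L
  cat("  consensus signals: ", n_sig, "\n")
  invisible(x)
}

#' Summarize a disproportionality screen
#'
#' @param object a \code{faers_screen}.
#' @param digits decimal places for the ratio statistics in the printed
#'   table (full precision is retained in \code{object$table}).
#' @param ... unused.
#' @return invisibly, the rounded consensus-signal table.
#' @export
summary.faers_screen <- function(object, digits = 2, ...) {
  print(object)
  sig <- signals(object)
  if (nrow(sig)) {
    num <- vapply(sig, is.double, logical(1))
    sig[num] <- lapply(sig[num], round_half_up, digits = digits)
    cat("\nConsensus signals:\n")
    print(sig[, setdiff(names(sig), c("a", "b", "c", "d", "ror_flag",
                                      "prr_flag", "mgps_flag",
                                      "bcpnn_flag", "consensus"))],
          row.names = FALSE)
  }
  invisible(sig)
}

#' @export
as.data.frame.faers_screen <- function(x, ...) x$table

#' Forest-style plot of a screen's reporting odds ratios
#'
#' Plots log2 ROR with its 95\% interval for the top events by report
#' count; consensus signals are drawn filled.
#'
#' @param x a \code{faers_screen}.
#' @param top number of events (by \code{n}) to draw.
#' @param ... passed to \code{plot}.
#' @export
plot.faers_screen <- function(x, top = 20, ...) {
  tab <- x$table
  tab <- tab[!is.na(tab$ror), , drop = FALSE]
  if (!nrow(tab)) {
    warning("nothing to plot: no defined ROR values")
    return(invisible(NULL))
  }
  tab <- utils::head(tab[order(-tab$n), , drop = FALSE], top)
  tab <- tab[rev(seq_len(nrow(tab))), ]
  ylim <- c(0.5, nrow(tab) + 0.5)
  xlim <- range(log2(c(tab$ror_lo95, tab$ror_hi95)), na.rm = TRUE)
  graphics::plot(log2(tab$ror), seq_len(nrow(tab)), xlim = xlim, ylim = ylim,
                 pch = ifelse(tab$consensus, 19, 1), yaxt = "n",
                 xlab = "log2 reporting odds ratio", ylab = "", ...)
  graphics::segments(log2(tab$ror_lo95), seq_len(nrow(tab)),
                     log2(tab$ror_hi95), seq_len(nrow(tab)))
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(nrow(tab)), labels = tab$event, las = 2,
                 cex.axis = 0.7)
  invisible(tab)
}
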