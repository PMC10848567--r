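## Success metrics, failure-tracking accounting, age-length regression
## and the assignment summary table. All printed percentages are rounded
## half-up to one decimal so tabulated rates are exact and reproducible.

pct <- function(num, den) {
  if (den == 0) return(0)
  round_half_up(100 * num / den, 1)
}

#' Success summary from explicit counts
#'
#' The count-based core of [success_summary()]: useful when the inputs
#' are published tallies rather than assembled barcodes. Recovery counts
#' barcodes with any non-N base; acceptability counts barcodes longer
#' than 300 non-N bp; genus-level success counts a genus when at least
#' one of its specimens is acceptable.
#'
#' @param n_total specimens attempted.
#' @param n_recovered specimens with a barcode > 0 bp.
#' @param n_acceptable specimens with a barcode > 300 bp.
#' @param n_flagged flagged records among the total.
#' @param n_genera genera attempted (optional).
#' @param n_genera_acceptable genera with >= 1 acceptable specimen.
#' @return a `success_summary` list with counts and percentages
#'   (`pct_recovered`, `pct_acceptable`, `pct_genera`).
#' @export
success_rates <- function(n_total, n_recovered, n_acceptable,
                          n_flagged = 0L, n_genera = NA_integer_,
                          n_genera_acceptable = NA_integer_) {
  if (n_acceptable > n_recovered || n_recovered > n_total) {
    stop("need n_acceptable <= n_recovered <= n_total")
  }
  structure(list(
    n_total = as.integer(n_total),
    n_recovered = as.integer(n_recovered),
    n_acceptable = as.integer(n_acceptable),
    n_flagged = as.integer(n_flagged),
    n_genera = as.integer(n_genera),
    n_genera_acceptable = as.integer(n_genera_acceptable),
    pct_recovered = pct(n_recovered, n_total),
    pct_acceptable = pct(n_acceptable, n_total),
    pct_genera = if (is.na(n_genera)) NA_real_ else
      pct(n_genera_acceptable, n_genera)),
    class = "success_summary")
}

#' @export
print.success_summary <- function(x, ...) {
  cat(sprintf(
    "<success_summary> %d specimens: %d recovered (%.1f%%), %d acceptable (%.1f%%)%s\n",
    x$n_total, x$n_recovered, x$pct_recovered, x$n_acceptable,
    x$pct_acceptable,
    if (!is.na(x$n_genera))
      sprintf("; %d/%d genera (%.1f%%)", x$n_genera_acceptable, x$n_genera,
              x$pct_genera) else ""))
  invisible(x)
}

#' Sequencing success summary from assembled barcodes
#'
#' @param barcodes list of `consensus_barcode` (one per specimen).
#' @param records matching `specimen_record` rows (by `sample_id`).
#' @return a `success_summary` (see [success_rates()]).
#' @export
success_summary <- function(barcodes, records) {
  ids <- vapply(barcodes, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_id among barcodes")
  if (anyDuplicated(records$sample_id)) stop("duplicate sample_id among records")
  m <- match(records$sample_id, ids)
  nonN <- vapply(records$sample_id, function(s) {
    i <- match(s, ids)
    if (is.na(i)) 0L else barcodes[[i]]$nonN_length
  }, integer(1))
  flagged <- vapply(seq_along(records$sample_id), function(k) {
    i <- m[k]
    bf <- if (is.na(i)) character(0) else barcodes[[i]]$flags
    rf <- records$flags[k]
    length(setdiff(bf, c("no_reads", "short"))) > 0 ||
      (nzchar(rf) && rf != "")
  }, logical(1))
  acceptable <- nonN > 300L
  genera <- records$genus
  has_genus <- nzchar(genera)
  success_rates(
    n_total = nrow(records),
    n_recovered = sum(nonN > 0L),
    n_acceptable = sum(acceptable),
    n_flagged = sum(flagged),
    n_genera = length(unique(genera[has_genus])),
    n_genera_acceptable = length(unique(genera[has_genus & acceptable])))
}

#' Regression of recovered barcode length on specimen age
#'
#' Ordinary least squares of non-N consensus length (bp) on specimen age
#' (years, `analysis_year - collection_year`). Flagged records can be
#' excluded, mirroring how contaminated records are dropped from
#' published length-age analyses.
#'
#' @param records `specimen_record` rows.
#' @param barcodes matching list of `consensus_barcode`.
#' @param exclude_flagged drop records carrying flags beyond
#'   `short`/`no_reads` (default TRUE).
#' @param analysis_year year ages are computed against (default 2017).
#' @return a `regression_result`: `slope`, `intercept`, `r_squared`,
#'   `p_value` (two-sided slope test), `n`.
#' @export
age_length_regression <- function(records, barcodes, exclude_flagged = TRUE,
                                  analysis_year = 2017) {
  ids <- vapply(barcodes, `[[`, character(1), "sample_id")
  m <- match(records$sample_id, ids)
  len <- ifelse(is.na(m), NA_integer_,
                vapply(barcodes, `[[`, integer(1), "nonN_length")[m])
  age <- specimen_age(records, analysis_year)
  keep <- !is.na(len) & !is.na(age)
  if (exclude_flagged) {
    bad <- vapply(seq_along(records$sample_id), function(k) {
      i <- m[k]
      if (is.na(i)) return(FALSE)
      length(setdiff(barcodes[[i]]$flags, c("short", "no_reads"))) > 0
    }, logical(1))
    keep <- keep & !bad
  }
  fit_length_age(len[keep], age[keep])
}

## OLS core shared by age_length_regression and direct fixture use.
fit_length_age <- function(length_bp, age) {
  n <- length(age)
  if (n < 3) stop("need at least 3 (age, length) pairs")
  if (stats::var(age) == 0) stop("zero variance in age")
  if (stats::var(length_bp) == 0) {
    # constant response: a flat line explains nothing and lm()'s
    # numerically-perfect fit would report nonsense R^2
    return(structure(list(slope = 0, intercept = length_bp[1],
                          r_squared = 0, p_value = 1, n = n),
                     class = "regression_result"))
  }
  fit <- lm(length_bp ~ age)
  # exactly colinear fixtures trip lm's perfect-fit warning; the fit is valid
  sm <- suppressWarnings(summary(fit))
  p <- if (nrow(sm$coefficients) < 2 || is.na(sm$coefficients[2, 4])) {
    if (sm$r.squared == 0) 1 else NA_real_
  } else sm$coefficients[2, 4]
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = p, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> n = %d: length = %.2f %+.3f * age, R^2 = %.3f, p = %.3g\n",
    x$n, x$intercept, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' Combine first-pass and failure-tracking success counts
#'
#' Failure tracking re-attempts, with a second protocol, exactly the
#' specimens that failed the first pass; its recovered set is therefore
#' disjoint from the first pass's, and the combined tallies are sums.
#' Arithmetic consistency (subset and disjointness) is enforced.
#'
#' @param first a `success_summary` for the first (e.g. Sanger) pass.
#' @param rerun a `success_summary` for the failure-tracking pass, whose
#'   `n_total` must not exceed the first pass's failures.
#' @return a `failure_tracking_summary` list with `first`, `rerun` and
#'   `combined` summaries plus `pct_rerun_recovered` (the rerun's
#'   recovery rate on its own denominator).
#' @export
failure_tracking_summary <- function(first, rerun) {
  n_failed_first <- first$n_total - first$n_recovered
  if (rerun$n_total > n_failed_first) {
    stop("failure-tracking subset (", rerun$n_total,
         ") exceeds first-pass failures (", n_failed_first, ")")
  }
  combined <- success_rates(
    n_total = first$n_total,
    n_recovered = first$n_recovered + rerun$n_recovered,
    n_acceptable = first$n_acceptable + rerun$n_acceptable,
    n_flagged = first$n_flagged + rerun$n_flagged,
    n_genera = first$n_genera,
    n_genera_acceptable = if (is.na(rerun$n_genera_acceptable))
      first$n_genera_acceptable else NA_integer_)
  structure(list(first = first, rerun = rerun, combined = combined,
                 pct_rerun_recovered = pct(rerun$n_recovered, rerun$n_total)),
            class = "failure_tracking_summary")
}

#' Combined genus-level success after failure tracking
#'
#' @param summary a `failure_tracking_summary`.
#' @param n_genera genera attempted.
#' @param n_genera_acceptable genera with >= 1 acceptable specimen across
#'   both passes.
#' @return the summary with the combined genus counts and `pct_genera`
#'   filled in.
#' @export
set_combined_genus_success <- function(summary, n_genera,
                                       n_genera_acceptable) {
  summary$combined$n_genera <- as.integer(n_genera)
  summary$combined$n_genera_acceptable <- as.integer(n_genera_acceptable)
  summary$combined$pct_genera <- pct(n_genera_acceptable, n_genera)
  summary
}

#' @export
print.failure_tracking_summary <- function(x, ...) {
  cat("First pass:    "); print(x$first)
  cat(sprintf("Failure track: %d of %d re-attempted recovered (%.1f%%)\n",
              x$rerun$n_recovered, x$rerun$n_total, x$pct_rerun_recovered))
  cat("Combined:      "); print(x$combined)
  invisible(x)
}

#' Method-by-rank assignment report with totals
#'
#' @param summary 2 x 2 integer matrix (`bin_match`/`id_engine` by
#'   `genus`/`species`), as produced by [assign_all()].
#' @return matrix with row, column and grand totals appended.
#' @export
assignment_report <- function(summary) {
  stopifnot(is.matrix(summary), nrow(summary) == 2, ncol(summary) == 2)
  out <- rbind(cbind(summary, total = rowSums(summary)),
               total = c(colSums(summary), sum(summary)))
  storage.mode(out) <- "integer"
  out
}

#' Write an assignment report as TSV
#'
#' @param report matrix from [assignment_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignment_report <- function(report, path) {
  df <- data.frame(method = rownames(report), report, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
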