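# The combined differential-expression filter: a per-dataset |log2 ratio|
# cutoff at the pooled mean + k SD, intersected with a p-value cutoff, and
# the expected-by-chance / apparent-FDR arithmetic. No multiple-testing
# correction is applied; the apparent FDR is the empirical control.

#' Ratio cutoff at k SD above the mean of the pooled ratio distribution
#'
#' Pools the signed log2 ratios of one concentration's arrays and returns
#' `mean + sd_multiplier * SD`, to be applied to |log2 ratio|. A
#' `per_array` mode returns one threshold per table instead.
#'
#' @param tables A comparison table or list of comparison tables (the
#'   concentration's arrays).
#' @param sd_multiplier Positive multiplier (default 2).
#' @param per_array If `TRUE`, return a named vector of per-table
#'   thresholds instead of one pooled threshold.
#' @return Threshold(s) in log2 units.
#' @export
ratio_sd_threshold <- function(tables, sd_multiplier = 2, per_array = FALSE) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (sd_multiplier < 0) stop("sd_multiplier must be nonnegative")
  one <- function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) stop("no finite log2 ratios")
    s <- sd(r)
    if (!is.finite(s) || s == 0)
      stop("ratio SD is zero; threshold undefined")
    # the cutoff is applied to |log2 ratio|, so it is reported nonnegative
    abs(mean(r) + sd_multiplier * s)
  }
  if (per_array)
    return(vapply(tables, function(tb) one(tb$log2_ratio), numeric(1)))
  one(unlist(lapply(tables, function(tb) tb$log2_ratio), use.names = FALSE))
}

#' Bundle of filter thresholds
#' @param alpha P-value cutoff in (0, 1), default 0.005.
#' @param ratio_threshold |log2 ratio| cutoff (> 0), typically from
#'   [ratio_sd_threshold()].
#' @param sd_multiplier The multiplier used to derive `ratio_threshold`
#'   (metadata only).
#' @return A `tfscope_thresholds` list.
#' @export
filter_thresholds <- function(alpha = 0.005, ratio_threshold,
                              sd_multiplier = 2) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (ratio_threshold <= 0) stop("ratio_threshold must be positive")
  structure(list(alpha = alpha, ratio_threshold = ratio_threshold,
                 sd_multiplier = sd_multiplier),
            class = "tfscope_thresholds")
}

#' Ternary significance calls for one array
#'
#' `up` when `log2_ratio > +ratio_threshold` and `p < alpha`; `down` when
#' `log2_ratio < -ratio_threshold` and `p < alpha`; `none` otherwise.
#'
#' @param table A comparison table.
#' @param thresholds A [filter_thresholds()].
#' @return Named character vector of calls (names = probe ids).
#' @export
call_significance <- function(table, thresholds) {
  stopifnot(inherits(thresholds, "tfscope_thresholds"))
  sig <- table$p_value < thresholds$alpha
  calls <- rep("none", nrow(table))
  calls[sig & table$log2_ratio > thresholds$ratio_threshold] <- "up"
  calls[sig & table$log2_ratio < -thresholds$ratio_threshold] <- "down"
  setNames(calls, table$probe_id)
}

#' Call matrix across conditions
#' @param tables Named list of comparison tables over one probe universe.
#' @param thresholds A [filter_thresholds()] applied to every table.
#' @return Character matrix probes x conditions of calls, row names =
#'   probe ids.
#' @export
call_matrix <- function(tables, thresholds) {
  ids <- tables[[1]]$probe_id
  m <- vapply(tables, function(tb) {
    calls <- call_significance(tb, thresholds)
    calls[ids]
  }, character(length(ids)))
  rownames(m) <- ids
  m
}

#' Expected-by-chance count and apparent FDR of the combined filter
#'
#' Of the probes passing the fold-change (ratio) filter alone, `alpha x
#' n_fc_pass` are expected to also pass the p-value filter by chance
#' (rounded to the nearest integer); the apparent FDR is that count
#' divided by the number actually passing both filters.
#'
#' @param alpha P-value cutoff.
#' @param n_fc_pass Probes passing the ratio filter alone.
#' @param n_combined_pass Probes passing both filters (> 0).
#' @return A `tfscope_fdr_report` list: `n_fc_pass`, `n_combined_pass`,
#'   `expected_by_chance`, `apparent_fdr` (fraction) and
#'   `apparent_fdr_percent` (percentage rounded to 2 decimals).
#' @examples
#' apparent_fdr(0.005, 5031, 3912)  # expected 25, apparent FDR 0.64%
#' @export
apparent_fdr <- function(alpha, n_fc_pass, n_combined_pass) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_fc_pass < 0 || n_combined_pass < 0) stop("counts must be nonnegative")
  if (n_combined_pass == 0)
    stop("apparent FDR undefined: no probes pass the combined filter")
  expected <- round(alpha * n_fc_pass)
  fdr <- expected / n_combined_pass
  structure(list(n_fc_pass = n_fc_pass,
                 n_combined_pass = n_combined_pass,
                 expected_by_chance = expected,
                 apparent_fdr = fdr,
                 apparent_fdr_percent = round(100 * fdr, 2)),
            class = "tfscope_fdr_report")
}

#' @export
print.tfscope_fdr_report <- function(x, ...) {
  cat(sprintf(
    "Combined-filter FDR report\n  ratio-filter pass: %d\n  combined pass:     %d\n  expected by chance: %d\n  apparent FDR:      %.2f%%\n",
    x$n_fc_pass, x$n_combined_pass, x$expected_by_chance,
    x$apparent_fdr_percent))
  invisible(x)
}

#' Filter summary for a set of arrays
#'
#' Convenience wrapper: counts probes passing the ratio filter on at least
#' one array, probes passing the combined filter on at least one array,
#' and derives the [apparent_fdr()] report.
#'
#' @param tables Named list of comparison tables (one concentration).
#' @param thresholds A [filter_thresholds()].
#' @return A `tfscope_fdr_report`.
#' @export
filter_report <- function(tables, thresholds) {
  if (is.data.frame(tables)) tables <- list(tables)
  ids <- tables[[1]]$probe_id
  fc_pass <- Reduce(`|`, lapply(tables, function(tb)
    abs(tb$log2_ratio[match(ids, tb$probe_id)]) > thresholds$ratio_threshold))
  comb_pass <- Reduce(`|`, lapply(tables, function(tb) {
    tb <- tb[match(ids, tb$probe_id), ]
    abs(tb$log2_ratio) > thresholds$ratio_threshold &
      tb$p_value < thresholds$alpha
  }))
  apparent_fdr(thresholds$alpha, sum(fc_pass), sum(comb_pass))
}
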