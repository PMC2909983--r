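# Comparison-table I/O and data conditioning: validation, intensity-trend
# (MA) normalization, dye-swap combination and redundant-probe collapse.

.REQUIRED_COLS <- c("probe_id", "log2_ratio", "p_value",
                    "intensity_ch1", "intensity_ch2")

#' Validate a comparison table in memory
#'
#' Checks the column contract shared by all pipeline stages: required
#' columns present, p-values in \[0, 1\], intensities nonnegative, one row
#' per probe.
#'
#' @param table data.frame with columns `probe_id`, `log2_ratio`,
#'   `p_value`, `intensity_ch1`, `intensity_ch2` and optionally
#'   `ratio_variance`.
#' @return The table, invisibly, after validation.
#' @export
validate_comparison_table <- function(table) {
  miss <- setdiff(.REQUIRED_COLS, names(table))
  if (length(miss))
    stop("comparison table is missing column(s): ", paste(miss, collapse = ", "))
  num_cols <- setdiff(.REQUIRED_COLS, "probe_id")
  for (cl in num_cols)
    if (!is.numeric(table[[cl]]))
      stop("column '", cl, "' must be numeric")
  bad <- which(!is.finite(table$p_value) | table$p_value < 0 | table$p_value > 1)
  if (length(bad))
    stop("p_value outside [0, 1] at row ", bad[1])
  bad <- which(table$intensity_ch1 < 0 | table$intensity_ch2 < 0)
  if (length(bad))
    stop("negative intensity at row ", bad[1])
  dup <- which(duplicated(table$probe_id))
  if (length(dup))
    stop("duplicate probe_id '", table$probe_id[dup[1]], "' at row ", dup[1])
  invisible(table)
}

#' Read a tab-delimited comparison table
#'
#' Rows with missing values in required columns, or with a nonzero `flag`
#' column (features flagged in either channel), are excluded; the exclusion
#' count is attached as attribute `n_excluded`.
#'
#' @param path TSV file with a header row and the columns of
#'   [validate_comparison_table()] (optional `ratio_variance`, `flag`).
#' @return A validated comparison table data.frame.
#' @export
read_comparison_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(.REQUIRED_COLS, names(raw))
  if (length(miss))
    stop("file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  n0 <- nrow(raw)
  keep <- stats::complete.cases(raw[, .REQUIRED_COLS])
  if ("flag" %in% names(raw))
    keep <- keep & (is.na(raw$flag) | raw$flag == 0)
  out <- raw[keep, setdiff(names(raw), "flag"), drop = FALSE]
  rownames(out) <- NULL
  validate_comparison_table(out)
  attr(out, "n_excluded") <- n0 - nrow(out)
  out
}

#' Write a comparison table as TSV (log2 ratios rounded to 6 decimals)
#' @param table A comparison table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(table, path) {
  out <- table
  out$log2_ratio <- round(out$log2_ratio, 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#' @param path TSV with columns `probe_id`, `accession` and optionally
#'   `symbol`.
#' @return data.frame with unique `probe_id`.
#' @export
read_probe_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "accession") %in% names(ann)))
    stop("annotation needs columns 'probe_id' and 'accession'")
  if (anyDuplicated(ann$probe_id))
    stop("duplicate probe_id in annotation: ",
         ann$probe_id[duplicated(ann$probe_id)][1])
  if (!"symbol" %in% names(ann)) ann$symbol <- ""
  ann
}

#' Remove the intensity-dependent ratio trend (MA loess normalization)
#'
#' Fits a local regression of the log2 ratio against the mean log
#' intensity A = (log2 ch1 + log2 ch2)/2 and subtracts the fit, the
#' standard within-array correction for dye/intensity trends on two-color
#' arrays. The regression is delegated to [limma::loessFit()].
#'
#' @param table A comparison table with positive intensities.
#' @param span Loess span in (0, 1].
#' @return The table with recentred `log2_ratio` (median approximately 0
#'   on trendless data).
#' @export
ma_normalize <- function(table, span = 0.4) {
  validate_comparison_table(table)
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (any(table$intensity_ch1 <= 0 | table$intensity_ch2 <= 0))
    stop("ma_normalize requires strictly positive intensities")
  a <- (log2(table$intensity_ch1) + log2(table$intensity_ch2)) / 2
  fit <- limma::loessFit(table$log2_ratio, a, span = span)
  out <- table
  out$log2_ratio <- table$log2_ratio - fit$fitted
  out
}

#' Combine a forward array with its dye swap
#'
#' The reverse (control vs treated) ratios are sign-flipped onto the
#' treated-vs-control scale, then the combined log2 ratio is the
#' inverse-variance weighted mean of the pair (equal weights when either
#' table lacks `ratio_variance`). The combined p-value is the two-sided
#' normal p of `z = weighted mean / SE(weighted mean)`. A symmetric dye
#' bias enters the two arrays with opposite signs and cancels.
#'
#' Channel intensities are averaged channel-wise after undoing the swap
#' (forward ch1 with reverse ch2, and vice versa).
#'
#' @param forward Comparison table, treated vs control.
#' @param reverse Comparison table, control vs treated (dye swap).
#' @return A combined comparison table with `ratio_variance` set to the
#'   variance of the weighted mean.
#' @export
combine_dye_swap <- function(forward, reverse) {
  validate_comparison_table(forward)
  validate_comparison_table(reverse)
  only_f <- setdiff(forward$probe_id, reverse$probe_id)
  only_r <- setdiff(reverse$probe_id, forward$probe_id)
  if (length(only_f) || length(only_r))
    stop("probe sets differ; only in forward: ",
         paste(head(only_f, 5), collapse = ", "),
         "; only in reverse: ", paste(head(only_r, 5), collapse = ", "))
  rev <- reverse[match(forward$probe_id, reverse$probe_id), ]
  r_f <- forward$log2_ratio
  r_r <- -rev$log2_ratio   # onto the treated-vs-control scale
  have_var <- !is.null(forward$ratio_variance) && !is.null(rev$ratio_variance)
  if (have_var) {
    v_f <- forward$ratio_variance
    v_r <- rev$ratio_variance
  } else {
    warning("ratio_variance missing; combining with equal weights")
    v_f <- v_r <- rep(1, nrow(forward))
  }
  w_f <- 1 / v_f
  w_r <- 1 / v_r
  combined <- (w_f * r_f + w_r * r_r) / (w_f + w_r)
  v_comb <- 1 / (w_f + w_r)
  p <- 2 * pnorm(-abs(combined) / sqrt(v_comb))
  data.frame(
    probe_id = forward$probe_id,
    log2_ratio = combined,
    p_value = p,
    intensity_ch1 = (forward$intensity_ch1 + rev$intensity_ch2) / 2,
    intensity_ch2 = (forward$intensity_ch2 + rev$intensity_ch1) / 2,
    ratio_variance = v_comb,
    stringsAsFactors = FALSE)
}

#' Collapse redundant probes sharing an accession and a call pattern
#'
#' Among probes mapped to the same accession whose ternary significance
#' calls agree across every condition, only the representative probe — the
#' one with the highest mean signal intensity across conditions — is
#' retained. Probes sharing an accession but differing in pattern are all
#' kept, as are probes without an accession.
#'
#' @param tables Named list of comparison tables, one per condition, all
#'   over the same probe universe.
#' @param annotation data.frame mapping `probe_id` to `accession`.
#' @param calls Character matrix probes x conditions of
#'   `"up"`/`"none"`/`"down"` calls (e.g. from [call_matrix()]), row names
#'   = probe ids.
#' @return List with `tables` (reduced, same structure) and `report`
#'   (data.frame `accession`, `pattern`, `n_probes`, `kept`).
#' @export
collapse_redundant_probes <- function(tables, annotation, calls) {
  probe_ids <- tables[[1]]$probe_id
  for (tb in tables)
    if (!identical(sort(tb$probe_id), sort(probe_ids)))
      stop("all tables must share one probe universe")
  if (is.null(rownames(calls)) || !all(probe_ids %in% rownames(calls)))
    stop("calls must be a matrix with probe ids as row names")
  calls <- calls[probe_ids, , drop = FALSE]
  acc <- annotation$accession[match(probe_ids, annotation$probe_id)]
  pattern <- apply(calls, 1L, paste, collapse = "|")
  mean_int <- Reduce(`+`, lapply(tables, function(tb) {
    tb <- tb[match(probe_ids, tb$probe_id), ]
    (tb$intensity_ch1 + tb$intensity_ch2) / 2
  })) / length(tables)

  has_acc <- !is.na(acc) & acc != ""
  key <- ifelse(has_acc, paste(acc, pattern, sep = "\r"), probe_ids)
  keep <- logical(length(probe_ids))
  split_idx <- split(seq_along(probe_ids), key)
  report <- vector("list", length(split_idx))
  for (k in seq_along(split_idx)) {
    idx <- split_idx[[k]]
    best <- idx[which.max(mean_int[idx])]
    keep[best] <- TRUE
    if (length(idx) > 1L)
      report[[k]] <- data.frame(accession = acc[best],
                                pattern = pattern[best],
                                n_probes = length(idx),
                                kept = probe_ids[best],
                                stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, report[!vapply(report, is.null, logical(1))])
  if (is.null(report))
    report <- data.frame(accession = character(), pattern = character(),
                         n_probes = integer(), kept = character(),
                         stringsAsFactors = FALSE)
  kept_ids <- probe_ids[keep]
  list(tables = lapply(tables, function(tb) {
         out <- tb[tb$probe_id %in% kept_ids, , drop = FALSE]
         rownames(out) <- NULL
         out
       }),
       report = report)
}
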