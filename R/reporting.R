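# Comparative-Ct qPCR fold changes, heat-map-style matrix export,
# call-matrix serialization, and the end-to-end pipeline orchestrator.

#' Comparative-Ct (delta-delta-Ct) fold change for one gene
#'
#' `dCt(arm) = mean Ct(target) - mean Ct(reference)`; `ddCt = dCt(treated)
#' - dCt(control)`; fold change `= 2^(-ddCt)`. The standard error of the
#' fold change is propagated from the replicate SDs of the four well means
#' by the delta method: `SE(FC) = ln(2) * FC * SE(ddCt)`.
#'
#' @param ct_table data.frame with columns `gene_id`, `role`
#'   (`"target"`/`"reference"`), `arm` (`"treated"`/`"control"`),
#'   `replicate`, `ct` (see [simulate_qpcr()]).
#' @param gene Gene id to evaluate.
#' @return List: `gene_id`, `ddct`, `fold_change`, `se`, `n_replicates`.
#' @examples
#' ct <- expand.grid(role = c("target", "reference"),
#'                   arm = c("treated", "control"), replicate = 1:3)
#' ct$gene_id <- "g1"
#' ct$ct <- ifelse(ct$role == "reference", 12,
#'                 ifelse(ct$arm == "treated", 20, 22))
#' ddct_fold_change(ct, "g1")$fold_change  # ddCt = -2 -> 4
#' @export
ddct_fold_change <- function(ct_table, gene) {
  rows <- ct_table[ct_table$gene_id == gene, , drop = FALSE]
  if (!nrow(rows)) stop("gene '", gene, "' absent from the Ct table")
  cell <- function(role, arm) {
    x <- rows$ct[rows$role == role & rows$arm == arm]
    if (!length(x))
      stop("missing ", role, " measurements in the ", arm,
           " arm for gene '", gene, "'")
    list(mean = mean(x), se = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
         n = length(x))
  }
  tt <- cell("target", "treated"); rt <- cell("reference", "treated")
  tc <- cell("target", "control"); rc <- cell("reference", "control")
  ddct <- (tt$mean - rt$mean) - (tc$mean - rc$mean)
  fc <- 2^(-ddct)
  se_ddct <- sqrt(tt$se^2 + rt$se^2 + tc$se^2 + rc$se^2)
  list(gene_id = gene, ddct = ddct, fold_change = fc,
       se = log(2) * fc * se_ddct,
       n_replicates = min(tt$n, rt$n, tc$n, rc$n))
}

#' Export a heat-map-ordered ratio matrix
#'
#' Genes are ordered by temporal subgroup (the order of
#' [subgroup_labels()]), and within each subgroup by average-linkage
#' hierarchical clustering on the Euclidean distance between log2-ratio
#' profiles. Rows are sorted by gene id before clustering, so the output
#' ordering is invariant to the input row order.
#'
#' @param mat Numeric matrix (genes x conditions), row names = gene ids.
#' @param subgroups Named character vector mapping every row to a label of
#'   [subgroup_labels()].
#' @param path Optional TSV output path.
#' @return The reordered matrix (invisibly if `path` is given).
#' @export
export_heatmap_matrix <- function(mat, subgroups, path = NULL) {
  mat <- as.matrix(mat)
  if (!nrow(mat)) stop("matrix is empty")
  if (is.null(rownames(mat)) || !all(rownames(mat) %in% names(subgroups)))
    stop("every row must have a subgroup label")
  sg <- subgroups[rownames(mat)]
  ordered_ids <- character(0)
  for (lab in subgroup_labels()) {
    ids <- sort(rownames(mat)[sg == lab])
    if (!length(ids)) next
    if (length(ids) > 2L) {
      hc <- hclust(dist(mat[ids, , drop = FALSE]), method = "average")
      ids <- ids[hc$order]
    }
    ordered_ids <- c(ordered_ids, ids)
  }
  out <- mat[ordered_ids, , drop = FALSE]
  if (!is.null(path)) {
    df <- data.frame(gene_id = rownames(out), subgroup = sg[ordered_ids],
                     out, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write a call matrix as TSV with cells U/N/D
#' @param calls Character matrix of `"up"`/`"none"`/`"down"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_matrix <- function(calls, path) {
  m <- matrix(c(up = "U", none = "N", down = "D")[calls],
              nrow(calls), ncol(calls), dimnames = dimnames(calls))
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a call matrix written by [write_call_matrix()]
#' @param path Input path.
#' @return Character matrix of calls.
#' @export
read_call_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c("U", "N", "D")))
    stop("call matrix cells must be U, N or D")
  out <- matrix(c(U = "up", N = "none", D = "down")[m],
                nrow(m), ncol(m),
                dimnames = list(df[[1]], colnames(m)))
  out
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Stages: simulate -> MA-normalize -> combine dye swaps -> collapse
#' redundant probes -> combined filter (per-concentration 2 SD ratio
#' threshold, p < alpha) -> TFS classification and census -> PCA ->
#' promoter simulation, motif discovery and enrichment -> qPCR validation
#' of example responders. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, stage outputs (tables,
#'   calls, census, FDR report, PCA loadings/scores, PWM, manifest) are
#'   written there.
#' @param alpha P-value cutoff (default 0.005).
#' @param sd_multiplier Ratio-filter SD multiplier (default 2).
#' @param motif_width Width for de novo discovery (default the planted
#'   consensus width).
#' @param scan_threshold_bits Log2-odds threshold for promoter scanning
#'   (default 12).
#' @return List with `manifest` and the per-stage results (`truth`,
#'   `combined`, `thresholds`, `calls`, `census`, `fdr`, `pca`, `motif`,
#'   `enrichment`, `qpcr`).
#' @export
run_pipeline <- function(config, out_dir = NULL, alpha = 0.005,
                         sd_multiplier = 2,
                         motif_width = nchar(config$motif_consensus),
                         scan_threshold_bits = 12) {
  stopifnot(inherits(config, "tfscope_sim_config"))
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  sim <- simulate_experiment(config); note("simulate")
  normalized <- lapply(sim$tables, function(pair)
    list(forward = ma_normalize(pair$forward),
         reverse = ma_normalize(pair$reverse)))
  note("normalize")
  combined <- lapply(normalized, function(pair)
    combine_dye_swap(pair$forward, pair$reverse))
  note("combine")

  cond <- config$conditions
  concs <- unique(cond$concentration)
  cn <- condition_names(cond)
  by_conc <- split(cn, cond$concentration)[concs]
  thresholds <- lapply(by_conc, function(nm)
    filter_thresholds(alpha,
                      ratio_sd_threshold(combined[nm], sd_multiplier),
                      sd_multiplier))
  calls_all <- do.call(cbind, lapply(concs, function(cc)
    call_matrix(combined[by_conc[[cc]]], thresholds[[cc]])))
  collapsed <- collapse_redundant_probes(combined, sim$truth$annotation,
                                         calls_all)
  combined <- collapsed$tables
  note("collapse")

  calls <- lapply(concs, function(cc)
    call_matrix(combined[by_conc[[cc]]], thresholds[[cc]]))
  names(calls) <- concs
  fdr <- filter_report(combined[by_conc[[1]]], thresholds[[1]])
  note("filter")

  census <- subgroup_census(calls[[1]])
  probe_gene <- sim$truth$probes$gene_id[
    match(rownames(calls[[1]]), sim$truth$probes$probe_id)]
  subgroups <- setNames(apply(calls[[1]], 1L, classify_subgroup),
                        rownames(calls[[1]]))
  note("classify")

  selected <- do.call(select_pca_genes, unname(calls))
  pca <- NULL
  if (length(selected) >= 2) {
    ratios <- vapply(combined, function(tb)
      tb$log2_ratio[match(selected, tb$probe_id)], numeric(length(selected)))
    rownames(ratios) <- selected
    pca <- svd_decompose(standardize_genes(ratios))
  }
  note("pca")

  promoters <- simulate_promoters(sim$truth, config)
  responsive_genes <- unique(probe_gene[subgroups[rownames(calls[[1]])] !=
                                          "null"])
  target_seqs <- promoters$sequences[
    names(promoters$sequences) %in% responsive_genes]
  motif <- NULL; enrichment <- NULL
  if (length(target_seqs) >= 5) {
    discovery_set <- target_seqs[seq_len(min(20L, length(target_seqs)))]
    motif <- gibbs_motif_discovery(discovery_set, motif_width,
                                   seed = config$seed + 3000017L)
    backgrounds <- build_background_sets(combined[by_conc[[1]]],
                                         sim$truth$annotation)
    bg_genes <- backgrounds$nonexpressed
    if (!length(bg_genes)) bg_genes <- backgrounds$expressed_nonresponsive
    scan <- scan_promoters(motif$pwm, promoters$sequences,
                           scan_threshold_bits)
    tgt <- scan$hits[names(scan$hits) %in% responsive_genes]
    bg <- scan$hits[names(scan$hits) %in% bg_genes]
    if (length(tgt) && length(bg))
      enrichment <- motif_enrichment_test(tgt, bg)
  }
  note("motif")

  resp_ids <- sim$truth$genes$gene_id[sim$truth$genes$archetype != "null"]
  qpcr <- NULL
  if (length(resp_ids)) {
    assay <- head(resp_ids, 3L)
    ct <- simulate_qpcr(sim$truth, assay)
    qpcr <- lapply(assay, function(g) ddct_fold_change(ct, g))
  }
  note("report")

  manifest <- list(
    package_version = as.character(utils::packageVersion("tfscope")),
    seed = config$seed,
    alpha = alpha,
    sd_multiplier = sd_multiplier,
    ratio_thresholds = lapply(thresholds, `[[`, "ratio_threshold"),
    stages = stages,
    n_probes_input = nrow(sim$tables[[1]]$forward),
    n_probes_collapsed = nrow(combined[[1]]),
    n_responsive = attr(census, "n_responsive"))

  result <- list(manifest = manifest, truth = sim$truth,
                 combined = combined, thresholds = thresholds,
                 calls = calls, subgroups = subgroups, census = census,
                 fdr = fdr, pca = pca, motif = motif,
                 enrichment = enrichment, qpcr = qpcr)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$combined))
    write_comparison_table(result$combined[[nm]],
                           file.path(out_dir, paste0(nm, "_combined.tsv")))
  for (cc in names(result$calls))
    write_call_matrix(result$calls[[cc]],
                      file.path(out_dir, paste0("calls_", cc, ".tsv")))
  jsonlite::write_json(result$census, file.path(out_dir, "census.json"),
                       dataframe = "rows")
  jsonlite::write_json(unclass(result$fdr), file.path(out_dir, "fdr.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$pca)) {
    write.table(result$pca$V, file.path(out_dir, "loadings.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(result$pca$X, file.path(out_dir, "scores.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    jsonlite::write_json(result$pca$variance_fraction,
                         file.path(out_dir, "variance.json"), digits = NA)
  }
  if (!is.null(result$motif))
    write_pwm(result$motif$pwm, file.path(out_dir, "motif_pwm.tsv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
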