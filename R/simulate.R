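# Synthetic two-color time-course experiments with planted ground truth.
#
# The generator plants temporal response archetypes (the early/mid/late
# taxonomy rows), probe redundancy, a symmetric dye bias removable by
# dye-swap averaging, and promoters carrying a planted motif. The observed
# log2 ratio of a probe is Gaussian around its planted effect with variance
# equal to a multiplicative (log-scale) component plus the delta-method
# contribution of additive channel noise at the probe's intensities; the
# same variance is reported per probe as `ratio_variance`, so the
# substitute error-model p-values are exactly calibrated under the null.
# Channel intensities carry the additive noise for display and for the
# expression-defined background sets; they are not re-used to recompute
# the ratio.

#' Configuration for a synthetic two-color time-course experiment
#'
#' @param n_genes Number of genes (each gets one primary probe).
#' @param n_redundant_probes Extra probes duplicating randomly chosen
#'   genes' signals with independent noise (exercises the redundant-probe
#'   collapse).
#' @param conditions data.frame with columns `concentration` and `time`,
#'   one row per array comparison, the first concentration block being the
#'   high-dose design. Default: (5 mM, 1 mM) x (3 h, 8 h, 24 h).
#' @param archetype_fractions Named numeric over the archetypes of
#'   [tfs_archetypes()] (including `"null"`); must sum to 1.
#' @param effect_size Mean |log2 ratio| planted at responding time points
#'   (log2 units). `0` yields an effect-free (null) experiment.
#' @param noise_sd_additive SD of additive channel noise (intensity units).
#' @param noise_sd_multiplicative SD of multiplicative ratio noise (log2
#'   units).
#' @param dye_bias Systematic log2 offset attached to the dye orientation;
#'   enters with opposite sign in forward and dye-swap arrays.
#' @param baseline_log_intensity_mean,baseline_log_intensity_sd Log2-normal
#'   baseline probe intensity parameters.
#' @param concentration_scaling Named multiplier of `effect_size` per
#'   concentration label; defaults to full effect at the high dose and an
#'   attenuated (0.5x) response at the low dose.
#' @param motif_consensus IUPAC consensus of the planted promoter motif.
#' @param motif_planting_rate_target,motif_planting_rate_background
#'   Probability that a responsive / non-responsive gene's promoter carries
#'   one planted motif instance.
#' @param promoter_length Promoter length in bases (>= motif width).
#' @param seed Integer seed; all simulation operations derive their RNG
#'   streams from it.
#' @return A validated `tfscope_sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_redundant_probes = 100L,
                       conditions = default_conditions(),
                       archetype_fractions = default_archetype_fractions(),
                       effect_size = 2,
                       noise_sd_additive = 30,
                       noise_sd_multiplicative = 0.25,
                       dye_bias = 0.3,
                       baseline_log_intensity_mean = 10,
                       baseline_log_intensity_sd = 1.5,
                       concentration_scaling = NULL,
                       motif_consensus = "TGACGTCA",
                       motif_planting_rate_target = 0.8,
                       motif_planting_rate_background = 0.1,
                       promoter_length = 1000L,
                       seed = 1L) {
  arcs <- tfs_archetypes()$archetype
  if (is.null(names(archetype_fractions)) ||
      !all(names(archetype_fractions) %in% arcs))
    stop("archetype_fractions must be named after tfs_archetypes()")
  fr <- setNames(numeric(length(arcs)), arcs)
  fr[names(archetype_fractions)] <- archetype_fractions
  if (abs(sum(fr) - 1) > 1e-9)
    stop("archetype fractions must sum to 1 (got ", sum(fr), ")")
  if (any(fr < 0)) stop("archetype fractions must be nonnegative")
  if (effect_size < 0) stop("effect_size must be nonnegative")
  if (noise_sd_additive < 0 || noise_sd_multiplicative < 0)
    stop("noise SDs must be nonnegative")
  for (r in c(motif_planting_rate_target, motif_planting_rate_background))
    if (r < 0 || r > 1) stop("motif planting rates must lie in [0, 1]")
  if (!all(c("concentration", "time") %in% names(conditions)))
    stop("conditions needs columns 'concentration' and 'time'")
  concs <- unique(conditions$concentration)
  if (is.null(concentration_scaling)) {
    concentration_scaling <- setNames(rep(1, length(concs)), concs)
    if (length(concs) > 1)
      concentration_scaling[-1] <- 0.5
  }
  if (!all(concs %in% names(concentration_scaling)))
    stop("concentration_scaling must cover every concentration label")
  w <- nchar(motif_consensus)
  if (!grepl("^[ACGTRYSWKMN]+$", motif_consensus))
    stop("motif_consensus must be IUPAC over {A,C,G,T,R,Y,S,W,K,M,N}")
  if (promoter_length < w)
    stop("promoter_length must be at least the motif width")
  structure(list(
    n_genes = as.integer(n_genes),
    n_redundant_probes = as.integer(n_redundant_probes),
    conditions = conditions,
    archetype_fractions = fr,
    effect_size = effect_size,
    noise_sd_additive = noise_sd_additive,
    noise_sd_multiplicative = noise_sd_multiplicative,
    dye_bias = dye_bias,
    baseline_log_intensity_mean = baseline_log_intensity_mean,
    baseline_log_intensity_sd = baseline_log_intensity_sd,
    concentration_scaling = concentration_scaling,
    motif_consensus = toupper(motif_consensus),
    motif_planting_rate_target = motif_planting_rate_target,
    motif_planting_rate_background = motif_planting_rate_background,
    promoter_length = as.integer(promoter_length),
    seed = as.integer(seed)
  ), class = "tfscope_sim_config")
}

#' Default array layout: two concentrations times three exposure times
#' @return data.frame with columns `concentration`, `time` (high dose
#'   first).
#' @export
default_conditions <- function() {
  data.frame(concentration = rep(c("5mM", "1mM"), each = 3L),
             time = rep(c("3h", "8h", "24h"), 2L),
             stringsAsFactors = FALSE)
}

#' Default archetype mixture: 86% null genes, 1% of each response archetype
#' @return Named numeric vector summing to 1.
#' @export
default_archetype_fractions <- function() {
  arcs <- tfs_archetypes()$archetype
  fr <- setNames(rep(0.01, length(arcs)), arcs)
  fr["null"] <- 1 - sum(fr) + fr["null"]
  fr
}

condition_names <- function(conditions)
  paste0(conditions$concentration, "_", conditions$time)

# deterministic largest-remainder allocation of n items to fractions
.allocate_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  as.integer(counts)
}

# variance of the observed log2 ratio: multiplicative component plus the
# delta-method contribution of additive channel noise
.ratio_variance <- function(i_treated, i_control, sd_add, sd_mult) {
  sd_mult^2 + (sd_add^2 / log(2)^2) * (1 / i_treated^2 + 1 / i_control^2)
}

#' Simulate a complete dye-swapped two-color experiment
#'
#' For each condition two comparison tables are produced: a forward array
#' (treated vs control, dye bias `+dye_bias`) and a dye-swap array
#' (control vs treated, the same dye artifact, so the bias cancels when
#' the sign-flipped ratios are averaged). P-values come from the normal
#' error model `z = log2_ratio / sqrt(ratio_variance)`.
#'
#' @param config A [sim_config()].
#' @return List with elements
#'   * `tables`: named list per condition, each `list(forward, reverse)` of
#'     comparison tables (`probe_id`, `log2_ratio`, `p_value`,
#'     `intensity_ch1`, `intensity_ch2`, `ratio_variance`);
#'   * `truth`: ground truth — `genes` (gene_id, archetype, subgroup),
#'     `probes` (probe_id, gene_id), `effects` (gene x condition matrix of
#'     planted log2 ratios), `annotation` (probe_id, accession, symbol),
#'     `conditions`, and the `config` (seed included).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "tfscope_sim_config"))
  withr::with_seed(config$seed, .simulate_experiment_impl(config))
}

.simulate_experiment_impl <- function(config) {
  arcs <- tfs_archetypes()
  counts <- .allocate_counts(config$archetype_fractions[arcs$archetype],
                             config$n_genes)
  gene_arch <- rep(arcs$archetype, counts)
  # shuffle so archetypes are not blocked by gene index
  gene_arch <- sample(gene_arch)
  gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
  genes <- data.frame(gene_id = gene_ids, archetype = gene_arch,
                      subgroup = arcs$subgroup[match(gene_arch, arcs$archetype)],
                      stringsAsFactors = FALSE)

  cond_names <- condition_names(config$conditions)
  n_cond <- length(cond_names)
  calls3 <- as.matrix(arcs[match(gene_arch, arcs$archetype),
                           c("call_3h", "call_8h", "call_24h")])
  sign3 <- (calls3 == "up") - (calls3 == "down")
  effects <- matrix(0, config$n_genes, n_cond,
                    dimnames = list(gene_ids, cond_names))
  times <- config$conditions$time
  time_idx <- match(times, c("3h", "8h", "24h"))
  for (j in seq_len(n_cond)) {
    scale_j <- config$concentration_scaling[[config$conditions$concentration[j]]]
    effects[, j] <- sign3[, time_idx[j]] * config$effect_size * scale_j
  }

  # probes: one per gene plus redundant duplicates of random genes
  n_probes <- config$n_genes + config$n_redundant_probes
  probe_gene <- c(seq_len(config$n_genes),
                  sample(config$n_genes, config$n_redundant_probes,
                         replace = config$n_redundant_probes > config$n_genes))
  probe_ids <- sprintf("probe%06d", seq_len(n_probes))
  probes <- data.frame(probe_id = probe_ids,
                       gene_id = gene_ids[probe_gene],
                       stringsAsFactors = FALSE)
  baseline <- 2^rnorm(n_probes, config$baseline_log_intensity_mean,
                      config$baseline_log_intensity_sd)

  tables <- vector("list", n_cond)
  names(tables) <- cond_names
  for (j in seq_len(n_cond)) {
    mu <- effects[probe_gene, j]
    i_control <- baseline
    i_treated <- baseline * 2^mu
    v <- .ratio_variance(i_treated, i_control,
                         config$noise_sd_additive,
                         config$noise_sd_multiplicative)
    mk <- function(true_ratio, ch1_base, ch2_base) {
      r <- true_ratio + rnorm(n_probes, 0, sqrt(v))
      data.frame(
        probe_id = probe_ids,
        log2_ratio = r,
        p_value = 2 * pnorm(-abs(r) / sqrt(v)),
        intensity_ch1 = pmax(ch1_base + rnorm(n_probes, 0, config$noise_sd_additive), 1),
        intensity_ch2 = pmax(ch2_base + rnorm(n_probes, 0, config$noise_sd_additive), 1),
        ratio_variance = v,
        stringsAsFactors = FALSE)
    }
    tables[[j]] <- list(
      forward = mk(mu + config$dye_bias, i_treated, i_control),
      reverse = mk(-mu + config$dye_bias, i_control, i_treated))
  }

  annotation <- data.frame(probe_id = probe_ids,
                           accession = probes$gene_id,
                           symbol = probes$gene_id,
                           stringsAsFactors = FALSE)
  list(tables = tables,
       truth = list(genes = genes, probes = probes, effects = effects,
                    annotation = annotation,
                    conditions = config$conditions, config = config))
}

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               N = c("A", "C", "G", "T"))

#' Simulate promoter sequences with a planted motif
#'
#' One promoter per gene, i.i.d. uniform background. Responsive genes
#' (archetype other than `"null"`) receive one realized instance of the
#' IUPAC consensus at a uniform position with probability
#' `motif_planting_rate_target`; null genes with probability
#' `motif_planting_rate_background`.
#'
#' @param truth Ground truth from [simulate_experiment()].
#' @param config The same [sim_config()] (motif fields are used).
#' @return List with `sequences` (a [Biostrings::DNAStringSet] named by
#'   gene id) and `motif_truth` (data.frame `gene_id`, `responsive`,
#'   `planted`, `start` — 0-based forward-strand start, `NA` when absent).
#' @export
simulate_promoters <- function(truth, config = truth$config) {
  stopifnot(inherits(config, "tfscope_sim_config"))
  withr::with_seed(config$seed + 1000003L, {
    genes <- truth$genes
    n <- nrow(genes)
    L <- config$promoter_length
    w <- nchar(config$motif_consensus)
    cons <- strsplit(config$motif_consensus, "")[[1]]
    responsive <- genes$archetype != "null"
    rate <- ifelse(responsive, config$motif_planting_rate_target,
                   config$motif_planting_rate_background)
    planted <- runif(n) < rate
    starts0 <- ifelse(planted,
                      sample.int(L - w + 1L, n, replace = TRUE) - 1L, NA_integer_)
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (planted[i]) {
        inst <- vapply(cons, function(b) {
          opts <- .IUPAC[[b]]
          if (length(opts) == 1L) opts else sample(opts, 1L)
        }, character(1))
        s[(starts0[i] + 1L):(starts0[i] + w)] <- inst
      }
      paste(s, collapse = "")
    }, character(1))
    sequences <- Biostrings::DNAStringSet(setNames(seqs, genes$gene_id))
    list(sequences = sequences,
         motif_truth = data.frame(gene_id = genes$gene_id,
                                  responsive = responsive,
                                  planted = planted,
                                  start = starts0,
                                  stringsAsFactors = FALSE))
  })
}

#' Simulate a comparative-Ct qPCR validation table
#'
#' Each requested gene is measured against an 18S-like internal reference
#' in treated and control arms. The treated-arm target Ct is shifted by
#' minus the planted log2 fold change at the chosen condition; the
#' reference is unshifted. Gaussian technical noise is added to every
#' well.
#'
#' @param truth Ground truth from [simulate_experiment()].
#' @param genes Character vector of gene ids to assay.
#' @param condition Condition name (column of `truth$effects`); default the
#'   first condition.
#' @param n_replicates Technical replicates per well (default 3).
#' @param noise_sd Ct noise SD in cycles (default 0.1).
#' @param config The [sim_config()] (seed source).
#' @return data.frame with columns `gene_id`, `role`
#'   (`"target"`/`"reference"`), `arm` (`"treated"`/`"control"`),
#'   `replicate`, `ct`.
#' @export
simulate_qpcr <- function(truth, genes,
                          condition = colnames(truth$effects)[1],
                          n_replicates = 3L, noise_sd = 0.1,
                          config = truth$config) {
  stopifnot(inherits(config, "tfscope_sim_config"))
  missing <- setdiff(genes, rownames(truth$effects))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  if (!condition %in% colnames(truth$effects))
    stop("unknown condition: ", condition)
  withr::with_seed(config$seed + 2000003L, {
    rows <- expand.grid(gene_id = genes,
                        role = c("target", "reference"),
                        arm = c("treated", "control"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    base_target <- setNames(runif(length(genes), 20, 28), genes)
    lfc <- truth$effects[rows$gene_id, condition]
    ct0 <- ifelse(rows$role == "reference", 12,
                  base_target[rows$gene_id] -
                    ifelse(rows$arm == "treated", lfc, 0))
    rows$ct <- ct0 + rnorm(nrow(rows), 0, noise_sd)
    rows[order(rows$gene_id, rows$role, rows$arm, rows$replicate), ]
  })
}
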