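# The synthetic-data generator: determinism, calibration and planted truth.

small_config <- function(seed = 11L, ...) {
  sim_config(n_genes = 200L, n_redundant_probes = 20L, seed = seed, ...)
}

test_that("identical seeds give byte-identical datasets", {
  a <- simulate_experiment(small_config())
  b <- simulate_experiment(small_config())
  expect_identical(a, b)
  c <- simulate_experiment(small_config(seed = 12L))
  expect_false(identical(a$tables[[1]]$forward$log2_ratio,
                         c$tables[[1]]$forward$log2_ratio))
  pa <- simulate_promoters(a$truth)
  pb <- simulate_promoters(b$truth)
  expect_identical(as.character(pa$sequences), as.character(pb$sequences))
})

test_that("config validation rejects bad fractions, rates and noise", {
  expect_error(sim_config(archetype_fractions = c(late_up = 0.5)),
               "sum to 1")
  expect_error(sim_config(archetype_fractions = c(bogus = 1)), "named after")
  expect_error(sim_config(noise_sd_additive = -1), "nonnegative")
  expect_error(sim_config(motif_planting_rate_target = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(promoter_length = 4, motif_consensus = "TGACGTCA"),
               "motif width")
  expect_error(sim_config(motif_consensus = "TGAXGTCA"), "IUPAC")
})

test_that("null simulation is calibrated at the nominal level", {
  cfg <- sim_config(n_genes = 8000L, n_redundant_probes = 0L,
                    effect_size = 0, seed = 3L)
  sim <- simulate_experiment(cfg)
  comb <- combine_dye_swap(sim$tables[["5mM_3h"]]$forward,
                           sim$tables[["5mM_3h"]]$reverse)
  alpha <- 0.005
  frac <- mean(comb$p_value < alpha)
  tol <- 3 * sqrt(alpha * (1 - alpha) / nrow(comb))
  expect_lt(abs(frac - alpha), tol)
})

test_that("planted archetypes force their ternary calls at low noise", {
  cfg <- sim_config(
    n_genes = 300L, n_redundant_probes = 0L, effect_size = 2,
    noise_sd_multiplicative = 0.05, noise_sd_additive = 5, seed = 5L,
    archetype_fractions = c(early_persistent_up = 0.1, late_down = 0.1,
                            null = 0.8))
  sim <- simulate_experiment(cfg)
  comb <- lapply(c("5mM_3h", "5mM_8h", "5mM_24h"), function(nm)
    combine_dye_swap(sim$tables[[nm]]$forward, sim$tables[[nm]]$reverse))
  th <- filter_thresholds(0.005, ratio_sd_threshold(comb))
  calls <- call_matrix(comb, th)
  epu <- sim$truth$probes$probe_id[
    sim$truth$genes$archetype[match(sim$truth$probes$gene_id,
                                    sim$truth$genes$gene_id)] ==
      "early_persistent_up"]
  for (p in epu)
    expect_identical(unname(calls[p, ]), c("up", "up", "up"))
  ld <- sim$truth$probes$probe_id[
    sim$truth$genes$archetype[match(sim$truth$probes$gene_id,
                                    sim$truth$genes$gene_id)] == "late_down"]
  for (p in ld)
    expect_identical(unname(calls[p, ]), c("none", "none", "down"))
})

test_that("dye bias enters arrays with opposite signs and cancels on combination", {
  cfg <- sim_config(n_genes = 4000L, n_redundant_probes = 0L,
                    effect_size = 0, dye_bias = 0.5, seed = 9L)
  sim <- simulate_experiment(cfg)
  fw <- sim$tables[[1]]$forward
  rv <- sim$tables[[1]]$reverse
  expect_gt(mean(fw$log2_ratio), 0.4)   # forward carries +bias
  expect_gt(mean(rv$log2_ratio), 0.4)   # reverse is control-vs-treated, +bias
  comb <- combine_dye_swap(fw, rv)
  expect_lt(abs(mean(comb$log2_ratio)), 0.02)
})

test_that("promoter planting rates are honored exactly at 0 and 1", {
  cfg <- sim_config(n_genes = 40L, n_redundant_probes = 0L, seed = 21L,
                    archetype_fractions = c(late_up = 0.5, null = 0.5),
                    motif_planting_rate_target = 1,
                    motif_planting_rate_background = 0,
                    promoter_length = 300L)
  sim <- simulate_experiment(cfg)
  pr <- simulate_promoters(sim$truth)
  expect_true(all(Biostrings::width(pr$sequences) == 300L))
  responsive <- pr$motif_truth$responsive
  expect_identical(pr$motif_truth$planted, responsive)
  has_cons <- vapply(as.character(pr$sequences), grepl,
                     pattern = cfg$motif_consensus, logical(1),
                     USE.NAMES = FALSE)
  expect_true(all(has_cons[responsive]))
  # planted start positions point at a real instance
  planted <- which(pr$motif_truth$planted)
  w <- nchar(cfg$motif_consensus)
  for (i in planted) {
    s0 <- pr$motif_truth$start[i]
    inst <- substr(as.character(pr$sequences[[i]]), s0 + 1, s0 + w)
    expect_identical(inst, cfg$motif_consensus)
  }
})

test_that("qPCR tables encode the planted fold change in their Ct shifts", {
  cfg <- small_config(effect_size = 2)
  sim <- simulate_experiment(cfg)
  resp <- sim$truth$genes$gene_id[
    sim$truth$genes$archetype == "early_persistent_up"][1]
  null_gene <- sim$truth$genes$gene_id[sim$truth$genes$archetype == "null"][1]
  ct <- simulate_qpcr(sim$truth, c(resp, null_gene), condition = "5mM_3h",
                      noise_sd = 0)
  fc <- ddct_fold_change(ct, resp)
  expect_equal(fc$fold_change, 4, tolerance = 1e-12)
  expect_equal(ddct_fold_change(ct, null_gene)$fold_change, 1,
               tolerance = 1e-12)
  noisy <- simulate_qpcr(sim$truth, resp, noise_sd = 0.1)
  expect_gt(ddct_fold_change(noisy, resp)$se, 0)
  expect_error(simulate_qpcr(sim$truth, "nope"), "unknown gene")
})
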