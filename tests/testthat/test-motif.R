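# Motif discovery, scanning, Fisher enrichment and over-representation.

test_that("Fisher enrichment p equals brute-force enumeration (margins <= 12)", {
  for (n1 in c(1, 3, 5, 8, 12)) for (n2 in c(1, 4, 7, 12)) {
    for (a in 0:n1) for (cc in 0:n2) {
      got <- motif_enrichment_test(
        c(rep(TRUE, a), rep(FALSE, n1 - a)),
        c(rep(TRUE, cc), rep(FALSE, n2 - cc)))
      expect_equal(got$fisher_p, fisher_oracle(a, n1 - a, cc, n2 - cc),
                   tolerance = 1e-10)
    }
  }
})

test_that("enrichment score and boundary p-values follow their definitions", {
  # all targets hit, no background hit: p = 1 / choose(20, 10)
  r <- motif_enrichment_test(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(r$fisher_p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_identical(r$enrichment_score, Inf)
  # a = 0 with identical proportions: nothing to exceed
  r2 <- motif_enrichment_test(rep(FALSE, 10), rep(FALSE, 10))
  expect_equal(r2$fisher_p, 1)
  # score arithmetic: (6/10) / (3/10) = 2
  r3 <- motif_enrichment_test(c(rep(TRUE, 6), rep(FALSE, 4)),
                              c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(r3$enrichment_score, 2)
  expect_error(motif_enrichment_test(logical(0), TRUE), "nonempty")
})

test_that("PWM scanning hits consensus matches on both strands", {
  # non-palindromic consensus so strand attribution is unambiguous
  pwm <- pwm_from_consensus("GGATGCAA")
  max_score <- sum(log2(apply(pwm$prob, 1, max) / 0.25))
  flank <- paste(rep("A", 20), collapse = "")
  fwd <- paste0(flank, "GGATGCAA", flank)
  rc <- paste0(flank, "GGATGCAA", flank)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rc)))
  none <- paste(rep(c("A", "C"), 24), collapse = "")
  seqs <- c(f = fwd, r = rc, n = none)
  scan <- scan_promoters(pwm, seqs, threshold_bits = max_score - 1e-6)
  expect_identical(unname(scan$hits), c(TRUE, TRUE, FALSE))
  # position is the 0-based forward-strand window start
  expect_identical(scan$positions$start[scan$positions$gene_id == "f"], 20L)
  expect_identical(scan$positions$strand[scan$positions$gene_id == "r"], "-")
  # a threshold above the maximum score hits nothing
  scan2 <- scan_promoters(pwm, seqs, threshold_bits = max_score + 1)
  expect_false(any(scan2$hits))
})

test_that("PWM round-trips through its text format", {
  pwm <- pwm_from_consensus("TGASNTCA")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(pwm, path)
  expect_identical(readLines(path, 1), "#width=8")
  back <- read_pwm(path)
  expect_equal(back$prob, pwm$prob, tolerance = 1e-6)
  expect_identical(back$consensus, pwm$consensus)
})

test_that("Gibbs discovery is seed-deterministic and prefers planted signal", {
  set.seed(99)
  planted <- random_promoters(12, 120, consensus = "TGACGTCA", rate = 1)
  m1 <- gibbs_motif_discovery(planted, 8, n_restarts = 3, seed = 5)
  m2 <- gibbs_motif_discovery(planted, 8, n_restarts = 3, seed = 5)
  expect_identical(m1$pwm$prob, m2$pwm$prob)
  expect_identical(m1$sites, m2$sites)
  # best-so-far information content never decreases
  expect_false(is.unsorted(m1$trajectory))
  # planted motif carries more information than pure random sequence
  rand <- random_promoters(12, 120)
  m0 <- gibbs_motif_discovery(rand, 8, n_restarts = 3, seed = 5)
  expect_gt(m1$pwm$information_content, m0$pwm$information_content)
  expect_error(gibbs_motif_discovery(planted[1:3], 8), "at least 5")
  expect_error(gibbs_motif_discovery(random_promoters(6, 6), 8), "width")
})

test_that("background sets follow the intensity and fold-change thresholds", {
  ids <- c("quiet_bright", "quiet_dim", "responsive", "quiet_mid")
  lr <- list(c(0.07, 0.0, 1.5, 0.1),   # |log2 ratio| per time point
             c(0.13, 0.05, 1.2, 0.0),
             c(0.0, 0.1, 0.8, 0.05))
  ints <- c(250, 40, 300, 120)
  tabs <- lapply(lr, function(r)
    make_table(r, int1 = ints, int2 = ints, ids = ids))
  bg <- build_background_sets(tabs)
  expect_identical(bg$expressed_nonresponsive, "quiet_bright")
  expect_identical(bg$nonexpressed, "quiet_dim")
  # responsive and intermediate-intensity genes are in neither set
  expect_false(any(c("responsive", "quiet_mid") %in% unlist(bg)))
  expect_length(intersect(bg$expressed_nonresponsive, bg$nonexpressed), 0)
})

test_that("over-representation test matches the hypergeometric closed form", {
  universe <- sprintf("g%03d", 1:100)
  terms <- list(tenpct = universe[1:10], other = universe[11:40])
  # list = the whole term: fold enrichment 10
  res <- ora_test(universe[1:10], terms["tenpct"], universe)
  expect_equal(res$fold_enrichment, 10)
  expect_equal(res$p, phyper(9, 10, 90, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  # empty intersection: p = 1, fold 0
  res2 <- ora_test(universe[41:60], terms, universe)
  expect_equal(res2$p, c(1, 1))
  expect_equal(res2$fold_enrichment, c(0, 0))
  expect_warning(
    ora_test(universe[1:5], list(ghost = "absent"), universe),
    "no overlap")
  expect_error(ora_test("absent", terms, universe), "subset")
  res3 <- ora_test(universe[1:10], terms, universe, adjust = TRUE)
  expect_true("p_bh" %in% names(res3))
})

test_that("planted-motif Fisher p-values are valid under equal planting rates", {
  # equal rates in target and background: the rejection rate at any level
  # must not exceed the level (Fisher p is conservative under discreteness)
  set.seed(123)
  n_rep <- 200
  pwm <- pwm_from_consensus("TGACGTCA")
  thr <- sum(log2(apply(pwm$prob, 1, max) / 0.25)) - 1e-6
  pvals <- replicate(n_rep, {
    tgt <- random_promoters(15, 250, consensus = "TGACGTCA", rate = 0.3)
    bg <- random_promoters(15, 250, consensus = "TGACGTCA", rate = 0.3,
                           prefix = "b")
    ht <- scan_promoters(pwm, tgt, thr)$hits
    hb <- scan_promoters(pwm, bg, thr)$hits
    motif_enrichment_test(ht, hb)$fisher_p
  })
  for (level in c(0.05, 0.1, 0.25)) {
    slack <- 3 * sqrt(level * (1 - level) / n_rep)
    expect_lte(mean(pvals < level), level + slack)
  }
})

test_that("nearest PWM library match finds the generating consensus", {
  lib <- list(cre = pwm_from_consensus("TGACGTCA"),
              sp1 = pwm_from_consensus("GGGGCGGGG"),
              gata = pwm_from_consensus("WGATAR"))
  query <- pwm_from_consensus("TGACGTCA", mismatch_prob = 0.12)
  res <- match_pwm_library(query, lib)
  expect_identical(res$name[1], "cre")
})
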