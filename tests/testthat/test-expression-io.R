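# Table I/O, MA normalization, dye-swap combination, probe collapse.

test_that("comparison-table reader validates and counts flagged rows", {
  tb <- make_table(c(0.5, -0.2, 1.1, 0, 0.3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_comparison_table(tb, path)
  back <- read_comparison_table(path)
  expect_identical(nrow(back), 5L)
  expect_identical(attr(back, "n_excluded"), 0L)
  expect_equal(back$log2_ratio, tb$log2_ratio, tolerance = 1e-6)

  bad <- tb; bad$p_value[2] <- 1.5
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_comparison_table(path2), "row 2")

  flagged <- tb; flagged$flag <- c(0, 1, 0, 0, 0)
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(flagged, path3, sep = "\t", quote = FALSE, row.names = FALSE)
  back3 <- read_comparison_table(path3)
  expect_identical(nrow(back3), 4L)
  expect_identical(attr(back3, "n_excluded"), 1L)
  expect_false("p002" %in% back3$probe_id)

  dup <- tb; dup$probe_id[2] <- "p001"
  expect_error(validate_comparison_table(dup), "duplicate probe_id")
  expect_error(validate_comparison_table(tb[, -2]), "missing column")
})

test_that("MA normalization recentres ratios and removes intensity trends", {
  set.seed(42)
  n <- 600
  a <- runif(n, 6, 14)
  int <- 2^a
  # trendless, centred data passes through nearly unchanged
  flat <- make_table(rnorm(n, 0, 0.05), int1 = int, int2 = int,
                     ids = sprintf("p%04d", 1:n))
  out <- ma_normalize(flat)
  expect_lt(abs(median(out$log2_ratio)), 0.02)
  expect_gt(cor(out$log2_ratio, flat$log2_ratio), 0.99)

  # constant offset is removed
  shifted <- flat; shifted$log2_ratio <- flat$log2_ratio + 0.5
  out2 <- ma_normalize(shifted)
  expect_lt(abs(median(out2$log2_ratio)), 0.02)

  # quadratic intensity trend: residual trend vanishes, checked against an
  # independent windowed running-mean smoother
  trend <- 0.05 * (a - 10)^2
  curved <- make_table(trend + rnorm(n, 0, 0.05), int1 = int, int2 = int,
                       ids = sprintf("p%04d", 1:n))
  out3 <- ma_normalize(curved, span = 0.3)
  resid_fit <- running_mean_fit(a, out3$log2_ratio, halfwidth = 1)
  expect_lt(max(abs(resid_fit)), 0.05)
  slope <- coef(lm(out3$log2_ratio ~ a))[2]
  expect_lt(abs(slope), 0.01)

  expect_error(ma_normalize(flat, span = 0), "span")
})

test_that("MA normalization preserves rank order at fixed intensity", {
  set.seed(7)
  n <- 200
  int <- rep(2^10, n)
  tb <- make_table(rnorm(n), int1 = int, int2 = int,
                   ids = sprintf("p%04d", 1:n))
  out <- ma_normalize(tb)
  expect_identical(order(out$log2_ratio), order(tb$log2_ratio))
})

test_that("dye-swap combination is the inverse-variance weighted mean", {
  # identical information: forward +1, reverse (after flip) +1
  f <- make_table(1, variance = c(1))
  r <- make_table(-1, variance = c(1))
  expect_equal(combine_dye_swap(f, r)$log2_ratio, 1)

  # equal variances average arithmetically: (+1 + +3)/2 = 2
  f <- make_table(1, variance = 1)
  r <- make_table(-3, variance = 1)
  expect_equal(combine_dye_swap(f, r)$log2_ratio, 2)

  # variances 1 and 4: (1*1 + 0.25*3)/(1.25) = 1.4 (hand-checked)
  f <- make_table(1, variance = 1)
  r <- make_table(-3, variance = 4)
  comb <- combine_dye_swap(f, r)
  expect_equal(comb$log2_ratio, 1.4)
  expect_equal(comb$ratio_variance, 1 / (1 + 0.25))

  # combined p is the two-sided normal p of the weighted-mean z
  z <- 1.4 / sqrt(0.8)
  expect_equal(comb$p_value, 2 * pnorm(-z))

  # missing variances: warn, equal weights
  expect_warning(
    eq <- combine_dye_swap(make_table(1), make_table(-3)),
    "equal weights")
  expect_equal(eq$log2_ratio, 2)

  expect_error(
    combine_dye_swap(make_table(1:2, ids = c("a", "b")),
                     make_table(1:2, ids = c("a", "c"))),
    "probe sets differ")
})

test_that("dye-swap combination is symmetric in the two array roles", {
  set.seed(3)
  f <- make_table(rnorm(50), variance = runif(50, 0.5, 2),
                  ids = sprintf("p%03d", 1:50))
  r <- make_table(rnorm(50), variance = runif(50, 0.5, 2),
                  ids = sprintf("p%03d", 1:50))
  ab <- combine_dye_swap(f, r)
  # exchanging roles: the old forward becomes the reverse of the swapped
  # orientation (ratios sign-flipped onto the other scale)
  f2 <- r; f2$log2_ratio <- -r$log2_ratio
  r2 <- f; r2$log2_ratio <- -f$log2_ratio
  ba <- combine_dye_swap(f2, r2)
  expect_equal(ba$log2_ratio, ab$log2_ratio)
  expect_equal(ba$p_value, ab$p_value)
})

test_that("redundant probes collapse by accession and identical call pattern", {
  ids <- c("a1", "a2", "b1", "b2", "c1")
  ann <- data.frame(probe_id = ids,
                    accession = c("ACC1", "ACC1", "ACC2", "ACC2", "ACC3"),
                    stringsAsFactors = FALSE)
  t1 <- make_table(c(2, 2, 2, -2, 0), int1 = c(100, 900, 500, 500, 500),
                   int2 = c(100, 900, 500, 500, 500), ids = ids)
  t2 <- make_table(c(0, 0, 2, -2, 0), int1 = c(100, 900, 500, 500, 500),
                   int2 = c(100, 900, 500, 500, 500), ids = ids)
  calls <- rbind(a1 = c("up", "none"), a2 = c("up", "none"),
                 b1 = c("up", "up"), b2 = c("down", "down"),
                 c1 = c("none", "none"))
  res <- collapse_redundant_probes(list(c1 = t1, c2 = t2), ann, calls)
  kept <- res$tables[[1]]$probe_id
  # a1/a2 share accession and pattern: the brighter a2 is the representative
  expect_false("a1" %in% kept)
  expect_true("a2" %in% kept)
  # b1/b2 share an accession but differ in pattern: both stay
  expect_true(all(c("b1", "b2") %in% kept))
  # unique accession untouched
  expect_true("c1" %in% kept)
  expect_identical(res$report$n_probes, 2L)
  expect_identical(res$report$kept, "a2")
  # collapse never removes the last probe of an accession
  expect_true(all(ann$accession %in%
                    ann$accession[ann$probe_id %in% kept]))
  expect_lte(length(kept), length(ids))
})
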