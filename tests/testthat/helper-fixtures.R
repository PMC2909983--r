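# Shared fixtures and independent oracles.

# minimal well-formed comparison table
make_table <- function(ratios, p = rep(0.5, length(ratios)),
                       int1 = rep(500, length(ratios)),
                       int2 = rep(500, length(ratios)),
                       variance = NULL,
                       ids = sprintf("p%03d", seq_along(ratios))) {
  tb <- data.frame(probe_id = ids, log2_ratio = ratios, p_value = p,
                   intensity_ch1 = int1, intensity_ch2 = int2,
                   stringsAsFactors = FALSE)
  if (!is.null(variance)) tb$ratio_variance <- variance
  tb
}

# all 3^n ternary call patterns as a matrix of call strings
all_patterns <- function(n) {
  lv <- c("up", "none", "down")
  as.matrix(expand.grid(rep(list(lv), n), stringsAsFactors = FALSE))
}

# independent oracle: one-sided (greater) Fisher p by brute-force
# enumeration of all tables at the observed margins with a' >= a
fisher_oracle <- function(a, b, cc, d) {
  n1 <- a + b
  k <- a + cc
  n <- a + b + cc + d
  a_values <- max(0, k - (n - n1)):min(n1, k)
  probs <- vapply(a_values, function(x)
    choose(n1, x) * choose(n - n1, k - x) / choose(n, k), numeric(1))
  sum(probs[a_values >= a])
}

# independent oracle: windowed running-mean smoother of y against x
running_mean_fit <- function(x, y, halfwidth) {
  ord <- order(x)
  vapply(seq_along(x), function(i) {
    sel <- abs(x - x[i]) <= halfwidth
    mean(y[sel])
  }, numeric(1))
}

# random promoter set with a planted consensus at a given per-sequence rate
random_promoters <- function(n, len, consensus = NULL, rate = 0,
                             prefix = "g") {
  vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (!is.null(consensus) && runif(1) < rate) {
      w <- nchar(consensus)
      p <- sample(len - w + 1L, 1L)
      s[p:(p + w - 1L)] <- strsplit(consensus, "")[[1]]
    }
    paste(s, collapse = "")
  }, character(1)) |> setNames(paste0(prefix, seq_len(n)))
}

# hand-built Ct table with exact means (no noise)
make_ct_table <- function(gene, ddct, n_rep = 3, base_target = 24,
                          base_ref = 12) {
  grid <- expand.grid(role = c("target", "reference"),
                      arm = c("treated", "control"),
                      replicate = seq_len(n_rep),
                      stringsAsFactors = FALSE)
  grid$gene_id <- gene
  grid$ct <- ifelse(grid$role == "reference", base_ref,
                    ifelse(grid$arm == "treated", base_target + ddct,
                           base_target))
  grid
}
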