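# Promoter motif analysis: ZOOPS Gibbs site sampler for de novo discovery,
# log-odds PWM scanning of both strands, Fisher exact enrichment against
# expression-defined background gene sets, and a generic hypergeometric
# over-representation test.

.BASES <- c("A", "C", "G", "T")

# sequences -> list of integer vectors (A=1 C=2 G=3 T=4, others NA)
.seq_to_int <- function(sequences) {
  if (inherits(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (!is.character(sequences))
    stop("sequences must be a character vector or DNAStringSet")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  lapply(sequences, function(s) {
    v <- match(strsplit(toupper(s), "")[[1]], .BASES)
    v
  })
}

.base_frequencies <- function(seq_ints) {
  tab <- tabulate(unlist(seq_ints, use.names = FALSE), nbins = 4L)
  if (sum(tab) == 0) stop("no A/C/G/T content in sequences")
  setNames(tab / sum(tab), .BASES)
}

.new_pwm <- function(prob, background) {
  colnames(prob) <- .BASES
  rownames(prob) <- seq_len(nrow(prob))
  structure(list(prob = prob, background = background,
                 width = nrow(prob),
                 consensus = paste(.BASES[apply(prob, 1L, which.max)],
                                   collapse = ""),
                 information_content = .pwm_ic(prob, background)),
            class = "tfscope_pwm")
}

.pwm_ic <- function(prob, background) {
  sum(prob * log2(sweep(prob, 2L, background, `/`)))
}

#' @export
print.tfscope_pwm <- function(x, ...) {
  cat("PWM width", x$width, "| consensus", x$consensus,
      sprintf("| information %.2f bits\n", x$information_content))
  print(round(x$prob, 3))
  invisible(x)
}

#' Position weight matrix from an IUPAC consensus
#'
#' Allowed bases at each position share probability `1 - mismatch_prob`
#' equally; the remaining bases share `mismatch_prob`.
#'
#' @param consensus IUPAC string over `{A,C,G,T,R,Y,S,W,K,M,N}`.
#' @param mismatch_prob Total probability mass on disallowed bases per
#'   position (default 0.06).
#' @param background Background base frequencies (default uniform).
#' @return A `tfscope_pwm`.
#' @export
pwm_from_consensus <- function(consensus, mismatch_prob = 0.06,
                               background = rep(0.25, 4)) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  if (!all(letters %in% names(.IUPAC)))
    stop("invalid IUPAC consensus: ", consensus)
  prob <- t(vapply(letters, function(b) {
    allowed <- .BASES %in% .IUPAC[[b]]
    k <- sum(allowed)
    p <- numeric(4)
    if (k == 4L) p[] <- 0.25
    else {
      p[allowed] <- (1 - mismatch_prob) / k
      p[!allowed] <- mismatch_prob / (4 - k)
    }
    p
  }, numeric(4)))
  .new_pwm(prob, setNames(background, .BASES))
}

# PWM (probability matrix, with pseudocounts) from site integer matrix
.pwm_from_sites <- function(site_matrix, pseudocount, background) {
  w <- ncol(site_matrix)
  counts <- matrix(pseudocount, w, 4L)
  for (pos in seq_len(w)) {
    tb <- tabulate(site_matrix[, pos], nbins = 4L)
    counts[pos, ] <- counts[pos, ] + tb
  }
  .new_pwm(counts / rowSums(counts), background)
}

# log-likelihood-ratio scores of every window start in one sequence
.window_scores <- function(s, loglr, w) {
  ns <- length(s) - w + 1L
  if (ns < 1L) return(numeric(0))
  sc <- numeric(ns)
  for (k in seq_len(w)) {
    lr <- loglr[k, ][s[k:(k + ns - 1L)]]
    sc <- sc + lr
  }
  sc[is.na(sc)] <- -Inf
  sc
}

#' De novo motif discovery with a ZOOPS Gibbs site sampler
#'
#' Zero-or-one-occurrence-per-sequence Gibbs sampling: one sequence at a
#' time is held out, a PWM (pseudocount 0.25 per base) is built from the
#' sites currently assigned in the remaining sequences, and the held-out
#' sequence's site is resampled among all window positions plus "no site",
#' with weights proportional to the PWM/background likelihood ratio and a
#' prior site probability. Every 10 sweeps a +/-1 phase-shift move is
#' tested and kept if it raises the information content. The best
#' assignment (highest information content) over `n_restarts` seeded
#' restarts is returned.
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet] (>= 5
#'   sequences, each >= `width` bases, A/C/G/T only).
#' @param width Motif width in bases (>= 4).
#' @param n_restarts Independent restarts (default 10).
#' @param max_iter Maximum sweeps per restart (default 150).
#' @param patience Stop a restart after this many sweeps without
#'   improvement (default 25).
#' @param pseudocount Per-base pseudocount for PWM estimation (default
#'   0.25).
#' @param site_prior Prior probability that a sequence contains a site
#'   (default 0.5).
#' @param seed Optional integer seed for reproducibility.
#' @return A `tfscope_motif` list: `pwm` (`tfscope_pwm`), `sites`
#'   (data.frame `seq_id`, `start` 0-based or `NA`), and `trajectory`
#'   (best-so-far information content per sweep, all restarts
#'   concatenated).
#' @export
gibbs_motif_discovery <- function(sequences, width, n_restarts = 10L,
                                  max_iter = 150L, patience = 25L,
                                  pseudocount = 0.25, site_prior = 0.5,
                                  seed = NULL) {
  if (width < 4) stop("motif width must be >= 4")
  seq_ints <- .seq_to_int(sequences)
  if (length(seq_ints) < 5)
    stop("Gibbs discovery needs at least 5 sequences")
  lens <- lengths(seq_ints)
  if (any(lens < width))
    stop("all sequences must be at least 'width' bases long")
  if (any(vapply(seq_ints, anyNA, logical(1))))
    stop("sequences must contain only A/C/G/T for discovery")
  run <- function() .gibbs_run(seq_ints, width, n_restarts, max_iter,
                               patience, pseudocount, site_prior)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.gibbs_run <- function(seq_ints, w, n_restarts, max_iter, patience,
                       pseudocount, site_prior) {
  n <- length(seq_ints)
  bg <- .base_frequencies(seq_ints)
  log_bg <- log(bg)
  ns_all <- lengths(seq_ints) - w + 1L
  site_mat <- function(starts) {
    idx <- which(!is.na(starts))
    if (!length(idx)) return(matrix(integer(0), 0, w))
    t(vapply(idx, function(i)
      seq_ints[[i]][starts[i]:(starts[i] + w - 1L)], integer(w)))
  }
  assignment_ic <- function(starts) {
    sm <- site_mat(starts)
    if (nrow(sm) < 2L) return(-Inf)
    .pwm_from_sites(sm, pseudocount, bg)$information_content
  }

  best <- list(ic = -Inf, starts = NULL)
  trajectory <- numeric(0)
  for (rs in seq_len(n_restarts)) {
    starts <- vapply(ns_all, function(m) sample.int(m, 1L), integer(1))
    stale <- 0L
    restart_best <- -Inf
    for (iter in seq_len(max_iter)) {
      for (i in sample.int(n)) {
        starts_i <- starts
        starts_i[i] <- NA_integer_
        sm <- site_mat(starts_i)
        if (nrow(sm) == 0L) {  # keep at least one anchor site
          starts[i] <- sample.int(ns_all[i], 1L)
          next
        }
        pwm <- .pwm_from_sites(sm, pseudocount, bg)
        loglr <- log(pwm$prob) - matrix(log_bg, w, 4L, byrow = TRUE)
        sc <- .window_scores(seq_ints[[i]], loglr, w)
        lw <- c(log(site_prior) - log(ns_all[i]) + sc, log(1 - site_prior))
        p <- exp(lw - max(lw))
        pick <- sample.int(length(p), 1L, prob = p)
        starts[i] <- if (pick > ns_all[i]) NA_integer_ else pick
      }
      if (iter %% 10L == 0L) {  # phase-shift move
        ic_now <- assignment_ic(starts)
        for (shift in c(-1L, 1L)) {
          cand <- starts + shift
          ok <- is.na(cand) | (cand >= 1L & cand <= ns_all)
          if (!all(ok)) next
          ic_cand <- assignment_ic(cand)
          if (ic_cand > ic_now) {
            starts <- cand
            ic_now <- ic_cand
          }
        }
      }
      ic <- assignment_ic(starts)
      if (ic > restart_best + 1e-12) {
        restart_best <- ic
        stale <- 0L
      } else stale <- stale + 1L
      if (ic > best$ic) best <- list(ic = ic, starts = starts)
      trajectory <- c(trajectory, best$ic)
      if (stale >= patience) break
    }
  }
  sm <- site_mat(best$starts)
  pwm <- .pwm_from_sites(sm, pseudocount, bg)
  structure(list(
    pwm = pwm,
    sites = data.frame(seq_id = names(seq_ints),
                       start = best$starts - 1L,
                       stringsAsFactors = FALSE),
    trajectory = trajectory),
    class = "tfscope_motif")
}

#' Scan promoters with a PWM on both strands
#'
#' Windows are scored by the log2-odds of the PWM against its background;
#' the reverse strand is scanned via the reverse-complemented PWM, with
#' positions reported as 0-based starts on the forward strand. A gene
#' "has the motif" when any window on either strand scores at or above
#' the threshold.
#'
#' @param pwm A `tfscope_pwm`.
#' @param sequences Character vector or [Biostrings::DNAStringSet], named
#'   by gene id.
#' @param threshold_bits Log2-odds score threshold (finite).
#' @return List with `hits` (named logical per gene) and `positions`
#'   (data.frame `gene_id`, `start` 0-based, `strand`, `score_bits` of
#'   every window meeting the threshold).
#' @export
scan_promoters <- function(pwm, sequences, threshold_bits) {
  stopifnot(inherits(pwm, "tfscope_pwm"))
  if (!is.finite(threshold_bits)) stop("threshold_bits must be finite")
  seq_ints <- .seq_to_int(sequences)
  w <- pwm$width
  loglr_f <- log2(pwm$prob) -
    matrix(log2(pwm$background), w, 4L, byrow = TRUE)
  # reverse complement: reverse position order, swap A<->T and C<->G
  prob_rc <- pwm$prob[rev(seq_len(w)), c(4L, 3L, 2L, 1L), drop = FALSE]
  bg_rc <- pwm$background[c(4L, 3L, 2L, 1L)]
  loglr_r <- log2(prob_rc) - matrix(log2(bg_rc), w, 4L, byrow = TRUE)

  hits <- logical(length(seq_ints))
  names(hits) <- names(seq_ints)
  pos_list <- vector("list", length(seq_ints))
  for (i in seq_along(seq_ints)) {
    s <- seq_ints[[i]]
    sc_f <- .window_scores(s, loglr_f, w)
    sc_r <- .window_scores(s, loglr_r, w)
    hf <- which(sc_f >= threshold_bits)
    hr <- which(sc_r >= threshold_bits)
    hits[i] <- length(hf) + length(hr) > 0
    if (hits[i])
      pos_list[[i]] <- data.frame(
        gene_id = names(seq_ints)[i],
        start = c(hf, hr) - 1L,
        strand = rep(c("+", "-"), c(length(hf), length(hr))),
        score_bits = c(sc_f[hf], sc_r[hr]),
        stringsAsFactors = FALSE)
  }
  positions <- do.call(rbind, pos_list[!vapply(pos_list, is.null, logical(1))])
  if (is.null(positions))
    positions <- data.frame(gene_id = character(), start = integer(),
                            strand = character(), score_bits = numeric(),
                            stringsAsFactors = FALSE)
  list(hits = hits, positions = positions)
}

#' Expression-defined background gene sets for motif enrichment
#'
#' From the (combined) comparison tables of one concentration's three time
#' points: genes that never move (|log2 ratio| < log2(1.2) at every time
#' point) are split by expression level into an expressed background
#' (mean control-channel intensity > 200) and a non-expressed background
#' (mean control-channel intensity < 50).
#'
#' @param tables Named list of three comparison tables over one probe
#'   universe (control channel = `intensity_ch2`).
#' @param annotation Optional probe annotation; when given, probe ids are
#'   mapped to accessions.
#' @param fc_limit Fold-change ceiling on the linear scale (default 1.2).
#' @param expressed_min,nonexpressed_max Intensity cutoffs (defaults 200
#'   and 50).
#' @return List with character vectors `expressed_nonresponsive` and
#'   `nonexpressed` (disjoint).
#' @export
build_background_sets <- function(tables, annotation = NULL,
                                  fc_limit = 1.2, expressed_min = 200,
                                  nonexpressed_max = 50) {
  ids <- tables[[1]]$probe_id
  lr <- vapply(tables, function(tb)
    abs(tb$log2_ratio[match(ids, tb$probe_id)]), numeric(length(ids)))
  quiet <- apply(lr < log2(fc_limit), 1L, all)
  intensity <- rowMeans(vapply(tables, function(tb)
    tb$intensity_ch2[match(ids, tb$probe_id)], numeric(length(ids))))
  expressed <- ids[quiet & intensity > expressed_min]
  nonexpr <- ids[quiet & intensity < nonexpressed_max]
  if (!is.null(annotation)) {
    map <- function(x) unique(annotation$accession[match(x, annotation$probe_id)])
    expressed <- map(expressed)
    nonexpr <- map(nonexpr)
  }
  if (!length(expressed))
    warning("expressed non-responsive background set is empty")
  if (!length(nonexpr))
    warning("non-expressed background set is empty")
  list(expressed_nonresponsive = expressed, nonexpressed = nonexpr)
}

#' Fisher exact test of motif enrichment in a target gene set
#'
#' One-sided (greater) Fisher exact test of the 2x2 table (target
#' with/without motif vs background with/without motif), plus the
#' enrichment score defined as the ratio of hit proportions,
#' `(a/(a+b)) / (c/(c+d))`.
#'
#' @param target_hits,background_hits Logical vectors: motif presence per
#'   gene in the target and background sets (both nonempty).
#' @return A `tfscope_enrichment` list: `a`, `b`, `c`, `d`, `fisher_p`,
#'   `enrichment_score`.
#' @export
motif_enrichment_test <- function(target_hits, background_hits) {
  if (!length(target_hits) || !length(background_hits))
    stop("target and background sets must be nonempty")
  a <- sum(target_hits); b <- sum(!target_hits)
  cc <- sum(background_hits); d <- sum(!background_hits)
  p <- fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE),
                   alternative = "greater")$p.value
  score <- (a / (a + b)) / (cc / (cc + d))
  structure(list(a = a, b = b, c = cc, d = d,
                 fisher_p = p, enrichment_score = score),
            class = "tfscope_enrichment")
}

#' @export
print.tfscope_enrichment <- function(x, ...) {
  cat(sprintf(
    "Motif enrichment: target %d/%d vs background %d/%d | score %.2f | one-sided Fisher p = %.3g\n",
    x$a, x$a + x$b, x$c, x$c + x$d, x$enrichment_score, x$fisher_p))
  invisible(x)
}

#' Gene-set over-representation test (one-sided hypergeometric)
#'
#' For each annotation term, tests whether the gene list overlaps the term
#' more than expected under hypergeometric sampling from the universe.
#' Benjamini-Hochberg adjusted p-values are an optional extension
#' (`adjust = TRUE`) and are labeled as such in the output.
#'
#' @param gene_list Character vector, a subset of `universe`.
#' @param term_to_genes Named list of character vectors (term -> genes).
#' @param universe Character vector of all assayed genes.
#' @param adjust Add a `p_bh` column of BH-adjusted p-values.
#' @return data.frame per term: `term`, `overlap`, `term_size`,
#'   `fold_enrichment`, `p` (and optionally `p_bh`). Terms with no
#'   universe overlap are skipped with a warning.
#' @export
ora_test <- function(gene_list, term_to_genes, universe, adjust = FALSE) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (!all(gene_list %in% universe))
    stop("gene_list must be a subset of the universe")
  n <- length(gene_list)
  N <- length(universe)
  rows <- lapply(names(term_to_genes), function(term) {
    tg <- intersect(term_to_genes[[term]], universe)
    K <- length(tg)
    if (K == 0L) {
      warning("term '", term, "' has no overlap with the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(gene_list, tg))
    data.frame(term = term, overlap = k, term_size = K,
               fold_enrichment = (k / n) / (K / N),
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(term = character(), overlap = integer(),
                      term_size = integer(), fold_enrichment = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  if (adjust && nrow(out)) out$p_bh <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Write a PWM as a tab-delimited position-probability matrix
#'
#' Format: a `#width=W` header line, a column header `A C G T`, then one
#' probability row per position.
#'
#' @param pwm A `tfscope_pwm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "tfscope_pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#width=", pwm$width), con)
  writeLines(paste(.BASES, collapse = "\t"), con)
  apply(pwm$prob, 1L, function(r)
    writeLines(paste(format(r, digits = 6), collapse = "\t"), con))
  invisible(path)
}

#' Read a PWM written by [write_pwm()]
#' @param path Input path.
#' @param background Background base frequencies (default uniform).
#' @return A `tfscope_pwm`.
#' @export
read_pwm <- function(path, background = rep(0.25, 4)) {
  lines <- readLines(path)
  if (!grepl("^#width=\\d+$", lines[1]))
    stop("PWM file must start with a '#width=W' header")
  w <- as.integer(sub("^#width=", "", lines[1]))
  body <- read.delim(text = lines[-1])
  if (nrow(body) != w || ncol(body) != 4L)
    stop("PWM body must be ", w, " x 4")
  prob <- as.matrix(body)
  if (any(abs(rowSums(prob) - 1) > 1e-6))
    stop("PWM rows must sum to 1")
  .new_pwm(prob, setNames(background, .BASES))
}

#' Nearest match of a PWM against a plain-text PWM library
#'
#' Compares by total Euclidean distance between aligned probability
#' columns, over all offsets of the shorter matrix within the longer
#' (forward orientation only); a lightweight stand-in for motif-database
#' lookup.
#'
#' @param pwm A `tfscope_pwm`.
#' @param library Named list of `tfscope_pwm` objects.
#' @return data.frame `name`, `distance`, sorted ascending.
#' @export
match_pwm_library <- function(pwm, library) {
  stopifnot(inherits(pwm, "tfscope_pwm"), length(library) > 0)
  dist_one <- function(q, r) {
    if (nrow(q) > nrow(r)) { tmp <- q; q <- r; r <- tmp }
    offs <- 0:(nrow(r) - nrow(q))
    min(vapply(offs, function(o)
      sqrt(sum((q - r[(o + 1):(o + nrow(q)), , drop = FALSE])^2)),
      numeric(1)))
  }
  d <- vapply(library, function(m) dist_one(pwm$prob, m$prob), numeric(1))
  out <- data.frame(name = names(library), distance = d,
                    stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}
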