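# Principal component analysis of the gene x condition ratio matrix by
# singular value decomposition, with the standard preprocessing: per-gene
# standardization to mean 0 / SD 1 across arrays.

#' Select genes for PCA: any call in any condition
#'
#' @param ... One or more call matrices (genes x conditions, cells
#'   `"up"`/`"none"`/`"down"`, row names = gene/probe ids) over the same
#'   gene universe.
#' @return Character vector of ids with at least one non-`"none"` call.
#' @export
select_pca_genes <- function(...) {
  mats <- list(...)
  if (!length(mats)) stop("at least one call matrix required")
  ids <- rownames(mats[[1]])
  any_call <- Reduce(`|`, lapply(mats, function(m) {
    m <- m[ids, , drop = FALSE]
    apply(m != "none", 1L, any)
  }))
  ids[any_call]
}

#' Standardize each gene's ratios to mean 0 and SD 1 across arrays
#'
#' Zero-variance rows (constant ratios) are dropped with a warning, since
#' their standardization is undefined.
#'
#' @param mat Numeric matrix, genes x conditions (M >= 2 columns), of log2
#'   ratios.
#' @return Standardized matrix; dropped gene ids in attribute `dropped`.
#' @export
standardize_genes <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("standardization needs at least 2 conditions")
  m <- rowMeans(mat)
  s <- apply(mat, 1L, sd)
  drop <- !is.finite(s) | s == 0
  if (any(drop))
    warning(sum(drop), " zero-variance gene(s) dropped: ",
            paste(head(rownames(mat)[drop], 5), collapse = ", "))
  out <- (mat[!drop, , drop = FALSE] - m[!drop]) / s[!drop]
  attr(out, "dropped") <- rownames(mat)[drop]
  out
}

#' Singular value decomposition of the standardized ratio matrix
#'
#' Computes the thin SVD `A = U D V^T` with singular values in descending
#' order, principal-component scores `X = U D`, and per-component variance
#' fractions `d_k^2 / sum(d_j^2)`. The sign indeterminacy of each
#' component is resolved by making the largest-magnitude loading in each
#' column of `V` positive, so results are reproducible across platforms.
#'
#' @param mat Numeric matrix with finite entries (typically from
#'   [standardize_genes()]).
#' @return A `tfscope_pca` list: `A`, `U`, `d`, `V`, `X`,
#'   `variance_fraction`.
#' @export
svd_decompose <- function(mat) {
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) stop("matrix must be finite")
  dec <- svd(mat)
  flip <- vapply(seq_along(dec$d), function(k) {
    v <- dec$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  dec$u <- sweep(dec$u, 2L, flip, `*`)
  dec$v <- sweep(dec$v, 2L, flip, `*`)
  X <- dec$u %*% diag(dec$d, nrow = length(dec$d))
  rownames(X) <- rownames(mat)
  rownames(dec$u) <- rownames(mat)
  rownames(dec$v) <- colnames(mat)
  colnames(X) <- colnames(dec$u) <- colnames(dec$v) <-
    paste0("PC", seq_along(dec$d))
  structure(list(A = mat, U = dec$u, d = dec$d, V = dec$v, X = X,
                 variance_fraction = dec$d^2 / sum(dec$d^2)),
            class = "tfscope_pca")
}

#' @export
print.tfscope_pca <- function(x, ...) {
  cat("SVD of", nrow(x$A), "x", ncol(x$A), "standardized ratio matrix\n")
  cat("variance fractions:",
      paste0(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}
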