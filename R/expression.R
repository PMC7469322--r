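# Soft-threshold expression adjacency: a_ij = |cor(x_i, x_j)|^beta
# (unsigned convention; fractional powers of negative correlations are
# undefined, so the absolute value is taken before exponentiation).

#' Soft-threshold adjacency from an expression matrix
#'
#' Computes pairwise Pearson correlations `s_ij` between gene expression
#' profiles (rows of `X`) and raises their absolute value to the
#' soft-threshold exponent: `a_ij = |s_ij|^beta`. The adjacency is symmetric
#' with entries in \[0, 1\]; the diagonal is excluded (`NA`). Genes with zero
#' variance have undefined correlations and are excluded with a warning.
#'
#' @param X numeric matrix, genes in rows, samples in columns (>= 2 samples).
#' @param beta soft-threshold exponent, > 0. Default 1 (no thresholding).
#' @return an [ExpressionAdjacency-class].
#' @examples
#' X <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 2))
#' softThresholdAdjacency(X, beta = 2)@adjacency
#' @export
softThresholdAdjacency <- function(X, beta = 1) {
  stopifnot(is.matrix(X), is.numeric(X), beta > 0)
  if (ncol(X) < 2L) stop("need >= 2 samples per gene")
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(nrow(X)))
  v <- apply(X, 1L, stats::var)
  dropped <- rownames(X)[v == 0 | is.na(v)]
  if (length(dropped)) {
    warning("excluding zero-variance gene(s): ", paste(dropped, collapse = ", "))
    X <- X[!(rownames(X) %in% dropped), , drop = FALSE]
  }
  if (nrow(X) < 2L) stop("fewer than 2 genes with non-zero variance")
  s <- stats::cor(t(X))
  a <- abs(s)^beta
  diag(a) <- NA_real_
  new("ExpressionAdjacency", correlations = s, adjacency = a,
      beta = beta, dropped = dropped)
}
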