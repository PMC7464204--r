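#' Log2 transform with offset
#'
#' Maps raw non-negative expression values (e.g. RNA-seq normalized counts)
#' onto the log2 scale: `log2(x + offset)`.
#'
#' @param x Numeric matrix of non-negative values.
#' @param offset Positive pseudo-count added before the log (default 1, so
#'   zero counts map to zero).
#' @return Matrix of the same shape on log2 scale.
#' @export
log2_offset <- function(x, offset = 1) {
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0) {
    stop("offset must be a single positive number")
  }
  if (any(x < 0, na.rm = TRUE)) stop("negative values cannot be log-transformed")
  log2(x + offset)
}

#' Gene-wise standardization (z-scores)
#'
#' Re-normalizes each gene row to mean 0 and unit sample standard deviation
#' (n - 1 denominator) across samples. This is the standardization applied to
#' both the training signature data and the target cohort before a compound
#' covariate classifier is projected across platforms. Genes with zero
#' variance carry no class information on the z-scale and are dropped.
#'
#' @param x Numeric genes-by-samples matrix with at least 2 columns.
#' @return Standardized matrix; zero-variance genes are removed and listed in
#'   the `"dropped"` attribute.
#' @examples
#' m <- matrix(c(0, 2, 5, 5), 2, 2, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("s1", "s2")))
#' standardize_genes(m)        # row A -> -0.707, 0.707; row B dropped
#' @export
standardize_genes <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L) stop("standardization needs at least 2 samples")
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1L))
  keep <- s > 0
  z <- (x[keep, , drop = FALSE] - m[keep]) / s[keep]
  attr(z, "dropped") <- rownames(x)[!keep]
  z
}

#' Restrict a list of expression matrices to their common genes
#'
#' Required before a signature trained on one platform can be applied to
#' another: all matrices are subset to the intersection of their gene sets,
#' in identical (sorted) row order.
#'
#' @param matrices List of at least two genes-by-samples matrices.
#' @return List of matrices restricted to the shared genes, with a
#'   `"dropped_counts"` attribute giving per-matrix counts of removed rows.
#' @export
align_genes <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2L)
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0L) stop("matrices share no genes")
  common <- sort(common)
  out <- lapply(matrices, function(m) m[common, , drop = FALSE])
  attr(out, "dropped_counts") <- vapply(matrices, function(m) {
    nrow(m) - length(common)
  }, integer(1))
  out
}
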