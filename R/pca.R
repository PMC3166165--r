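#' Sample-level principal component analysis
#'
#' PCA of the samples in gene space, used to check replicate
#' reproducibility and the trajectory of the time course: replicates of a
#' timepoint should aggregate, and timepoints should order along the
#' leading components. Genes are mean-centered across samples and not
#' scaled to unit variance (intensities share a scale after quantile
#' normalization). Restricting to the responsive-gene subset is the usual
#' call; pass `genes = rownames(m)` for the full matrix.
#'
#' Each component's sign is fixed deterministically: the loading of
#' largest magnitude is made positive (first index on exact ties), so
#' scores and plots are stable across platforms.
#'
#' @param m expression matrix, log2 scale expected.
#' @param genes gene ids to use (default: all rows).
#' @param n_components number of components to keep (default 2).
#' @return list with `scores` (samples x components), `loadings`
#'   (genes x components), `variance_explained` (fraction per component),
#'   class `"reox_pca"`.
#' @export
pca_samples <- function(m, genes = rownames(m), n_components = 2L) {
  unknown <- setdiff(genes, rownames(m))
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  if (ncol(m) < 2L) stop("PCA needs at least 2 samples")
  x <- t(unclass(m)[genes, , drop = FALSE])   # samples x genes
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(n_samples, n_genes)")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  scores <- fit$x[, k, drop = FALSE]
  loadings <- fit$rotation[, k, drop = FALSE]
  for (j in k) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve[k]),
            class = "reox_pca")
}

#' @export
print.reox_pca <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d components (%s of variance)\n",
              nrow(x$scores), ncol(x$scores),
              paste0(round(100 * x$variance_explained, 1), "%",
                     collapse = " + ")))
  invisible(x)
}
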