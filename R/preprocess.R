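#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common intensity distribution of
#' the across-sample rank means: sort each column, average across columns
#' at each rank to get the reference distribution, then hand each value the
#' reference value of its rank. Ties within a column receive the mean of
#' the reference values over the tied span, so the map is deterministic and
#' the transform is exactly idempotent. Rank order within each column is
#' preserved.
#'
#' @param m expression matrix (genes x samples) or plain numeric matrix.
#' @return matrix of the same shape, ids preserved; every column holds the
#'   same multiset of values.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2L) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(m)
  }
  if (any(!is.finite(m))) stop("matrix contains non-finite values")
  ref <- rowMeans(apply(unclass(m), 2L, sort))
  out <- apply(unclass(m), 2L, function(v) {
    o <- order(v)
    # tie groups along the sorted column; each group gets the mean of the
    # reference values over its span
    grp <- cumsum(!duplicated(v[o]))
    res <- numeric(length(v))
    res[o] <- stats::ave(ref, grp)
    res
  })
  dimnames(out) <- dimnames(m)
  attrs <- attributes(m)
  attributes(out) <- c(attributes(out),
                       attrs[setdiff(names(attrs), c("dim", "dimnames"))])
  out
}

#' Transform an expression matrix to log2 scale
#'
#' Downstream statistics (t-tests, PCA, fold-changes) run on log2
#' intensities by default; `offset` guards against zeros in
#' background-adjusted data.
#'
#' @param m expression matrix (linear scale).
#' @param offset added to every value before taking log2 (default 1).
#' @return matrix of `log2(value + offset)` with the scale flag set to
#'   `"log2"`.
#' @export
to_log2 <- function(m, offset = 1) {
  bad <- which(unclass(m) + offset <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("nonpositive log2 argument at gene '%s', sample '%s'",
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  out <- log2(unclass(m) + offset)
  if (inherits(m, "reox_expr")) out <- expression_matrix(out, scale = "log2")
  out
}

#' Invert [to_log2()]
#'
#' @param m log2-scale matrix.
#' @param offset the offset used in the forward transform.
#' @return linear-scale matrix.
#' @export
from_log2 <- function(m, offset = 1) {
  out <- 2^unclass(m) - offset
  if (inherits(m, "reox_expr")) out <- expression_matrix(out, scale = "linear")
  out
}
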