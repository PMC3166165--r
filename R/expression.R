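#' Construct a validated expression matrix
#'
#' The package's central container is a plain numeric matrix of intensities
#' (genes in rows, samples in columns) carrying a `"scale"` attribute that
#' records whether values are linear intensities or log2 intensities. Row
#' names are gene identifiers (opaque strings: probe ids or symbols; any
#' probe-to-gene collapsing is the caller's concern), column names are
#' sample identifiers.
#'
#' @param values numeric matrix, genes x samples, with unique non-empty
#'   rownames and colnames and all values finite.
#' @param scale `"linear"` or `"log2"`.
#' @return the matrix with class `"reox_expr"` and a `"scale"` attribute.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(gid))
    stop("duplicate gene id(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values")
  structure(values, scale = scale, class = c("reox_expr", class(values)))
}

#' @export
print.reox_expr <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

expr_scale <- function(m) {
  s <- attr(m, "scale")
  if (is.null(s)) "linear" else s
}

#' Validate a sample design table against an expression matrix
#'
#' The design describes the reoxygenation time course: each array sample is
#' one (timepoint, replicate) combination. Timepoint 0 is the hypoxia
#' control and is the baseline of every downstream test, so it must be
#' present; every tested timepoint needs at least two replicates.
#'
#' @param design data.frame with columns `sample_id`, `timepoint_h`,
#'   `replicate`.
#' @param m optional expression matrix whose samples must match
#'   `design$sample_id` exactly (as sets).
#' @return the design, with `timepoint_h` numeric and rows ordered by
#'   timepoint then replicate.
#' @export
validate_design <- function(design, m = NULL) {
  need <- c("sample_id", "timepoint_h", "replicate")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  design$timepoint_h <- as.numeric(design$timepoint_h)
  design$replicate <- as.integer(design$replicate)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  if (any(!is.finite(design$timepoint_h)))
    stop("non-numeric timepoint_h in design")
  if (any(design$replicate < 1L))
    stop("replicate must be a positive integer")
  if (!0 %in% design$timepoint_h)
    stop("design lacks timepoint 0 (the hypoxia-control baseline)")
  if (!is.null(m)) {
    sid <- colnames(m)
    missing_in_design <- setdiff(sid, design$sample_id)
    missing_in_matrix <- setdiff(design$sample_id, sid)
    if (length(missing_in_design) || length(missing_in_matrix))
      stop("design/matrix sample mismatch; in matrix only: [",
           paste(missing_in_design, collapse = ", "),
           "]; in design only: [",
           paste(missing_in_matrix, collapse = ", "), "]")
  }
  design[order(design$timepoint_h, design$replicate), , drop = FALSE]
}

#' Read an expression matrix and its sample design from TSV
#'
#' The expression file is tab-separated with a header row of sample ids and
#' gene ids in the first column; the design file has columns `sample_id`,
#' `timepoint_h`, `replicate`.
#'
#' @param path expression TSV.
#' @param design_path design TSV.
#' @param scale scale flag to stamp on the matrix (`"linear"` default:
#'   background-adjusted array intensities are linear).
#' @return list with elements `values` (a [expression_matrix()]) and
#'   `design` (validated data.frame).
#' @export
read_expression <- function(path, design_path, scale = "linear") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression file needs gene id column plus samples")
  gid <- raw[[1L]]
  if (anyDuplicated(gid))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L,
                                     dimnames = list(NULL, names(raw)[-1L]))
  bad <- which(is.na(num) & as.matrix(raw[-1L]) != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 gid[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]))
  }
  rownames(num) <- gid
  m <- expression_matrix(num, scale = scale)
  design <- utils::read.delim(design_path, header = TRUE, sep = "\t",
                              check.names = FALSE)
  list(values = m, design = validate_design(design, m))
}

#' Write an expression matrix (and optionally its design) to TSV
#'
#' Inverse of [read_expression()]: round-tripping preserves values to the
#' formatting precision (15 significant digits).
#'
#' @param m expression matrix.
#' @param path output TSV for the matrix.
#' @param design optional design data.frame; written next to the matrix.
#' @param design_path output TSV for the design.
#' @param id_col header for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, design = NULL, design_path = NULL,
                             id_col = "gene_id") {
  df <- data.frame(rownames(m), format(unclass(m), digits = 15, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design)) {
    if (is.null(design_path))
      stop("design_path required when writing a design")
    utils::write.table(design, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
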