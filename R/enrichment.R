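#' Hypergeometric over-representation of a gene list in pathway sets
#'
#' For each set, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap when `n` genes are sampled without
#' replacement from a universe of `N` genes containing `K` set members:
#' `p = sum_{i=k..min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`. The universe is
#' the collection's universe (conventionally the analyzed array, since
#' selection was performed over it, not the genome). Query genes outside
#' the universe are dropped with a message; set members outside the
#' universe do not count toward `K`. Raw p-values are reported — no
#' multiple-testing correction, matching the per-pathway threshold
#' convention — and only sets overlapping the query (k >= 1) appear.
#'
#' @param query character vector of gene ids.
#' @param sets a `gene_set_collection`.
#' @param threshold significance threshold on the raw p (default 0.01).
#' @param min_overlap smallest overlap k reported (default 1; with 0, a
#'   disjoint set appears with its degenerate tail p = 1).
#' @return data.frame sorted by ascending p with columns `set`, `N`, `K`,
#'   `n`, `k`, `p_value`, `passes`.
#' @export
hypergeom_enrich <- function(query, sets, threshold = 0.01,
                             min_overlap = 1L) {
  universe <- sets$universe
  if (!length(universe)) stop("empty universe")
  query <- unique(as.character(query))
  outside <- sum(!query %in% universe)
  if (outside > 0L)
    message(outside, " query gene(s) outside the universe dropped")
  q <- intersect(query, universe)
  N <- length(universe)
  n <- length(q)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    K <- length(members)
    k <- length(intersect(q, members))
    if (k < min_overlap || K < 1L) return(NULL)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, N = N, K = K, n = n, k = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  out$passes <- out$p_value < threshold
  out[order(out$p_value, out$set), , drop = FALSE]
}

#' Per-timepoint pathway over-representation
#'
#' Runs [hypergeom_enrich()] once with the union of all responsive genes
#' (`"any"`) and once per timepoint with the genes significant at that
#' timepoint, mirroring the usual per-column pathway table. A timepoint
#' with zero significant genes yields an empty result.
#'
#' @param tbl a `responsive_table`.
#' @param sets a `gene_set_collection`.
#' @param threshold significance threshold (default 0.01).
#' @return named list of enrichment data.frames: `"any"` plus one entry
#'   per timepoint (names are the timepoints in hours).
#' @export
enrich_by_timepoint <- function(tbl, sets, threshold = 0.01) {
  res <- list()
  res[["any"]] <- hypergeom_enrich(tbl$genes$gene[tbl$genes$responsive],
                                   sets, threshold = threshold)
  for (j in seq_along(tbl$timepoints)) {
    t <- as.character(tbl$timepoints[j])
    genes_t <- rownames(tbl$p)[tbl$significant[, j]]
    res[[t]] <- if (length(genes_t))
      hypergeom_enrich(genes_t, sets, threshold = threshold)
    else
      hypergeom_enrich(character(0), sets, threshold = threshold)
  }
  res
}

#' Lay per-timepoint enrichment out as a pathway x query table
#'
#' One row per pathway that passes the threshold in at least one query,
#' one column per query ("any" plus each timepoint, annotated with its
#' query size); cells hold the raw p-value where it passes and `"-"`
#' otherwise.
#'
#' @param res result of [enrich_by_timepoint()].
#' @param threshold same threshold used for the dashes.
#' @return character data.frame ready for TSV export.
#' @export
enrichment_table <- function(res, threshold = 0.01) {
  passing <- unique(unlist(lapply(res, function(df)
    df$set[df$p_value < threshold])))
  cols <- lapply(res, function(df) {
    p <- df$p_value[match(passing, df$set)]
    ifelse(!is.na(p) & p < threshold, formatC(p, format = "e", digits = 2),
           "-")
  })
  sizes <- vapply(res, function(df)
    if (nrow(df)) df$n[1L] else 0L, 1L)
  out <- data.frame(pathway = passing, cols, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("pathway",
                  sprintf("%s (n = %d)", names(res), sizes))
  out
}
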