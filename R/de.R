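#' Per-gene Student's t-test of one timepoint versus the baseline
#'
#' Two-sided, two-sample pooled-variance Student's t-test of the replicates
#' at timepoint `t` against the replicates at timepoint 0 (the hypoxia
#' control), applied row-wise. The log-ratio is the difference of group
#' means, i.e. the log2 fold-change when the matrix is on log2 scale (the
#' pipeline's default analysis scale).
#'
#' Degenerate case: when the pooled variance is exactly zero the statistic
#' is undefined; equal means give t = 0, p = 1, while unequal means are
#' treated as infinitely significant (p = 0) and counted in the
#' `n_zero_variance` attribute. A positive `var_floor` replaces the pooled
#' variance by `max(pooled, var_floor)` for data (e.g. integer-valued
#' simulations) where exact ties are expected.
#'
#' @param m expression matrix, log2 scale expected.
#' @param design validated sample design.
#' @param t a non-zero timepoint present in the design.
#' @param var_floor lower bound on the pooled variance (default 0: none).
#' @return data.frame with columns `gene`, `t_statistic`, `p_value`,
#'   `log_ratio`; attribute `n_zero_variance` counts degenerate genes.
#' @export
ttest_vs_baseline <- function(m, design, t, var_floor = 0) {
  if (t == 0) stop("t must be a non-zero timepoint (0 is the baseline)")
  s0 <- design$sample_id[design$timepoint_h == 0]
  st <- design$sample_id[design$timepoint_h == t]
  if (!length(st)) stop("no samples at timepoint ", t)
  if (length(s0) < 2L || length(st) < 2L)
    stop("need >= 2 replicates in baseline and timepoint groups")
  x0 <- unclass(m)[, s0, drop = FALSE]
  xt <- unclass(m)[, st, drop = FALSE]
  n0 <- length(s0); nt <- length(st)
  m0 <- rowMeans(x0); mt <- rowMeans(xt)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1L)
  vt <- rowSums((xt - mt)^2) / (nt - 1L)
  df <- n0 + nt - 2L
  sp2 <- ((n0 - 1L) * v0 + (nt - 1L) * vt) / df
  sp2 <- pmax(sp2, var_floor)
  diff <- mt - m0
  se <- sqrt(sp2 * (1 / n0 + 1 / nt))
  tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df = df),
              0)
  n_degenerate <- sum(se == 0 & diff != 0)
  if (n_degenerate > 0L)
    warning(n_degenerate, " gene(s) with zero pooled variance and unequal ",
            "means at timepoint ", t, "; p set to 0")
  structure(data.frame(gene = rownames(m), t_statistic = tstat,
                       p_value = p, log_ratio = diff,
                       row.names = NULL, stringsAsFactors = FALSE),
            n_zero_variance = n_degenerate)
}

#' Test every post-baseline timepoint against the baseline
#'
#' @inheritParams ttest_vs_baseline
#' @return list of matrices `p`, `log_ratio`, `t_statistic`
#'   (genes x timepoints, columns named by timepoint, ascending), plus
#'   `timepoints`.
#' @export
ttest_all_timepoints <- function(m, design, var_floor = 0) {
  tps <- sort(unique(design$timepoint_h))
  tps <- tps[tps != 0]
  if (!length(tps)) stop("design has no post-baseline timepoints")
  res <- lapply(tps, function(t) ttest_vs_baseline(m, design, t,
                                                   var_floor = var_floor))
  grab <- function(col) {
    out <- do.call(cbind, lapply(res, `[[`, col))
    dimnames(out) <- list(rownames(m), as.character(tps))
    out
  }
  list(p = grab("p_value"), log_ratio = grab("log_ratio"),
       t_statistic = grab("t_statistic"), timepoints = tps)
}

#' Select oxygen-responsive genes from per-timepoint p-values
#'
#' A gene is O2-responsive when its t-test p-value against the hypoxia
#' baseline is strictly below `alpha` at one or more timepoints. The strict
#' inequality matters at the boundary: a gene with p exactly equal to
#' `alpha` is not selected. No multiple-testing correction is applied: the
#' selection rule is a raw per-test threshold (alpha defaults to the very
#' stringent 1e-4).
#'
#' @param tests result of [ttest_all_timepoints()] (or a compatible list
#'   with `p`, `log_ratio`, `timepoints`).
#' @param alpha significance threshold (default `1e-4`).
#' @return a `responsive_table`: list with the input matrices, `alpha`,
#'   logical matrix `significant`, and per-gene data.frame `genes` with
#'   columns `gene`, `responsive`, `first_time`, `n_significant_timepoints`,
#'   `min_p`, `min_p_time`, `direction` (direction filled by
#'   [classify_direction()], which this function calls).
#' @export
select_responsive <- function(tests, alpha = 1e-4) {
  p <- tests$p
  if (any(p < 0 | p > 1)) stop("p-values outside [0,1]")
  sig <- p < alpha
  tps <- tests$timepoints
  first_idx <- apply(sig, 1L, function(s) if (any(s)) which(s)[1L] else NA_integer_)
  nsig <- rowSums(sig)
  # minimal p; ties broken toward the earlier timepoint (which.min is
  # first-index, columns are in ascending timepoint order)
  min_idx <- apply(p, 1L, which.min)
  genes <- data.frame(
    gene = rownames(p),
    responsive = nsig > 0L,
    first_time = tps[first_idx],
    n_significant_timepoints = as.integer(nsig),
    min_p = p[cbind(seq_len(nrow(p)), min_idx)],
    min_p_time = tps[min_idx],
    direction = NA_character_,
    row.names = NULL, stringsAsFactors = FALSE)
  tbl <- structure(list(p = p, log_ratio = tests$log_ratio,
                        significant = sig, timepoints = tps,
                        alpha = alpha, genes = genes),
                   class = "responsive_table")
  classify_direction(tbl)
}

#' Assign an up/down direction to each responsive gene
#'
#' Direction is read off the log-ratio at the gene's most significant
#' timepoint (minimal p; ties go to the earlier timepoint): positive means
#' up-regulated upon reoxygenation, otherwise down. A log-ratio of exactly
#' zero at that timepoint is labelled down by convention, with a warning.
#' Non-responsive genes keep `NA`.
#'
#' @param tbl a `responsive_table`.
#' @return the table with `genes$direction` filled in.
#' @export
classify_direction <- function(tbl) {
  g <- tbl$genes
  idx <- match(as.character(g$min_p_time), colnames(tbl$log_ratio))
  lr <- tbl$log_ratio[cbind(seq_len(nrow(g)), idx)]
  dir <- ifelse(lr > 0, "up", "down")
  zero <- g$responsive & lr == 0
  if (any(zero))
    warning(sum(zero), " responsive gene(s) with log-ratio exactly 0 at ",
            "the minimal-p timepoint; labelled 'down' by convention")
  g$direction <- ifelse(g$responsive, dir, NA_character_)
  tbl$genes <- g
  tbl
}

#' @export
print.responsive_table <- function(x, ...) {
  cat(sprintf(
    "Responsive-gene table: %d genes x %d timepoints, alpha = %g\n%s\n",
    nrow(x$p), length(x$timepoints), x$alpha,
    sprintf("  %d responsive (%d up, %d down)",
            sum(x$genes$responsive),
            sum(x$genes$direction == "up", na.rm = TRUE),
            sum(x$genes$direction == "down", na.rm = TRUE))))
  invisible(x)
}

#' Summarize response dynamics across the time course
#'
#' Bookkeeping behind the first-appearance bar chart: at each timepoint,
#' how many genes are significant, how many appear for the first time
#' (`n_new`), and how many had already appeared earlier (`n_repeat`); plus
#' global tallies of genes significant at exactly one, exactly two, or more
#' than two timepoints, and up/down totals. By construction
#' `n_significant = n_new + n_repeat` at every timepoint and
#' `n_one + n_two + n_more = n_up + n_down = n_responsive`.
#'
#' @param tbl a `responsive_table`.
#' @return list with `per_timepoint` data.frame (`timepoint_h`,
#'   `n_significant`, `n_new`, `n_repeat`, `repeat_fraction`) and scalar
#'   totals.
#' @export
summarize_dynamics <- function(tbl) {
  sig <- tbl$significant
  tps <- tbl$timepoints
  first <- tbl$genes$first_time
  per <- data.frame(timepoint_h = tps)
  per$n_significant <- as.integer(colSums(sig))
  per$n_new <- vapply(tps, function(t) sum(first == t, na.rm = TRUE), 1L)
  per$n_repeat <- per$n_significant - per$n_new
  per$repeat_fraction <- ifelse(per$n_significant > 0,
                                per$n_repeat / per$n_significant, NA_real_)
  nsig <- tbl$genes$n_significant_timepoints
  list(per_timepoint = per,
       n_responsive = sum(tbl$genes$responsive),
       n_one_timepoint = sum(nsig == 1L),
       n_two_timepoints = sum(nsig == 2L),
       n_more_than_two = sum(nsig > 2L),
       n_up = sum(tbl$genes$direction == "up", na.rm = TRUE),
       n_down = sum(tbl$genes$direction == "down", na.rm = TRUE))
}

#' Relative expression profiles against the baseline
#'
#' For each requested gene and timepoint, the mean log2 intensity at that
#' timepoint minus the mean at time 0 — the log2 fold-change relative to
#' the hypoxia control, the quantity plotted in time-course heatmaps. The
#' time-0 column is identically zero.
#'
#' @param m expression matrix, log2 scale expected.
#' @param design validated sample design.
#' @param genes character vector of gene ids (subset of rownames).
#' @return genes x timepoints numeric matrix (all timepoints, ascending,
#'   including 0).
#' @export
relative_profiles <- function(m, design, genes = rownames(m)) {
  unknown <- setdiff(genes, rownames(m))
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  tps <- sort(unique(design$timepoint_h))
  x <- unclass(m)[genes, , drop = FALSE]
  means <- vapply(tps, function(t) {
    rowMeans(x[, design$sample_id[design$timepoint_h == t], drop = FALSE])
  }, numeric(length(genes)))
  if (length(genes) == 1L) means <- matrix(means, nrow = 1L)
  dimnames(means) <- list(genes, as.character(tps))
  means - means[, "0"]
}

#' Write a responsive-gene table as TSV
#'
#' Long format: one row per gene x timepoint with p-value, log-ratio and
#' significance flag, joined with the per-gene summary columns.
#'
#' @param tbl a `responsive_table`.
#' @param path output TSV.
#' @param responsive_only keep only responsive genes (default TRUE).
#' @return `path`, invisibly.
#' @export
write_responsive_table <- function(tbl, path, responsive_only = TRUE) {
  long <- do.call(rbind, lapply(seq_along(tbl$timepoints), function(j) {
    data.frame(gene = rownames(tbl$p),
               timepoint_h = tbl$timepoints[j],
               p_value = tbl$p[, j],
               log_ratio = tbl$log_ratio[, j],
               significant = tbl$significant[, j],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  long <- merge(long, tbl$genes, by = "gene", sort = TRUE)
  if (responsive_only) long <- long[long$responsive, , drop = FALSE]
  long <- long[order(long$gene, long$timepoint_h), , drop = FALSE]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
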