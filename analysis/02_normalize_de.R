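#!/usr/bin/env Rscript
# Stage 2: normalization and per-timepoint differential expression.
#
# Quantile-normalizes the raw intensities, moves to log2, runs the pooled
# Student's t-test of every post-reoxygenation timepoint against the
# hypoxia control, and selects oxygen-responsive genes. The stringent
# production threshold (p < 1e-4, no multiple-testing correction) is
# reported next to the recovery-oriented alpha = 0.01 scoring against the
# simulation's ground truth.

suppressMessages(library(reoxflow))
fix <- "results/fixtures"
outdir <- "results/de"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

dat <- read_expression(file.path(fix, "expression.tsv"),
                       file.path(fix, "design.tsv"))
truth <- read.delim(file.path(fix, "truth.tsv"))

norm <- quantile_normalize(dat$values)
m <- to_log2(norm)
write_expression(norm, file.path(outdir, "normalized.tsv"))

tests <- ttest_all_timepoints(m, dat$design)

for (alpha in c(1e-4, 0.01)) {
  tbl <- select_responsive(tests, alpha = alpha)
  dyn <- summarize_dynamics(tbl)
  tag <- format(alpha, scientific = TRUE)
  write_responsive_table(tbl, file.path(outdir, sprintf(
    "responsive_alpha%s.tsv", tag)))
  jsonlite::write_json(dyn, file.path(outdir, sprintf(
    "dynamics_alpha%s.json", tag)), auto_unbox = TRUE, digits = NA)
  per <- dyn$per_timepoint
  cat(sprintf(
    "alpha = %g: %d responsive genes (%d up / %d down); per-timepoint n = %s; new = %s\n",
    alpha, dyn$n_responsive, dyn$n_up, dyn$n_down,
    paste(per$n_significant, collapse = "/"),
    paste(per$n_new, collapse = "/")))

  scored <- merge(tbl$genes, truth, by = "gene")
  recall <- with(scored, mean(responsive.x[responsive.y]))
  fdr_like <- with(scored, if (sum(responsive.x) > 0)
    mean(!responsive.y[responsive.x]) else NA)
  cat(sprintf("  vs truth: recall %.3f, false-discovery fraction %.3f\n",
              recall, fdr_like))
}

tbl <- select_responsive(tests, alpha = 0.01)
resp <- tbl$genes$gene[tbl$genes$responsive]
prof <- relative_profiles(m, dat$design, resp)
write.table(data.frame(gene = rownames(prof), prof, check.names = FALSE),
            file.path(outdir, "relative_profiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf(
  "relative profiles (log2 vs time 0) for %d genes -> %s\n",
  length(resp), file.path(outdir, "relative_profiles.tsv")))
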