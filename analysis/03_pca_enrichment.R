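#!/usr/bin/env Rscript
# Stage 3: sample PCA and pathway over-representation.
#
# PCA of the responsive-gene expression checks that replicates of a
# timepoint cluster and that timepoints order along the leading
# components; hypergeometric enrichment against the simulated pathway
# collection should single out the planted enriched set, overall and at
# the timepoints where its members are active.

suppressMessages(library(reoxflow))
fix <- "results/fixtures"
outdir <- "results/pathways"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

dat <- read_expression(file.path(fix, "expression.tsv"),
                       file.path(fix, "design.tsv"))
m <- to_log2(quantile_normalize(dat$values))
tests <- ttest_all_timepoints(m, dat$design)
tbl <- select_responsive(tests, alpha = 0.01)
resp <- tbl$genes$gene[tbl$genes$responsive]

pca <- pca_samples(m, resp, n_components = 2)
scores <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                     check.names = FALSE)
scores <- merge(scores, dat$design, by = "sample_id")
write.table(scores, file.path(outdir, "pca_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCA on %d responsive genes: PC1+PC2 explain %.1f%% of variance\n",
            length(resp), 100 * sum(pca$variance_explained)))
# replicate tightness vs timepoint spread on PC1
within <- mean(tapply(scores$PC1, scores$timepoint_h, sd))
between <- sd(tapply(scores$PC1, scores$timepoint_h, mean))
cat(sprintf("  PC1 spread between timepoints %.2f vs within replicates %.2f\n",
            between, within))

gsc <- read_gmt(file.path(fix, "pathways.gmt"),
                universe = rownames(m))
res <- enrich_by_timepoint(tbl, gsc, threshold = 0.01)
tab <- enrichment_table(res, threshold = 0.01)
write.table(tab, file.path(outdir, "enrichment_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- res[["any"]][1, ]
cat(sprintf("top enriched set overall: %s (k=%d/%d, p=%.2e)\n",
            top$set, top$k, top$K, top$p_value))
cat("per-timepoint table ->", file.path(outdir, "enrichment_table.tsv"),
    "\n")
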