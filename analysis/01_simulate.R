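#!/usr/bin/env Rscript
# Stage 1: generate the synthetic reoxygenation study.
#
# Emulates the target design — 6 timepoints (0 = hypoxia control, then 1,
# 4, 8, 12, 24 h of reoxygenation) x 3 replicates, ~2000 genes of which 5%
# respond with a sustained log2 step of 1.0-2.5 starting mostly at 8-12 h
# — plus a pathway collection with one genuinely enriched set, and
# promoter/3'UTR sequences with planted regulatory sites. Everything is
# written as plain text under results/fixtures/ with the ground truth
# alongside, so the later stages can be scored against what was planted.

suppressMessages(library(reoxflow))
seed <- 20260925L
outdir <- "results/fixtures"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(rng_seed = seed)
sim <- simulate_expression(cfg)
write_expression(sim$values, file.path(outdir, "expression.tsv"),
                 design = sim$design,
                 design_path = file.path(outdir, "design.tsv"))
write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# distinct derived seed: reusing the expression seed would replay the same
# RNG stream that drew the spiked genes and correlate the "random" sets
# with the truth
gsc <- simulate_gene_sets(sim$truth, n_sets = 20, set_size = 20,
                          enriched_set_overlap = 1.0, rng_seed = seed + 1L)
write_gmt(gsc, file.path(outdir, "pathways.gmt"))

# one crisp 8-mer matrix planted on both strands of random promoters
mat <- pwm("M_SYNTH", rbind(c(9, 0, 0, 0), c(0, 9, 0, 0), c(0, 0, 9, 0),
                            c(0, 0, 0, 9), c(9, 0, 0, 0), c(0, 9, 0, 0),
                            c(0, 0, 0, 9), c(0, 0, 9, 0)))
mir <- c(`mir-synth` = "UCAGUGCAUUACAGAACUUUGU")
seqs <- simulate_sequences(
  n_promoters = 10, promoter_length = 500, pwm = mat,
  planted_sites = data.frame(seq_index = 1:10,
                             start = as.integer(seq(25, 430,
                                                    length.out = 10)),
                             strand = rep(c("+", "-"), 5)),
  n_utrs = 10, utr_length = 300, mirna = mir,
  planted_seed_sites = data.frame(
    seq_index = 1:10, start = 50,
    edit_type = rep(c("perfect", "wobble", "mismatch", "deletion",
                      "insertion"), 2)),
  rng_seed = seed)
write_fasta(seqs$promoters, file.path(outdir, "promoters.fa"))
write_fasta(seqs$utrs, file.path(outdir, "utrs.fa"))
write_fasta(mir, file.path(outdir, "mirnas.fa"))
writeLines(c("NA M_SYNTH", apply(mat$counts, 1, paste, collapse = " ")),
           file.path(outdir, "pwms.txt"))
write.table(seqs$plants, file.path(outdir, "planted_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "simulated %d genes x %d samples (%d spiked responsive, %.0f%% up)\n",
  nrow(sim$values), ncol(sim$values), sum(sim$truth$responsive),
  100 * mean(sim$truth$direction[sim$truth$responsive] == "up")))
cat(sprintf("pathways: %d sets (1 enriched by construction); %s\n",
            length(gsc$sets),
            "10 promoters + 10 UTRs with planted sites"))
cat("fixtures written under", outdir, "\n")
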