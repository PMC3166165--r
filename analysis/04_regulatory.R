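#!/usr/bin/env Rscript
# Stage 4: regulatory-sequence searches on the simulated promoters/UTRs.
#
# Scans both strands of each promoter with the PWM (core similarity >=
# 0.75, matrix similarity >= 0.80) and searches each 3'UTR for
# seed-complementary sites of the miRNA allowing one mismatch, G:U
# wobble, deletion, or insertion. Recovery is scored against the planted
# site records from stage 1.

suppressMessages(library(reoxflow))
fix <- "results/fixtures"
outdir <- "results/regulatory"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

promoters <- read_fasta(file.path(fix, "promoters.fa"), "DNA")
utrs <- read_fasta(file.path(fix, "utrs.fa"), "DNA")
mirnas <- read_fasta(file.path(fix, "mirnas.fa"), "RNA")
pwms <- read_pwm(file.path(fix, "pwms.txt"))
plants <- read.delim(file.path(fix, "planted_sites.tsv"))

tf <- scan_pwm(promoters, pwms, core_min = 0.75, matrix_min = 0.80)
write_hits(tf, file.path(outdir, "tf_hits.bed"))
pw <- plants[plants$kind == "pwm_consensus", ]
rec <- vapply(seq_len(nrow(pw)), function(k)
  any(tf$seq_id == pw$seq_id[k] & tf$start == pw$start[k] &
        tf$strand == pw$strand[k]), logical(1))
cat(sprintf("PWM scan: %d hits; %d/%d planted consensus sites recovered (%d on - strand)\n",
            nrow(tf), sum(rec), nrow(pw),
            sum(pw$strand == "-" & rec)))

seeds <- scan_seed_sites(utrs, mirnas)
seeds$name <- paste(seeds$mirna, seeds$edit_type, sep = ":")
write_hits(seeds, file.path(outdir, "seed_hits.bed"))
sp <- plants[plants$kind == "seed_site", ]
srec <- vapply(seq_len(nrow(sp)), function(k)
  any(seeds$seq_id == sp$seq_id[k] & seeds$start == sp$start[k] &
        seeds$end == sp$end[k] & seeds$edit_type == sp$edit_type[k]),
  logical(1))
cat(sprintf("seed search: %d sites; %d/%d planted single-edit sites recovered with their labels\n",
            nrow(seeds), sum(srec), nrow(sp)))
cat(sprintf("  by type: %s\n",
            paste(names(table(seeds$edit_type)), table(seeds$edit_type),
                  sep = "=", collapse = ", ")))

# calibrated per-matrix threshold from shuffled background
opt <- optimize_matrix_min(promoters, pwms, n_shuffles = 3, seed = 1)
tf_opt <- scan_pwm(promoters, pwms, core_min = 0.75,
                   matrix_min = unname(opt[1]))
cat(sprintf("background-calibrated matrix_min = %.3f -> %d hits\n",
            opt[1], nrow(tf_opt)))
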