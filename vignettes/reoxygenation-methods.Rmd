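---
title: "Methods: expression dynamics and regulatory-sequence searches during reoxygenation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression dynamics and regulatory-sequence searches during reoxygenation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

reoxflow analyses what happens to a tumor cell transcriptome when oxygen
returns after a hypoxic episode. The experimental template is a bulk
expression time course: cells held under severe hypoxia, then shifted to
normoxia and sampled at 0 h (the hypoxia control), 1, 4, 8, 12 and 24 h of
reoxygenation, three independent replicates per timepoint, one array per
sample. This vignette describes each statistical step, the tunable
parameters and their defaults, the synthetic-data generator the tests are
scored against, and the design decisions taken where the procedure was
genuinely open.

## Normalization and analysis scale

Input intensities are assumed background-adjusted; no background model is
implemented. `quantile_normalize()` forces every sample onto the common
distribution of across-sample rank means: sort each column, average across
columns at each rank, hand each value the reference value of its rank.
Ties within a column receive the mean of the reference values over the
tied span, which makes the map deterministic. Two consequences worth
knowing:

* On tie-free data the transform is exactly idempotent and every column
  ends up with the identical sorted vector. With ties, the span-averaging
  collapses reference values, so column multisets can differ slightly and
  a second application is no longer a strict no-op. We judged the
  deterministic averaging convention more valuable than formal
  idempotence under ties; integer-quantized intensities are the only
  common case where this surfaces.
* Downstream statistics run on `log2(value + offset)` by default
  (`log_offset = 1`), the standard variance-stabilizing choice for array
  t-tests. The scale is a configuration switch (`analysis_scale:
  log2|linear`) because the original analysis does not state it; log2 is
  the default and the one the tests exercise.

## Responsive-gene selection

For each post-baseline timepoint `t`, `ttest_vs_baseline()` runs a
two-sided two-sample Student's t-test with pooled variance (df
`n1 + n2 - 2`) of the replicates at `t` against the hypoxia control. The
pooled form (rather than Welch) is deliberate: "Student's t-test" as
named, and with 3 replicates per group there is no room to estimate
separate variances usefully. The log-ratio is the difference of group
means on the analysis scale, i.e. the log2 fold-change.

A gene is *oxygen-responsive* when p < alpha at one or more timepoints,
with strict inequality at the boundary and **no multiple-testing
correction** — the selection rule is a raw per-test threshold, and the
production default alpha = 1e-4 is stringent precisely because it is
uncorrected. This should be understood as a labelling rule, not an
error-rate guarantee: with ~2000 genes and 5 timepoints, alpha = 0.01
uncorrected admits a substantial false-discovery fraction (the synthetic
runs measure it at roughly 45% under the default noise model), while
alpha = 1e-4 with n = 3 per group has limited power. Both thresholds are
kept: 1e-4 as the production default, 0.01 for power/recovery scoring.

Degenerate variance (all six values identical up to group means) is not
floored by default; a zero pooled variance with unequal means is treated
as infinitely significant (p = 0) with a warning and a counter, and a
`var_floor` is available for integer-valued or otherwise quantized data.

Bookkeeping then follows the time axis: `first_time` is the earliest
significant timepoint; per timepoint, genes split into newly identified
(`n_new`) versus already seen (`n_repeat`), which is how the
activation window of the transcriptional response is read off;
`direction` (up/down) is taken from the log-ratio at the gene's
minimal-p timepoint, ties resolved toward the earlier timepoint, and an
exact-zero log-ratio there labelled "down" by convention with a warning.
A gene significant at several timepoints with mixed signs is thus
labelled by its most significant response, a choice the original
procedure leaves open. `relative_profiles()` exports the heat-map
quantity: mean log2 at each timepoint minus mean log2 at time 0.

## PCA

`pca_samples()` performs sample-level PCA of the responsive-gene
submatrix (full matrix on request): genes are mean-centered across
samples, not scaled to unit variance — after quantile normalization all
samples share one intensity scale, and unit-variance scaling would
up-weight flat genes. Scores come from `stats::prcomp`; each component's
sign is fixed by making its largest-magnitude loading positive, so
results are reproducible across platforms. Replicate tightness and the
ordering of timepoints along PC1/PC2 are the intended readouts.

## Pathway over-representation

`hypergeom_enrich()` computes, per gene set, the upper-tail
hypergeometric probability of the observed overlap between the
responsive-gene query and the set. The universe is the analyzed matrix's
gene complement, not the genome, because selection was performed over
the array. The test statistic is the standard over-representation choice;
the database behind the original pathway table is a web service whose
exact statistic is unpublished, so numerical equivalence with that table
is not asserted anywhere — the structure (overall column plus one column
per timepoint, dashes where p >= 0.01, raw uncorrected p-values,
minimum overlap of one gene) is what the package reproduces via
`enrich_by_timepoint()` and `enrichment_table()`. Gene identifiers are
opaque strings throughout; probe-to-gene collapsing is left to the caller
because the array-to-gene mapping is many-to-one and any collapsing rule
would silently change universe sizes.

## Promoter PWM scanning

Matrices arrive as TRANSFAC-like count blocks and are converted to
per-position frequencies with a configurable pseudocount (default 0).
The per-position conservation index is entropy-based,
`ci = 100 (1 - H / ln 4)` with H the Shannon entropy in nats: 100 at an
invariant position, 0 at a uniform one. The published method's exact
index formula is proprietary; any index strictly decreasing in entropy
chooses the same core on untied inputs, which is the only role the index
plays, so the entropy form is recorded as this package's convention and
kept behind one function. The *core* is the 4 consecutive positions with
the highest summed ci (leftmost on ties).

A window of PWM length scores

    score = sum_i ci(i) f(i, base_i) / sum_i ci(i) max_b f(i, b)

over the region's positions — matrix similarity over all positions, core
similarity over the 4 core positions — so the consensus scores exactly 1
and the score is invariant to rescaling counts. `scan_pwm()` slides every
matrix over both strands (the minus strand scores the reverse complement
of the window) and reports windows with core similarity >= 0.75 (the
published cutoff) and matrix similarity >= `matrix_min`. The published
pipeline "optimizes" the matrix threshold opaquely;
`optimize_matrix_min()` offers a transparent stand-in — the maximum score
seen in composition-preserving shuffles of the input — and otherwise a
plain threshold (default 0.80) applies.

## miRNA seed-site search

The seed is nucleotides 2–7 of the mature miRNA. A site is a UTR
substring pairing antiparallel with the seed under at most one departure
from Watson–Crick pairing: one G:U wobble, one mismatch, one deleted
target base (site length 5), or one extra target base inside the site
(length 7). U/T are unified internally; only the sense strand is
searched, mRNA being single-stranded. Sites admitting several
explanations take the least-edited label (perfect > wobble > mismatch;
the length-changing edits cannot collide with the others). Edits are
allowed at the seed boundary positions 2 and 7 by default — the published
wording ("between the second and seventh nucleotides") is ambiguous — and
`interior_only = TRUE` restricts them to positions 3–6. All qualifying
windows are reported, overlapping ones included; note that the 5-mer
flanks of a perfect 6-mer site necessarily qualify as deletion sites
under this definition, so downstream site *counts* depend on a
deduplication policy, which is why the hit table keeps every interval and
leaves deduplication to the caller.

The test suite checks this scanner exactly — interval, label and edit
position — against an independent brute-force oracle that literally
enumerates every single-edit site string and matches it against every
UTR window.

## The synthetic study and what it does (not) show

`simulate_expression()` generates the fixture every statistical claim is
scored against: 2000 genes x 6 timepoints x 3 replicates; 5% of genes
responsive; onset drawn from {4, 8, 12} h with weights 0.2/0.4/0.4
(placing the activation window at 8–12 h); absolute log2 effects uniform
on [1.0, 2.5]; 53% of responses upward; sustained step response from the
onset onward (a transient pulse is a config option); i.i.d. Gaussian
noise, SD 0.25 on log2; per-gene baselines uniform on log2 [6, 12]; the
matrix exported on the linear scale so normalization is exercised. These
values were fixed once as a realistic caricature of triplicate BeadChip
data and are not tuned per test.

What the generator does *not* emulate: probe-level structure and
probe-to-gene multiplicity, intensity-dependent (heteroskedastic) noise,
correlated genes, batch or chip effects, and distribution differences
between samples before normalization beyond what sampling noise creates.
Passing recovery tests therefore demonstrate correctness of the
statistical machinery under the stated error model, not performance on
real arrays.

Two measurement choices deserve a note. First, recovery ("do we find
what was planted?") is scored at alpha = 0.01 on spiked genes with onset
8 h: alpha = 1e-4 with n = 3 is deliberately stringent and would conflate
the selection rule's stringency with implementation defects. Second,
recall is pooled over ten replicate simulations (~400 onset-8 genes)
rather than one: a gene's tests at different timepoints share the same
three baseline replicates, so misses are correlated and a single
simulation's ~35 genes estimate recall with considerable noise. The
pooled estimate sits near 0.96 under the default conditions.

Problem sizes throughout the tests and the acceptance script (2000-gene
simulations, 120–300 nt sequences, 200 oracle comparisons) were chosen so
the full suite runs in about a minute on one CPU while keeping every
binomial check adequately powered.

## Degenerate inputs and numerical conventions

* Coordinates: 0-based half-open in memory and on disk (BED convention);
  1-based inclusive in log messages.
* Single-sample matrices pass through normalization unchanged, with a
  warning.
* An all-uniform PWM region (total conservation zero) scores 1 against
  any window: with nothing informative to match, no window can be worse
  than any other.
* Windows containing bases outside A/C/G/T are skipped and counted, not
  errors: masked repeats and ambiguity codes are expected in real
  promoter extracts.
* Empty queries, empty timepoints and empty GMT files yield empty —
  never missing — results, so per-timepoint tables keep their shape
  (a timepoint with zero significant genes is a real column).
* All randomness flows through explicit integer seeds; reruns are
  byte-identical, which the pipeline manifest verifies with checksums.

## Limitations

The t-test is unmoderated — no information sharing across genes (as an
empirical-Bayes approach would provide) — and uncorrected, both faithful
to the procedure being reproduced and both poor choices for a de novo
study design. The enrichment universe convention (array, not genome)
changes p-values relative to web tools. The PWM similarity and the
tolerant seed search reproduce published *criteria*, not the proprietary
implementations around them, so site lists on real sequences will differ
from the original supplementary tables wherever those tools applied
additional undocumented filters.
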