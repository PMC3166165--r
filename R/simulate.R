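#' Configuration for the synthetic reoxygenation time course
#'
#' Defaults emulate the study design the pipeline targets: 6 timepoints
#' (0, 1, 4, 8, 12, 24 h after reoxygenation) x 3 replicates on a log2
#' intensity scale, with a small fraction of genes responding in a
#' sustained (step) fashion from an onset drawn mostly at 8-12 h — the
#' window where the transcriptional response is activated — slightly more
#' up- than down-regulation, and i.i.d. Gaussian replicate noise on the
#' log2 scale.
#'
#' @param n_genes number of genes (default 2000).
#' @param timepoints_h sampling times in hours (default
#'   `c(0, 1, 4, 8, 12, 24)`).
#' @param n_replicates replicates per timepoint (default 3).
#' @param fraction_responsive fraction of spiked genes (default 0.05).
#' @param onset_times_h possible onset times (default `c(4, 8, 12)`).
#' @param onset_weights sampling weights over `onset_times_h` (default
#'   `c(0.2, 0.4, 0.4)`).
#' @param effect_size_log2 range of absolute effect sizes in log2 units
#'   (default `c(1.0, 2.5)`).
#' @param direction_up_prob probability a spiked gene goes up (default
#'   0.53).
#' @param noise_sd_log2 replicate noise SD on log2 scale (default 0.25).
#' @param baseline_log2 range of per-gene baseline log2 intensities
#'   (default `c(6, 12)`).
#' @param response_shape `"step"` (sustained, default) or `"pulse"`
#'   (transient: effect at the onset timepoint only).
#' @param rng_seed integer seed; mandatory for reproducibility.
#' @return classed list of settings.
#' @export
simulation_config <- function(n_genes = 2000L,
                              timepoints_h = c(0, 1, 4, 8, 12, 24),
                              n_replicates = 3L,
                              fraction_responsive = 0.05,
                              onset_times_h = c(4, 8, 12),
                              onset_weights = c(0.2, 0.4, 0.4),
                              effect_size_log2 = c(1.0, 2.5),
                              direction_up_prob = 0.53,
                              noise_sd_log2 = 0.25,
                              baseline_log2 = c(6, 12),
                              response_shape = c("step", "pulse"),
                              rng_seed) {
  response_shape <- match.arg(response_shape)
  if (missing(rng_seed) || !is.finite(rng_seed))
    stop("rng_seed is mandatory")
  stopifnot(n_genes >= 1L, n_replicates >= 2L,
            fraction_responsive >= 0, fraction_responsive <= 1,
            direction_up_prob >= 0, direction_up_prob <= 1,
            noise_sd_log2 >= 0,
            length(effect_size_log2) == 2L,
            effect_size_log2[1] <= effect_size_log2[2],
            length(baseline_log2) == 2L,
            baseline_log2[1] <= baseline_log2[2],
            0 %in% timepoints_h,
            length(onset_weights) == length(onset_times_h),
            all(onset_weights >= 0), sum(onset_weights) > 0,
            all(onset_times_h %in% timepoints_h))
  structure(list(n_genes = as.integer(n_genes),
                 timepoints_h = sort(unique(timepoints_h)),
                 n_replicates = as.integer(n_replicates),
                 fraction_responsive = fraction_responsive,
                 onset_times_h = onset_times_h,
                 onset_weights = onset_weights / sum(onset_weights),
                 effect_size_log2 = effect_size_log2,
                 direction_up_prob = direction_up_prob,
                 noise_sd_log2 = noise_sd_log2,
                 baseline_log2 = baseline_log2,
                 response_shape = response_shape,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Simulate a reoxygenation expression time course with ground truth
#'
#' Per gene, the log2 intensity is a baseline plus, for spiked
#' (responsive) genes, a signed step effect from the onset timepoint
#' onward (or a pulse at the onset only), plus i.i.d. Gaussian noise per
#' sample. The matrix is exported on the linear scale (2^log2) so the
#' preprocessing stage is exercised. Identical seeds give identical
#' output.
#'
#' @param cfg a [simulation_config()].
#' @return list with `values` (linear-scale [expression_matrix()]),
#'   `design` (sample design data.frame), `truth` (per-gene data.frame:
#'   `gene`, `responsive`, `onset_h`, `direction`, `effect_log2`), and
#'   `config`.
#' @export
simulate_expression <- function(cfg) {
  set.seed(cfg$rng_seed)
  tps <- cfg$timepoints_h
  design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        timepoint_h = tps)
  design <- data.frame(
    sample_id = sprintf("t%g_r%d", design$timepoint_h, design$replicate),
    timepoint_h = design$timepoint_h,
    replicate = design$replicate,
    stringsAsFactors = FALSE)
  ng <- cfg$n_genes
  gene_ids <- sprintf("g%05d", seq_len(ng))
  n_spiked <- round(cfg$fraction_responsive * ng)
  if (cfg$fraction_responsive > 0 && n_spiked < 1L)
    warning("fraction_responsive * n_genes < 1; no genes spiked")
  spiked <- sort(sample.int(ng, n_spiked))
  truth <- data.frame(gene = gene_ids, responsive = FALSE,
                      onset_h = NA_real_, direction = NA_character_,
                      effect_log2 = 0, stringsAsFactors = FALSE)
  truth$responsive[spiked] <- TRUE
  truth$onset_h[spiked] <- cfg$onset_times_h[
    sample.int(length(cfg$onset_times_h), n_spiked, replace = TRUE,
               prob = cfg$onset_weights)]
  truth$direction[spiked] <- ifelse(
    stats::runif(n_spiked) < cfg$direction_up_prob, "up", "down")
  truth$effect_log2[spiked] <- stats::runif(
    n_spiked, cfg$effect_size_log2[1], cfg$effect_size_log2[2]) *
    ifelse(truth$direction[spiked] == "up", 1, -1)
  baseline <- stats::runif(ng, cfg$baseline_log2[1], cfg$baseline_log2[2])
  signal <- matrix(baseline, nrow = ng, ncol = nrow(design))
  for (j in seq_len(nrow(design))) {
    t <- design$timepoint_h[j]
    on <- if (cfg$response_shape == "step") {
      truth$responsive & !is.na(truth$onset_h) & t >= truth$onset_h
    } else {
      truth$responsive & !is.na(truth$onset_h) & t == truth$onset_h
    }
    signal[on, j] <- signal[on, j] + truth$effect_log2[on]
  }
  noise <- matrix(stats::rnorm(ng * nrow(design), sd = cfg$noise_sd_log2),
                  nrow = ng)
  log2_values <- signal + noise
  values <- 2^log2_values
  dimnames(values) <- list(gene_ids, design$sample_id)
  list(values = expression_matrix(values, scale = "linear"),
       design = validate_design(design),
       truth = truth, config = cfg)
}

#' Simulate a gene-set collection with one designated enriched set
#'
#' Builds `n_sets` sets over the simulated gene universe: the first set
#' (`"enriched_set"`) draws `round(overlap * set_size)` members from the
#' responsive genes and the rest from non-responsive genes; the remaining
#' sets are drawn uniformly from the universe. With `overlap` near the
#' background responsive fraction, the designated set is null.
#'
#' @param truth ground-truth data.frame from [simulate_expression()].
#' @param n_sets number of sets (0 gives an empty collection).
#' @param set_size members per set (default 20).
#' @param enriched_set_overlap fraction of the designated set drawn from
#'   responsive genes (default 1.0).
#' @param rng_seed integer seed.
#' @return a `gene_set_collection` with the simulated genes as universe.
#' @export
simulate_gene_sets <- function(truth, n_sets, set_size = 20L,
                               enriched_set_overlap = 1.0, rng_seed = 1L) {
  if (enriched_set_overlap > 1 || enriched_set_overlap < 0)
    stop("enriched_set_overlap must be in [0, 1]")
  set.seed(rng_seed)
  universe <- truth$gene
  if (n_sets == 0L)
    return(gene_set_collection(list(), universe = universe))
  resp <- truth$gene[truth$responsive]
  nonresp <- truth$gene[!truth$responsive]
  n_from_resp <- round(enriched_set_overlap * set_size)
  if (n_from_resp > length(resp))
    stop("not enough responsive genes for the requested overlap")
  sets <- list(enriched_set = c(sample(resp, n_from_resp),
                                sample(nonresp, set_size - n_from_resp)))
  if (n_sets > 1L) {
    for (i in seq_len(n_sets - 1L)) {
      sets[[sprintf("random_set_%02d", i)]] <- sample(universe, set_size)
    }
  }
  gene_set_collection(sets, universe = universe)
}

# build the literal site string for one planted edit type
.planted_site <- function(seed, edit_type) {
  schars <- strsplit(seed, "", fixed = TRUE)[[1L]]
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  perfect <- rev(unname(wc[schars]))   # site 5'->3'
  if (edit_type == "perfect") return(paste(perfect, collapse = ""))
  if (edit_type == "wobble") {
    cand <- which(schars %in% c("G", "U"))
    if (!length(cand)) stop("seed has no G or U: wobble plant impossible")
    d <- cand[1L]
    perfect[7L - d] <- if (schars[d] == "G") "U" else "G"
    return(paste(perfect, collapse = ""))
  }
  if (edit_type == "mismatch") {
    d <- 1L
    bad <- setdiff(c("A", "C", "G", "U"),
                   c(wc[[schars[d]]],
                     if (schars[d] == "G") "U",
                     if (schars[d] == "U") "G"))
    perfect[7L - d] <- bad[1L]
    return(paste(perfect, collapse = ""))
  }
  if (edit_type == "deletion") {
    return(paste(rev(unname(wc[schars[-3L]])), collapse = ""))
  }
  if (edit_type == "insertion") {
    return(paste(c(perfect[1:3], "A", perfect[4:6]), collapse = ""))
  }
  stop("unknown edit type: ", edit_type)
}

#' Simulate promoter and 3'UTR sequences with planted sites
#'
#' Uniform-random background sequences with, at recorded coordinates, a
#' PWM consensus (forward or reverse-complemented, per strand) planted in
#' the promoters and single-edit seed-site variants planted in the UTRs,
#' enabling plant-and-recover tests of the scanners. Plants within one
#' sequence must not overlap.
#'
#' @param n_promoters,promoter_length background promoter count/length.
#' @param pwm a [pwm()] whose consensus gets planted.
#' @param planted_sites data.frame with columns `seq_index`, `start`
#'   (0-based), `strand` (`"+"`/`"-"`); NULL for no plants.
#' @param n_utrs,utr_length background UTR count/length.
#' @param mirna named character string: mature miRNA (>= 7 nt).
#' @param planted_seed_sites data.frame with columns `seq_index`, `start`
#'   (0-based), `edit_type`; NULL for no plants.
#' @param rng_seed integer seed.
#' @return list with `promoters`, `utrs` (named character vectors, DNA
#'   alphabet) and `plants` (data.frame of what was planted where:
#'   `seq_id`, `start`, `end`, `kind`, `strand`, `edit_type`).
#' @export
simulate_sequences <- function(n_promoters = 0L, promoter_length = 500L,
                               pwm = NULL, planted_sites = NULL,
                               n_utrs = 0L, utr_length = 300L,
                               mirna = NULL, planted_seed_sites = NULL,
                               rng_seed = 1L) {
  set.seed(rng_seed)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  plant <- function(seqs, df, strings, kind) {
    for (k in seq_len(nrow(df))) {
      i <- df$seq_index[k]
      s <- df$start[k] + 1L                       # to 1-based
      site <- strings[k]
      e <- s + nchar(site) - 1L
      if (e > nchar(seqs[[i]]))
        stop(kind, " plant does not fit: sequence ", i, ", interval ",
             s, "-", e, " (1-based)")
      prior <- df[seq_len(k - 1L), , drop = FALSE]
      prior <- prior[prior$seq_index == i, , drop = FALSE]
      if (nrow(prior)) {
        pe <- prior$start + nchar(strings[seq_len(k - 1L)][
          df$seq_index[seq_len(k - 1L)] == i])
        if (any(df$start[k] < pe & prior$start < df$start[k] + nchar(site)))
          stop("overlapping plants in sequence ", i)
      }
      substr(seqs[[i]], s, e) <- site
    }
    seqs
  }
  promoters <- character(0); utrs <- character(0)
  plants <- list()
  if (n_promoters > 0L) {
    promoters <- vapply(seq_len(n_promoters), function(i)
      rand_seq(promoter_length), character(1))
    names(promoters) <- sprintf("promoter_%02d", seq_len(n_promoters))
    if (!is.null(planted_sites) && nrow(planted_sites)) {
      if (is.null(pwm)) stop("planted_sites given without a pwm")
      consensus <- paste(colnames(pwm$freq)[max.col(pwm$freq, "first")],
                         collapse = "")
      strings <- ifelse(planted_sites$strand == "+", consensus,
                        vapply(rep(consensus, nrow(planted_sites)),
                               .revcomp_dna, character(1),
                               USE.NAMES = FALSE))
      promoters <- plant(promoters, planted_sites, strings, "PWM")
      plants[[length(plants) + 1L]] <- data.frame(
        seq_id = names(promoters)[planted_sites$seq_index],
        start = planted_sites$start,
        end = planted_sites$start + nchar(strings),
        kind = "pwm_consensus", strand = planted_sites$strand,
        edit_type = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (n_utrs > 0L) {
    utrs <- vapply(seq_len(n_utrs), function(i)
      rand_seq(utr_length), character(1))
    names(utrs) <- sprintf("utr_%02d", seq_len(n_utrs))
    if (!is.null(planted_seed_sites) && nrow(planted_seed_sites)) {
      if (is.null(mirna)) stop("planted_seed_sites given without a mirna")
      seed <- substr(.U(mirna[[1L]]), 2L, 7L)
      strings <- vapply(planted_seed_sites$edit_type, function(et)
        chartr("U", "T", .planted_site(seed, et)), character(1),
        USE.NAMES = FALSE)
      utrs <- plant(utrs, planted_seed_sites, strings, "seed")
      plants[[length(plants) + 1L]] <- data.frame(
        seq_id = names(utrs)[planted_seed_sites$seq_index],
        start = planted_seed_sites$start,
        end = planted_seed_sites$start + nchar(strings),
        kind = "seed_site", strand = "+",
        edit_type = planted_seed_sites$edit_type, stringsAsFactors = FALSE)
    }
  }
  plants <- if (length(plants)) do.call(rbind, plants) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               kind = character(), strand = character(),
               edit_type = character(), stringsAsFactors = FALSE)
  list(promoters = promoters, utrs = utrs, plants = plants)
}
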