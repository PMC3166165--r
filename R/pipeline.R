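#' Build a run configuration for the end-to-end pipeline
#'
#' Collects the input paths and the analysis parameters (defaults are the
#' study's printed thresholds: selection alpha 1e-4, enrichment threshold
#' 0.01, core similarity 0.75).
#'
#' @param expression,design paths to the expression and design TSVs.
#' @param gmt optional path to a pathway GMT.
#' @param promoters,pwms optional paths to promoter FASTA and PWM text.
#' @param utrs,mirnas optional paths to 3'UTR FASTA and mature-miRNA FASTA.
#' @param alpha responsive-gene p threshold (default 1e-4).
#' @param enrich_threshold enrichment p threshold (default 0.01).
#' @param core_min,matrix_min PWM scan thresholds (defaults 0.75, 0.80).
#' @param interior_only seed-search boundary policy (default FALSE).
#' @param analysis_scale `"log2"` (default) or `"linear"`: scale on which
#'   the t-tests run.
#' @param log_offset offset for the log2 transform (default 1).
#' @param var_floor pooled-variance floor for the t-tests (default 0).
#' @param n_components PCA components (default 2).
#' @return classed list.
#' @export
run_config <- function(expression, design, gmt = NULL,
                       promoters = NULL, pwms = NULL,
                       utrs = NULL, mirnas = NULL,
                       alpha = 1e-4, enrich_threshold = 0.01,
                       core_min = 0.75, matrix_min = 0.80,
                       interior_only = FALSE,
                       analysis_scale = c("log2", "linear"),
                       log_offset = 1, var_floor = 0,
                       n_components = 2L) {
  analysis_scale <- match.arg(analysis_scale)
  structure(list(expression = expression, design = design, gmt = gmt,
                 promoters = promoters, pwms = pwms, utrs = utrs,
                 mirnas = mirnas, alpha = alpha,
                 enrich_threshold = enrich_threshold, core_min = core_min,
                 matrix_min = matrix_min, interior_only = interior_only,
                 analysis_scale = analysis_scale, log_offset = log_offset,
                 var_floor = var_floor,
                 n_components = as.integer(n_components)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the whole reoxygenation analysis
#'
#' Orchestrates the six stages — normalize, de, dynamics, pca, enrichment,
#' regulatory — over one configuration and writes every stage's table plus
#' a JSON manifest into `outdir`. Stages whose inputs are not configured
#' (no GMT, no sequences) are recorded as skipped in the manifest. The
#' manifest carries the package version, a checksum of the configuration,
#' input-file checksums (recorded before and verified after the run, so no
#' stage can silently mutate an input), and per-stage row counts; reruns
#' on identical inputs and configuration are bit-identical.
#'
#' @param cfg a [run_config()].
#' @param outdir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_all <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inputs <- unlist(cfg[c("expression", "design", "gmt", "promoters",
                         "pwms", "utrs", "mirnas")])
  checksums <- tools::md5sum(inputs)
  manifest <- list(package = "reoxflow",
                   version = as.character(utils::packageVersion("reoxflow")),
                   config = unclass(cfg),
                   config_md5 = .object_md5(unclass(cfg)),
                   inputs = as.list(checksums),
                   stages = list())
  note <- function(name, status, rows) {
    manifest$stages[[name]] <<- list(status = status, rows = rows)
  }

  dat <- .stage("normalize", {
    x <- read_expression(cfg$expression, cfg$design)
    norm <- quantile_normalize(x$values)
    analysed <- if (cfg$analysis_scale == "log2")
      to_log2(norm, offset = cfg$log_offset) else norm
    write_expression(norm, file.path(outdir, "normalized.tsv"))
    list(m = analysed, design = x$design)
  })
  note("normalize", "ok", nrow(dat$m))

  tbl <- .stage("de", {
    tests <- ttest_all_timepoints(dat$m, dat$design,
                                  var_floor = cfg$var_floor)
    tbl <- select_responsive(tests, alpha = cfg$alpha)
    write_responsive_table(tbl, file.path(outdir, "responsive.tsv"))
    tbl
  })
  note("de", "ok", sum(tbl$genes$responsive))

  dyn <- .stage("dynamics", {
    dyn <- summarize_dynamics(tbl)
    jsonlite::write_json(dyn, file.path(outdir, "dynamics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    resp <- tbl$genes$gene[tbl$genes$responsive]
    if (length(resp)) {
      prof <- relative_profiles(dat$m, dat$design, resp)
      utils::write.table(
        data.frame(gene = rownames(prof), prof, check.names = FALSE),
        file.path(outdir, "relative_profiles.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    dyn
  })
  note("dynamics", "ok", nrow(dyn$per_timepoint))

  pca <- .stage("pca", {
    genes <- tbl$genes$gene[tbl$genes$responsive]
    if (length(genes) < cfg$n_components) genes <- rownames(dat$m)
    pca <- pca_samples(dat$m, genes, n_components = cfg$n_components)
    utils::write.table(
      data.frame(sample_id = rownames(pca$scores), pca$scores,
                 check.names = FALSE),
      file.path(outdir, "pca_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    pca
  })
  note("pca", "ok", nrow(pca$scores))

  if (!is.null(cfg$gmt)) {
    enr <- .stage("enrichment", {
      sets <- read_gmt(cfg$gmt, universe = rownames(dat$m))
      res <- enrich_by_timepoint(tbl, sets,
                                 threshold = cfg$enrich_threshold)
      table1 <- enrichment_table(res, threshold = cfg$enrich_threshold)
      utils::write.table(table1, file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
    note("enrichment", "ok", sum(vapply(enr, nrow, 1L)))
  } else note("enrichment", "skipped", 0L)

  if (!is.null(cfg$promoters) || !is.null(cfg$utrs)) {
    reg <- .stage("regulatory", {
      n <- 0L
      if (!is.null(cfg$promoters)) {
        seqs <- read_fasta(cfg$promoters, "DNA")
        pwms <- read_pwm(cfg$pwms)
        tf <- scan_pwm(seqs, pwms, core_min = cfg$core_min,
                       matrix_min = cfg$matrix_min)
        write_hits(tf, file.path(outdir, "tf_hits.bed"))
        n <- n + nrow(tf)
      }
      if (!is.null(cfg$utrs)) {
        utrs <- read_fasta(cfg$utrs, "DNA")
        mirnas <- read_fasta(cfg$mirnas, "RNA")
        seeds <- scan_seed_sites(utrs, mirnas,
                                 interior_only = cfg$interior_only)
        seeds$name <- paste(seeds$mirna, seeds$edit_type, sep = ":")
        write_hits(seeds, file.path(outdir, "seed_hits.bed"))
        n <- n + nrow(seeds)
      }
      n
    })
    note("regulatory", "ok", reg)
  } else note("regulatory", "skipped", 0L)

  after <- tools::md5sum(inputs)
  if (!identical(unname(checksums), unname(after)))
    stop("input file(s) changed during the run: ",
         paste(names(checksums)[checksums != after], collapse = ", "))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# md5 of a canonical serialization (version-2, so stable across R >= 3.5)
.object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
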