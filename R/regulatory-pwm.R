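# Promoter PWM scanning with conservation-weighted core/matrix similarity.
# The conservation index weights each matrix position by how invariant it
# is; the 4-position window with the highest total conservation is the
# "core", and candidate sites must match the core well before the full
# matrix score is consulted.

#' Per-position conservation profile of a PWM
#'
#' The conservation index ci(i) is an entropy-based information measure of
#' position i's base frequencies: `ci = 100 * (1 - H/ln 4)` with H the
#' Shannon entropy in nats, so an invariant position scores 100 and a
#' uniform one 0. The core region is the 4 consecutive positions
#' maximizing the summed ci (leftmost window on ties). Any index strictly
#' decreasing in entropy selects the same core on untied inputs; this one
#' is recorded as the package's convention.
#'
#' @param pwm a [pwm()] object.
#' @return list with `ci` (numeric per position, 0-100) and `core_start`
#'   (1-based index of the core's first position), class
#'   `"conservation_profile"`.
#' @export
conservation_index <- function(pwm) {
  f <- pwm$freq
  if (any(abs(rowSums(f) - 1) > 1e-9))
    stop("PWM '", pwm$name, "': frequencies must sum to 1 per position")
  H <- apply(f, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  ci <- 100 * (1 - H / log(4))
  core_sums <- vapply(seq_len(length(ci) - 3L),
                      function(s) sum(ci[s:(s + 3L)]), numeric(1))
  structure(list(ci = ci, core_start = which.max(core_sums)),
            class = "conservation_profile")
}

.BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Conservation-weighted similarity of a sequence window to a PWM
#'
#' `score = sum_i ci(i) f(i, base_i) / sum_i ci(i) max_b f(i, b)` over the
#' chosen region's positions: the observed per-position frequencies,
#' conservation-weighted, relative to the best attainable. The score is 1
#' exactly when the window carries the consensus (argmax) base at every
#' position with ci > 0, and is invariant to rescaling all counts. With
#' `region = "core"` the sums run over the 4 core positions only.
#'
#' @param pwm a [pwm()] object.
#' @param profile its [conservation_index()] profile.
#' @param window DNA string of the PWM's length (A/C/G/T only).
#' @param region `"all"` (matrix similarity) or `"core"` (core similarity).
#' @return number in \[0, 1\], or `NA_real_` if the window contains a base
#'   outside A/C/G/T (callers skip and log such windows).
#' @export
similarity <- function(pwm, profile, window, region = c("all", "core")) {
  region <- match.arg(region)
  L <- nrow(pwm$freq)
  if (nchar(window) != L)
    stop("window length ", nchar(window), " != PWM length ", L)
  idx <- .BASE_IDX[strsplit(toupper(window), "", fixed = TRUE)[[1L]]]
  if (anyNA(idx)) return(NA_real_)
  pos <- if (region == "core") profile$core_start + 0:3 else seq_len(L)
  ci <- profile$ci[pos]
  fobs <- pwm$freq[cbind(pos, idx[pos])]
  fmax <- apply(pwm$freq[pos, , drop = FALSE], 1L, max)
  denom <- sum(ci * fmax)
  if (denom == 0) return(1)   # fully uninformative region matches anything
  sum(ci * fobs) / denom
}

.revcomp_dna <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

#' Scan promoter sequences with PWMs on both strands
#'
#' Slides every matrix over every sequence; at each offset the forward
#' window is scored as-is (+ strand) and its reverse complement is scored
#' (- strand), so both orientations of a double-stranded promoter are
#' searched. A window is reported when its core similarity is at least
#' `core_min` and its matrix similarity at least `matrix_min`. Windows
#' containing bases outside A/C/G/T are skipped and counted in the
#' `n_skipped` attribute; sequences shorter than a matrix contribute no
#' windows.
#'
#' @param seqs named character vector of DNA sequences.
#' @param pwms list of [pwm()] objects (a single `pwm` is accepted).
#' @param core_min minimum core similarity (default 0.75).
#' @param matrix_min minimum matrix similarity (default 0.80).
#' @return data.frame of hits sorted by sequence then start: `seq_id`,
#'   `start`, `end` (0-based half-open), `name`, `score`
#'   (= matrix similarity), `strand`, `core_similarity`,
#'   `matrix_similarity`.
#' @export
scan_pwm <- function(seqs, pwms, core_min = 0.75, matrix_min = 0.80) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(names(seqs)))
    stop("sequences must be named")
  n_skipped <- 0L
  rows <- list()
  for (sid in names(seqs)) {
    s <- toupper(seqs[[sid]])
    L <- nchar(s)
    for (p in pwms) {
      w <- nrow(p$counts)
      if (L < w) {
        message("sequence '", sid, "' shorter than PWM '", p$name,
                "'; no windows")
        next
      }
      prof <- conservation_index(p)
      for (start in seq_len(L - w + 1L)) {
        win <- substr(s, start, start + w - 1L)
        for (strand in c("+", "-")) {
          scored <- if (strand == "+") win else .revcomp_dna(win)
          ms <- similarity(p, prof, scored, region = "all")
          if (is.na(ms)) { n_skipped <- n_skipped + 1L; next }
          cs <- similarity(p, prof, scored, region = "core")
          if (cs >= core_min && ms >= matrix_min) {
            rows[[length(rows) + 1L]] <- data.frame(
              seq_id = sid, start = start - 1L, end = start + w - 1L,
              name = p$name, score = ms, strand = strand,
              core_similarity = cs, matrix_similarity = ms,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               name = character(), score = numeric(), strand = character(),
               core_similarity = numeric(), matrix_similarity = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$seq_id, out$start, out$name, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_skipped = n_skipped)
}

#' Calibrate a per-matrix similarity threshold on shuffled background
#'
#' An "optimized" matrix-similarity cutoff: for each matrix, scan
#' base-composition-preserving shuffles of the supplied sequences and take the
#' maximum matrix similarity observed in that background. Scanning real
#' promoters at this cutoff then only reports windows scoring above
#' anything the shuffled background produced.
#'
#' @param seqs named character vector of DNA sequences.
#' @param pwms list of [pwm()] objects.
#' @param n_shuffles shuffles per sequence (default 5).
#' @param seed RNG seed for the shuffles.
#' @return named numeric vector: maximal background matrix similarity per
#'   matrix.
#' @export
optimize_matrix_min <- function(seqs, pwms, n_shuffles = 5L, seed = 1L) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  set.seed(seed)
  shuffled <- unlist(lapply(seq_len(n_shuffles), function(i) {
    out <- vapply(seqs, function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
    }, character(1))
    names(out) <- paste0(names(seqs), "_shuf", i)
    out
  }))
  hits <- scan_pwm(shuffled, pwms, core_min = 0, matrix_min = 0)
  vapply(pwms, function(p) {
    sc <- hits$matrix_similarity[hits$name == p$name]
    if (length(sc)) max(sc) else 0
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(vapply(pwms, `[[`, character(1), "name"))
}
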