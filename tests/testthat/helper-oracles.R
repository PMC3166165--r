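# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive each quantity by a different route than the
# package (explicit loops, exhaustive enumeration, literal string sets).

# quantile normalization by an explicit rank walk: sort each column, average
# across columns rank by rank, then walk each column's order statistics back
# to their rows, averaging the reference over tied spans.
oracle_quantile_normalize <- function(x) {
  n <- nrow(x); k <- ncol(x)
  sorted <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) sorted[, j] <- sort(x[, j])
  ref <- numeric(n)
  for (i in seq_len(n)) ref[i] <- mean(sorted[i, ])
  out <- x
  for (j in seq_len(k)) {
    o <- order(x[, j])
    i <- 1L
    while (i <= n) {
      span <- i
      while (span < n && x[o[span + 1L], j] == x[o[i], j]) span <- span + 1L
      val <- mean(ref[i:span])
      for (r in i:span) out[o[r], j] <- val
      i <- span + 1L
    }
  }
  out
}

# upper-tail hypergeometric by exhaustive enumeration of every n-draw from
# an N-universe containing K marked items (feasible for N <= 12)
oracle_hypergeom <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# literal string sets for every single-edit seed site; labels follow the
# least-edited precedence. Returns a data.frame like seed_sites().
oracle_seed_sites <- function(utr, mirna) {
  to_rna <- function(s) chartr("T", "U", toupper(s))
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  rc <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste(rev(unname(wc[ch])), collapse = "")
  }
  u <- to_rna(utr)
  seed <- substr(to_rna(mirna), 2L, 7L)
  sc <- strsplit(seed, "", fixed = TRUE)[[1L]]
  perfect <- rc(seed)
  pc <- strsplit(perfect, "", fixed = TRUE)[[1L]]
  # site index i opposes seed index 7-i
  sites <- list(perfect = list(list(s = perfect, pos = NA_integer_)))
  wobble <- list(); mismatch <- list()
  for (i in 1:6) {
    sidx <- 7L - i
    sbase <- sc[sidx]
    wob <- if (sbase == "G") "U" else if (sbase == "U") "G" else NA
    for (b in c("A", "C", "G", "U")) {
      if (b == pc[i]) next
      v <- pc; v[i] <- b
      entry <- list(s = paste(v, collapse = ""), pos = sidx + 1L)
      if (!is.na(wob) && b == wob) wobble[[length(wobble) + 1L]] <- entry
      else mismatch[[length(mismatch) + 1L]] <- entry
    }
  }
  deletion <- lapply(1:6, function(d)
    list(s = rc(paste(sc[-d], collapse = "")), pos = d + 1L))
  insertion <- list()
  for (j in 2:6) {
    for (b in c("A", "C", "G", "U")) {
      v <- append(pc, b, after = j - 1L)
      insertion[[length(insertion) + 1L]] <-
        list(s = paste(v, collapse = ""), pos = 8L - j)
    }
  }
  catalog <- list(perfect = sites$perfect, wobble = wobble,
                  mismatch = mismatch, deletion = deletion,
                  insertion = insertion)
  rows <- list()
  for (wl in c(5L, 6L, 7L)) {
    if (nchar(u) < wl) next
    for (start in seq_len(nchar(u) - wl + 1L)) {
      win <- substr(u, start, start + wl - 1L)
      if (grepl("N", win, fixed = TRUE)) next
      for (lab in c("perfect", "wobble", "mismatch", "deletion",
                    "insertion")) {
        match_here <- Filter(function(e) e$s == win, catalog[[lab]])
        if (length(match_here)) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = start - 1L, end = start + wl - 1L, edit_type = lab,
            edit_position = match_here[[1L]]$pos,
            stringsAsFactors = FALSE)
          break  # least-edited precedence
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(),
               edit_type = character(), edit_position = integer(),
               stringsAsFactors = FALSE)
  out[order(out$start, out$end), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# small labelled expression fixture: ng genes x (2 timepoints x r reps)
tiny_expression <- function(values, timepoints = c(0, 4), reps = 3) {
  d <- expand.grid(replicate = seq_len(reps), timepoint_h = timepoints)
  d <- data.frame(sample_id = sprintf("t%g_r%d", d$timepoint_h, d$replicate),
                  timepoint_h = d$timepoint_h, replicate = d$replicate,
                  stringsAsFactors = FALSE)
  stopifnot(ncol(values) == nrow(d))
  dimnames(values) <- list(sprintf("g%02d", seq_len(nrow(values))),
                           d$sample_id)
  list(m = expression_matrix(values, "log2"), design = validate_design(d))
}

# responsive_table built directly from a p-value matrix (timepoint columns)
table_from_p <- function(p, lr = NULL, alpha = 1e-4) {
  if (is.null(lr)) lr <- matrix(1, nrow(p), ncol(p), dimnames = dimnames(p))
  tests <- list(p = p, log_ratio = lr,
                t_statistic = lr, timepoints = as.numeric(colnames(p)))
  select_responsive(tests, alpha = alpha)
}
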