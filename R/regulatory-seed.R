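# Tolerant miRNA seed-site search in 3'UTRs.
#
# The seed is nucleotides 2-7 of the mature miRNA (5'->3'). A target site
# is a UTR substring (sense strand, since mRNA is single-stranded) that
# pairs antiparallel with the seed, allowing at most one departure from
# Watson-Crick pairing: a G:U wobble, a mismatch, a deleted target base
# opposite a seed base (site length 5), or an extra unpaired target base
# inside the site (site length 7). T and U are unified internally, so DNA
# and RNA inputs behave identically.

.U <- function(s) chartr("T", "U", toupper(s))

# reverse complement in RNA alphabet
.revcomp_rna <- function(s) {
  chartr("ACGU", "UGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# pair class of target base (sense strand) opposite seed base:
# 2 = Watson-Crick, 1 = G:U wobble, 0 = mismatch
.pair_class <- function(target, seed) {
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  if (wc[[seed]] == target) return(2L)
  if ((seed == "U" && target == "G") || (seed == "G" && target == "U"))
    return(1L)
  0L
}

# classify one window against the seed; returns NULL or
# list(edit_type, edit_position) with edit_position in miRNA coordinates
# (2-7; NA for perfect; for an insertion, the seed coordinate 5' of the gap)
.classify_window <- function(win, seed, interior_only = FALSE) {
  wchars <- strsplit(win, "", fixed = TRUE)[[1L]]
  schars <- strsplit(seed, "", fixed = TRUE)[[1L]]
  wl <- length(wchars)
  if (wl == 6L) {
    # window base i (5'->3') pairs seed base 7-i
    cls <- vapply(1:6, function(i) .pair_class(wchars[i], schars[7L - i]), 1L)
    n_wc <- sum(cls == 2L); n_wob <- sum(cls == 1L)
    if (n_wc == 6L)
      return(list(edit_type = "perfect", edit_position = NA_integer_))
    if (n_wc == 5L) {
      sidx <- 7L - which(cls != 2L)      # seed index 1..6 of the edit
      pos <- sidx + 1L                   # miRNA coordinate 2..7
      if (interior_only && !(pos %in% 3:6)) return(NULL)
      if (n_wob == 1L)
        return(list(edit_type = "wobble", edit_position = pos))
      return(list(edit_type = "mismatch", edit_position = pos))
    }
    return(NULL)
  }
  if (wl == 5L) {
    # one seed base unpaired (deleted target base); remaining 5 pairs WC
    for (d in 1:6) {
      pos <- d + 1L
      if (interior_only && !(pos %in% 3:6)) next
      rest <- schars[-d]
      ok <- all(vapply(1:5, function(i)
        .pair_class(wchars[i], rest[6L - i]), 1L) == 2L)
      if (ok) return(list(edit_type = "deletion", edit_position = pos))
    }
    return(NULL)
  }
  if (wl == 7L) {
    # one extra target base unpaired inside the site; remaining 6 pairs WC
    for (j in 2:6) {
      red <- wchars[-j]
      ok <- all(vapply(1:6, function(i)
        .pair_class(red[i], schars[7L - i]), 1L) == 2L)
      # gap lies between miRNA coordinates 8-j and 9-j; record the 5' one
      if (ok) return(list(edit_type = "insertion", edit_position = 8L - j))
    }
    return(NULL)
  }
  NULL
}

#' Search a 3'UTR for tolerant miRNA seed-complementary sites
#'
#' Reports every UTR substring that can form an antiparallel duplex with
#' the miRNA seed (nucleotides 2-7) under at most one departure from
#' Watson-Crick pairing:
#' \describe{
#'   \item{perfect}{all six pairs Watson-Crick (the site is the exact
#'     reverse complement of the seed); length 6.}
#'   \item{wobble}{exactly one G:U pair, the rest Watson-Crick; length 6.}
#'   \item{mismatch}{exactly one opposition that neither pairs nor
#'     wobbles; length 6.}
#'   \item{deletion}{one seed base has no partner (missing target base);
#'     the remaining five pairs Watson-Crick; length 5.}
#'   \item{insertion}{one extra target base sits unpaired inside the
#'     site; the six flanking pairs Watson-Crick; length 7.}
#' }
#' A window admitting several explanations gets the least-edited label
#' (perfect > wobble > mismatch; deletion and insertion have distinct
#' lengths so cannot collide). All qualifying windows are reported,
#' overlapping ones included. Windows containing N are skipped.
#'
#' @param utr single named character string (DNA or RNA, sense strand) or a
#'   one-element named vector.
#' @param mirna single named character string: the mature miRNA, 5'->3',
#'   length >= 7.
#' @param interior_only restrict wobble/mismatch/deletion edits to seed
#'   positions 3-6, excluding the boundary positions 2 and 7
#'   (default FALSE: boundary-inclusive).
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open on the UTR), `mirna`, `edit_type`, `edit_position` (miRNA
#'   coordinate 2-7; NA for perfect), `strand` (always "+"), `score`
#'   (edit count: 0 for perfect, 1 otherwise).
#' @export
seed_sites <- function(utr, mirna, interior_only = FALSE) {
  utr_id <- if (!is.null(names(utr))) names(utr)[1L] else "utr"
  mir_id <- if (!is.null(names(mirna))) names(mirna)[1L] else "mirna"
  u <- .U(utr[[1L]])
  m <- .U(mirna[[1L]])
  if (nchar(m) < 7L) stop("miRNA '", mir_id, "' shorter than 7 nt")
  seed <- substr(m, 2L, 7L)
  L <- nchar(u)
  rows <- list()
  for (wl in c(6L, 5L, 7L)) {
    if (L < wl) next
    for (start in seq_len(L - wl + 1L)) {
      win <- substr(u, start, start + wl - 1L)
      if (grepl("N", win, fixed = TRUE)) next
      lab <- .classify_window(win, seed, interior_only = interior_only)
      if (!is.null(lab)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = utr_id, start = start - 1L, end = start + wl - 1L,
          mirna = mir_id, edit_type = lab$edit_type,
          edit_position = lab$edit_position, strand = "+",
          score = if (lab$edit_type == "perfect") 0L else 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               mirna = character(), edit_type = character(),
               edit_position = integer(), strand = character(),
               score = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Seed-site search over many UTRs and miRNAs
#'
#' Convenience loop over every (UTR, miRNA) combination; see
#' [seed_sites()].
#'
#' @param utrs named character vector of UTR sequences.
#' @param mirnas named character vector of mature miRNA sequences.
#' @param interior_only see [seed_sites()].
#' @return combined hits data.frame.
#' @export
scan_seed_sites <- function(utrs, mirnas, interior_only = FALSE) {
  rows <- list()
  for (ui in seq_along(utrs)) {
    for (mi in seq_along(mirnas)) {
      rows[[length(rows) + 1L]] <-
        seed_sites(utrs[ui], mirnas[mi], interior_only = interior_only)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
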