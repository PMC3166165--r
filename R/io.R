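#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated — set name, description,
#' then member gene ids. Duplicate members within a set are collapsed (set
#' semantics). The universe defaults to the union of all members; pass the
#' analyzed matrix's gene ids to use the array as the universe (the
#' convention used by the enrichment stage). Members outside the universe
#' are kept on read but reported, so enrichment can drop them explicitly.
#'
#' @param path GMT file.
#' @param universe optional character vector of gene ids.
#' @return list with elements `sets` (named list of character vectors) and
#'   `universe` (character vector), class `"gene_set_collection"`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list(),
                               universe = if (is.null(universe)) character()
                                          else universe))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, %s",
                   i, length(f), "and at least one member"))
    sets[[f[[1L]]]] <- unique(f[-(1:2)])
  }
  gene_set_collection(sets, universe = universe)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (no empty sets).
#' @param universe character vector of gene ids; defaults to the union of
#'   all set members.
#' @return classed list; members outside the universe are reported via a
#'   message but retained.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every gene set must be named")
    if (anyDuplicated(names(sets)))
      stop("duplicate set name(s): ",
           paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
    empty <- vapply(sets, length, 1L) == 0L
    if (any(empty))
      stop("empty gene set(s): ", paste(names(sets)[empty], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  stray <- sum(vapply(sets, function(s) sum(!s %in% universe), 1L))
  if (stray > 0L)
    message(stray, " set member(s) fall outside the universe")
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param gsc gene-set collection.
#' @param path output path.
#' @param descriptions optional character vector (recycled) for field 2.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(gsc$sets))
  lines <- vapply(seq_along(gsc$sets), function(i) {
    paste(c(names(gsc$sets)[i], descriptions[i], gsc$sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Thin wrapper over Biostrings returning named character strings, with the
#' molecule-type bookkeeping the seed search relies on: a record may use U
#' or T but never both, and `moltype` declares how downstream code should
#' read it.
#'
#' @param path FASTA file.
#' @param moltype `"DNA"` or `"RNA"`.
#' @return named character vector with attribute `moltype`.
#' @export
read_fasta <- function(path, moltype = c("DNA", "RNA")) {
  moltype <- match.arg(moltype)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  if (!length(seqs)) stop("no sequences in ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad))
    stop("record(s) with characters outside {A,C,G,T,U,N}: ",
         paste(names(seqs)[bad], collapse = ", "))
  mixed <- grepl("T", seqs) & grepl("U", seqs)
  if (any(mixed))
    stop("record(s) mixing U and T: ",
         paste(names(seqs)[mixed], collapse = ", "))
  structure(seqs, moltype = moltype)
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read position-weight matrices from TRANSFAC-like text
#'
#' Format: blocks separated by blank lines (or `//`); each block starts
#' with a name line (`NA <name>`, `>name`, or a bare token) optionally
#' followed by a header `PO A C G T`, then one row per position with four
#' whitespace-separated nonnegative counts (an optional leading position
#' index and trailing consensus letter are ignored).
#'
#' @param path matrix file.
#' @param pseudocount nonnegative number added to every count when
#'   frequencies are derived (default 0).
#' @return list of PWM objects (see [pwm()]).
#' @export
read_pwm <- function(path, pseudocount = 0) {
  lines <- trimws(readLines(path))
  blocks <- split(lines, cumsum(lines == "" | lines == "//"))
  pwms <- list()
  for (blk in blocks) {
    blk <- blk[nzchar(blk) & blk != "//"]
    if (!length(blk)) next
    name_line <- blk[[1L]]
    name <- if (grepl("^NA\\s+", name_line)) sub("^NA\\s+", "", name_line)
            else if (startsWith(name_line, ">")) sub("^>\\s*", "", name_line)
            else name_line
    body <- blk[-1L]
    body <- body[!grepl("^(PO|P0)\\b", body)]
    if (!length(body))
      stop("PWM block '", name, "' has no count rows")
    rows <- lapply(body, function(ln) {
      tok <- strsplit(ln, "\\s+")[[1L]]
      # drop a leading integer position index and a trailing consensus letter
      if (length(tok) >= 5L && grepl("^[0-9]+$", tok[[1L]])) tok <- tok[-1L]
      if (length(tok) >= 5L && grepl("^[A-Za-z]$", tok[[length(tok)]]))
        tok <- tok[-length(tok)]
      v <- suppressWarnings(as.numeric(tok))
      if (length(v) != 4L || anyNA(v))
        stop("malformed count row in PWM block '", name, "': ", ln)
      v
    })
    counts <- do.call(rbind, rows)
    colnames(counts) <- c("A", "C", "G", "T")
    pwms[[length(pwms) + 1L]] <- pwm(name, counts, pseudocount = pseudocount)
  }
  if (!length(pwms)) stop("no PWM blocks found in ", path)
  pwms
}

#' Construct a position-weight matrix
#'
#' @param name matrix name.
#' @param counts positions x 4 nonnegative matrix, columns A, C, G, T.
#'   At least 4 positions (a 4-position core region must exist) and no
#'   all-zero position.
#' @param pseudocount nonnegative number added to each count before
#'   normalizing to frequencies.
#' @return classed list with `name`, `counts`, `freq`, `pseudocount`.
#' @export
pwm <- function(name, counts, pseudocount = 0) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("PWM '", name, "': counts must have 4 columns")
  if (is.null(colnames(counts))) colnames(counts) <- c("A", "C", "G", "T")
  if (!identical(colnames(counts), c("A", "C", "G", "T")))
    counts <- counts[, c("A", "C", "G", "T"), drop = FALSE]
  if (nrow(counts) < 4L)
    stop("PWM '", name, "': fewer than 4 positions")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("PWM '", name, "': counts must be finite and nonnegative")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  tot <- rowSums(counts + pseudocount)
  if (any(tot == 0))
    stop("PWM '", name, "': position(s) with all-zero counts: ",
         paste(which(tot == 0), collapse = ", "))
  freq <- (counts + pseudocount) / tot
  structure(list(name = name, counts = counts, freq = freq,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d positions, consensus %s\n", x$name,
              nrow(x$counts),
              paste(colnames(x$freq)[max.col(x$freq, "first")],
                    collapse = "")))
  invisible(x)
}

#' Write sequence hits as a BED-like table
#'
#' Six tab-separated columns: sequence id, start, end, name, score, strand.
#' Coordinates are 0-based half-open on disk (the BED convention); any
#' coordinates quoted in log messages are 1-based inclusive.
#'
#' @param hits data.frame with columns `seq_id`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  need <- c("seq_id", "start", "end", "name", "score", "strand")
  if (!all(need %in% names(hits)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  utils::write.table(hits[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like hits table written by [write_hits()]
#'
#' @param path input path.
#' @return data.frame with the six BED-like columns.
#' @export
read_hits <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("seq_id", "start", "end",
                                        "name", "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character"))
  df
}
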