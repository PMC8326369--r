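# Query-vs-reference sequence match records (12-column tabular alignment
# format) and the hit criteria used to transfer traits between studies.

.match_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")

#' Read a 12-column tabular alignment file
#'
#' Standard BLAST-style tabular output: `qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`, tab-separated, no header.
#'
#' @param path file path.
#' @return data.frame with the twelve standard columns, rows in file order
#'   (zero rows for an empty file).
#' @export
read_match_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("malformed match table ", path, ": line ", which(nf != 12L)[1L],
         " has ", nf[nf != 12L][1L], " columns (expected 12)")
  m <- do.call(rbind, parts)
  out <- data.frame(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE)
  if (any(!is.finite(out$pident)) || any(!is.finite(out$evalue)))
    stop("malformed match table ", path, ": non-numeric pident or evalue")
  if (any(out$pident < 0 | out$pident > 100))
    stop("pident outside [0, 100] in ", path)
  if (any(out$evalue < 0)) stop("negative e-value in ", path)
  out
}

#' Apply hit criteria and keep the best hit per query
#'
#' A record counts as a hit when `pident >= min_identity` and
#' `evalue <= max_evalue` (both bounds inclusive). Among a query's hits the
#' best is the one with the highest bitscore; ties go to the lowest e-value,
#' then to the lexicographically smallest subject id, so the result does not
#' depend on input row order.
#'
#' @param hits data.frame as returned by [read_match_table()].
#' @param min_identity inclusive minimum percent identity (default 97).
#' @param max_evalue inclusive maximum e-value (default 0.001).
#' @return data.frame of best hits, one row per matched query.
#' @export
apply_hit_criteria <- function(hits, min_identity = 97.0, max_evalue = 0.001) {
  keep <- hits$pident >= min_identity & hits$evalue <= max_evalue
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  out <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of query OTUs with a best hit
#'
#' @param query_ids character vector of all query OTU ids.
#' @param best_hits data.frame from [apply_hit_criteria()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_hits <- function(query_ids, best_hits) {
  if (!length(query_ids)) stop("query_ids must be non-empty")
  100 * mean(query_ids %in% best_hits$qseqid)
}

#' Match proportion per abundance-rank bin
#'
#' Queries are sorted by decreasing total abundance (ties broken by
#' lexicographic id) and split into `n_bins` near-equal contiguous bins
#' (earlier bins take the remainder); the proportion of each bin with a best
#' hit is returned. This reproduces the coverage-by-rank picture in which
#' matches to the reference set decline as query taxa become rarer.
#'
#' @param query_abundances named numeric vector of total counts per query OTU.
#' @param best_hits data.frame from [apply_hit_criteria()].
#' @param n_bins number of rank bins (default 1000).
#' @return data.frame with columns `bin`, `n_otus`, `prop_matched`.
#' @export
rank_bin_match_rates <- function(query_abundances, best_hits, n_bins = 1000) {
  stopifnot(n_bins >= 1)
  n <- length(query_abundances)
  if (n < n_bins)
    stop("fewer OTUs (", n, ") than bins (", n_bins,
         "); use a smaller n_bins")
  ids <- names(query_abundances)
  if (is.null(ids)) stop("query_abundances must be named by OTU id")
  ord <- order(-query_abundances, ids)
  matched <- ids[ord] %in% best_hits$qseqid
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bin <- rep(seq_len(n_bins), times = sizes)
  data.frame(
    bin = seq_len(n_bins),
    n_otus = sizes,
    prop_matched = as.numeric(tapply(matched, bin, mean)))
}
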