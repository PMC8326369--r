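#' Construct an OTU count table with sample metadata
#'
#' Bundles an integer count matrix (one row per OTU, one column per sample)
#' with per-sample metadata. Sample depth is always recomputed as the column
#' sum of the count matrix, never trusted from metadata, so the two can never
#' disagree.
#'
#' @param counts integer matrix, OTUs in rows (rownames = OTU ids), samples in
#'   columns (colnames = sample ids). No negative or non-integer entries.
#' @param metadata data.frame with at least columns `sample_id`, `pH` and
#'   `habitat`. Extra columns are preserved but ignored by the package. Every
#'   sample in `counts` must appear exactly once, and vice versa.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `samples` (metadata data.frame ordered to match the
#'   columns of `counts`, with a recomputed `depth` column).
#' @seealso [read_otu_table()], [filter_samples()],
#'   [filter_otus_by_prevalence()], [relative_abundance()]
#' @export
otu_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no OTUs: count table has zero rows")
  if (ncol(counts) == 0L) stop("count table has zero samples")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in counts: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is_count_vector(as.vector(counts)))
    stop("counts must be finite non-negative integers")
  storage.mode(counts) <- "integer"

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  required <- c("sample_id", "pH", "habitat")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "))

  only_counts <- setdiff(colnames(counts), metadata$sample_id)
  if (length(only_counts))
    stop("samples in counts missing from metadata: ",
         paste(only_counts, collapse = ", "))
  only_meta <- setdiff(metadata$sample_id, colnames(counts))
  if (length(only_meta))
    stop("samples in metadata missing from counts: ",
         paste(only_meta, collapse = ", "))

  bad_ph <- metadata$sample_id[!is.finite(metadata$pH)]
  if (length(bad_ph))
    stop("missing or non-finite pH for sample(s): ",
         paste(bad_ph, collapse = ", "))

  metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  metadata$depth <- as.integer(colSums(counts))

  structure(list(counts = counts, samples = metadata), class = "otu_table")
}

#' Read an OTU table from a counts TSV and a metadata CSV
#'
#' The counts file is tab-separated with a header of sample ids and a first
#' column named `otu_id`; the metadata file is comma-separated with header
#' columns `sample_id`, `pH`, `habitat` (extra columns preserved, ignored).
#'
#' @param counts_path path to the tab-separated count matrix.
#' @param metadata_path path to the comma-separated sample metadata.
#' @return An [otu_table()] object with depth recomputed from column sums.
#' @export
read_otu_table <- function(counts_path, metadata_path) {
  raw <- read.table(counts_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no OTUs: ", counts_path, " has no data rows")
  if (ncol(raw) < 2L) stop("counts file needs an otu_id column plus samples")
  ids <- as.character(raw[[1L]])
  counts <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric count entries in ", counts_path)
  if (any(counts != round(counts)))
    stop("non-integer count entries in ", counts_path)
  rownames(counts) <- ids
  metadata <- read.table(metadata_path, header = TRUE, sep = ",",
                         check.names = FALSE, stringsAsFactors = FALSE)
  otu_table(counts, metadata)
}

#' Keep samples with at least a minimum sequencing depth
#'
#' Mirrors the survey-cleaning rule of retaining samples with at least 5,000
#' reads. The threshold is inclusive. OTU rows are left untouched (all-zero
#' rows may remain until [filter_otus_by_prevalence()]).
#'
#' @param table an [otu_table()].
#' @param min_reads inclusive minimum column sum; default 5000.
#' @return An `otu_table` restricted to the retained samples (may have zero
#'   samples).
#' @export
filter_samples <- function(table, min_reads = 5000) {
  stopifnot(inherits(table, "otu_table"), min_reads >= 0)
  keep <- table$samples$depth >= min_reads
  out <- table
  out$counts <- table$counts[, keep, drop = FALSE]
  out$samples <- table$samples[keep, , drop = FALSE]
  rownames(out$samples) <- NULL
  out
}

#' Keep OTUs occurring in at least a minimum number of samples
#'
#' Occurrence means a nonzero count. The threshold is inclusive; the survey
#' default of 30 samples restricts modelling to common taxa.
#'
#' @param table an [otu_table()].
#' @param min_samples inclusive minimum number of samples with nonzero counts;
#'   default 30.
#' @return An `otu_table` restricted to the retained OTUs.
#' @export
filter_otus_by_prevalence <- function(table, min_samples = 30) {
  stopifnot(inherits(table, "otu_table"), min_samples >= 0)
  prevalence <- rowSums(table$counts > 0L)
  keep <- prevalence >= min_samples
  out <- table
  out$counts <- table$counts[keep, , drop = FALSE]
  # depths unchanged; recompute anyway so the invariant holds by construction
  out$samples$depth <- as.integer(colSums(out$counts))
  out
}

#' Within-sample relative abundances
#'
#' @param table an [otu_table()] whose samples all have positive depth.
#' @return Numeric matrix of the same shape as the counts; each column sums
#'   to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  depth <- colSums(table$counts)
  if (any(depth == 0))
    stop("zero-depth sample(s): ",
         paste(table$samples$sample_id[depth == 0], collapse = ", "))
  sweep(table$counts, 2L, depth, "/")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "OTUs x", ncol(x$counts), "samples\n")
  if (ncol(x$counts)) {
    cat(sprintf("  pH %.2f-%.2f; depth %d-%d reads\n",
                min(x$samples$pH), max(x$samples$pH),
                min(x$samples$depth), max(x$samples$depth)))
    cat("  habitats:", paste(sort(unique(x$samples$habitat)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Write an OTU table to counts TSV + metadata CSV
#'
#' Inverse of [read_otu_table()]; used by the pipeline stages and the
#' simulation writer.
#'
#' @param table an [otu_table()].
#' @param counts_path,metadata_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_otu_table <- function(table, counts_path, metadata_path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(otu_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(table$samples, metadata_path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}
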