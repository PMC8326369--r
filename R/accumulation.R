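# Sample-based species accumulation curves with permutation standard
# deviations.

# All permutations of 1..n (n small), as a list.
.all_orderings <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- .all_orderings(n - 1L)
    out <- c(out, lapply(rest, function(p) c(i, (seq_len(n)[-i])[p])))
  }
  out
}

# Cumulative richness along one ordering of sample indices.
.cum_richness <- function(pres, ord) {
  p <- pres[, ord, drop = FALSE]
  has <- rowSums(p) > 0L
  if (!any(has)) return(integer(ncol(p)))
  first <- max.col(p[has, , drop = FALSE], ties.method = "first")
  cumsum(tabulate(first, nbins = ncol(p)))
}

#' Sample-based species accumulation curve
#'
#' Expected cumulative OTU richness as samples are added in random order.
#' The mean and standard deviation at each depth are taken over `n_perm`
#' random permutations of the sample order (or over all `n!` orderings when
#' `exact = TRUE`, feasible for small tables). The mean is non-decreasing and
#' the final value always equals the total observed richness, so the SD at
#' full depth is 0.
#'
#' @param table an [otu_table()] (or a count matrix with OTUs in rows).
#' @param n_perm number of random permutations (default 100); ignored when
#'   `exact = TRUE`.
#' @param seed integer seed for deterministic permutations.
#' @param exact enumerate all orderings instead of sampling (requires at most
#'   8 samples).
#' @param stratum label stored on the curve (default `"All sites"`).
#' @return data.frame of class `accum_curve` with columns `n_samples`,
#'   `mean_richness`, `sd_richness`; attributes `stratum` and `n_perm`.
#' @export
accumulation_curve <- function(table, n_perm = 100, seed = NULL,
                               exact = FALSE, stratum = "All sites") {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  n <- ncol(counts)
  if (n < 1L) stop("need at least one sample")
  pres <- counts > 0
  storage.mode(pres) <- "integer"
  orderings <- if (exact) {
    if (n > 8L) stop("exact enumeration limited to 8 samples (n! orderings)")
    .all_orderings(n)
  } else {
    with_seed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  }
  rich <- vapply(orderings, function(o) as.numeric(.cum_richness(pres, o)),
                 numeric(n))
  if (n == 1L) rich <- matrix(rich, nrow = 1L)
  out <- data.frame(
    n_samples = seq_len(n),
    mean_richness = rowMeans(rich),
    sd_richness = apply(rich, 1L, sd))
  if (length(orderings) == 1L) out$sd_richness <- 0
  attr(out, "stratum") <- stratum
  attr(out, "n_perm") <- length(orderings)
  class(out) <- c("accum_curve", "data.frame")
  out
}

#' Accumulation curves per habitat plus the pooled curve
#'
#' @param table an [otu_table()] with habitat labels in its metadata.
#' @param n_perm,seed passed to [accumulation_curve()]; each stratum gets a
#'   seed derived from `seed` and its label.
#' @return Named list of `accum_curve` data.frames: one per habitat plus
#'   `"All sites"`.
#' @export
per_habitat_curves <- function(table, n_perm = 100, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  habitats <- sort(unique(table$samples$habitat))
  curves <- lapply(habitats, function(h) {
    keep <- table$samples$habitat == h
    accumulation_curve(table$counts[, keep, drop = FALSE], n_perm = n_perm,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, h),
                       stratum = h)
  })
  names(curves) <- habitats
  curves[["All sites"]] <- accumulation_curve(
    table, n_perm = n_perm,
    seed = if (is.null(seed)) NULL else derive_seed(seed, "All sites"))
  curves
}

#' @export
plot.accum_curve <- function(x, ...) {
  plot(x$n_samples, x$mean_richness, type = "l", lwd = 2,
       xlab = "samples", ylab = "cumulative OTU richness",
       main = attr(x, "stratum"), ...)
  lines(x$n_samples, x$mean_richness + x$sd_richness, lty = 3)
  lines(x$n_samples, pmax(x$mean_richness - x$sd_richness, 0), lty = 3)
  invisible(x)
}
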