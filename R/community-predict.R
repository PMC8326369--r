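# Predicting a query study's community matrix from reference HOF fits and
# query sample pH, and comparing predicted vs observed NMDS ordinations.

#' Predicted relative abundance of one OTU at a given pH
#'
#' Evaluates the fitted HOF curve at the query pH and divides by the reference
#' study's median sample depth, putting the prediction on a relative scale.
#' pH outside the fitted gradient range is evaluated by affine extension, with
#' a warning (from [predict.hof_fit()]).
#'
#' @param fit a [hof_fit()] for the matched reference OTU.
#' @param ph query sample pH value(s).
#' @param ref_median_depth median sequencing depth of the reference samples.
#' @return Predicted relative abundance(s).
#' @export
predict_abundance <- function(fit, ph, ref_median_depth) {
  stopifnot(ref_median_depth > 0)
  predict(fit, ph) / ref_median_depth
}

#' Predict a query community matrix from matched reference fits
#'
#' @param fits a `hof_fit_list` (or named list of [hof_fit()] objects) keyed
#'   by reference OTU id.
#' @param shared_map named character vector mapping query OTU ids to reference
#'   OTU ids (e.g. best-hit subjects).
#' @param query_samples data.frame with `sample_id` and `pH` for the query
#'   samples.
#' @param ref_median_depth reference median depth used for the relative scale.
#' @return An object of class `predicted_community`: list with `predicted`
#'   (matrix, query OTUs x query samples) and `query_samples`.
#' @export
predict_community <- function(fits, shared_map, query_samples,
                              ref_median_depth) {
  missing_fit <- setdiff(unname(shared_map), names(fits))
  if (length(missing_fit))
    stop("no finalized fit for matched reference OTU(s): ",
         paste(head(missing_fit, 5L), collapse = ", "))
  rngs <- vapply(unname(shared_map), function(r) fits[[r]]$gradient_range,
                 numeric(2L))
  if (any(query_samples$pH < max(rngs[1L, ])) ||
      any(query_samples$pH > min(rngs[2L, ])))
    warning("some query pH values lie outside fitted gradient ranges; ",
            "those predictions extrapolate")
  pred <- t(vapply(names(shared_map), function(q)
    suppressWarnings(
      predict_abundance(fits[[shared_map[[q]]]], query_samples$pH,
                        ref_median_depth)),
    numeric(nrow(query_samples))))
  if (length(shared_map) == 1L)
    pred <- matrix(pred, nrow = 1L,
                   dimnames = list(names(shared_map), NULL))
  colnames(pred) <- query_samples$sample_id
  if (all(apply(pred, 1L, function(r) max(r) - min(r) < 1e-12)))
    message("all predicted responses are flat; ordination will be degenerate")
  structure(list(predicted = pred, query_samples = query_samples),
            class = "predicted_community")
}

#' Top-n most abundant query OTUs that have a best hit
#'
#' Dominance is total count across all query samples; ranking is
#' rank-then-match: OTUs are ranked by decreasing abundance and the `n` most
#' abundant ones possessing a best hit are kept.
#'
#' @param query_table the query [otu_table()].
#' @param best_hits data.frame from [apply_hit_criteria()].
#' @param n how many matched dominant OTUs to keep (default 100).
#' @return Named character vector mapping the selected query OTU ids to their
#'   matched reference OTU ids.
#' @export
top_matched_otus <- function(query_table, best_hits, n = 100) {
  tot <- rowSums(query_table$counts)
  ord <- order(-tot, rownames(query_table$counts))
  ids <- rownames(query_table$counts)[ord]
  matched <- ids[ids %in% best_hits$qseqid]
  sel <- head(matched, n)
  setNames(best_hits$sseqid[match(sel, best_hits$qseqid)], sel)
}

#' Bray-Curtis dissimilarities between samples
#'
#' `d(j, k) = sum |x_ij - x_ik| / sum (x_ij + x_ik)` over OTUs `i`, computed
#' with [vegan::vegdist()]. Columns are samples.
#'
#' @param m non-negative matrix, OTUs in rows, samples in columns.
#' @param renormalize divide each column by its sum first (default `TRUE`), so
#'   the dissimilarity compares community composition rather than totals.
#' @return A symmetric dissimilarity matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(m, renormalize = TRUE) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative entries are not allowed")
  cs <- colSums(m)
  if (any(cs == 0)) stop("sample(s) with all-zero composition: ",
                         paste(head(which(cs == 0), 5L), collapse = ", "))
  if (renormalize) m <- sweep(m, 2L, cs, "/")
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal's NMDS (stress-1, monotone regression) via [vegan::monoMDS()],
#' taking the best of `n_restarts` seeded random initializations. Scores are
#' centered per axis.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param k embedding dimension (default 2).
#' @param n_restarts number of random starts (default 20).
#' @param seed integer seed for reproducible starts.
#' @return A list of class `nmds_fit`: `points` (samples x k score matrix),
#'   `stress` (final Kruskal stress-1, on vegan's 0-1 scale) and `k`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = NULL) {
  dm <- as.matrix(as.dist(d))
  if (all(dm == 0)) stop("all dissimilarities are zero")
  n <- nrow(dm)
  labels <- rownames(dm) %||% as.character(seq_len(n))

  # samples at zero dissimilarity from an earlier sample are duplicates:
  # embed unique representatives only, then copy scores back
  rep_of <- integer(n)
  reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- reps[dm[i, reps] == 0]
    rep_of[i] <- if (length(hit)) hit[1L] else i
    if (rep_of[i] == i) reps <- c(reps, i)
  }
  du <- as.dist(dm[reps, reps, drop = FALSE])
  if (length(reps) < 3L)
    stop("need at least 3 distinct samples for an ordination")

  best <- with_seed(seed, {
    sols <- lapply(seq_len(n_restarts), function(i)
      vegan::monoMDS(du, k = k, model = "global", maxit = 500,
                     y = matrix(runif(length(reps) * k, -1, 1), ncol = k)))
    sols[[which.min(vapply(sols, `[[`, numeric(1L), "stress"))]]
  })
  pts <- best$points[match(rep_of, reps), , drop = FALSE]
  pts <- scale(pts, center = TRUE, scale = FALSE)
  dimnames(pts) <- list(labels, paste0("NMDS", seq_len(k)))
  structure(list(points = pts, stress = best$stress, k = k),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): %d samples, stress = %.4f\n",
              x$k, nrow(x$points), x$stress))
  invisible(x)
}

#' Squared correlation of first-axis ordination scores
#'
#' NMDS axes are defined up to reflection, so the sign of one axis is chosen
#' to make the correlation non-negative before squaring; the result is
#' invariant to reflection and affine rescaling of either axis.
#'
#' @param pred_scores,obs_scores numeric vectors of axis-1 scores (length >=
#'   3, equal).
#' @return Squared Pearson correlation.
#' @export
axis1_agreement <- function(pred_scores, obs_scores) {
  if (length(pred_scores) != length(obs_scores))
    stop("score vectors differ in length")
  if (length(pred_scores) < 3L) stop("need at least 3 samples")
  r <- cor(pred_scores, obs_scores)
  r^2
}
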