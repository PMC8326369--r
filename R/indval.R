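# Indicator species analysis (Dufrene-Legendre IndVal, group-equalized
# variant) with a label-permutation significance test, and the cross-check of
# query indicators against reference pH classifications.

#' Assign samples to pH bands
#'
#' Same boundary convention as [classify_response()]: below `t_low` is acid,
#' above `t_high` is neutral, the closed middle band (boundaries included) is
#' mid.
#'
#' @param samples an [otu_table()] or a data.frame with `sample_id` and `pH`.
#' @param t_low,t_high pH thresholds; defaults 5.2 and 7.0.
#' @return Named character vector (`sample_id` -> band).
#' @export
assign_ph_groups <- function(samples, t_low = 5.2, t_high = 7.0) {
  if (inherits(samples, "otu_table")) samples <- samples$samples
  if (any(!is.finite(samples$pH))) stop("pH missing for some samples")
  setNames(.ph_band(samples$pH, t_low, t_high), samples$sample_id)
}

#' Indicator values (IndVal) per OTU and group
#'
#' Group-equalized IndVal: specificity `A[i, g]` is the mean within-sample
#' relative abundance of OTU `i` in group `g` divided by the sum of those
#' group means across groups (so each group counts equally regardless of
#' size); fidelity `B[i, g]` is the fraction of group-`g` samples in which the
#' OTU occurs; `indval = 100 * A * B`. The reported group per OTU is the one
#' maximizing indval.
#'
#' @param table an [otu_table()].
#' @param groups named character vector mapping every sample id of `table` to
#'   a group label; at least two non-empty groups.
#' @return A list of class `indval_result`: matrices `A`, `B`, `indval`
#'   (OTU x group) and data.frame `best` (`otu_id`, `group`, `indval`, `A`,
#'   `B`).
#' @export
indval <- function(table, groups) {
  stopifnot(inherits(table, "otu_table"))
  ids <- table$samples$sample_id
  if (!all(ids %in% names(groups)))
    stop("groups missing for sample(s): ",
         paste(setdiff(ids, names(groups)), collapse = ", "))
  g <- factor(groups[ids])
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(table(g) == 0L)) stop("empty group")
  rel <- relative_abundance(table)
  iv <- .indval_stat(rel, table$counts > 0L, g)
  best_idx <- max.col(iv$indval, ties.method = "first")
  best <- data.frame(
    otu_id = rownames(table$counts),
    group = colnames(iv$indval)[best_idx],
    indval = iv$indval[cbind(seq_len(nrow(iv$indval)), best_idx)],
    A = iv$A[cbind(seq_len(nrow(iv$A)), best_idx)],
    B = iv$B[cbind(seq_len(nrow(iv$B)), best_idx)],
    stringsAsFactors = FALSE)
  rownames(best) <- NULL
  structure(list(A = iv$A, B = iv$B, indval = iv$indval, best = best),
            class = "indval_result")
}

# Core statistic on a relative-abundance matrix and presence matrix.
.indval_stat <- function(rel, pres, g) {
  lev <- levels(g)
  mean_rel <- vapply(lev, function(l)
    rowMeans(rel[, g == l, drop = FALSE]), numeric(nrow(rel)))
  occ <- vapply(lev, function(l)
    rowMeans(pres[, g == l, drop = FALSE]), numeric(nrow(rel)))
  if (is.null(dim(mean_rel))) { # single OTU
    mean_rel <- matrix(mean_rel, nrow = 1L, dimnames = list(NULL, lev))
    occ <- matrix(occ, nrow = 1L, dimnames = list(NULL, lev))
  }
  tot <- rowSums(mean_rel)
  A <- mean_rel / ifelse(tot > 0, tot, 1)
  list(A = A, B = occ, indval = 100 * A * occ)
}

#' Permutation p-values for indicator status
#'
#' The per-OTU statistic is the maximum IndVal over groups; group labels are
#' permuted over samples `n_perm` times and
#' `p = (1 + #\{permuted >= observed\}) / (1 + n_perm)`, so p is always in
#' `(0, 1]`.
#'
#' @param table an [otu_table()].
#' @param groups named character vector as in [indval()].
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for deterministic permutations.
#' @return Named numeric vector of p-values per OTU.
#' @export
indval_permutation_test <- function(table, groups, n_perm = 999, seed = NULL) {
  stopifnot(n_perm >= 1)
  ids <- table$samples$sample_id
  g <- factor(groups[ids])
  rel <- relative_abundance(table)
  pres <- table$counts > 0L
  obs <- apply(.indval_stat(rel, pres, g)$indval, 1L, max)
  n <- length(g)
  exceed <- with_seed(seed, {
    acc <- integer(length(obs))
    for (i in seq_len(n_perm)) {
      gp <- g[sample.int(n)]
      perm_max <- apply(.indval_stat(rel, pres, gp)$indval, 1L, max)
      acc <- acc + (perm_max >= obs - 1e-12)
    }
    acc
  })
  setNames((1 + exceed) / (1 + n_perm), rownames(table$counts))
}

#' Full indicator analysis of a table grouped by pH band
#'
#' Convenience wrapper: [assign_ph_groups()], [indval()] and
#' [indval_permutation_test()] in one call.
#'
#' @param table an [otu_table()].
#' @param t_low,t_high pH band thresholds.
#' @param n_perm,seed passed to [indval_permutation_test()].
#' @param alpha significance threshold on the permutation p-value
#'   (default 0.05).
#' @return data.frame with one row per OTU: `otu_id`, `group`, `indval`, `A`,
#'   `B`, `p_value`, `significant`.
#' @export
indicator_analysis <- function(table, t_low = 5.2, t_high = 7.0,
                               n_perm = 999, alpha = 0.05, seed = NULL) {
  groups <- assign_ph_groups(table, t_low, t_high)
  iv <- indval(table, groups)
  p <- indval_permutation_test(table, groups, n_perm = n_perm, seed = seed)
  out <- iv$best
  out$p_value <- unname(p[out$otu_id])
  out$significant <- out$p_value <= alpha
  out
}

#' Cross-tabulate query indicators against matched reference pH classes
#'
#' Each significant indicator with a best hit inherits the matched reference
#' OTU's pH class and optimum. Agreement is the fraction of matched indicators
#' whose inherited class is consistent with their observed pH band; a range
#' class counts as agreeing with every band it spans (e.g. `acid_to_mid`
#' agrees with both acid and mid). Indicators without a best hit are excluded
#' from the agreement denominator and counted separately.
#'
#' @param indicators data.frame of significant indicators with columns
#'   `otu_id` and `group` (observed band), e.g. the significant rows of
#'   [indicator_analysis()].
#' @param best_hits data.frame from [apply_hit_criteria()] keyed by `qseqid`.
#' @param reference_classes data.frame with columns `otu_id`, `pH_class`,
#'   `opt1_pH`, `opt2_pH` for the reference OTUs (see [classify_fits()]).
#' @return A list with `detail` (per-indicator data.frame with inherited class
#'   and optimum, plus `agrees`), `table` (observed band x inherited class
#'   contingency), `agreement` (fraction agreeing among matched), `n_matched`
#'   and `n_unmatched`.
#' @export
crosstab_indicators_vs_reference <- function(indicators, best_hits,
                                             reference_classes) {
  hit_idx <- match(indicators$otu_id, best_hits$qseqid)
  subject <- best_hits$sseqid[hit_idx]
  ref_idx <- match(subject, reference_classes$otu_id)
  detail <- data.frame(
    otu_id = indicators$otu_id,
    observed_band = indicators$group,
    matched_ref = subject,
    ref_class = reference_classes$pH_class[ref_idx],
    ref_opt1_pH = reference_classes$opt1_pH[ref_idx],
    ref_opt2_pH = reference_classes$opt2_pH[ref_idx],
    stringsAsFactors = FALSE)
  spans <- list(acid = "acid", mid = "mid", neutral = "neutral",
                acid_to_mid = c("acid", "mid"),
                mid_to_neutral = c("mid", "neutral"),
                acid_to_neutral = c("acid", "mid", "neutral"),
                no_preference = character(0))
  detail$agrees <- mapply(function(band, cls) {
    if (is.na(cls)) NA else band %in% spans[[cls]]
  }, detail$observed_band, detail$ref_class)
  matched <- !is.na(detail$ref_class)
  list(
    detail = detail,
    table = table(observed = detail$observed_band[matched],
                  reference = detail$ref_class[matched]),
    agreement = if (any(matched)) mean(detail$agrees[matched]) else NA_real_,
    n_matched = sum(matched),
    n_unmatched = sum(!matched))
}
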