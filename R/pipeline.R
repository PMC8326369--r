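# End-to-end orchestration: filter -> fit -> classify -> match -> indval ->
# accumulate -> predict, with a manifest and per-stage derived seeds.

#' Pipeline configuration
#'
#' Validates and bundles input paths and the analysis constants: the sample
#' depth and OTU prevalence filters, the pH band thresholds, the hit criteria,
#' and the sizes of the stochastic stages. All randomness downstream flows
#' from the single `seed` via per-stage derived seeds.
#'
#' @param ref_counts,ref_metadata paths to the reference study's counts TSV
#'   and metadata CSV.
#' @param query_counts,query_metadata paths for the query study.
#' @param matches path to the 12-column query-vs-reference match table.
#' @param min_reads,min_prevalence sample and OTU filters (defaults 5000, 30).
#' @param t_low,t_high pH band thresholds (defaults 5.2, 7.0).
#' @param min_identity,max_evalue hit criteria (defaults 97.0, 0.001).
#' @param n_boot bootstrap resamples per OTU fit (default 100).
#' @param n_perm permutations for the indicator test and accumulation curves
#'   (default 199).
#' @param n_bins abundance-rank bins for the coverage curve (default 1000).
#' @param top_n matched dominant query OTUs used for community prediction
#'   (default 100).
#' @param seed master seed (mandatory; every stochastic stage derives its own
#'   seed from it).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(ref_counts, ref_metadata, query_counts,
                            query_metadata, matches,
                            min_reads = 5000, min_prevalence = 30,
                            t_low = 5.2, t_high = 7.0,
                            min_identity = 97.0, max_evalue = 0.001,
                            n_boot = 100, n_perm = 199, n_bins = 1000,
                            top_n = 100, seed) {
  stopifnot(min_reads >= 0, min_prevalence >= 0, t_low < t_high,
            min_identity >= 0, min_identity <= 100, max_evalue >= 0,
            n_boot >= 0, n_perm >= 1, n_bins >= 1, top_n >= 1)
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory: stochastic stages must be reproducible")
  for (p in c(ref_counts, ref_metadata, query_counts, query_metadata,
              matches))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(
    ref_counts = ref_counts, ref_metadata = ref_metadata,
    query_counts = query_counts, query_metadata = query_metadata,
    matches = matches, min_reads = min_reads,
    min_prevalence = min_prevalence, t_low = t_low, t_high = t_high,
    min_identity = min_identity, max_evalue = max_evalue, n_boot = n_boot,
    n_perm = n_perm, n_bins = n_bins, top_n = top_n,
    seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: sample/OTU filtering of the reference table, HOF fits
#' with bootstrap selection, pH response classification, hit criteria +
#' coverage on the match table, indicator analysis of the query study,
#' accumulation curves, and community prediction with NMDS validation. Each
#' stage writes a CSV into `out_dir` and the run ends with `manifest.json`
#' recording the config, the package version, per-stage seeds and the MD5
#' checksum of every output, so identical configs give byte-identical
#' stochastic outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  results <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  # 1. filter
  ref <- stage("filter", {
    tab <- read_otu_table(config$ref_counts, config$ref_metadata)
    tab <- filter_samples(tab, config$min_reads)
    if (ncol(tab$counts) == 0L) stop("0 samples after filtering")
    tab <- filter_otus_by_prevalence(tab, config$min_prevalence)
    if (nrow(tab$counts) == 0L) stop("0 OTUs after filtering")
    tab
  })
  emit(data.frame(otu_id = rownames(ref$counts),
                  prevalence = rowSums(ref$counts > 0)), "filtered_otus.csv")
  results$reference <- ref

  # 2. fit
  fits <- stage("fit", hof_fit_table(ref, n_boot = config$n_boot,
                                     seed = derive_seed(config$seed, "fit")))
  emit(as.data.frame(fits), "fits.csv")
  results$fits <- fits

  # 3. classify
  classes <- stage("classify",
                   classify_fits(fits, config$t_low, config$t_high))
  emit(classes, "classes.csv")
  results$classes <- classes

  # 4. match
  query <- stage("match", read_otu_table(config$query_counts,
                                         config$query_metadata))
  coverage <- stage("match", {
    hits <- read_match_table(config$matches)
    best <- apply_hit_criteria(hits, config$min_identity, config$max_evalue)
    pct <- percent_hits(rownames(query$counts), best)
    bins <- rank_bin_match_rates(
      setNames(rowSums(query$counts), rownames(query$counts)), best,
      n_bins = min(config$n_bins, nrow(query$counts)))
    list(best = best, percent_hits = pct, bins = bins)
  })
  emit(coverage$bins, "coverage.csv")
  results$coverage <- coverage

  # 5. indval
  indicators <- stage("indval", indicator_analysis(
    query, config$t_low, config$t_high, n_perm = config$n_perm,
    seed = derive_seed(config$seed, "indval")))
  emit(indicators, "indicators.csv")
  results$indicators <- indicators

  # 6. accumulate
  curves <- stage("accumulate", per_habitat_curves(
    ref, n_perm = min(config$n_perm, 100),
    seed = derive_seed(config$seed, "accumulate")))
  curve_df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(stratum = attr(cv, "stratum"), as.data.frame(cv))))
  emit(curve_df, "curves.csv")
  results$curves <- curves

  # 7. predict
  prediction <- stage("predict", {
    shared <- top_matched_otus(query, coverage$best, n = config$top_n)
    shared <- shared[shared %in% names(fits)] # subject must survive filtering
    if (!length(shared)) stop("no matched dominant OTUs to predict from")
    pc <- predict_community(fits, shared, query$samples,
                            ref_median_depth = median(ref$samples$depth))
    pred_ord <- nmds(bray_curtis(pc$predicted),
                     seed = derive_seed(config$seed, "predict-nmds"))
    obs_ord <- nmds(bray_curtis(relative_abundance(query),
                                renormalize = FALSE),
                    seed = derive_seed(config$seed, "observed-nmds"))
    r2 <- axis1_agreement(pred_ord$points[, 1L], obs_ord$points[, 1L])
    list(predicted = pc, scores = data.frame(
      sample_id = query$samples$sample_id,
      predicted_axis1 = pred_ord$points[, 1L],
      observed_axis1 = obs_ord$points[, 1L]),
      stress = c(predicted = pred_ord$stress, observed = obs_ord$stress),
      axis1_r2 = r2)
  })
  emit(data.frame(otu_id = rownames(prediction$predicted$predicted),
                  prediction$predicted$predicted, check.names = FALSE),
       "predicted.csv")
  emit(prediction$scores, "scores.csv")
  results$prediction <- prediction

  manifest <- list(
    package = "ecohof",
    version = as.character(packageVersion("ecohof")),
    r_version = R.version.string,
    config = unclass(config),
    input_md5 = as.list(md5sum(c(config$ref_counts, config$ref_metadata,
                                 config$query_counts, config$query_metadata,
                                 config$matches))),
    percent_hits = coverage$percent_hits,
    axis1_r2 = prediction$axis1_r2,
    outputs = as.list(md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
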