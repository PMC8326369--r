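# Synthetic gradient communities with known HOF response truths, and paired
# reference/query studies for end-to-end validation without any downloads.

.cs_habitats <- c("crops and weeds", "fertile grassland", "heath and bog",
                  "infertile grassland", "lowland wooded",
                  "moorland grass mosaics", "tall grass and herb",
                  "upland wooded")

#' Generate samples along a pH gradient
#'
#' pH is uniform on `[ph_min, ph_max]` (defaults to the survey gradient
#' 3.63-8.75); nominal sequencing depths are log-normal (median 10,000,
#' sigma 0.5) truncated below at 1,000, emulating the depth spread of a large
#' soil survey; habitats are drawn uniformly from the survey's eight aggregate
#' vegetation classes.
#'
#' @param n_samples number of samples (>= 1).
#' @param ph_min,ph_max gradient endpoints.
#' @param seed integer seed; same seed gives identical samples.
#' @return data.frame with columns `sample_id`, `pH`, `depth`, `habitat`.
#' @export
generate_gradient <- function(n_samples, ph_min = 3.63, ph_max = 8.75,
                              seed = NULL) {
  if (n_samples < 1L) stop("n_samples must be at least 1")
  if (!(ph_min < ph_max)) stop("invalid pH range")
  with_seed(seed, {
    data.frame(
      sample_id = sprintf("S%05d", seq_len(n_samples)),
      pH = runif(n_samples, ph_min, ph_max),
      depth = pmax(1000L, as.integer(round(rlnorm(n_samples,
                                                  meanlog = log(10000),
                                                  sdlog = 0.5)))),
      habitat = sample(.cs_habitats, n_samples, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

# Expected response of one truth row at scaled gradient position x.
.truth_mu <- function(truth_row, x) {
  p <- unlist(truth_row[c("a", "b", "c", "d")])
  fit <- list(model_type = truth_row$model_type,
              params = p, rev = isTRUE(truth_row$rev), M = truth_row$M)
  .fit_response(fit, x)
}

# One prior draw of parameters for a given type.
.draw_truth_params <- function(type, strong_signal) {
  b_lo <- if (strong_signal) 10 else 2
  m_lo <- if (strong_signal) 50 else 5
  list(a = runif(1, -10, 5),
       b = if (type == "I") NA_real_ else runif(1, b_lo, 60),
       c = if (type %in% c("I", "II")) NA_real_ else runif(1, -10, 5),
       d = if (type != "V") NA_real_ else runif(1, b_lo, 60),
       M = exp(runif(1, log(m_lo), log(500))),
       rev = if (type %in% c("II", "III")) runif(1) < 0.5 else FALSE)
}

#' Generate known HOF response truths, stratified over types and classes
#'
#' Draws per-type parameters from broad priors (`a`, `c` uniform on
#' `[-10, 5]`; `b`, `d` uniform on `[2, 60]`, or `[10, 60]` for the
#' strong-signal cohort; `M` log-uniform on `[5, 500]`, floor 50 when strong)
#' and derives each truth's pH optima and response class with the same
#' machinery used on fitted curves. Within each type the draws cycle over that
#' type's attainable response classes by rejection sampling, so every class
#' has support downstream. Truths whose expected occupancy along the gradient
#' would fall below 15% (taxa effectively invisible to a survey's prevalence
#' filter) are rejected and redrawn.
#'
#' @param n_per_type truths per HOF type (vector of 5 or a scalar).
#' @param ph_min,ph_max gradient range the truths live on.
#' @param strong_signal draw steep, abundant responses (`|b| >= 10`,
#'   `M >= 50`).
#' @param seed integer seed.
#' @return data.frame with columns `otu_id`, `model_type`, `a`, `b`, `c`, `d`,
#'   `M`, `rev`, `opt1_pH`, `opt2_pH`, `response_class`; attribute
#'   `gradient_range`.
#' @export
generate_truths <- function(n_per_type = 10, ph_min = 3.63, ph_max = 8.75,
                            strong_signal = FALSE, seed = NULL) {
  if (length(n_per_type) == 1L) n_per_type <- rep(n_per_type, 5L)
  stopifnot(length(n_per_type) == 5L, all(n_per_type >= 0))
  feasible <- list(
    I = "no_preference",
    II = c("acid", "neutral"),
    III = c("acid", "mid", "neutral", "acid_to_mid", "mid_to_neutral",
            "acid_to_neutral"),
    IV = c("acid", "mid", "neutral"),
    V = c("acid", "mid", "neutral"))
  xs <- seq(0, 1, by = 0.01)
  with_seed(seed, {
    rows <- list()
    for (ti in seq_along(.hof_types)) {
      type <- .hof_types[ti]
      n_t <- n_per_type[ti]
      if (n_t == 0L) next
      targets <- rep_len(feasible[[type]], n_t)
      for (j in seq_len(n_t)) {
        draw <- NULL
        for (try in seq_len(500L)) {
          p <- .draw_truth_params(type, strong_signal)
          row <- data.frame(model_type = type, a = p$a, b = p$b, c = p$c,
                            d = p$d, M = p$M, rev = p$rev,
                            stringsAsFactors = FALSE)
          mu <- .truth_mu(row, xs)
          if (mean(1 - exp(-mu)) < 0.15) next # effectively undetectable
          fit <- list(model_type = type,
                      params = c(a = p$a, b = p$b, c = p$c, d = p$d),
                      rev = p$rev, M = p$M,
                      gradient_range = c(ph_min, ph_max))
          opt <- extract_optima(fit)
          cls <- classify_response(opt)
          row$opt1_pH <- if (length(opt) >= 1L) opt[1L] else NA_real_
          row$opt2_pH <- if (length(opt) >= 2L) opt[2L] else NA_real_
          row$response_class <- cls
          draw <- row
          if (cls == targets[j]) break
        }
        if (is.null(draw)) stop("could not draw a detectable truth")
        rows[[length(rows) + 1L]] <- draw
      }
    }
    out <- do.call(rbind, rows)
    out <- cbind(otu_id = sprintf("OTU%04d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    attr(out, "gradient_range") <- c(ph_min, ph_max)
    out
  })
}

#' Noiseless expected count matrix for a set of truths
#'
#' @param truths data.frame from [generate_truths()].
#' @param samples data.frame from [generate_gradient()].
#' @return Matrix of expected counts `mu` (OTUs x samples).
#' @export
synthetic_mu <- function(truths, samples) {
  rng <- attr(truths, "gradient_range") %||% c(3.63, 8.75)
  x <- scale_gradient(samples$pH, rng[1L], rng[2L])
  mu <- t(vapply(seq_len(nrow(truths)), function(i)
    .truth_mu(truths[i, ], x), numeric(length(x))))
  if (nrow(truths) == 1L) mu <- matrix(mu, nrow = 1L)
  dimnames(mu) <- list(truths$otu_id, samples$sample_id)
  if (any(!is.finite(mu))) stop("non-finite expected counts")
  mu
}

#' Generate a synthetic OTU table from truths with Poisson noise
#'
#' `count[i, j] ~ Poisson(mu_ij)` independently, with `mu_ij` the truth's HOF
#' response at sample `j`'s scaled pH — the same error model later assumed by
#' the fitting.
#'
#' @param samples data.frame from [generate_gradient()].
#' @param truths data.frame from [generate_truths()] (non-empty).
#' @param seed integer seed.
#' @return An [otu_table()].
#' @export
generate_community <- function(samples, truths, seed = NULL) {
  if (!nrow(truths)) stop("truths must be non-empty")
  mu <- synthetic_mu(truths, samples)
  counts <- with_seed(seed, {
    matrix(rpois(length(mu), lambda = mu), nrow = nrow(mu),
           dimnames = dimnames(mu))
  })
  otu_table(counts, samples)
}

#' Generate a paired reference/query study
#'
#' Builds a reference study with known truths and a query study in which a
#' fraction of OTUs share the reference truths (same response parameters)
#' while the rest are novel. Sharing probability increases with a query OTU's
#' expected abundance rank — the rarest taxa are the least likely to be shared
#' — so the decline of reference coverage with query rarity is reproducible in
#' silico. Synthetic match records place shared OTUs cleanly above the usual
#' hit criteria (identity 97-100, e-value 1e-50) and novel OTUs below
#' (identity 80-96.9).
#'
#' @param n_ref_otus,n_query_otus numbers of reference and query OTUs.
#' @param shared_fraction fraction of query OTUs sharing reference truths, in
#'   `[0, 1]`.
#' @param n_samples_each samples per study.
#' @param seed master seed; stage seeds are derived from it.
#' @param strong_signal passed to [generate_truths()].
#' @return A list of class `study_pair`: `reference` and `query` (each with
#'   `table` and `truths`), `shared_map` (query id -> reference id) and
#'   `matches` (12-column match record data.frame).
#' @export
generate_study_pair <- function(n_ref_otus = 150, n_query_otus = 200,
                                shared_fraction = 0.6, n_samples_each = 300,
                                seed = NULL, strong_signal = TRUE) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1)
  per_type <- function(n) {
    base <- n %/% 5L
    extra <- n %% 5L
    rep(base, 5L) + c(rep(1L, extra), rep(0L, 5L - extra))
  }
  sd1 <- function(tag) if (is.null(seed)) NULL else derive_seed(seed, tag)

  ref_truths <- generate_truths(per_type(n_ref_otus),
                                strong_signal = strong_signal,
                                seed = sd1("ref_truths"))
  ref_truths$otu_id <- sprintf("REF%04d", seq_len(nrow(ref_truths)))
  ref_samples <- generate_gradient(n_samples_each, seed = sd1("ref_samples"))
  ref_table <- generate_community(ref_samples, ref_truths,
                                  seed = sd1("ref_counts"))

  query_truths <- generate_truths(per_type(n_query_otus),
                                  strong_signal = strong_signal,
                                  seed = sd1("query_truths"))
  query_truths$otu_id <- sprintf("QRY%04d", seq_len(nrow(query_truths)))

  xs <- seq(0, 1, by = 0.01)
  exp_ab <- function(truths) vapply(seq_len(nrow(truths)), function(i)
    mean(.truth_mu(truths[i, ], xs)), numeric(1L))

  n_shared <- round(shared_fraction * n_query_otus)
  shared_map <- character(0)
  if (n_shared > 0) {
    q_ab <- exp_ab(query_truths)
    # weight decreasing in abundance rank: rank 1 (most abundant) heaviest
    q_rank <- rank(-q_ab, ties.method = "first")
    r_ab <- exp_ab(ref_truths)
    r_rank <- rank(-r_ab, ties.method = "first")
    pick <- with_seed(sd1("sharing"), {
      qs <- sample.int(n_query_otus, n_shared,
                       prob = (n_query_otus - q_rank + 1)^2)
      rs <- sample.int(nrow(ref_truths), n_shared,
                       replace = n_shared > nrow(ref_truths),
                       prob = (nrow(ref_truths) - r_rank + 1)^2)
      list(qs = qs, rs = rs)
    })
    # order both picks by abundance so dominant queries reuse dominant refs
    qs <- pick$qs[order(q_rank[pick$qs])]
    rs <- pick$rs[order(r_rank[pick$rs])]
    shared_map <- setNames(ref_truths$otu_id[rs], query_truths$otu_id[qs])
    carry <- c("model_type", "a", "b", "c", "d", "M", "rev",
               "opt1_pH", "opt2_pH", "response_class")
    query_truths[qs, carry] <- ref_truths[rs, carry]
  }

  query_samples <- generate_gradient(n_samples_each,
                                     seed = sd1("query_samples"))
  query_table <- generate_community(query_samples, query_truths,
                                    seed = sd1("query_counts"))

  matches <- with_seed(sd1("matches"), {
    is_shared <- query_truths$otu_id %in% names(shared_map)
    n_q <- nrow(query_truths)
    pid <- ifelse(is_shared, runif(n_q, 97, 100), runif(n_q, 80, 96.9))
    subj <- ifelse(is_shared, shared_map[query_truths$otu_id],
                   ref_truths$otu_id[sample.int(nrow(ref_truths), n_q,
                                                replace = TRUE)])
    alen <- 250L
    data.frame(
      qseqid = query_truths$otu_id, sseqid = unname(subj),
      pident = round(pid, 2), length = alen,
      mismatch = as.integer(round((100 - pid) / 100 * alen)),
      gapopen = 0L, qstart = 1L, qend = alen, sstart = 1L, send = alen,
      evalue = ifelse(is_shared, 1e-50, 1e-30),
      bitscore = round(ifelse(is_shared, runif(n_q, 400, 500),
                              runif(n_q, 100, 200)), 1),
      stringsAsFactors = FALSE)
  })

  structure(list(
    reference = list(table = ref_table, truths = ref_truths),
    query = list(table = query_table, truths = query_truths),
    shared_map = shared_map,
    matches = matches), class = "study_pair")
}

#' @export
print.study_pair <- function(x, ...) {
  cat("Synthetic study pair\n  reference:",
      nrow(x$reference$table$counts), "OTUs x",
      ncol(x$reference$table$counts), "samples\n  query:    ",
      nrow(x$query$table$counts), "OTUs x",
      ncol(x$query$table$counts), "samples\n  shared:   ",
      length(x$shared_map), "query OTUs mapped to reference truths\n")
  invisible(x)
}

#' Write a synthetic study pair to plain-text files
#'
#' Writes reference and query counts (TSV) + metadata (CSV), the truth tables
#' (CSV) and the synthetic match records (headerless 12-column TSV) into a
#' directory, in the formats the pipeline reads back.
#'
#' @param pair a [generate_study_pair()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation <- function(pair, dir) {
  stopifnot(inherits(pair, "study_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ref_counts = file.path(dir, "ref_counts.tsv"),
    ref_metadata = file.path(dir, "ref_metadata.csv"),
    ref_truth = file.path(dir, "ref_truth.csv"),
    query_counts = file.path(dir, "query_counts.tsv"),
    query_metadata = file.path(dir, "query_metadata.csv"),
    query_truth = file.path(dir, "query_truth.csv"),
    matches = file.path(dir, "matches.tsv"))
  write_otu_table(pair$reference$table, paths["ref_counts"],
                  paths["ref_metadata"])
  write.table(pair$reference$truths, paths["ref_truth"], sep = ",",
              quote = FALSE, row.names = FALSE)
  write_otu_table(pair$query$table, paths["query_counts"],
                  paths["query_metadata"])
  write.table(pair$query$truths, paths["query_truth"], sep = ",",
              quote = FALSE, row.names = FALSE)
  write.table(pair$matches, paths["matches"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
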