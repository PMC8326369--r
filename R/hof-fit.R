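#' Fit HOF response curves to one OTU with AIC + bootstrap model selection
#'
#' Fits all five HOF shapes to one OTU's counts along pH by Poisson maximum
#' likelihood, initially selects the shape with the lowest AIC, then hardens
#' the choice with a bootstrap vote: the data pairs `(pH, count)` are resampled
#' with replacement `n_boot` times, all shapes are refitted on each resample
#' and the AIC-best shape recorded; if the most frequent bootstrap choice
#' differs from the initial AIC choice, the bootstrap mode is selected instead.
#' The final parameters are the fit of the selected shape on the original data,
#' and pH optima are extracted from that curve.
#'
#' @param counts non-negative integer vector of reads for one OTU.
#' @param ph sample pH values, same length as `counts`.
#' @param n_boot number of bootstrap resamples (default 100); `0` skips the
#'   vote and keeps the AIC choice.
#' @param seed integer seed making the bootstrap deterministic; `NULL` uses the
#'   current RNG stream.
#' @param otu_id identifier carried into outputs.
#' @param gradient_range pH range defining the scaled gradient (defaults to
#'   `range(ph)`); kept fixed across bootstrap resamples.
#' @param M scaling constant, by default the maximum observed count; kept fixed
#'   across bootstrap resamples.
#' @return An object of class `hof_fit` with elements `otu_id`, `model_type`,
#'   `params` (named `a`-`d`, `NA` where unused), `rev`, `M`, `k`, `logLik`,
#'   `AIC`, `optima_pH` (0, 1 or 2 values), `initial_type`, `bootstrap_tally`
#'   (named counts over types I-V), `n_boot`, `n_boot_failed`,
#'   `gradient_range`, `candidates` (per-type AIC table) and `data`.
#' @seealso [fit_single_model()], [extract_optima()], [classify_response()],
#'   [hof_fit_table()]
#' @examples
#' ph <- seq(3.7, 8.7, length.out = 120)
#' mu <- hof_response(scale_gradient(ph, 3.63, 8.75), "IV",
#'                    c(a = -2, b = 8, c = 4), M = 60)
#' y <- rpois(length(mu), mu)
#' fit <- hof_fit(y, ph, n_boot = 20, seed = 1, gradient_range = c(3.63, 8.75))
#' fit
#' @export
hof_fit <- function(counts, ph, n_boot = 100, seed = NULL, otu_id = "otu",
                    gradient_range = range(ph), M = max(counts)) {
  stopifnot(n_boot >= 0)
  # fit shapes in nesting order, seeding each with the solution of the shape
  # it nests so the attained likelihoods respect I <= II <= {III, IV} <= V
  fit1 <- function(type, extra = NULL)
    fit_single_model(counts, ph, type, M = M,
                     gradient_range = gradient_range, extra_starts = extra)
  candidates <- list(I = fit1("I"))
  candidates$II <- fit1("II", list(c(candidates$I$params["a"], b = 1e-8)))
  p2 <- candidates$II$params
  candidates$III <- fit1("III", list(c(p2[c("a", "b")], c = -45)))
  candidates$IV <- fit1("IV", list(c(p2[c("a", "b")], c = -45)))
  p3 <- candidates$III$params
  p4 <- candidates$IV$params
  candidates$V <- fit1("V", list(c(p3[c("a", "b", "c")], d = 1e-8),
                                 c(p4[c("a", "b", "c")], d = p4[["b"]])))
  initial_type <- select_model(candidates)

  tally <- setNames(integer(5L), .hof_types)
  n_failed <- 0L
  if (n_boot > 0) {
    n <- length(counts)
    boot_types <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- counts[idx]
        xb <- ph[idx]
        cand_b <- lapply(.hof_types, function(t) {
          tryCatch(
            fit_single_model(yb, xb, t, M = M,
                             gradient_range = gradient_range,
                             starts = if (t != "I")
                               list(candidates[[t]]$params[.hof_par_names[[t]]])
                             else NULL,
                             orientations = candidates[[t]]$rev),
            error = function(e) NULL)
        })
        names(cand_b) <- .hof_types
        cand_b <- Filter(Negate(is.null), cand_b)
        if (!length(cand_b)) NA_character_ else select_model(cand_b)
      }, character(1L))
    })
    n_failed <- sum(is.na(boot_types))
    tb <- table(factor(boot_types[!is.na(boot_types)], levels = .hof_types))
    tally[] <- as.integer(tb)
  }

  final_type <- resolve_boot_choice(initial_type, tally)

  final <- candidates[[final_type]]
  fit <- structure(
    list(otu_id = otu_id, model_type = final_type, params = final$params,
         rev = final$rev, M = M, k = final$k, logLik = final$logLik,
         AIC = final$AIC, optima_pH = numeric(0), initial_type = initial_type,
         bootstrap_tally = tally, n_boot = as.integer(n_boot),
         n_boot_failed = n_failed, gradient_range = gradient_range,
         candidates = data.frame(
           model_type = .hof_types,
           k = unname(.hof_k),
           logLik = vapply(candidates, `[[`, numeric(1L), "logLik"),
           AIC = vapply(candidates, `[[`, numeric(1L), "AIC"),
           row.names = NULL),
         data = list(counts = counts, ph = ph)),
    class = "hof_fit")
  fit$optima_pH <- extract_optima(fit)
  fit
}

# Bootstrap-vote rule: keep the initial AIC choice when it equals the
# modal bootstrap choice, otherwise take the mode; a tied mode goes to the
# shape with fewer parameters (earlier type). An empty tally (n_boot = 0 or
# all resamples failed) keeps the initial choice.
resolve_boot_choice <- function(initial_type, tally) {
  if (sum(tally) == 0) return(initial_type)
  tally <- tally[.hof_types] # parsimony order for ties
  mode_type <- names(tally)[which.max(tally)]
  if (mode_type == initial_type) initial_type else mode_type
}

#' Select the best HOF shape by AIC
#'
#' Argmin of AIC over candidate fits; ties go to the shape with fewer free
#' parameters (and then to the lower type in I < II < III < IV < V order).
#'
#' @param candidates named list of candidate fits as returned by
#'   [fit_single_model()].
#' @return The selected model type as a character scalar.
#' @export
select_model <- function(candidates) {
  if (!length(candidates)) stop("no candidates to select from")
  aic <- vapply(candidates, `[[`, numeric(1L), "AIC")
  k <- vapply(candidates, `[[`, numeric(1L), "k")
  ord <- order(aic, k, match(names(candidates), .hof_types))
  names(candidates)[ord[1L]]
}

#' Extract pH optima from a fitted HOF curve
#'
#' Type I (flat) yields no optimum; type II yields the gradient endpoint with
#' the higher response; types IV and V yield the single pH at which the fitted
#' response is maximal, located on a fine grid (step 1e-3 on the scaled
#' gradient) and refined locally; type III (plateau) yields the two pH values
#' bounding the region where the response is at least 0.95 of the fitted
#' maximum.
#'
#' @param fit a [hof_fit()] object, or any list with elements `model_type`,
#'   `params`, `rev`, `M` and `gradient_range`.
#' @return Numeric vector of 0, 1 or 2 pH values (sorted when 2).
#' @export
extract_optima <- function(fit) {
  type <- fit$model_type
  rng <- fit$gradient_range
  if (type == "I") return(numeric(0))
  resp <- function(x) .fit_response(fit, x)
  if (type == "II") {
    ends <- resp(c(0, 1))
    return(unscale_gradient(if (ends[2L] > ends[1L]) 1 else 0,
                            rng[1L], rng[2L]))
  }
  grid <- seq(0, 1, by = 1e-3)
  vals <- resp(grid)
  if (type == "III") {
    thr <- 0.95 * max(vals)
    xs <- range(grid[vals >= thr])
    return(sort(unscale_gradient(xs, rng[1L], rng[2L])))
  }
  # IV, V: grid argmax + local refinement
  i <- which.max(vals)
  lo <- grid[max(1L, i - 2L)]
  hi <- grid[min(length(grid), i + 2L)]
  x_star <- if (hi > lo) {
    opt <- optimize(resp, c(lo, hi), maximum = TRUE, tol = 1e-9)
    if (opt$objective >= vals[i]) opt$maximum else grid[i]
  } else grid[i]
  unscale_gradient(x_star, rng[1L], rng[2L])
}

#' Fit HOF models to every OTU of a table
#'
#' Applies [hof_fit()] row by row. Each OTU gets its own deterministic seed
#' derived from `seed` and the OTU id, so results do not depend on fitting
#' order or subsetting.
#'
#' @param table an [otu_table()].
#' @param n_boot,seed passed to [hof_fit()].
#' @param gradient_range pH range defining the scaled gradient; defaults to the
#'   range observed in the table.
#' @param progress print a dot every 25 OTUs.
#' @return An object of class `hof_fit_list`: a named list of `hof_fit`
#'   objects with an [as.data.frame()] method producing the flat trait table
#'   (columns `otu_id`, `model_type`, `a`-`d`, `M`, `logLik`, `AIC`,
#'   `opt1_pH`, `opt2_pH`, `boot_I`..`boot_V`, `n_boot_failed`).
#' @export
hof_fit_table <- function(table, n_boot = 100, seed = NULL,
                          gradient_range = range(table$samples$pH),
                          progress = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  ids <- rownames(table$counts)
  fits <- vector("list", length(ids))
  names(fits) <- ids
  for (i in seq_along(ids)) {
    fits[[i]] <- hof_fit(
      table$counts[i, ], table$samples$pH, n_boot = n_boot,
      seed = if (is.null(seed)) NULL else derive_seed(seed, ids[i]),
      otu_id = ids[i], gradient_range = gradient_range)
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  structure(fits, class = "hof_fit_list")
}

#' @export
as.data.frame.hof_fit_list <- function(x, ...) {
  rows <- lapply(unclass(x), function(f) {
    opt <- f$optima_pH
    data.frame(
      otu_id = f$otu_id, model_type = f$model_type,
      a = f$params[["a"]], b = f$params[["b"]], c = f$params[["c"]],
      d = f$params[["d"]], M = f$M, logLik = f$logLik, AIC = f$AIC,
      opt1_pH = if (length(opt) >= 1L) opt[1L] else NA_real_,
      opt2_pH = if (length(opt) >= 2L) opt[2L] else NA_real_,
      boot_I = f$bootstrap_tally[["I"]], boot_II = f$bootstrap_tally[["II"]],
      boot_III = f$bootstrap_tally[["III"]],
      boot_IV = f$bootstrap_tally[["IV"]], boot_V = f$bootstrap_tally[["V"]],
      n_boot_failed = f$n_boot_failed,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.hof_fit_list <- function(x, ...) {
  types <- vapply(unclass(x), `[[`, character(1L), "model_type")
  cat("HOF fits for", length(x), "OTUs\n")
  print(table(factor(types, levels = .hof_types)))
  invisible(x)
}
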