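# pH response-group classification from fitted optima.

.response_classes <- c("acid", "mid", "neutral", "acid_to_mid",
                       "acid_to_neutral", "mid_to_neutral", "no_preference")

.ph_band <- function(ph, t_low, t_high) {
  # boundary values (exactly t_low or t_high) fall in the closed middle band
  ifelse(ph < t_low, "acid", ifelse(ph > t_high, "neutral", "mid"))
}

#' Classify fitted pH optima into response groups
#'
#' A single optimum below `t_low` is `acid`, above `t_high` is `neutral`, and
#' between them is `mid`. Plateau fits carry two optima: if both fall in one
#' band the OTU gets that band's class, otherwise one of the range classes
#' `acid_to_mid`, `mid_to_neutral` or `acid_to_neutral`. No optimum (a flat,
#' type I fit) gives `no_preference`. Optima exactly on a threshold are
#' assigned to the closed middle band.
#'
#' @param optima numeric vector of 0, 1 or 2 pH optima (sorted ascending when
#'   2), or `NULL`.
#' @param t_low,t_high pH thresholds; defaults 5.2 and 7.0.
#' @return One of `"acid"`, `"mid"`, `"neutral"`, `"acid_to_mid"`,
#'   `"acid_to_neutral"`, `"mid_to_neutral"`, `"no_preference"`.
#' @export
classify_response <- function(optima, t_low = 5.2, t_high = 7.0) {
  if (!(t_low < t_high)) stop("t_low must be below t_high")
  optima <- optima[!is.na(optima)]
  if (length(optima) == 0L) return("no_preference")
  if (length(optima) > 2L) stop("at most two optima are supported")
  if (length(optima) == 1L) return(.ph_band(optima, t_low, t_high))
  if (optima[1L] > optima[2L]) stop("two optima must be sorted ascending")
  bands <- .ph_band(optima, t_low, t_high)
  if (bands[1L] == bands[2L]) return(bands[1L])
  key <- paste(bands, collapse = "-")
  switch(key,
         "acid-mid" = "acid_to_mid",
         "acid-neutral" = "acid_to_neutral",
         "mid-neutral" = "mid_to_neutral",
         stop("unexpected band pair: ", key))
}

#' Proportion of OTUs in each pH response group
#'
#' @param classes character vector of response classes (values among the seven
#'   recognised groups).
#' @return Named numeric vector over all seven classes, summing to 1.
#' @export
summarize_classes <- function(classes) {
  if (!length(classes)) stop("no classes to summarize")
  bad <- setdiff(unique(classes), .response_classes)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  tab <- table(factor(classes, levels = .response_classes))
  setNames(as.numeric(tab) / length(classes), .response_classes)
}

#' Build the flat pH-trait table from a set of HOF fits
#'
#' One row per OTU in the released flat-file style: model type, optima and
#' response class.
#'
#' @param fits a `hof_fit_list` from [hof_fit_table()] (or a list of
#'   [hof_fit()] objects).
#' @param t_low,t_high thresholds passed to [classify_response()].
#' @return data.frame with columns `otu_id`, `model_type`, `opt1_pH`,
#'   `opt2_pH`, `pH_class`.
#' @export
classify_fits <- function(fits, t_low = 5.2, t_high = 7.0) {
  rows <- lapply(unclass(fits), function(f) {
    opt <- f$optima_pH
    data.frame(
      otu_id = f$otu_id, model_type = f$model_type,
      opt1_pH = if (length(opt) >= 1L) opt[1L] else NA_real_,
      opt2_pH = if (length(opt) >= 2L) opt[2L] else NA_real_,
      pH_class = classify_response(opt, t_low, t_high),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
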