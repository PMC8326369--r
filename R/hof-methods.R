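# S3 methods for "hof_fit" model objects.

#' @export
print.hof_fit <- function(x, ...) {
  cat(sprintf("HOF fit for '%s': type %s (initial AIC choice %s)\n",
              x$otu_id, x$model_type, x$initial_type))
  p <- x$params[!is.na(x$params)]
  cat("  params:", paste(sprintf("%s = %.4g", names(p), p), collapse = ", "),
      sprintf("%s| M = %.4g\n", if (isTRUE(x$rev)) "(reversed gradient) " else "",
              x$M))
  cat(sprintf("  logLik = %.3f, k = %d, AIC = %.3f\n", x$logLik, x$k, x$AIC))
  if (length(x$optima_pH))
    cat("  pH optima:", paste(sprintf("%.3f", x$optima_pH), collapse = ", "),
        "\n")
  else cat("  pH optima: none (flat response)\n")
  if (x$n_boot > 0)
    cat("  bootstrap tally:",
        paste(sprintf("%s:%d", names(x$bootstrap_tally), x$bootstrap_tally),
              collapse = " "),
        if (x$n_boot_failed) sprintf("(%d failed)", x$n_boot_failed) else "",
        "\n")
  invisible(x)
}

#' @export
summary.hof_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.hof_fit")
}

#' @export
print.summary.hof_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nCandidate shapes (fitted on original data):\n")
  print(f$candidates, row.names = FALSE)
  cat(sprintf("\nresponse class: %s\n",
              classify_response(f$optima_pH)))
  invisible(x)
}

#' @export
coef.hof_fit <- function(object, ...) {
  object$params[!is.na(object$params)]
}

#' @export
logLik.hof_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = length(object$data$counts),
            class = "logLik")
}

#' Predicted expected counts from a fitted HOF curve
#'
#' @param object a [hof_fit()].
#' @param newdata numeric pH vector, or a data.frame with a `pH` column;
#'   defaults to the pH values the model was fitted on. Values outside the
#'   fitted gradient range are evaluated by affine extension of the scaled
#'   gradient, with a warning.
#' @param ... unused.
#' @return Expected counts (same scale as the fitted data).
#' @export
predict.hof_fit <- function(object, newdata = NULL, ...) {
  ph <- if (is.null(newdata)) object$data$ph
        else if (is.data.frame(newdata)) newdata$pH
        else newdata
  if (is.null(ph)) stop("newdata must be a pH vector or have a pH column")
  rng <- object$gradient_range
  x <- scale_gradient(ph, rng[1L], rng[2L])
  if (any(x < 0 | x > 1))
    warning("pH outside the fitted gradient range [",
            rng[1L], ", ", rng[2L], "]; extrapolating")
  .fit_response(object, x)
}

#' @export
fitted.hof_fit <- function(object, ...) predict(object)

#' @export
residuals.hof_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$data$counts - mu
  if (type == "pearson") r / sqrt(pmax(mu, .hof_mu_floor)) else r
}

#' @export
simulate.hof_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, rpois(length(mu), mu)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Plot a fitted HOF response curve over the data
#'
#' @param x a [hof_fit()].
#' @param n_grid number of points for the fitted curve.
#' @param ... passed to `plot()` for the data points.
#' @return `x`, invisibly.
#' @export
plot.hof_fit <- function(x, n_grid = 200, ...) {
  ph <- x$data$ph
  plot(ph, x$data$counts, xlab = "soil pH", ylab = "reads",
       main = sprintf("%s: HOF type %s", x$otu_id, x$model_type), ...)
  grid_ph <- seq(min(ph), max(ph), length.out = n_grid)
  lines(grid_ph, predict(x, grid_ph), lwd = 2)
  if (length(x$optima_pH))
    abline(v = x$optima_pH, lty = 2)
  invisible(x)
}
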