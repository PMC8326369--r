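# The five HOF (Huisman-Olff-Fresco) response shapes on a [0,1]-scaled
# gradient, their Poisson negative log-likelihood, and the bounded multi-start
# optimizer used to fit a single shape. All shapes are built from the
# decreasing logistic g(t) = 1/(1 + exp(t)):
#
#   I   mu = M * g(a)                     flat
#   II  mu = M * g(a + b x)               monotone
#   III mu = M * g(a + b x) * g(c)        monotone reaching a plateau < M
#   IV  mu = M * g(a + b x) * g(c - b x)  symmetric unimodal
#   V   mu = M * g(a + b x) * g(c - d x)  skewed unimodal
#
# M is a fixed scaling constant (the OTU's maximum observed count), not a free
# parameter, so AIC is comparable across shapes; only a-d are counted in k.
# b, d >= 0; increasing monotone shapes are reached by also fitting on the
# reversed gradient 1 - x and keeping the better likelihood.

.hof_types <- c("I", "II", "III", "IV", "V")
.hof_k <- c(I = 1L, II = 2L, III = 3L, IV = 3L, V = 4L)
.hof_par_names <- list(I = "a", II = c("a", "b"), III = c("a", "b", "c"),
                       IV = c("a", "b", "c"), V = c("a", "b", "c", "d"))
.hof_lower <- c(a = -50, b = 0, c = -50, d = 0)
.hof_upper <- c(a = 50, b = 200, c = 50, d = 200)
.hof_mu_floor <- 1e-10

.g <- function(t) plogis(-t)

#' Scale pH onto the unit gradient
#'
#' Affine map of pH onto `[0, 1]` over the fitted gradient range. Values
#' outside the range map outside `[0, 1]`, which is permitted for prediction.
#'
#' @param ph numeric pH value(s).
#' @param ph_min,ph_max gradient endpoints, `ph_max > ph_min`.
#' @return `(ph - ph_min) / (ph_max - ph_min)`.
#' @export
scale_gradient <- function(ph, ph_min, ph_max) {
  if (!(ph_max > ph_min)) stop("ph_max must exceed ph_min")
  (ph - ph_min) / (ph_max - ph_min)
}

#' Inverse of [scale_gradient()]
#' @param x scaled gradient position(s).
#' @inheritParams scale_gradient
#' @return pH values.
#' @export
unscale_gradient <- function(x, ph_min, ph_max) {
  if (!(ph_max > ph_min)) stop("ph_max must exceed ph_min")
  ph_min + x * (ph_max - ph_min)
}

#' Evaluate a HOF response shape
#'
#' @param x scaled gradient position(s), usually in `[0, 1]`.
#' @param model_type one of `"I"`..`"V"`.
#' @param params named numeric vector with elements among `a`, `b`, `c`, `d`
#'   as required by the type.
#' @param M positive scaling constant (maximum attainable response).
#' @return Expected response `mu`, with `0 <= mu <= M` everywhere.
#' @export
hof_response <- function(x, model_type, params, M) {
  model_type <- match.arg(model_type, .hof_types)
  p <- as.list(params)
  need <- .hof_par_names[[model_type]]
  vals <- unlist(p[need])
  if (length(vals) != length(need) || any(!is.finite(vals)))
    stop("non-finite or missing parameter(s) for type ", model_type, ": ",
         paste(need, collapse = ", "))
  if (!is.finite(M) || M <= 0) stop("M must be a positive finite scalar")
  a <- p$a; b <- p$b; c <- p$c; d <- p$d
  switch(model_type,
    I   = rep(M * .g(a), length(x)),
    II  = M * .g(a + b * x),
    III = M * .g(a + b * x) * .g(c),
    IV  = M * .g(a + b * x) * .g(c - b * x),
    V   = M * .g(a + b * x) * .g(c - d * x))
}

#' Poisson negative log-likelihood
#'
#' `sum(mu - y * log(mu) + log(y!))`, the exact negative log of the Poisson
#' probability mass. `mu` is floored at `1e-10` to avoid `log(0)`.
#'
#' @param counts non-negative integer vector.
#' @param mu expected values, same length.
#' @return The negative log-likelihood (a single number).
#' @export
poisson_nll <- function(counts, mu) {
  if (length(counts) != length(mu)) stop("counts and mu differ in length")
  if (!is_count_vector(counts)) stop("counts must be non-negative integers")
  mu <- pmax(mu, .hof_mu_floor)
  sum(mu - counts * log(mu) + lgamma(counts + 1))
}

# mu and its Jacobian w.r.t. the free parameters, for one shape on data x.
.hof_mu_grad <- function(x, type, theta, M) {
  a <- theta[1L]
  if (type == "II") {
    gu <- .g(a + theta[2L] * x)
    mu <- M * gu
    J <- cbind(-mu * (1 - gu), -mu * (1 - gu) * x)
  } else if (type == "III") {
    gu <- .g(a + theta[2L] * x)
    gc_ <- .g(theta[3L])
    mu <- M * gu * gc_
    J <- cbind(-mu * (1 - gu), -mu * (1 - gu) * x, -mu * (1 - gc_))
  } else if (type == "IV") {
    gu <- .g(a + theta[2L] * x)
    gv <- .g(theta[3L] - theta[2L] * x)
    mu <- M * gu * gv
    J <- cbind(-mu * (1 - gu),
               (-mu * (1 - gu) + mu * (1 - gv)) * x,
               -mu * (1 - gv))
  } else { # V
    gu <- .g(a + theta[2L] * x)
    gv <- .g(theta[3L] - theta[4L] * x)
    mu <- M * gu * gv
    J <- cbind(-mu * (1 - gu), -mu * (1 - gu) * x,
               -mu * (1 - gv), mu * (1 - gv) * x)
  }
  list(mu = mu, J = J)
}

# Deterministic multi-starts: a 3x3 grid of (a, b) around a logit-linear
# regression of the scaled counts, spread starts for c (and d), and
# data-informed starts placing a unimodal optimum at the empirical abundance
# peak or a plateau at the empirical saturation level.
.hof_starts <- function(type, x, y, M) {
  z <- (y + 0.5) / (M + 1)
  z <- qlogis(pmin(pmax(z, 1e-6), 1 - 1e-6))
  fit <- lm.fit(cbind(1, x), -z) # g(a + b x) ~ z  =>  -(a + b x) ~ logit(z)
  a0 <- -fit$coefficients[1L]
  b0 <- -fit$coefficients[2L]
  if (!is.finite(a0)) a0 <- 0
  if (!is.finite(b0) || b0 < 0.5) b0 <- 2
  a0 <- min(max(a0, -45), 45)
  b0 <- min(max(b0, 0.5), 150)

  # binned abundance profile: where is the peak, and how high is it?
  bin <- pmax(pmin(findInterval(x, seq(0, 1, length.out = 11L),
                                rightmost.closed = TRUE), 10L), 1L)
  prof <- vapply(split(y, factor(bin, levels = 1:10)),
                 function(v) if (length(v)) mean(v) else -Inf, numeric(1L))
  x_peak <- (which.max(prof) - 0.5) / 10
  peak_rel <- min(max(max(prof) / M, 1e-4), 1 - 1e-4)
  t_uni <- -qlogis(sqrt(peak_rel)) # g(t)^2 = peak_rel at the optimum
  c_plateau <- -qlogis(peak_rel)   # g(c) = plateau level for type III

  grid_ab <- expand.grid(a = a0 + c(-2, 0, 2), b = b0 * c(0.5, 1, 2))
  ab_starts <- function(extra) lapply(seq_len(nrow(grid_ab)), function(i)
    c(a = grid_ab$a[i], b = grid_ab$b[i], extra))
  peak_starts <- function(with_d = FALSE) lapply(c(5, 15, 40), function(b)
    c(a = t_uni - b * x_peak, b = b, c = t_uni + b * x_peak,
      if (with_d) c(d = b)))

  st <- switch(type,
    II = ab_starts(NULL),
    III = c(
      ab_starts(c(c = 0)),
      lapply(c(-2, 2, c_plateau), function(cc) c(a = a0, b = b0, c = cc)),
      list(c(a = a0, b = 25, c = c_plateau))),
    IV = c(
      ab_starts(c(c = 0)),
      lapply(c(-2, 2), function(cc) c(a = a0, b = b0, c = cc)),
      peak_starts()),
    V = c(
      ab_starts(c(c = 0, d = b0)),
      lapply(as.data.frame(t(expand.grid(c = c(-2, 0, 2),
                                         d = c(0, 2, b0)))),
             function(cd) c(a = a0, b = b0, c = cd[1L], d = cd[2L])),
      peak_starts(with_d = TRUE)))
  lapply(st, function(s) {
    nm <- .hof_par_names[[type]]
    pmin(pmax(setNames(as.numeric(s), nm), .hof_lower[nm] + 1e-8),
         .hof_upper[nm] - 1e-8)
  })
}

# Fit one shape on prepared scaled data for one orientation.
.hof_optim <- function(type, x, y, M, starts) {
  nm <- .hof_par_names[[type]]
  fn <- function(theta) {
    mu <- pmax(.hof_mu_grad(x, type, theta, M)$mu, .hof_mu_floor)
    sum(mu - y * log(mu))
  }
  gr <- function(theta) {
    mg <- .hof_mu_grad(x, type, theta, M)
    mu <- pmax(mg$mu, .hof_mu_floor)
    colSums((1 - y / mu) * mg$J)
  }
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, fn, gr, method = "L-BFGS-B",
            lower = .hof_lower[nm], upper = .hof_upper[nm],
            control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  best
}

#' Fit one HOF shape to counts along a pH gradient
#'
#' Poisson maximum likelihood for a single response shape over a bounded
#' parameter box (`a, c` in `[-50, 50]`; `b, d` in `[0, 200]`), from a
#' deterministic multi-start set; both gradient orientations (`x` and `1 - x`)
#' are tried and the better likelihood kept, so increasing and decreasing
#' shapes are both reachable with `b, d >= 0`.
#'
#' @param counts non-negative integer vector (one OTU's reads per sample).
#' @param ph sample pH values, same length.
#' @param model_type one of `"I"`..`"V"`.
#' @param M scaling constant; defaults to the maximum observed count.
#' @param gradient_range length-2 pH range defining the scaled gradient;
#'   defaults to `range(ph)`.
#' @param starts optional list of start vectors (used internally for warm
#'   starts); by default a deterministic multi-start grid is built from a
#'   logit-linear regression.
#' @param extra_starts additional start vectors appended to the default set;
#'   used by [hof_fit()] to seed each shape with the solution of the shape it
#'   nests, which guarantees the likelihood ordering of nested shapes.
#' @param orientations logical vector of gradient orientations to try
#'   (`FALSE` = as-is, `TRUE` = reversed); defaults to both for types II-V.
#' @return A list with `model_type`, `params` (named a-d, `NA` where unused),
#'   `rev` (fitted on the reversed gradient?), `M`, `k`, `logLik`, `AIC`,
#'   `gradient_range`.
#' @export
fit_single_model <- function(counts, ph, model_type, M = max(counts),
                             gradient_range = range(ph), starts = NULL,
                             extra_starts = NULL, orientations = NULL) {
  model_type <- match.arg(model_type, .hof_types)
  if (length(counts) != length(ph)) stop("counts and ph differ in length")
  if (!is_count_vector(counts)) stop("counts must be non-negative integers")
  if (all(counts == 0)) stop("cannot fit: counts are all zero")
  k <- .hof_k[[model_type]]
  if (length(counts) < k + 1L)
    stop("need at least ", k + 1L, " samples to fit type ", model_type)
  x0 <- scale_gradient(ph, gradient_range[1L], gradient_range[2L])
  ll_const <- sum(lgamma(counts + 1))

  finish <- function(theta, rev, value) {
    params <- setNames(rep(NA_real_, 4L), c("a", "b", "c", "d"))
    params[.hof_par_names[[model_type]]] <- theta
    logLik <- -(value + ll_const)
    list(model_type = model_type, params = params, rev = rev, M = M,
         k = k, logLik = logLik, AIC = 2 * k - 2 * logLik,
         gradient_range = gradient_range)
  }

  if (model_type == "I") {
    gbar <- min(max(mean(counts) / M, 1e-12), 1 - 1e-12)
    a <- min(max(log(1 / gbar - 1), .hof_lower["a"]), .hof_upper["a"])
    mu <- pmax(rep(M * .g(a), length(counts)), .hof_mu_floor)
    return(finish(c(a = unname(a)), FALSE,
                  sum(mu - counts * log(mu))))
  }

  if (is.null(orientations)) orientations <- c(FALSE, TRUE)
  best <- NULL
  best_rev <- FALSE
  nm_free <- .hof_par_names[[model_type]]
  clamp <- function(s)
    pmin(pmax(setNames(as.numeric(s[nm_free]), nm_free),
              .hof_lower[nm_free] + 1e-9), .hof_upper[nm_free] - 1e-9)
  for (rev in orientations) {
    x <- if (rev) 1 - x0 else x0
    st <- starts %||% .hof_starts(model_type, x, counts, M)
    if (!is.null(extra_starts)) st <- c(st, lapply(extra_starts, clamp))
    res <- .hof_optim(model_type, x, counts, M, st)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
      best_rev <- rev
    }
  }
  if (is.null(best))
    stop("optimizer failed to converge from every start for type ",
         model_type)
  finish(best$par, best_rev, best$value)
}

# Evaluate a fitted candidate's response at scaled gradient positions,
# honouring the fitted orientation.
.fit_response <- function(fit, x) {
  xx <- if (isTRUE(fit$rev)) 1 - x else x
  hof_response(xx, fit$model_type, fit$params[!is.na(fit$params)], fit$M)
}
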