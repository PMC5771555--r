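#' Sample autocorrelation profile with a white-noise band
#'
#' @param series Numeric series (counts or residuals).
#' @param max_lag Largest lag to evaluate.
#' @return List with `acf` (lags 1..`max_lag`), `ci_halfwidth`
#'   (\eqn{1.96/\sqrt n}) and `n`.
#' @export
acf_profile <- function(series, max_lag = 10) {
  n <- length(series)
  if (n <= max_lag + 1) stop("series too short for requested max_lag")
  if (sd(series) == 0) stop("constant series: autocorrelation undefined")
  a <- acf(series, lag.max = max_lag, plot = FALSE, demean = TRUE)
  list(acf = as.numeric(a$acf)[-1], ci_halfwidth = 1.96 / sqrt(n), n = n)
}

#' Choose a systematic thinning interval from an autocorrelation profile
#'
#' Returns `L + 1` where `L` is the smallest lag such that the
#' autocorrelation at `L` and at every in-range multiple of `L` lies inside
#' the 95% white-noise band. A series whose ACF first becomes acceptable at a
#' multiple of lag 4 therefore yields interval 5 — retain every fifth record.
#'
#' @param acf_values Autocorrelations at lags 1, 2, ... (e.g.
#'   `acf_profile(x)$acf`).
#' @param ci_halfwidth Half-width of the white-noise band.
#' @return Integer thinning interval (>= 2).
#' @export
select_thinning_interval <- function(acf_values, ci_halfwidth) {
  L_max <- length(acf_values)
  for (L in seq_len(L_max)) {
    mult <- seq(L, L_max, by = L)
    if (all(abs(acf_values[mult]) <= ci_halfwidth)) return(L + 1L)
  }
  stop("series too persistent: no acceptable lag within range")
}

#' Choose one thinning interval for a whole count table
#'
#' Mirrors the field protocol: a separate autocorrelation analysis per camera
#' position, pooling deployments — per-ASU sample autocorrelations are
#' averaged within each position and compared against a white-noise band
#' pooled over the contributing records (\eqn{1.96/\sqrt{N}}). Each position
#' yields an interval via [select_thinning_interval()]; the largest is
#' returned so the thinned table is acceptable at every position.
#'
#' @param table A `count_table`.
#' @param response Column to analyse (default `"abundance"`).
#' @param max_lag Largest lag examined.
#' @return Integer thinning interval.
#' @export
select_table_thinning <- function(table, response = "abundance",
                                  max_lag = 10) {
  validate_count_table(table)
  pos_interval <- function(pos, L) {
    sub <- table[table$camera_position == pos, , drop = FALSE]
    acfs <- list(); ns <- integer(0)
    for (ix in split(seq_len(nrow(sub)), sub$asu_id)) {
      s <- sub[[response]][ix[order(sub$minute_index[ix])]]
      if (length(s) <= L + 1 || sd(s) == 0) next
      acfs[[length(acfs) + 1]] <-
        as.numeric(acf(s, lag.max = L, plot = FALSE)$acf)[-1]
      ns <- c(ns, length(s))
    }
    if (!length(acfs)) return(NA_integer_)
    avg <- Reduce(`+`, acfs) / length(acfs)
    select_thinning_interval(avg, 1.96 / sqrt(sum(ns)))
  }
  intervals <- integer(0)
  for (pos in levels(factor(table$camera_position))) {
    iv <- tryCatch(pos_interval(pos, max_lag), error = function(e) {
      # persistent within max_lag: look further out before giving up
      pos_interval(pos, max_lag + 5)
    })
    if (!is.na(iv)) intervals <- c(intervals, iv)
  }
  if (!length(intervals)) stop("no usable series for autocorrelation analysis")
  max(intervals)
}

#' Systematically thin a count table
#'
#' Within each `(asu_id, camera_position)` group, rows are ordered by
#' `minute_index` and every `interval`-th record retained, starting from the
#' first (offset configurable; the field protocol's offset is unstated, so a
#' fixed offset keeps the operation deterministic).
#'
#' @param table A `count_table`.
#' @param interval Thinning interval (>= 1; 1 is the identity).
#' @param offset 0-based phase of the first retained record.
#' @return The thinned `count_table`.
#' @export
thin_table <- function(table, interval, offset = 0L) {
  stopifnot(interval >= 1, offset >= 0, offset < interval)
  validate_count_table(table)
  grp <- interaction(table$asu_id, table$camera_position, drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(table)), grp), function(ix) {
    ix <- ix[order(table$minute_index[ix])]
    ix[seq(1L + offset, length(ix), by = interval)]
  }), use.names = FALSE)
  out <- table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# tau-quantile check loss and its smooth convex surrogate
check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

#' Polynomial quantile regression by smoothed check-loss minimisation
#'
#' Fits a degree-`degree` polynomial through the `tau`-quantile of `y` given
#' `x` by minimising the check loss \eqn{\sum_i \rho_\tau(y_i - p(x_i))}. The
#' non-smooth loss is replaced by the convex surrogate
#' \eqn{\rho_\tau^s(r) = \tau r + s\,\log(1 + e^{-r/s})} and minimised by
#' BFGS with an analytic gradient, annealing the smoothing scale `s` towards
#' zero; the covariate is standardised internally for conditioning. The
#' default is the exploratory fit used on the count data: a single global
#' quadratic through the median.
#'
#' @param x,y Covariate (e.g. water velocity, cm s^-1) and response.
#' @param degree Polynomial degree (default 2).
#' @param tau Quantile level in (0, 1) (default 0.5, the median).
#' @return A `quantile_poly_fit` object: `coefficients` (ascending powers of
#'   raw `x`), `loss` (exact check loss at the solution), `tau`, `degree`,
#'   and `predict`-able via the usual method.
#' @examples
#' x <- runif(200, 0, 40); y <- 2 + 0.3 * x + rnorm(200)
#' coef(quantile_poly_fit(x, y))
#' @export
quantile_poly_fit <- function(x, y, degree = 2, tau = 0.5) {
  stopifnot(length(x) == length(y), tau > 0, tau < 1, degree >= 1)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < degree + 2)
    stop("need at least degree + 2 distinct x values")
  mx <- mean(x); sx <- sd(x)
  if (sx == 0) stop("degenerate covariate")
  z <- (x - mx) / sx
  Z <- outer(z, 0:degree, `^`)
  beta <- qr.solve(crossprod(Z), crossprod(Z, y))  # LS start
  scale_y <- max(mad(y - Z %*% beta), 1e-6 * max(abs(y), 1), .Machine$double.eps)
  softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
  obj <- function(b, s) {
    r <- y - Z %*% b
    sum(tau * r + s * softplus(-r / s))
  }
  grad <- function(b, s) {
    r <- as.numeric(y - Z %*% b)
    w <- tau - 1 / (1 + exp(r / s))   # d rho / d r
    -as.numeric(crossprod(Z, w))
  }
  for (s in scale_y * c(1, 0.1, 0.01, 1e-3, 1e-5)) {
    fit <- optim(beta, obj, grad, s = s, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    beta <- fit$par
  }
  # map coefficients in standardised z back to raw x by interpolation at
  # degree + 1 nodes (exact for a polynomial)
  xs <- seq(min(x), max(x), length.out = degree + 1)
  zs <- (xs - mx) / sx
  ys <- outer(zs, 0:degree, `^`) %*% beta
  V <- outer(xs, 0:degree, `^`)
  coefs <- as.numeric(solve(V, ys))
  pred <- function(newx) as.numeric(outer(newx, 0:degree, `^`) %*% coefs)
  structure(list(coefficients = coefs, tau = tau, degree = degree,
                 loss = check_loss(y - pred(x), tau),
                 predict = pred, n = length(x)),
            class = "quantile_poly_fit")
}

#' @export
coef.quantile_poly_fit <- function(object, ...) object$coefficients

#' @export
predict.quantile_poly_fit <- function(object, newdata, ...) {
  object$predict(as.numeric(newdata))
}
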