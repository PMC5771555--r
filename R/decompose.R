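#' Split velocity components into low-pass mean and turbulent fluctuation
#'
#' Each component is decomposed as \eqn{u = \bar u + u'} where the
#' time-varying mean \eqn{\bar u} is the zero-phase low-pass filtered series
#' (4th-order Butterworth run forward and backward) and the fluctuation is the
#' residual, so the reconstruction `mean + fluct == input` holds exactly by
#' construction. Defining the mean by low-pass filtering (rather than the
#' burst average) removes slow non-turbulent motions — tidal drift, surface
#' waves — from the fluctuating signal before any turbulence statistic is
#' formed.
#'
#' The series mean is removed before filtering and restored afterwards; with
#' zero initial filter conditions this keeps the edge transient proportional
#' to the fluctuation amplitude rather than to the mean flow.
#'
#' @param burst A `velocity_burst` (see [simulate_adv_burst()],
#'   [read_burst_csv()]).
#' @param cutoff Low-pass cutoff (Hz); must be below the Nyquist frequency.
#'   The default 0.1 Hz separates tidal/wave motion from the turbulence band
#'   at typical estuarine advection speeds.
#' @return A `decomposed_burst`: the burst fields plus `mean_u/v/w`,
#'   `fluct_u/v/w` and `cutoff`.
#' @export
decompose <- function(burst, cutoff = 0.1) {
  fs <- burst$sample_rate
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  n <- length(burst$u)
  if (n < 10 * fs / cutoff)
    warning("burst shorter than 10 filter time constants; mean series unreliable")
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  lp <- function(x) {
    m <- mean(x)
    m + as.numeric(signal::filtfilt(bf, x - m))
  }
  out <- unclass(burst)
  for (cn in c("u", "v", "w")) {
    mu <- lp(burst[[cn]])
    out[[paste0("mean_", cn)]] <- mu
    out[[paste0("fluct_", cn)]] <- burst[[cn]] - mu
  }
  out$cutoff <- cutoff
  class(out) <- c("decomposed_burst", "velocity_burst")
  out
}

# central first difference with one-sided ends
canopy_diff <- function(x) {
  n <- length(x)
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
}

#' Phase-space threshold despiking
#'
#' Implements the phase-space thresholding method for ADV records: the
#' fluctuating series `x`, its first difference and its second difference span
#' a three-dimensional phase space; in each of the three two-dimensional
#' projections an ellipse with semi-axes \eqn{\lambda \sigma} is drawn, where
#' \eqn{\lambda = \sqrt{2 \ln n}} is the universal threshold and
#' \eqn{\sigma} a robust (median-absolute-deviation) scale estimate. The
#' x--second-difference projection is rotated by its principal angle before
#' thresholding. Samples outside any ellipse are flagged, replaced by linear
#' interpolation across good neighbours (nearest good value at the edges), and
#' the procedure iterates until no new spikes are found or the number of good
#' points stops changing (hard cap `max_iter`).
#'
#' @param fluct Fluctuating velocity series (m s^-1); must be finite
#'   (pre-screen missing values separately) and of length >= 100.
#' @param max_iter Iteration cap (default 20).
#' @return List with `clean` (despiked series) and `mask`, a `spike_mask`
#'   carrying `indices`, `iterations` and `replaced_values`.
#' @examples
#' x <- rnorm(1000); x[500] <- 12
#' despike(x)$mask$indices
#' @export
despike <- function(fluct, max_iter = 20) {
  n <- length(fluct)
  if (n < 100) stop("series too short to despike (need >= 100 samples)")
  if (any(!is.finite(fluct)))
    stop("non-finite values in input; screen missing data before despiking")
  x <- fluct
  lambda <- sqrt(2 * log(n))
  flagged <- logical(n)
  it <- 0
  repeat {
    it <- it + 1
    d1 <- canopy_diff(x)
    d2 <- canopy_diff(d1)
    xs <- x - median(x)
    s_x <- mad(x); s_d1 <- mad(d1); s_d2 <- mad(d2)
    if (s_x == 0 || s_d1 == 0 || s_d2 == 0) break  # e.g. constant series
    new <- (xs / (lambda * s_x))^2 + (d1 / (lambda * s_d1))^2 > 1
    new <- new | (d1 / (lambda * s_d1))^2 + (d2 / (lambda * s_d2))^2 > 1
    # principal-angle rotation of the (x, d2) projection; the angle is
    # estimated on samples passing the first two checks, since a spike
    # contributes ~ -2 A^2 to sum(x * d2) and would tilt the ellipse into
    # the body of the point cloud
    ok <- !new & !flagged
    theta <- atan2(sum(xs[ok] * d2[ok]), sum(xs[ok]^2))
    ct <- cos(theta); st <- sin(theta)
    # ellipse semi-axes a, b solve the projection extents along x and d2
    A <- matrix(c(ct^2, st^2, st^2, ct^2), 2, byrow = TRUE)
    ab2 <- solve(A, c((lambda * s_x)^2, (lambda * s_d2)^2))
    if (all(ab2 > 0)) {
      p <- xs * ct + d2 * st
      q <- -xs * st + d2 * ct
      new <- new | (p^2 / ab2[1] + q^2 / ab2[2] > 1)
    }
    new <- new & !flagged
    n_new <- sum(new)
    flagged <- flagged | new
    if (n_new > 0) {
      good <- which(!flagged)
      if (length(good) < 2) stop("despiking flagged nearly all samples")
      x[flagged] <- approx(good, fluct[good], xout = which(flagged),
                           method = "linear", rule = 2)$y
    }
    if (n_new == 0 || it >= max_iter) break
  }
  # Refinement: central differences smear a single-sample spike over its
  # neighbours, which get flagged alongside it. With all detections replaced,
  # restore each flagged sample on its own and keep it flagged only if it is
  # still outside an ellipse in the cleaned context; neighbours of true
  # spikes are unremarkable once the spike is gone and are restored.
  if (any(flagged)) {
    s_x <- mad(x); s_d1 <- mad(canopy_diff(x)); s_d2 <- mad(canopy_diff(canopy_diff(x)))
    med_x <- median(x)
    if (s_x > 0 && s_d1 > 0 && s_d2 > 0) {
      for (i in which(flagged)) {
        lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
        y <- x[lo:hi]
        y[i - lo + 1L] <- fluct[i]
        dy1 <- canopy_diff(y); dy2 <- canopy_diff(dy1)
        j <- i - lo + 1L
        xs_i <- y[j] - med_x
        out <- (xs_i / (lambda * s_x))^2 + (dy1[j] / (lambda * s_d1))^2 > 1 ||
          (dy1[j] / (lambda * s_d1))^2 + (dy2[j] / (lambda * s_d2))^2 > 1 ||
          (xs_i / (lambda * s_x))^2 + (dy2[j] / (lambda * s_d2))^2 > 1
        if (!out) {
          flagged[i] <- FALSE
          x[i] <- fluct[i]
        }
      }
      if (any(flagged)) {
        good <- which(!flagged)
        x[flagged] <- approx(good, fluct[good], xout = which(flagged),
                             method = "linear", rule = 2)$y
      }
    }
  }
  idx <- which(flagged)
  mask <- structure(list(indices = idx, iterations = it,
                         replaced_values = x[idx], n = n),
                    class = "spike_mask")
  list(clean = x, mask = mask)
}
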