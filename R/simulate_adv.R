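#' Parameters for a synthetic ADV turbulence burst
#'
#' Bundles everything needed to synthesise one acoustic Doppler velocimeter
#' (ADV) burst with a known turbulence energy dissipation rate. Defaults
#' reproduce the burst geometry of the field deployment the package emulates:
#' 25 Hz sampling in four-minute bursts, mean tidal flow of about 0.2 m s^-1.
#'
#' @param epsilon Turbulence energy dissipation rate (m^2 s^-3, >= 0). Zero
#'   disables the turbulent fluctuations.
#' @param mean_speed Mean streamwise speed \eqn{\bar u} (m s^-1, >= 0). Must be
#'   positive when `epsilon > 0`: the frozen-turbulence mapping between
#'   frequency and wavenumber is undefined at zero advection speed.
#' @param sample_rate Sampling rate (Hz).
#' @param duration Burst duration (s); `sample_rate * duration` must be a
#'   whole number of samples.
#' @param noise_sd Instrument white-noise standard deviation (m s^-1), a
#'   single value or a length-3 vector `(u, v, w)`. ADV geometry gives the
#'   vertical beam a lower noise floor, hence the smaller default for `w`.
#' @param spike_rate Fraction of samples (per component) replaced by spikes,
#'   in `[0, 0.05]`.
#' @param spike_amplitude Spike offset in multiples of the pre-spike
#'   fluctuation SD (>= 4).
#' @param angles Sensor misalignment, degrees, `c(theta_xy, theta_xz,
#'   theta_roll)`. Defined as the *correction* angles: running
#'   [estimate_rotation_angles()] on the misaligned burst recovers exactly
#'   these values.
#' @param wave_amp,wave_freq Amplitude (m s^-1) and frequency (Hz) of a
#'   low-frequency non-turbulent oscillation added to `u`; keep `wave_freq`
#'   below the decomposition cutoff so the low-pass mean absorbs it.
#' @param synth_fmin Low-frequency truncation (Hz) of the synthesis band; the
#'   model spectrum is only populated above this bound so that the wave term
#'   and the turbulence are separable by the decomposition filter.
#' @param alpha1 One-dimensional Kolmogorov spectral constant (default 1.5).
#' @param seed Integer seed governing all randomness for this burst.
#' @return An object of class `turb_sim_params`.
#' @seealso [simulate_adv_burst()], [simulate_profile()]
#' @export
turb_sim_params <- function(epsilon = 1e-5, mean_speed = 0.2, sample_rate = 25,
                            duration = 240,
                            noise_sd = c(u = 0.004, v = 0.004, w = 0.002),
                            spike_rate = 0, spike_amplitude = 8,
                            angles = c(0, 0, 0), wave_amp = 0, wave_freq = 0.05,
                            synth_fmin = 0.1, alpha1 = 1.5, seed = 1L) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon >= 0,
            is.numeric(mean_speed), length(mean_speed) == 1, mean_speed >= 0,
            sample_rate > 0, duration > 0,
            spike_amplitude >= 4, length(angles) == 3,
            wave_amp >= 0, wave_freq > 0, synth_fmin > 0, alpha1 > 0)
  n <- sample_rate * duration
  if (abs(n - round(n)) > 1e-8)
    stop("sample_rate * duration must give an integer number of samples")
  if (epsilon > 0 && mean_speed <= 0)
    stop("mean_speed must be > 0 when epsilon > 0: Taylor conversion undefined")
  if (spike_rate < 0 || spike_rate > 0.05)
    stop("spike_rate must lie in [0, 0.05]")
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, 3)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  names(noise_sd) <- c("u", "v", "w")
  structure(list(epsilon = epsilon, mean_speed = mean_speed,
                 sample_rate = sample_rate, duration = duration,
                 noise_sd = noise_sd, spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude, angles = angles,
                 wave_amp = wave_amp, wave_freq = wave_freq,
                 synth_fmin = synth_fmin, alpha1 = alpha1,
                 seed = as.integer(seed)),
            class = "turb_sim_params")
}

# Closed-form integral of the inertial-subrange model over [f1, f2] in the
# frequency domain: S(f) = A f^(-5/3) with A = C (2*pi/U)^(-2/3) and C the
# component constant. Used for cell-averaged synthesis and for oracles.
model_band_variance <- function(component, epsilon, U, f1, f2, alpha1 = 1.5) {
  C <- if (component == "w") (4 / 3) * (9 / 55) * alpha1 else (9 / 55) * alpha1
  A <- C * epsilon^(2 / 3) * (2 * pi / U)^(-2 / 3)
  (3 / 2) * A * (f1^(-2 / 3) - f2^(-2 / 3))
}

# Random-phase spectral synthesis with deterministic amplitudes: each retained
# frequency bin carries exactly the model variance integrated over its cell,
# so the sample variance equals the continuous band integral to machine
# precision and the DC component is exactly zero.
synth_turbulence <- function(n, fs, component, epsilon, U, fmin, alpha1) {
  if (epsilon <= 0) return(numeric(n))
  nf <- floor(n / 2)
  even <- n %% 2 == 0
  jmax <- if (even) nf - 1L else nf   # Nyquist bin left empty
  f <- (1:jmax) * fs / n
  df <- fs / n
  lo <- pmax(f - df / 2, fmin)
  hi <- f + df / 2
  pow <- ifelse(hi > fmin,
                model_band_variance(component, epsilon, U, lo, hi, alpha1), 0)
  phases <- runif(jmax, 0, 2 * pi)
  # Parseval: sum(x^2) = (2/n) * sum(|X_j|^2) for interior bins
  amp <- sqrt(pow * n^2 / 2)
  X <- complex(modulus = amp, argument = phases)
  full <- complex(length.out = n)
  full[2:(jmax + 1)] <- X
  full[n:(n - jmax + 1)] <- Conj(X)
  Re(fft(full, inverse = TRUE)) / n
}

rot2 <- function(a, b, theta_rad) {
  list(a =  a * cos(theta_rad) + b * sin(theta_rad),
       b = -a * sin(theta_rad) + b * cos(theta_rad))
}

#' Simulate one ADV velocity burst with known ground truth
#'
#' Builds the three fluctuating components by random-phase spectral synthesis
#' of the inertial-subrange model spectra (the `u`/`v` form and the 4/3
#' vertical form), adds the mean flow and an optional low-frequency wave
#' oscillation to `u`, adds per-component white instrument noise, injects
#' single-sample spikes at recorded indices, and finally mis-rotates the
#' triplet by the sensor misalignment angles. All ground truth (parameters,
#' spike indices, synthesis band) is kept in the `truth` field.
#'
#' @param params A [turb_sim_params()] object.
#' @param elevation Elevation above the seabed (cm), metadata.
#' @param location Location label (`"A"`, `"B"` or `"C"`), metadata.
#' @param profile_id Profile identifier, metadata.
#' @return A `velocity_burst`: list with `t`, `u`, `v`, `w`, `sample_rate`,
#'   `elevation`, `location`, `profile_id` and `truth`.
#' @examples
#' b <- simulate_adv_burst(turb_sim_params(epsilon = 1e-5, seed = 42))
#' sd(b$w)
#' @export
simulate_adv_burst <- function(params, elevation = NA, location = NA,
                               profile_id = NA) {
  stopifnot(inherits(params, "turb_sim_params"))
  p <- params
  n <- as.integer(round(p$sample_rate * p$duration))
  t <- (seq_len(n) - 1) / p$sample_rate

  set.seed(p$seed)
  fl <- list(
    u = synth_turbulence(n, p$sample_rate, "u", p$epsilon, p$mean_speed,
                         p$synth_fmin, p$alpha1),
    v = synth_turbulence(n, p$sample_rate, "v", p$epsilon, p$mean_speed,
                         p$synth_fmin, p$alpha1),
    w = synth_turbulence(n, p$sample_rate, "w", p$epsilon, p$mean_speed,
                         p$synth_fmin, p$alpha1))
  wave_phase <- runif(1, 0, 2 * pi)
  for (cn in c("u", "v", "w"))
    if (p$noise_sd[[cn]] > 0) fl[[cn]] <- fl[[cn]] + rnorm(n, 0, p$noise_sd[[cn]])

  u <- p$mean_speed + fl$u +
    p$wave_amp * sin(2 * pi * p$wave_freq * t + wave_phase)
  v <- fl$v
  w <- fl$w

  # spikes: indices and signs drawn before scaling so that changing
  # spike_amplitude leaves all non-spike samples untouched for a given seed
  n_spk <- round(p$spike_rate * n)
  spikes <- list(u = integer(0), v = integer(0), w = integer(0))
  comps <- list(u = u, v = v, w = w)
  if (n_spk > 0) {
    for (cn in c("u", "v", "w")) {
      idx <- sort(sample.int(n, n_spk))
      sgn <- sample(c(-1, 1), n_spk, replace = TRUE)
      s <- sd(fl[[cn]])
      if (s == 0) s <- max(p$noise_sd[[cn]], 1e-3)
      comps[[cn]][idx] <- comps[[cn]][idx] + sgn * p$spike_amplitude * s
      spikes[[cn]] <- idx
    }
  }

  # misalignment: inverse of the streamline-correction composition, so the
  # correction sequence (x-y, then x-z, then roll) recovers exactly `angles`
  a <- p$angles * pi / 180
  r <- rot2(comps$v, comps$w, -a[3])                 # roll about x
  comps$v <- r$a; comps$w <- r$b
  r <- rot2(comps$u, comps$w, -a[2])                 # x-z plane
  comps$u <- r$a; comps$w <- r$b
  r <- rot2(comps$u, comps$v, -a[1])                 # x-y plane
  comps$u <- r$a; comps$v <- r$b

  even <- n %% 2 == 0
  jmax <- if (even) floor(n / 2) - 1L else floor(n / 2)
  structure(list(t = t, u = comps$u, v = comps$v, w = comps$w,
                 sample_rate = p$sample_rate,
                 elevation = elevation, location = location,
                 profile_id = profile_id,
                 truth = list(params = p, spikes = spikes,
                              synth_band = c(p$synth_fmin,
                                             jmax * p$sample_rate / n + p$sample_rate / (2 * n)))),
            class = "velocity_burst")
}

#' @export
print.velocity_burst <- function(x, ...) {
  cat(sprintf("<velocity_burst> n = %d at %g Hz (%.1f s)\n",
              length(x$t), x$sample_rate, length(x$t) / x$sample_rate))
  cat(sprintf("  elevation %s cmab, location %s, profile %s\n",
              format(x$elevation), format(x$location), format(x$profile_id)))
  cat(sprintf("  mean (u, v, w) = (%.4f, %.4f, %.4f) m s^-1\n",
              mean(x$u), mean(x$v), mean(x$w)))
  invisible(x)
}

#' Simulate a vertical profile of ADV bursts
#'
#' One burst per elevation, sharing a profile identifier and (by default, the
#' rigid-frame assumption) identical misalignment angles. Per-burst seeds are
#' derived deterministically from the first parameter set's seed.
#'
#' @param params_by_elevation Named list mapping elevation (cmab, as the name)
#'   to a [turb_sim_params()] object.
#' @param location Location label shared by the profile.
#' @param profile_id Profile identifier.
#' @return List of `velocity_burst` objects, ordered by increasing elevation.
#' @examples
#' pars <- lapply(c(`15` = 4e-5, `23` = 2e-5, `26` = 1.5e-5, `38` = 1e-5),
#'                function(e) turb_sim_params(epsilon = e))
#' pr <- simulate_profile(pars, location = "C", profile_id = 1)
#' @export
simulate_profile <- function(params_by_elevation, location = NA,
                             profile_id = 1L) {
  if (length(params_by_elevation) == 0) stop("empty elevation map")
  elev <- as.numeric(names(params_by_elevation))
  if (anyNA(elev)) stop("elevation map must be named by numeric elevations")
  if (anyDuplicated(elev)) stop("duplicate elevations in profile")
  ord <- order(elev)
  base_seed <- params_by_elevation[[ord[1]]]$seed
  bursts <- vector("list", length(elev))
  for (i in seq_along(ord)) {
    p <- params_by_elevation[[ord[i]]]
    p$seed <- derive_seed(base_seed, i)
    bursts[[i]] <- simulate_adv_burst(p, elevation = elev[ord[i]],
                                      location = location,
                                      profile_id = profile_id)
  }
  bursts
}
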