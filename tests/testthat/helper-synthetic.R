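# Shared fixture builders; everything is generated in code at test time.

# Deterministic burst: constant mean flow plus integer-cycle sinusoid
# fluctuations (exactly zero sample means and v'w' covariance), optionally
# misaligned by `angles` (degrees) using the inverse of the streamline
# correction so recovery is exact.
make_deterministic_burst <- function(angles = c(0, 0, 0), n = 6000, fs = 25,
                                     mean_u = 0.2, amp = c(0.01, 0.02, 0.015)) {
  t <- (seq_len(n) - 1) / fs
  u <- rep(mean_u, n) + amp[1] * sin(2 * pi * 1 * t)
  v <- amp[2] * sin(2 * pi * 2 * t)
  w <- amp[3] * sin(2 * pi * 3 * t)
  a <- angles * pi / 180
  r <- canopyflow:::rot2(v, w, -a[3]); v <- r$a; w <- r$b
  r <- canopyflow:::rot2(u, w, -a[2]); u <- r$a; w <- r$b
  r <- canopyflow:::rot2(u, v, -a[1]); u <- r$a; v <- r$b
  structure(list(t = t, u = u, v = v, w = w, sample_rate = fs,
                 elevation = 30, location = "A", profile_id = 1, truth = NULL),
            class = "velocity_burst")
}

# Decomposed view without filtering: burst-average means, residual
# fluctuations. Valid because the deterministic fixtures have no
# low-frequency content.
make_decomposed <- function(burst) {
  d <- unclass(burst)
  for (cn in c("u", "v", "w")) {
    d[[paste0("mean_", cn)]] <- rep(mean(burst[[cn]]), length(burst[[cn]]))
    d[[paste0("fluct_", cn)]] <- burst[[cn]] - mean(burst[[cn]])
  }
  d$cutoff <- NA_real_
  class(d) <- c("decomposed_burst", "velocity_burst")
  d
}

# standard study-condition burst parameters with selectable seed
study_params <- function(epsilon = 1e-5, seed = 1, duration = 240, ...) {
  turb_sim_params(epsilon = epsilon, mean_speed = 0.2, sample_rate = 25,
                  duration = duration, seed = seed, ...)
}
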