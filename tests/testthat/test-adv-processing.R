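test_that("decomposition reconstructs exactly and handles constants", {
  b <- make_deterministic_burst()
  d <- decompose(b, cutoff = 0.1)
  expect_equal(d$mean_u + d$fluct_u, b$u, tolerance = 1e-13)
  expect_equal(d$mean_w + d$fluct_w, b$w, tolerance = 1e-13)
  cb <- b; cb$u <- rep(0.3, length(b$t)); cb$v <- cb$w <- rep(0, length(b$t))
  dc <- decompose(cb, cutoff = 0.1)
  expect_equal(dc$mean_u, rep(0.3, length(b$t)), tolerance = 1e-10)
  expect_equal(max(abs(dc$fluct_u)), 0, tolerance = 1e-10)
  expect_error(decompose(b, cutoff = 13), "Nyquist")
})

test_that("the low-pass split allocates variance by frequency", {
  fs <- 25; t <- (0:(600 * fs - 1)) / fs
  slow <- sin(2 * pi * 0.01 * t)
  fast <- sin(2 * pi * 5 * t)
  mk <- function(x) structure(list(t = t, u = x, v = 0 * t, w = 0 * t,
                                   sample_rate = fs, elevation = NA,
                                   location = NA, profile_id = NA),
                              class = "velocity_burst")
  ds <- decompose(mk(slow), cutoff = 0.1)
  expect_gt(var(ds$mean_u) / var(slow), 0.95)
  df <- decompose(mk(fast), cutoff = 0.1)
  expect_gt(var(df$fluct_u) / var(fast), 0.99)
})

test_that("despiking flags essentially nothing in clean Gaussian noise", {
  # universal threshold sqrt(2 ln 6000) ~ 4.17 robust SD; per-projection
  # outside-ellipse mass ~ exp(-lambda^2/2) = 1/n, so a handful at most
  counts <- vapply(1:5, function(s) {
    set.seed(s)
    length(despike(rnorm(6000))$mask$indices)
  }, numeric(1))
  expect_lte(mean(counts), 5)
  expect_lte(max(counts), 12)
})

test_that("a single large spike is flagged and sensibly replaced", {
  set.seed(42)
  x <- rnorm(2000)
  j <- 1000L
  x[j] <- 10
  r <- despike(x)
  expect_true(j %in% r$mask$indices)
  expect_lte(abs(r$clean[j] - (x[j - 1] + x[j + 1]) / 2), 3)
})

test_that("degenerate despike inputs behave", {
  z <- rep(0, 500)
  r <- despike(z)
  expect_length(r$mask$indices, 0)
  expect_identical(r$mask$iterations, 1)
  expect_error(despike(c(rnorm(200), NaN)), "non-finite")
  expect_error(despike(rnorm(50)), "short")
})

test_that("despiking its own output flags nothing new", {
  p <- study_params(epsilon = 1e-5, spike_rate = 0.01, seed = 3)
  d <- decompose(simulate_adv_burst(p))
  first <- despike(d$fluct_w)
  expect_gt(length(first$mask$indices), 0)
  expect_length(despike(first$clean)$mask$indices, 0)
})

test_that("rotation angles are recovered exactly on noise-free bursts", {
  d0 <- make_decomposed(make_deterministic_burst(c(0, 0, 0)))
  a0 <- estimate_rotation_angles(d0)
  expect_equal(c(a0$theta_xy, a0$theta_xz, a0$theta_cross), c(0, 0, 0),
               tolerance = 1e-8)
  for (ang in list(c(6, -4, 0), c(2, 3, 1.5), c(-8, 5, -3))) {
    d <- make_decomposed(make_deterministic_burst(ang))
    a <- estimate_rotation_angles(d)
    expect_equal(c(a$theta_xy, a$theta_xz, a$theta_cross), ang,
                 tolerance = 1e-6)
  }
})

test_that("streamline geometry matches hand-computable cases", {
  b <- make_deterministic_burst()
  b$v <- b$v - mean(b$v) + 0.2   # mean flow (0.2, 0.2, 0)
  a <- estimate_rotation_angles(make_decomposed(b))
  expect_equal(a$theta_xy, 45, tolerance = 1e-8)
  bz <- make_deterministic_burst()
  bz$u <- rep(1e-6, length(bz$t)); bz$v <- bz$w <- bz$u * 0
  expect_error(estimate_rotation_angles(make_decomposed(bz)),
               "indeterminate")
})

test_that("applying rotations conserves energy and zeroes the targets", {
  b <- simulate_adv_burst(study_params(1e-5, angles = c(4, 3, 2), seed = 8))
  d <- decompose(b)
  zero <- structure(list(theta_xy = 0, theta_xz = 0, theta_cross = 0,
                         third_rotation = "roll", source_elevations = NA),
                    class = "rotation_angles")
  expect_identical(apply_rotation(d, zero)$u, d$u)
  a <- estimate_rotation_angles(d)
  r <- apply_rotation(d, a)
  e_before <- sum(d$u^2 + d$v^2 + d$w^2)
  e_after <- sum(r$u^2 + r$v^2 + r$w^2)
  expect_equal(e_after / e_before, 1, tolerance = 1e-12)
  expect_lt(abs(mean(r$v)), 1e-10)
  expect_lt(abs(mean(r$w)), 1e-10)
  cvw <- mean(r$fluct_v * r$fluct_w) - mean(r$fluct_v) * mean(r$fluct_w)
  expect_lt(abs(cvw), 1e-10)
})

test_that("profile rotation averages the two upper elevations", {
  mk <- function(elev, ang) {
    b <- make_deterministic_burst(ang)
    b$elevation <- elev
    make_decomposed(b)
  }
  prof <- list(mk(15, c(2, 1, 0)), mk(23, c(2, 1, 0)),
               mk(26, c(2, 1, 0)), mk(38, c(4, 3, 0)))
  rp <- rotate_profile(prof)
  expect_equal(rp$angles$theta_xy, 3, tolerance = 1e-6)  # mean of 2 and 4
  expect_equal(rp$angles$theta_xz, 2, tolerance = 1e-6)
  expect_equal(rp$angles$source_elevations, c(26, 38))
  same <- rotate_profile(prof[1:3])
  expect_equal(same$angles$theta_xy, 2, tolerance = 1e-6)
  expect_error(rotate_profile(prof[1]), ">= 2")
})

test_that("rigid-frame misalignment is corrected across a whole profile", {
  pars <- lapply(c(`15` = 4e-5, `23` = 2e-5, `26` = 1.5e-5, `38` = 1e-5),
                 function(e) study_params(epsilon = e, angles = c(5, 3, 1),
                                          seed = 11))
  prof <- lapply(simulate_profile(pars), decompose)
  rp <- rotate_profile(prof)
  for (b in rp$bursts) {
    expect_lt(abs(mean(b$v)), 5e-3)
    expect_lt(abs(mean(b$w)), 5e-3)
  }
})

test_that("burst summaries report means, variances and covariance", {
  b <- make_deterministic_burst(c(0, 0, 0))
  b$u <- rep(0.2, length(b$t)); b$v <- b$w <- b$u * 0
  s <- burst_summary(make_decomposed(b))
  expect_equal(s$u_mean, 0.2)
  expect_equal(s$var_u + s$var_v + s$var_w, 0)
  p <- study_params(epsilon = 1e-5, noise_sd = 0, seed = 3)
  bs <- simulate_adv_burst(p)
  sm <- burst_summary(make_decomposed(bs))
  target <- integrate(function(f)
    model_spectrum("w", 1e-5, 2 * pi * f / 0.2) * 2 * pi / 0.2,
    bs$truth$synth_band[1], bs$truth$synth_band[2])$value
  expect_equal(sm$var_w, target, tolerance = 0.05)
})
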