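test_that("autocorrelation profiles match known processes", {
  set.seed(11)
  x <- rnorm(400)
  pr <- acf_profile(x, max_lag = 20)
  expect_equal(pr$ci_halfwidth, 1.96 / 20)
  expect_lte(mean(abs(pr$acf) > pr$ci_halfwidth), 0.15)
  ar <- as.numeric(arima.sim(list(ar = 0.8), 2000))
  expect_equal(acf_profile(ar, 5)$acf[1], 0.8, tolerance = 0.08)
  alt <- rep(c(1, -1), 100)
  expect_equal(acf_profile(alt, 3)$acf[1], -1, tolerance = 0.01)
  expect_error(acf_profile(rep(2, 50), 5), "constant")
})

test_that("the thinning interval mirrors the lag-acceptability rule", {
  # ACF inside the band first at lag 4 (and its multiples) -> keep every 5th
  acfv <- c(0.5, 0.45, 0.3, 0.05, 0.3, 0.25, 0.15, 0.02, 0.12, 0.1)
  expect_identical(select_thinning_interval(acfv, 0.1), 5L)
  # white noise: lag 1 already acceptable -> interval 2
  expect_identical(select_thinning_interval(rep(0.01, 10), 0.1), 2L)
  expect_error(select_thinning_interval(rep(0.9, 10), 0.1), "persistent")
})

test_that("thinning retains every k-th record within each group", {
  tab <- simulate_counts(count_sim_params(seed = 6))
  expect_identical(thin_table(tab, 1)$abundance, tab$abundance)
  th <- thin_table(tab, 5)
  for (ix in split(seq_len(nrow(th)),
                   interaction(th$asu_id, th$camera_position, drop = TRUE))) {
    expect_equal(th$minute_index[ix], c(1, 6, 11, 16, 21))
  }
  expect_equal(nrow(th), nrow(tab) / 23 * 5)  # ceiling(23/5) = 5 per group
})

test_that("table-level interval selection pools deployments by position", {
  k <- select_table_thinning(simulate_counts(count_sim_params(seed = 1)))
  expect_gte(k, 2)
  expect_lte(k, 15)
})

test_that("median polynomial quantile regression recovers exact fits", {
  set.seed(5)
  x <- runif(60, 0, 10)
  y <- 1 + 2 * x - 0.3 * x^2
  f <- quantile_poly_fit(x, y)
  expect_lt(f$loss, 1e-6)
  expect_equal(coef(f), c(1, 2, -0.3), tolerance = 1e-4)
  expect_equal(predict(f, c(0, 2)), c(1, 1 + 4 - 1.2), tolerance = 1e-4)
})

test_that("the median fit is consistent and outlier-robust", {
  set.seed(7)
  x <- runif(400, 0, 40)
  y <- 2 + x + rnorm(400)
  f1 <- quantile_poly_fit(x, y)
  expect_equal(coef(f1)[2], 1, tolerance = 0.1)
  expect_lt(abs(coef(f1)[3]), 0.01)
  y2 <- y; y2[1] <- y2[1] + 1000
  f2 <- quantile_poly_fit(x, y2)
  expect_lt(max(abs(coef(f1) - coef(f2))), 0.1)
  expect_error(quantile_poly_fit(rep(1, 10), rnorm(10)), "distinct")
})

test_that("the abundance GLM reports the study's term structure", {
  tab <- thin_table(simulate_counts(count_sim_params(seed = 2)), 5)
  r <- fit_abundance_glm(tab)
  expect_identical(r$terms$term,
                   c("tide", "camera_position", "tide:camera_position"))
  expect_identical(r$terms$df, c(1L, 3L, 3L))
  expect_true(all(r$terms$statistic_type == "F"))
  expect_gt(r$dispersion, 1)
  expect_true(all(fitted(r$fit) > 0))
  # deviance never increases as terms are added
  dev <- anova(r$fit)$"Resid. Dev"
  expect_true(all(diff(dev) <= 1e-8))
  rm_ <- fit_abundance_glm(tab, tests = "marginal")
  expect_setequal(rm_$terms$term,
                  c("tide", "camera_position", "tide:camera_position"))
})

test_that("quasi-Poisson dispersion is estimated near truth under equidispersion", {
  p <- count_sim_params(n_asu = 20, minutes_per_deployment = 50,
                        beta_pos = rep(0, 4), beta_tide = 0,
                        phi_ar = 0, ar_sd = 0, dispersion = 1, seed = 8)
  r <- fit_abundance_glm(simulate_counts(p))
  expect_equal(r$dispersion, 1, tolerance = 0.15)
})

test_that("abundance GLM input contracts are enforced", {
  tab <- simulate_counts(count_sim_params(seed = 2))
  z <- tab; z$abundance <- 0L; z$watercolumn_count <- 0L
  expect_error(fit_abundance_glm(z), "all-zero")
  one_tide <- tab[tab$tide == "flood", ]
  expect_error(fit_abundance_glm(one_tide), "levels")
  bad <- tab; bad$watercolumn_count[3] <- bad$abundance[3] + 5L
  expect_error(fit_abundance_glm(bad), "row")
})

test_that("the proportion GLM recovers null and effect structure", {
  p0 <- count_sim_params(n_asu = 20, minutes_per_deployment = 50,
                         gamma_pos = rep(0, 4), gamma_tide = 0,
                         gamma0 = qlogis(0.3), phi_ar = 0, ar_sd = 0,
                         seed = 3)
  tab <- simulate_counts(p0)
  r <- fit_proportion_glm(tab)
  expect_identical(unique(r$terms$statistic_type), "Chisq")
  pr <- fitted(r$fit)
  expect_true(all(pr > 0 & pr < 1))
  expect_equal(mean(pr), 0.3, tolerance = 0.05)
  # flood effect is detected with the right sign at study-like sizes
  hits <- vapply(1:10, function(s) {
    tt <- thin_table(simulate_counts(count_sim_params(seed = s)), 5)
    f <- fit_proportion_glm(tt)
    coef(f$fit)[["tideflood"]] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate proportions trigger a separation warning", {
  p <- count_sim_params(gamma0 = -30, gamma_pos = rep(0, 4), gamma_tide = 0,
                        seed = 4)
  w <- capture_warnings(fit_proportion_glm(simulate_counts(p)))
  expect_true(any(grepl("separation", w)))
})

test_that("Tukey contrasts enumerate all position pairs", {
  tab <- thin_table(simulate_counts(count_sim_params(seed = 5)), 5)
  r <- tukey_pairwise(fit_abundance_glm(tab))
  expect_equal(nrow(r$contrasts), 6)
  expect_true(all(r$contrasts$adjusted_p >= 0 & r$contrasts$adjusted_p <= 1))
  expect_error(tukey_pairwise(fit_abundance_glm(tab), factor = "depth"),
               "not in the fitted model")
})

test_that("Tukey adjustment controls the family-wise error under the null", {
  clean <- vapply(1:150, function(s) {
    p <- count_sim_params(beta_pos = rep(0, 4), beta_tide = 0,
                          phi_ar = 0, ar_sd = 0, dispersion = 1.5, seed = s)
    tab <- thin_table(simulate_counts(p), 5)
    r <- tukey_pairwise(fit_abundance_glm(tab))
    min(r$contrasts$adjusted_p) >= 0.05
  }, logical(1))
  expect_gte(mean(clean), 0.88)
})

test_that("simulated position preference is recovered by the fitted means", {
  # under the default effects and overdispersion the correct level tops the
  # ranking in ~80% of replicates -- well above the 25% chance level
  hits <- vapply(1:20, function(s) {
    tt <- thin_table(simulate_counts(count_sim_params(seed = s)), 5)
    f <- fit_abundance_glm(tt)
    em <- suppressMessages(emmeans::emmeans(f$fit, "camera_position"))
    s <- as.data.frame(em)
    s$camera_position[which.max(s$emmean)] == "down-current 1 m"
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})
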