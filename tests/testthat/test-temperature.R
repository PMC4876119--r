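test_that("bottle means average all time points", {
  st <- tidyr::expand_grid(
    month = "Jan", treatment = "C", offset = 0, temperature = 15,
    replicate = 1, group = "HNA", time = c(0, 2, 4)
  )
  st$mean_volume <- 0.05
  st$mean_gf_fru <- 0.03
  st$abundance <- c(1e5, 1e5, 1e5)
  bm <- bottle_means(st)
  expect_equal(bm$mean_volume, 0.05)

  st$mean_volume <- c(0.04, 0.05, 0.06)
  bm <- bottle_means(st)
  expect_equal(bm$mean_volume, 0.05)
  expect_equal(bm$n_timepoints, 3)
})

test_that("phase drift separates whole-experiment and growth-phase means", {
  amp <- 0.05
  tr <- zero_noise_truth()
  tr$drift_lag <- amp
  tr$drift_exponential <- -amp
  d <- small_design(1, sampling_times = c(0, 1, 2, 3, 4, 5, 6))
  ex <- simulate_experiment(d, tr, seed = 41, n_events = 300)
  st <- gate_experiment(ex)
  bm <- quietly(bottle_means(st)) |>
    dplyr::filter(treatment == "F", group == "HNA", offset == 0,
                  replicate == 1)
  truthv <- ex$truth$bottles |>
    dplyr::filter(treatment == "F", group == "HNA", offset == 0,
                  replicate == 1)
  # growth-phase mean sits at the exponential-phase drifted level; the
  # whole-experiment mean mixes lag, exponential and stationary levels
  expect_equal(bm$mean_volume_growth,
               truthv$mean_volume_true * (1 - amp), tolerance = 1e-6)
  expect_gt(bm$mean_volume, bm$mean_volume_growth)
})

test_that("temperature slope matches the closed-form OLS oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- sample(c(12, 15, 18), n, replace = TRUE)
    while (length(unique(x)) < 2) x <- sample(c(12, 15, 18), n, replace = TRUE)
    y <- 0.06 - 0.005 * x + rnorm(n, 0, 0.01)
    s <- fit_temperature_slope(
      tibble::tibble(temperature = x, mean_volume = y), "volume")
    o <- ols_oracle(x, y)
    expect_equal(s$slope, o$slope, tolerance = 1e-12)
    expect_equal(s$se, o$se, tolerance = 1e-12)
    expect_equal(c(s$ci_lo, s$ci_hi), o$ci, tolerance = 1e-12)
  }
  # hand-computable small instance
  x <- c(12, 12, 15, 15, 18, 18)
  y <- c(1, 2, 2, 3, 3, 4)
  s <- fit_temperature_slope(tibble::tibble(temperature = x, mean_volume = y),
                             "volume")
  expect_equal(s$slope, sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2),
               tolerance = 1e-12)
})

test_that("an exactly linear response returns the injected slope with r2 = 1", {
  sm <- tidyr::expand_grid(temperature = c(12, 15, 18), replicate = 1:3)
  sm$mean_volume <- 0.06 - 5.3e-3 * (sm$temperature - 15)
  s <- fit_temperature_slope(sm, "volume")
  expect_equal(s$slope, -5.3e-3, tolerance = 1e-12)
  expect_equal(s$r_squared, 1)
  expect_true(s$significant)
  expect_equal(s$n, 9)
  # degenerate design rejected
  sm$temperature <- 15
  expect_error(fit_temperature_slope(sm, "volume"), "equal")
})

test_that("null responses keep the nominal type-I error rate", {
  set.seed(43)
  reps <- 500
  hits <- replicate(reps, {
    sm <- simulate_bottle_summaries(0, 0.06, 0.005)
    names(sm)[names(sm) == "value"] <- "mean_volume"
    fit_temperature_slope(sm, "volume")$significant
  })
  # binomial(500, 0.05)99.9% envelope
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("percent per degC normalisation and its invariances", {
  expect_equal(percent_per_degc(0, 1), 0)
  expect_equal(percent_per_degc(-0.0045, 1.0), 0.45)
  # unit rescaling of slope and reference leaves the percent unchanged
  expect_equal(percent_per_degc(-0.0045 * 1e3, 1.0 * 1e3), 0.45)
  expect_error(percent_per_degc(-0.0045, 0), "> 0")
  expect_error(percent_per_degc(-0.0045, -1), "> 0")
})

test_that("NAC percent converts to base pairs through the genome anchors", {
  expect_equal(nac_to_basepairs(0.35, "LNA"), 7)    # 0.0035 x 2 Mbp
  expect_equal(nac_to_basepairs(0.52, "HNA"), 26)   # 0.0052 x 5 Mbp
  expect_equal(nac_to_basepairs(0, "HNA"), 0)
  expect_equal(genome_anchors(), c(LNA = 2, HNA = 5))
  expect_error(nac_to_basepairs(0.4, "XNA"), "unknown group")
})

test_that("sign coherence: negative slope, positive percent, positive kbp loss", {
  for (g in c("LNA", "HNA")) {
    slope <- -2e-3
    pct <- percent_per_degc(slope, 0.03)
    expect_gt(pct, 0)
    expect_gt(nac_to_basepairs(pct, g), 0)
  }
})

test_that("correlation of monthly responses: exact limits and zero-variance flag", {
  set.seed(45)
  a <- rnorm(6)
  slopes <- tibble::tibble(
    month = rep(month.abb[1:6], times = 2),
    treatment = "F",
    group = rep(c("HNA", "LNA"), each = 6),
    response = "volume",
    slope = c(a, -a)
  )
  out <- correlate_responses(slopes)
  expect_equal(out$r[1], -1)
  eq <- dplyr::mutate(slopes, slope = rep(a, 2))
  expect_equal(correlate_responses(eq)$r[1], 1)
  degen <- dplyr::mutate(slopes, slope = ifelse(group == "LNA", 0, slope))
  res <- correlate_responses(degen)
  expect_true(res$degenerate[1])
  expect_true(is.na(res$r[1]))
})

test_that("injected between-series correlation of monthly slopes is recovered", {
  set.seed(44)
  rho <- 0.77
  rs <- replicate(40, {
    z <- rnorm(12)
    a <- z
    b <- rho * z + sqrt(1 - rho^2) * rnorm(12)
    # monthly slope series with the injected correlation, estimated through
    # the regression machinery with small estimation noise
    est <- vapply(seq_len(12), function(m) {
      sm <- simulate_bottle_summaries(-4e-3 + 1e-3 * a[m], 0.06, 5e-4)
      names(sm)[3] <- "mean_volume"
      fit_temperature_slope(sm, "volume")$slope
    }, numeric(1))
    est_b <- vapply(seq_len(12), function(m) {
      sm <- simulate_bottle_summaries(-4e-3 + 1e-3 * b[m], 0.06, 5e-4)
      names(sm)[3] <- "mean_volume"
      fit_temperature_slope(sm, "volume")$slope
    }, numeric(1))
    cor(est, est_b)
  })
  # mean recovered r within sampling error of the injection (SE ~ 0.02)
  expect_lt(abs(mean(rs) - rho), 0.06)
})
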