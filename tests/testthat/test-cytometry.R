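test_that("bead normalisation is a fixed point, scale invariant, and divides exactly", {
  ev <- tibble::tibble(
    ssc_raw = c(rep(500, 25), 50),
    gf_raw = c(rep(2000, 25), 200),
    label = factor(c(rep("bead", 25), "LNA"), levels = c("bead", "LNA", "HNA"))
  )
  nb <- normalize_to_beads(ev)
  expect_equal(nb$ssc_ru[1], 1.0)           # bead maps to exactly 1 ru
  expect_equal(nb$ssc_ru[26], 0.1)          # 50 / 500
  expect_equal(nb$gf_fru[26], 0.1)

  # instrument gain change: all signals doubled, relative units unchanged
  ev2 <- dplyr::mutate(ev, ssc_raw = ssc_raw * 2, gf_raw = gf_raw * 2)
  nb2 <- normalize_to_beads(ev2)
  expect_equal(nb2$ssc_ru, nb$ssc_ru)
  expect_equal(nb2$gf_fru, nb$gf_fru)

  # too few beads is an explicit failure naming the acquisition
  few <- ev[c(1:10, 26), ]
  expect_error(normalize_to_beads(few, acquisition = "Jan/C/+0"),
               "too few bead events.*Jan/C")
})

test_that("gating recovers truth labels and the injected fru ratio", {
  # locations ~6 combined SDs apart in log fluorescence
  ev <- simulate_cytogram(5e4, 5e4, 500,
                          lna = list(ssc = 25, gf = 40),
                          hna = list(ssc = 30, gf = 68),
                          sdlog_ssc = 0.15, sdlog_gf = 0.09, seed = 21)
  g <- gate_populations(ev, bead = list(ssc = 500, gf = 2000))
  expect_false(attr(g, "gate")$unimodal)
  acc <- mean(as.character(g$label) == as.character(ev$truth_label))
  expect_gt(acc, 0.99)

  nb <- normalize_to_beads(g)
  ratio <- mean(nb$gf_fru[nb$label == "HNA"]) /
    mean(nb$gf_fru[nb$label == "LNA"])
  expect_lt(abs(ratio / 1.7 - 1), 0.05)

  # group abundances within 2% of truth
  st <- population_stats(nb, acquired_volume_mL = 0.1)
  truth_n <- table(ev$truth_label)
  expect_lt(abs(st$n_events[st$group == "LNA"] / truth_n[["LNA"]] - 1), 0.02)
  expect_lt(abs(st$n_events[st$group == "HNA"] / truth_n[["HNA"]] - 1), 0.02)
})

test_that("a unimodal fluorescence distribution is flagged, not mis-split", {
  ev <- tibble::tibble(ssc_raw = rep(25, 100), gf_raw = rep(40, 100))
  expect_warning(g <- gate_populations(ev), "unimodal")
  expect_true(attr(g, "gate")$unimodal)
  expect_equal(dplyr::n_distinct(g$label), 1)
})

test_that("relative units are invariant to any common rescaling of raw signals", {
  ev <- simulate_cytogram(2000, 2000, 100, seed = 22)
  g1 <- gate_populations(ev, bead = list(ssc = 500, gf = 2000))
  n1 <- normalize_to_beads(g1)
  for (c_scale in c(0.25, 7)) {
    ev2 <- dplyr::mutate(ev, ssc_raw = ssc_raw * c_scale,
                         gf_raw = gf_raw * c_scale)
    g2 <- gate_populations(ev2, bead = list(ssc = 500 * c_scale,
                                            gf = 2000 * c_scale))
    n2 <- normalize_to_beads(g2)
    expect_equal(n2$ssc_ru, n1$ssc_ru, tolerance = 1e-12)
    expect_equal(n2$gf_fru, n1$gf_fru, tolerance = 1e-12)
  }
})

test_that("SSC-to-diameter calibration evaluates, flags extrapolation, rejects non-monotone", {
  ident <- ssc_calibration(a = 1, b = 1)
  expect_equal(as.numeric(ssc_to_diameter(1, ident)), 1)
  sqrtm <- ssc_calibration(a = 1, b = 0.5)
  expect_equal(as.numeric(ssc_to_diameter(4, sqrtm)), 2)
  expect_warning(d <- ssc_to_diameter(1e-5, sqrtm), "extrapolated")
  expect_true(attr(d, "extrapolated")[1])
  expect_error(ssc_calibration(a = 1, b = -0.5), "non-monotone")
  expect_error(ssc_to_diameter(-1, sqrtm), "> 0")
  # loglog parameterisation is the same model
  ll <- ssc_calibration(a = 0, b = 0.5, form = "loglog")
  expect_equal(as.numeric(ssc_to_diameter(4, ll)), 2)
})

test_that("sphere volume closed form, cubic scaling and round trip", {
  expect_equal(diameter_to_volume(1), pi / 6)
  expect_equal(round(diameter_to_volume(1), 4), 0.5236)
  expect_equal(diameter_to_volume(2), 8 * diameter_to_volume(1))
  expect_equal(round(diameter_to_volume(2), 4), 4.1888)
  d <- volume_to_diameter(0.047)   # a realistic bacterial volume
  expect_equal(diameter_to_volume(d), 0.047, tolerance = 1e-12)
  expect_error(diameter_to_volume(0), "> 0")
  expect_error(diameter_to_volume(-2), "> 0")
})

test_that("dye inter-calibration recovers an injected linear relation", {
  set.seed(31)
  # 21 paired samples run with both stains
  syto <- runif(21, 0.01, 0.09)
  sybr <- 0.8 * syto + 0.01 + rnorm(21, 0, 0.002)
  m <- fit_dye_calibration(tibble::tibble(syto = syto, sybr = sybr))
  co <- summary(m$fit)$coefficients
  expect_lt(abs(m$slope - 0.8), 2 * co[2, 2])
  expect_lt(abs(m$intercept - 0.01), 2 * co[1, 2])
  expect_gt(m$r_squared, 0.9)

  ident <- m
  ident$intercept <- 0; ident$slope <- 1
  expect_equal(syto_to_sybr(c(0.02, 0.05), ident), c(0.02, 0.05))
  expect_error(syto_to_sybr(0.02, NULL), "no dye calibration")
  expect_error(
    fit_dye_calibration(tibble::tibble(syto = syto, sybr = -2 * syto)),
    "non-monotone"
  )
})

test_that("population stats divide counts by volume and flag empty gates", {
  ev <- tibble::tibble(
    ssc_raw = rep(500, 1025), gf_raw = rep(2000, 1025),
    label = factor(c(rep("bead", 25), rep("HNA", 1000)),
                   levels = c("bead", "LNA", "HNA"))
  )
  nb <- normalize_to_beads(ev)
  st <- population_stats(nb, acquired_volume_mL = 0.04)
  expect_equal(st$abundance[st$group == "HNA"], 25000)
  lna <- st[st$group == "LNA", ]
  expect_true(lna$empty)
  expect_equal(lna$abundance, 0)
  expect_true(is.na(lna$mean_volume))
  expect_error(population_stats(nb, acquired_volume_mL = 0), "> 0")
})

test_that("population mean volume increases under a uniform SSC shift", {
  ev <- simulate_cytogram(5000, 5000, 100, seed = 23)
  g <- gate_populations(ev, bead = list(ssc = 500, gf = 2000))
  nb <- normalize_to_beads(g)
  st1 <- population_stats(nb, 0.1)
  nb2 <- dplyr::mutate(nb, ssc_ru = ifelse(label == "LNA", ssc_ru * 1.2,
                                           ssc_ru))
  st2 <- population_stats(nb2, 0.1)
  expect_gt(st2$mean_volume[st2$group == "LNA"],
            st1$mean_volume[st1$group == "LNA"])
  expect_equal(st2$mean_volume[st2$group == "HNA"],
               st1$mean_volume[st1$group == "HNA"])
})

test_that("pipeline event-level volume-NAC correlation matches the injection", {
  ev <- simulate_cytogram(0, 1e5, 300, correlation = 0.82, seed = 24)
  g <- gate_populations(ev, bead = list(ssc = 500, gf = 2000))
  nb <- normalize_to_beads(g)
  cal <- ssc_calibration()
  sel <- nb$label == "HNA"
  vol <- diameter_to_volume(as.numeric(
    suppressWarnings(ssc_to_diameter(nb$ssc_ru[sel], cal))))
  r <- cor(log(vol), log(nb$gf_fru[sel]))
  expect_lt(abs(r - 0.82), 0.03)
})

test_that("generator-known mean volume is recovered through the full conversion", {
  tr <- zero_noise_truth()
  d <- small_design(1, sampling_times = c(0, 1, 2, 3))
  ex <- simulate_experiment(d, tr, seed = 25, n_events = 400)
  st <- gate_experiment(ex)
  joined <- dplyr::inner_join(
    st, ex$truth$bottles,
    by = c("month", "treatment", "offset", "temperature", "replicate", "group")
  )
  expect_lt(max(abs(joined$mean_volume / joined$mean_volume_true - 1)), 1e-9)
})
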