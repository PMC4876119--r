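# Synthetic flow-cytometry and incubation-experiment generator.
# Every injected quantity is echoed back in a ground-truth record so that
# downstream estimators can be validated against known values.

# bivariate log-normal cluster; `loc` are the target *arithmetic* means of
# the two channels, `rho` the log-scale correlation
rlnorm_cluster <- function(n, loc_ssc, loc_gf, sdlog_ssc, sdlog_gf, rho = 0) {
  if (n == 0) {
    return(tibble::tibble(ssc_raw = numeric(0), gf_raw = numeric(0)))
  }
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  ssc <- exp(log(loc_ssc) - sdlog_ssc^2 / 2 + sdlog_ssc * z1)
  gf <- exp(log(loc_gf) - sdlog_gf^2 / 2 + sdlog_gf * z2)
  tibble::tibble(ssc_raw = ssc, gf_raw = gf)
}

#' Simulate one flow-cytometry acquisition (cytogram)
#'
#' Draws a tri-modal event cloud: LNA and HNA bacterial populations plus the
#' 1 um reference beads, each bivariate log-normal in side scatter and green
#' fluorescence with a common log-scale between-channel correlation for the
#' bacterial clusters. Cluster locations are the target arithmetic means of
#' the raw signals. The hidden population membership of every event is kept
#' as `truth_label`.
#'
#' @param n_lna,n_hna,n_beads Event counts per cluster (0 allowed: that
#'   cluster is simply absent).
#' @param lna,hna Lists with elements `ssc` and `gf`: raw-signal cluster
#'   locations. The HNA fluorescence location must exceed the LNA location
#'   (that is what defines the groups); violations are rejected.
#' @param bead List with `ssc`, `gf` and `cv` (coefficient of variation of
#'   the bead cluster).
#' @param sdlog_ssc,sdlog_gf Log-scale dispersion of the bacterial clusters
#'   (0 gives a point mass).
#' @param correlation Log-scale SSC-fluorescence correlation within each
#'   bacterial cluster.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `ssc_raw`, `gf_raw`, `truth_label`.
#' @export
#' @examples
#' ev <- simulate_cytogram(500, 500, 100,
#'   lna = list(ssc = 25, gf = 40), hna = list(ssc = 30, gf = 68), seed = 1)
#' table(ev$truth_label)
simulate_cytogram <- function(n_lna, n_hna, n_beads = 0,
                              lna = list(ssc = 25, gf = 40),
                              hna = list(ssc = 30, gf = 68),
                              bead = list(ssc = 500, gf = 2000, cv = 0.05),
                              sdlog_ssc = 0.18, sdlog_gf = 0.18,
                              correlation = 0.82, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n_lna > 0) stop_if_not_positive(c(lna$ssc, lna$gf), "lna location")
  if (n_hna > 0) stop_if_not_positive(c(hna$ssc, hna$gf), "hna location")
  if (n_lna > 0 && n_hna > 0 && hna$gf <= lna$gf) {
    rlang::abort("HNA fluorescence location must exceed the LNA location")
  }
  sd_bead <- sqrt(log(1 + bead$cv^2))
  parts <- list(
    LNA = rlnorm_cluster(n_lna, lna$ssc, lna$gf, sdlog_ssc, sdlog_gf, correlation),
    HNA = rlnorm_cluster(n_hna, hna$ssc, hna$gf, sdlog_ssc, sdlog_gf, correlation),
    bead = rlnorm_cluster(n_beads, bead$ssc, bead$gf, sd_bead, sd_bead, 0)
  )
  dplyr::bind_rows(parts, .id = "truth_label") |>
    dplyr::relocate("ssc_raw", "gf_raw") |>
    dplyr::mutate(truth_label = factor(.data$truth_label,
                                       levels = c("bead", "LNA", "HNA")))
}

# three-phase abundance curve: flat lag, exact exponential growth, then a
# carrying-capacity ceiling -- log-abundance is exactly linear in the
# exponential window
growth_curve <- function(t, mu, lag, n0, k) {
  te <- pmax(0, t - lag)
  pmin(n0 * exp(mu * te), k)
}

# Arrhenius temperature scaling of the reference rate
arrhenius_rate <- function(mu_ref, e_ev, temp_c, ref_c) {
  kb <- boltzmann_ev()
  mu_ref * exp(-(e_ev / kb) * (1 / celsius_to_kelvin(temp_c) -
                                 1 / celsius_to_kelvin(ref_c)))
}

growth_phase <- function(t, n, lag, k) {
  dplyr::case_when(
    t <= lag ~ "lag",
    n >= k ~ "stationary",
    .default = "exponential"
  )
}

#' Simulate a full year of warming incubations
#'
#' Generates the complete dataset of a monthly incubation study: one
#' cytometry acquisition per bottle and sampling time (with hidden truth
#' labels), the per-bottle abundance time series, and CARD-FISH / ARISA
#' community tables, together with a ground-truth record echoing every
#' injected parameter. Abundance follows lag, exponential (Arrhenius rate at
#' the bottle temperature) and saturating phases; population mean volume and
#' NAC at temperature T equal the ambient value plus the injected slope times
#' (T - T_ambient), perturbed by the stated bottle-level noise and optional
#' phase drift.
#'
#' One master seed is split deterministically into per-bottle substreams, so
#' identical `(design, truth, seed)` give identical output.
#'
#' @param design An [experiment_design()].
#' @param truth A [truth_params()] object.
#' @param seed Integer master seed.
#' @param n_events Bacterial events per acquisition (split between LNA and
#'   HNA in proportion to their current abundances).
#' @param calibration The [ssc_calibration()] used to place event clouds so
#'   that target mean volumes round-trip through the analysis calibration.
#' @return An object of class `mt_experiment`: a list with `acquisitions`
#'   (tibble, one row per bottle x time with an `events` list-column),
#'   `abundance` (per bottle x time x group, cells mL^-1), `cardfish`,
#'   `arisa`, and `truth` (the ground-truth record).
#' @export
simulate_experiment <- function(design, truth = truth_params(), seed = 1,
                                n_events = 2000,
                                calibration = ssc_calibration()) {
  stopifnot(inherits(design, "mt_design"), inherits(truth, "mt_truth"))
  grid <- design_grid(design)
  times <- design$sampling_times
  gr <- truth$growth
  bottle_seeds <- split_seed(seed, nrow(grid) + 1)
  community_seed <- bottle_seeds[length(bottle_seeds)]
  bottle_seeds <- bottle_seeds[-length(bottle_seeds)]

  acq_list <- vector("list", nrow(grid))
  abund_list <- vector("list", nrow(grid))
  bottle_truth <- vector("list", nrow(grid))

  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    set.seed(bottle_seeds[i])
    pars <- dplyr::filter(truth$groups, .data$treatment == row$treatment)
    pars <- pars[match(c("LNA", "HNA"), pars$group), ]

    # per-bottle realisations, constant over the incubation
    eps_v <- stats::rnorm(2, 0, truth$bottle_sd_volume)
    eps_n <- stats::rnorm(2, 0, truth$bottle_sd_nac)
    rate_fac <- if (gr$rate_cv > 0) {
      exp(stats::rnorm(2, -log(1 + gr$rate_cv^2) / 2, sqrt(log(1 + gr$rate_cv^2))))
    } else c(1, 1)
    mu <- arrhenius_rate(gr$mu_ref, gr$activation_energy,
                         row$temperature, row$ambient_temperature) *
      unname(gr$group_factor[pars$group]) * rate_fac
    n0_g <- rep(gr$n0 / 2, 2)
    k_g <- rep(gr$carrying_capacity / 2, 2)

    dt <- row$temperature - row$ambient_temperature
    mean_v <- pmax(pars$ambient_volume + pars$size_slope * dt + eps_v, 1e-6)
    mean_n <- pmax(pars$ambient_nac + pars$nac_slope * dt + eps_n, 1e-6)

    per_time <- vector("list", length(times))
    ab_time <- vector("list", length(times))
    for (j in seq_along(times)) {
      t <- times[j]
      n_true <- growth_curve(t, mu, gr$lag_days, n0_g, k_g)
      meas_fac <- if (gr$abundance_cv > 0) {
        exp(stats::rnorm(1, -log(1 + gr$abundance_cv^2) / 2,
                         sqrt(log(1 + gr$abundance_cv^2))))
      } else 1
      n_meas <- n_true * meas_fac
      phase <- growth_phase(t, n_true, gr$lag_days, k_g)
      drift <- dplyr::case_when(
        phase == "lag" ~ 1 + truth$drift_lag,
        phase == "exponential" ~ 1 + truth$drift_exponential,
        .default = 1
      )
      loc_v <- mean_v * drift
      loc_n <- mean_n * drift
      loc_ssc <- ssc_from_diameter(volume_to_diameter(loc_v), calibration) *
        truth$bead$ssc
      loc_gf <- loc_n * truth$bead$gf

      n_bact <- round(n_events * n_meas / sum(n_meas))
      ev <- simulate_cytogram(
        n_lna = n_bact[1], n_hna = n_bact[2], n_beads = truth$bead$n,
        lna = list(ssc = loc_ssc[1], gf = loc_gf[1]),
        hna = list(ssc = loc_ssc[2], gf = loc_gf[2]),
        bead = truth$bead,
        sdlog_ssc = truth$sdlog_ssc, sdlog_gf = truth$sdlog_gf,
        correlation = truth$event_correlation
      )
      per_time[[j]] <- tibble::tibble(
        time = t,
        acquired_volume_mL = sum(n_bact) / sum(n_meas),
        n_lna = n_bact[1], n_hna = n_bact[2],
        events = list(ev)
      )
      ab_time[[j]] <- tibble::tibble(
        time = t, group = pars$group, phase = phase,
        abundance = n_meas, abundance_true = n_true
      )
    }
    keys <- row[c("month", "ambient_temperature", "treatment", "offset",
                  "temperature", "replicate", "bottle")]
    acq_list[[i]] <- tidyr::expand_grid(keys, dplyr::bind_rows(per_time))
    abund_list[[i]] <- tidyr::expand_grid(keys, dplyr::bind_rows(ab_time))
    bottle_truth[[i]] <- tidyr::expand_grid(
      keys,
      tibble::tibble(group = pars$group, eps_volume = eps_v, eps_nac = eps_n,
                     mu_realised = mu, mean_volume_true = mean_v,
                     mean_nac_true = mean_n)
    )
  }

  comm <- simulate_community_tables(
    samples = dplyr::distinct(grid, .data$month, .data$treatment, .data$offset,
                              .data$temperature),
    community = truth$community, seed = community_seed
  )

  structure(
    list(
      acquisitions = dplyr::bind_rows(acq_list),
      abundance = dplyr::bind_rows(abund_list),
      cardfish = comm$cardfish,
      arisa = comm$arisa,
      truth = list(design = design, params = truth, calibration = calibration,
                   bottles = dplyr::bind_rows(bottle_truth),
                   community = comm$truth, seed = seed, n_events = n_events)
    ),
    class = "mt_experiment"
  )
}

#' @export
print.mt_experiment <- function(x, ...) {
  cat("<mt_experiment> ", nrow(x$acquisitions), " acquisitions, ",
      nrow(x$cardfish), " CARD-FISH samples, ",
      length(unique(x$arisa$sample)), " ARISA samples\n", sep = "")
  invisible(x)
}

#' Simulate per-bottle summaries for slope-recovery studies
#'
#' A lightweight generator at the bottle-summary level: per-bottle mean
#' values linear in temperature with Gaussian replicate noise, for studying
#' the sampling properties of the temperature-slope regression without
#' simulating individual events.
#'
#' @param slope Injected per-degC slope.
#' @param ambient_value Value at the ambient temperature.
#' @param sd Bottle-level noise SD.
#' @param ambient_temperature Ambient temperature (degC).
#' @param offsets Temperature offsets (degC).
#' @param replicates Bottles per temperature.
#' @param seed Optional seed.
#' @return A tibble with `temperature`, `replicate`, `value`.
#' @export
simulate_bottle_summaries <- function(slope, ambient_value, sd,
                                      ambient_temperature = 15,
                                      offsets = c(-3, 0, 3), replicates = 3,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- tidyr::expand_grid(offset = offsets, replicate = seq_len(replicates))
  dplyr::mutate(g,
    temperature = ambient_temperature + .data$offset,
    value = ambient_value + slope * .data$offset +
      stats::rnorm(dplyr::n(), 0, sd)
  )[, c("temperature", "replicate", "value")]
}
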