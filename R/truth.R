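#' Ground-truth parameters for the synthetic-data generator
#'
#' Collects every injected quantity the generator uses, so that downstream
#' estimates can be compared against known truth. Defaults emulate the study
#' conditions of the warming incubations: ambient HNA/LNA cell volumes inside
#' the observed 0.035-0.091 um^3 range, HNA nucleic-acid fluorescence 70%
#' above LNA (ratio 1.7), annual-mean per-degC size and NAC effects expressed
#' as percent of the ambient value per group and treatment (so the injected
#' populations stay ordered across the temperature span), an event-level
#' log-scale size-NAC correlation of 0.82, Arrhenius-type growth with
#' activation energy 0.65 eV, and bottle-to-bottle scatter whose implied
#' slope standard errors keep the reported SE-to-slope ratios at the n = 9
#' design.
#'
#' @param groups Tibble with one row per `group` x `treatment`:
#'   `ambient_volume` (um^3), `ambient_nac` (fru), `size_slope`
#'   (um^3 degC^-1), `nac_slope` (fru degC^-1).
#' @param event_correlation Event-level correlation between log SSC and log
#'   green fluorescence within a population, in \[-1, 1\].
#' @param sdlog_ssc,sdlog_gf Log-scale dispersion of the two channels within
#'   a population.
#' @param bottle_sd_volume,bottle_sd_nac SD of the per-bottle random offset
#'   added to the population mean volume (um^3) / NAC (fru); this is the
#'   replicate scatter the temperature regressions see.
#' @param drift_lag,drift_exponential Relative drift of the population mean
#'   signal by growth phase (lag phase up, exponential phase down is the
#'   typical pattern); stationary phase is undrifted. Set both to 0 for
#'   phase-free means.
#' @param growth List: `mu_ref` (d^-1 at ambient temperature),
#'   `activation_energy` (eV), `lag_days`, `carrying_capacity` and `n0`
#'   (cells mL^-1), `group_factor` (named multiplier on `mu_ref` per group),
#'   `rate_cv` (lognormal CV of the per-bottle realised rate),
#'   `abundance_cv` (lognormal measurement CV on sampled abundances).
#' @param bead List: nominal raw `ssc` and `gf` positions of the 1 um
#'   reference beads, their `cv`, and `n` bead events per acquisition.
#' @param community List: `cardfish_props` (named probe proportions of DAPI,
#'   summing to <= 1; remainder is unclassified), `dapi_cells` counted per
#'   sample, `prop_cv` (between-sample jitter of proportions), `n_fragments`
#'   true ARISA fragments per monthly community, `length_jitter_bp`
#'   (measurement SD of fragment lengths, bp), `rfi_cv` (intensity noise),
#'   `n_noise_peaks` below-cutoff nuisance peaks and `n_outside_peaks`
#'   out-of-range nuisance peaks per sample.
#' @return An object of class `mt_truth`.
#' @export
#' @examples
#' truth_params()$groups
truth_params <- function(groups = NULL,
                         event_correlation = 0.82,
                         sdlog_ssc = 0.15,
                         sdlog_gf = 0.09,
                         bottle_sd_volume = 5e-4,
                         bottle_sd_nac = 2.5e-4,
                         drift_lag = 0.02,
                         drift_exponential = -0.02,
                         growth = list(),
                         bead = list(),
                         community = list()) {
  if (is.null(groups)) {
    # Per-degC effects expressed as percent of the ambient value, so the
    # injected event clouds remain coherent (HNA stays above LNA) across the
    # +-3 degC span; the percent pattern follows the annual-mean group x
    # treatment contrast (HNA strongest in C, LNA C weakest).
    groups <- tibble::tribble(
      ~group, ~treatment, ~ambient_volume, ~ambient_nac, ~size_pct, ~nac_pct,
      "HNA", "F", 0.060, 0.034, 0.42, 0.22,
      "LNA", "F", 0.045, 0.020, 0.16, 0.12,
      "HNA", "C", 0.060, 0.034, 0.53, 0.44,
      "LNA", "C", 0.045, 0.020, 0.05, 0.04
    )
    groups <- dplyr::mutate(groups,
      size_slope = -.data$size_pct / 100 * .data$ambient_volume,
      nac_slope = -.data$nac_pct / 100 * .data$ambient_nac
    )
    groups <- dplyr::select(groups, -"size_pct", -"nac_pct")
  }
  need <- c("group", "treatment", "ambient_volume", "ambient_nac",
            "size_slope", "nac_slope")
  if (!all(need %in% names(groups))) {
    rlang::abort(paste("`groups` needs columns:", paste(need, collapse = ", ")))
  }
  stop_if_not_positive(groups$ambient_volume, "ambient_volume")
  stop_if_not_positive(groups$ambient_nac, "ambient_nac")
  if (abs(event_correlation) > 1) {
    rlang::abort("`event_correlation` must lie in [-1, 1]")
  }
  if (sdlog_ssc < 0 || sdlog_gf < 0 || bottle_sd_volume < 0 || bottle_sd_nac < 0) {
    rlang::abort("dispersions must be >= 0")
  }

  growth <- utils::modifyList(list(
    mu_ref = 0.6,
    activation_energy = 0.65,
    lag_days = 1,
    carrying_capacity = 6e6,
    n0 = 2e5,
    group_factor = c(HNA = 1, LNA = 0.7),
    rate_cv = 0.05,
    abundance_cv = 0.03
  ), growth)
  if (growth$carrying_capacity <= growth$n0) {
    rlang::abort("carrying capacity must exceed initial abundance")
  }
  stop_if_not_positive(c(growth$mu_ref, growth$n0, growth$carrying_capacity),
                       "growth parameters")

  bead <- utils::modifyList(list(ssc = 500, gf = 2000, cv = 0.05, n = 200), bead)
  stop_if_not_positive(c(bead$ssc, bead$gf), "bead position")

  community <- utils::modifyList(list(
    cardfish_props = c(SAR11 = 0.35, Rhodobacteraceae = 0.12,
                       Gammaproteobacteria = 0.13, Bacteroidetes = 0.104),
    dapi_cells = 800,
    prop_cv = 0.05,
    month_sd = 0.5,
    coverage_sd = 0.012,
    n_fragments = 35,
    n_dominant = 6,
    dominant_mass = 0.85,
    length_jitter_bp = 0.4,
    rfi_cv = 0.1,
    n_noise_peaks = 3,
    n_outside_peaks = 2
  ), community)
  if (any(community$cardfish_props < 0) || sum(community$cardfish_props) > 1) {
    rlang::abort("probe proportions must be >= 0 and sum to <= 1")
  }

  structure(
    list(
      groups = tibble::as_tibble(groups),
      event_correlation = event_correlation,
      sdlog_ssc = sdlog_ssc,
      sdlog_gf = sdlog_gf,
      bottle_sd_volume = bottle_sd_volume,
      bottle_sd_nac = bottle_sd_nac,
      drift_lag = drift_lag,
      drift_exponential = drift_exponential,
      growth = growth,
      bead = bead,
      community = community
    ),
    class = "mt_truth"
  )
}

#' @export
print.mt_truth <- function(x, ...) {
  cat("<mt_truth> injected parameters\n")
  print(x$groups)
  cat("event correlation:", x$event_correlation,
      " growth E:", x$growth$activation_energy, "eV\n")
  invisible(x)
}
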