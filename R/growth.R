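# Growth rates from log-linear abundance windows and Boltzmann-Arrhenius
# activation energies.

#' Growth rate from the linear phase of log abundance
#'
#' The growth rate is the OLS slope of the natural log of abundance against
#' time (days) over the linear (exponential) phase. The phase is located by
#' exhaustive search over contiguous windows of at least `min_window` points:
#' among windows whose fit reaches `r^2 >= min_r2`, the one with the largest
#' slope wins, ties going to the longer and then the earlier window. If no
#' window reaches the threshold the best-slope window is returned flagged;
#' a non-positive best slope (declining series) is flagged too.
#'
#' @param abundance Abundances (cells mL^-1), > 0.
#' @param times Sampling times in days, strictly increasing, same length.
#' @param min_window Minimum window length (points).
#' @param min_r2 Window acceptance threshold on r^2.
#' @return A one-row tibble of class `mt_growth`: `rate` (d^-1), `r_squared`,
#'   `t_start`, `t_end`, `n_window`, `r2_ok`, `positive`.
#' @export
#' @examples
#' t <- 0:5
#' fit_growth_rate(1e5 * exp(0.6 * t), t)$rate # 0.6
fit_growth_rate <- function(abundance, times, min_window = 3, min_r2 = 0.95) {
  if (length(abundance) != length(times)) {
    rlang::abort("`abundance` and `times` must have equal length")
  }
  if (length(times) < 4) rlang::abort("need >= 4 time points")
  if (any(diff(times) <= 0)) rlang::abort("`times` must be strictly increasing")
  stop_if_not_positive(abundance, "abundance")
  y <- log(abundance)
  n <- length(y)
  wins <- purrr::map_dfr(seq_len(n - min_window + 1), function(i) {
    purrr::map_dfr(seq(i + min_window - 1, n), function(j) {
      f <- ols_line(times[i:j], y[i:j])
      tibble::tibble(i = i, j = j, len = j - i + 1,
                     slope = f$slope, r2 = f$r2)
    })
  })
  pick <- function(w) {
    smax <- max(w$slope)
    cand <- w[w$slope >= smax - 1e-12, ]
    cand <- cand[order(-cand$len, cand$i), ]
    cand[1, ]
  }
  passing <- wins[wins$r2 >= min_r2, ]
  r2_ok <- nrow(passing) > 0
  best <- pick(if (r2_ok) passing else wins)
  out <- tibble::tibble(
    rate = best$slope, r_squared = best$r2,
    t_start = times[best$i], t_end = times[best$j],
    n_window = best$len, r2_ok = r2_ok,
    positive = best$slope > 0
  )
  if (!out$positive) {
    rlang::warn("no positive growth detected (declining or flat series)")
  }
  class(out) <- c("mt_growth", class(out))
  out
}

#' Growth rates for every bottle and group
#'
#' @param abundance_table Tidy abundance series with key columns among
#'   `month`, `treatment`, `offset`, `temperature`, `replicate`, `group` and
#'   value columns `time`, `abundance`.
#' @param ... Passed to [fit_growth_rate()].
#' @return A tibble of per-series growth fits (one row per key combination).
#' @export
growth_rates <- function(abundance_table, ...) {
  keys <- intersect(c("month", "treatment", "offset", "temperature",
                      "replicate", "group"), names(abundance_table))
  abundance_table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time)
      tryCatch(
        suppressWarnings(fit_growth_rate(df$abundance, df$time, ...)),
        error = function(e) tibble::tibble(rate = NA_real_)
      )
    }) |>
    dplyr::ungroup()
}

#' Activation energy from an Arrhenius plot of growth rates
#'
#' Regresses ln(rate) on 1/(kT) (T in Kelvin, k the Boltzmann constant in
#' eV K^-1). The raw regression slope of ln(rate) on 1/(kT) is negative when
#' rates increase with temperature; the activation energy is reported as the
#' negated slope, so `E > 0` means faster growth when warmer. Non-positive
#' rates cannot be log-transformed and are dropped with a warning.
#'
#' @param rates Growth rates in d^-1.
#' @param temperature_c Matching incubation temperatures in degC.
#' @return A one-row tibble of class `mt_arrhenius`: `e_ev` (activation
#'   energy, eV), `slope` (raw regression slope, eV), `se` (eV), `n`,
#'   `r_squared`; the temperatures used (K) are in
#'   `attr(, "temperatures_K")`.
#' @export
#' @examples
#' tc <- c(12, 15, 18)
#' mu <- 2e9 * exp(-0.65 / (boltzmann_ev() * (tc + 273.15)))
#' activation_energy(mu, tc)$e_ev # 0.65
activation_energy <- function(rates, temperature_c) {
  if (length(rates) != length(temperature_c)) {
    rlang::abort("`rates` and `temperature_c` must have equal length")
  }
  keep <- is.finite(rates) & rates > 0
  if (any(!keep)) {
    rlang::warn(paste0(sum(!keep), " non-positive rate(s) dropped from the ",
                       "Arrhenius fit"))
  }
  rates <- rates[keep]
  tk <- celsius_to_kelvin(temperature_c[keep])
  if (length(rates) < 2 || length(unique(tk)) < 2) {
    rlang::abort("need >= 2 positive rates at distinct temperatures")
  }
  x <- 1 / (boltzmann_ev() * tk)
  fit <- stats::lm(log(rates) ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  out <- tibble::tibble(
    e_ev = -slope, slope = slope,
    se = sm$coefficients[2, 2],
    n = length(rates),
    r_squared = sm$r.squared
  )
  class(out) <- c("mt_arrhenius", class(out))
  attr(out, "temperatures_K") <- tk
  attr(out, "fit") <- fit
  out
}

#' Activation energies for every month, treatment and group
#'
#' Bottle-level growth rates are averaged per temperature before the
#' Arrhenius fit when replicates are present.
#'
#' @param rate_table Output of [growth_rates()] (needs `month`, `treatment`,
#'   `group`, `temperature`, `rate`).
#' @return A tibble with one Arrhenius fit per month x treatment x group;
#'   combinations with fewer than two usable temperatures yield `e_ev = NA`.
#' @export
activation_energies <- function(rate_table) {
  rate_table |>
    dplyr::filter(is.finite(.data$rate)) |>
    dplyr::group_by(.data$month, .data$treatment, .data$group,
                    .data$temperature) |>
    dplyr::summarise(rate = mean(.data$rate[.data$rate > 0], na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::group_by(.data$month, .data$treatment, .data$group) |>
    dplyr::group_modify(function(df, key) {
      tryCatch(
        suppressWarnings(activation_energy(df$rate, df$temperature)),
        error = function(e) tibble::tibble(e_ev = NA_real_, n = nrow(df))
      )
    }) |>
    dplyr::ungroup()
}
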