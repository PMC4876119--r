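# Per-bottle means, OLS temperature-response slopes, percent-per-degC and
# base-pair conversions -- the core inference of the analysis.

#' Per-bottle experiment means
#'
#' Averages the per-acquisition population summaries over the course of the
#' incubation, giving one mean volume and one mean NAC per bottle and group:
#' the quantities regressed against incubation temperature. Because cell size
#' drifts with growth phase, the whole-experiment mean is accompanied by two
#' robustness variants: the mean over the detected exponential-growth window
#' and the value at the time of maximum abundance.
#'
#' @param stats Tidy per-acquisition table with key columns `month`,
#'   `treatment`, `offset`, `temperature`, `replicate`, `time`, `group` and
#'   value columns `mean_volume`, `mean_gf_fru` (or `mean_nac`), `abundance`.
#' @param min_timepoints Bottles with fewer usable time points are dropped
#'   with a warning (missing time points themselves are logged, not fatal).
#' @return A tibble with one row per bottle x group: `mean_volume`,
#'   `mean_nac`, the growth-phase means `mean_volume_growth` /
#'   `mean_nac_growth`, the at-peak values `volume_at_peak` / `nac_at_peak`,
#'   and `n_timepoints`.
#' @export
bottle_means <- function(stats, min_timepoints = 2) {
  stopifnot(is.data.frame(stats))
  nac_col <- pick_col(stats, c("mean_gf_fru", "mean_nac"), "NAC")
  keys <- c("month", "treatment", "offset", "temperature", "replicate", "group")
  keys <- intersect(keys, names(stats))
  out <- stats |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time)
      ok <- is.finite(df$mean_volume) & is.finite(df[[nac_col]])
      if (any(!ok)) {
        rlang::inform(paste0(sum(!ok), " missing time point(s) dropped for ",
                             paste(unlist(key), collapse = "/")))
      }
      df <- df[ok, ]
      if (nrow(df) < min_timepoints) return(tibble::tibble())
      in_growth <- rep(TRUE, nrow(df))
      peak <- which.max(df$abundance)
      if ("abundance" %in% names(df) && nrow(df) >= 4 &&
          all(df$abundance > 0)) {
        gw <- fit_growth_rate(df$abundance, df$time)
        in_growth <- df$time >= gw$t_start & df$time <= gw$t_end
      }
      tibble::tibble(
        mean_volume = mean(df$mean_volume),
        mean_nac = mean(df[[nac_col]]),
        mean_volume_growth = mean(df$mean_volume[in_growth]),
        mean_nac_growth = mean(df[[nac_col]][in_growth]),
        volume_at_peak = df$mean_volume[peak],
        nac_at_peak = df[[nac_col]][peak],
        n_timepoints = nrow(df)
      )
    }) |>
    dplyr::ungroup()
  dropped <- dplyr::n_distinct(stats[intersect(keys, names(stats))]) - nrow(out)
  if (dropped > 0) {
    rlang::warn(paste0(dropped, " bottle/group series with < ", min_timepoints,
                       " time points dropped"))
  }
  out
}

#' Ambient reference values per month, treatment and group
#'
#' The values used to express slopes as percent change per degC: the mean
#' over replicates of the time-0, ambient-temperature (offset 0) acquisition.
#'
#' @inheritParams bottle_means
#' @return A tibble keyed by `month`, `treatment`, `group` with
#'   `ambient_volume` and `ambient_nac`.
#' @export
ambient_reference <- function(stats) {
  nac_col <- pick_col(stats, c("mean_gf_fru", "mean_nac"), "NAC")
  stats |>
    dplyr::filter(.data$offset == 0, .data$time == 0) |>
    dplyr::group_by(.data$month, .data$treatment, .data$group) |>
    dplyr::summarise(
      ambient_volume = mean(.data$mean_volume, na.rm = TRUE),
      ambient_nac = mean(.data[[nac_col]], na.rm = TRUE),
      .groups = "drop"
    )
}

#' OLS temperature-response slope for one month, treatment and group
#'
#' Regresses a per-bottle summary on incubation temperature by ordinary
#' least squares (typically n = 9: three replicates at three temperatures).
#' The 95% confidence interval uses the t distribution with n - 2 degrees of
#' freedom, and the slope is called significant when the interval excludes
#' zero.
#'
#' @param summaries [bottle_means()] rows for one month x treatment x group
#'   (must contain `temperature` and the response column).
#' @param response `"volume"`, `"nac"`, or the name of a column in
#'   `summaries`.
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble of class `mt_tslope`: `slope`, `se`, `ci_lo`,
#'   `ci_hi`, `n`, `r_squared`, `p_value`, `significant`; the underlying lm
#'   fit is in `attr(, "fit")`.
#' @export
fit_temperature_slope <- function(summaries, response = c("volume", "nac"),
                                  conf_level = 0.95) {
  stopifnot(is.data.frame(summaries))
  col <- if (length(response) == 1 && response %in% names(summaries)) {
    response
  } else {
    switch(match.arg(response), volume = "mean_volume", nac = "mean_nac")
  }
  y <- summaries[[col]]
  x <- summaries$temperature
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) rlang::abort("need >= 3 bottle summaries")
  if (length(unique(x)) < 2) {
    rlang::abort("all incubation temperatures are equal; slope undefined")
  }
  if (n < 4) rlang::warn("temperature regression on fewer than 4 bottles")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  se <- sm$coefficients[2, 2]
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  ci <- slope + c(-1, 1) * tcrit * se
  out <- tibble::tibble(
    response = col, slope = slope, se = se,
    ci_lo = ci[1], ci_hi = ci[2], n = n,
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    significant = ci[1] > 0 | ci[2] < 0
  )
  class(out) <- c("mt_tslope", class(out))
  attr(out, "fit") <- fit
  out
}

#' Temperature-response slopes for every month, treatment and group
#'
#' @param summaries Output of [bottle_means()].
#' @param responses Which responses to fit.
#' @return A tidy tibble of [fit_temperature_slope()] rows keyed by `month`,
#'   `treatment`, `group`, `response` (the Figure-3-style monthly slope
#'   table).
#' @export
temperature_slopes <- function(summaries, responses = c("volume", "nac")) {
  summaries |>
    dplyr::group_by(.data$month, .data$treatment, .data$group) |>
    dplyr::group_modify(function(df, key) {
      purrr::map_dfr(responses, function(r) {
        s <- fit_temperature_slope(df, r)
        s$response <- r
        s
      })
    }) |>
    dplyr::ungroup()
}

#' Express a temperature slope as percent change per degC
#'
#' `percent = -100 * slope / ambient_value`, so a negative (decreasing)
#' slope gives a positive percent reduction. The result is invariant under a
#' common rescaling of the measurement units of slope and reference, and the
#' reference may equally be the ambient or the initial value.
#'
#' @param slope Slope in measurement units per degC.
#' @param ambient_value Reference value in the same measurement units, > 0.
#' @return Percent change per degC (positive = reduction).
#' @export
#' @examples
#' percent_per_degc(-0.0045, 1.0) # 0.45 % per degC
percent_per_degc <- function(slope, ambient_value) {
  if (any(!is.finite(ambient_value)) || any(ambient_value <= 0)) {
    rlang::abort("`ambient_value` must be finite and > 0")
  }
  -100 * slope / ambient_value
}

#' Genome-size anchors for the flow-cytometric groups
#'
#' The bimodal distribution of bacterial genome sizes, with peaks at 2 and
#' 5 Mbp, is taken as equivalent to the LNA and HNA groups, anchoring the
#' conversion of relative fluorescence to base pairs.
#'
#' @return A named numeric vector of anchor genome sizes in Mbp.
#' @export
genome_anchors <- function() c(LNA = 2, HNA = 5)

#' Convert a percent NAC change per degC into base pairs per degC
#'
#' `kbp = (percent / 100) * anchor_Mbp * 1000`, equating the ambient mean
#' NAC of each group to its anchor genome size.
#'
#' @param percent Percent NAC change per degC (positive = loss).
#' @param group `"LNA"` or `"HNA"` (recycled against `percent`).
#' @param anchors Named anchor genome sizes in Mbp, see [genome_anchors()].
#' @return Base-pair change per degC in kbp.
#' @export
#' @examples
#' nac_to_basepairs(0.35, "LNA") # 7 kbp per degC
#' nac_to_basepairs(0.52, "HNA") # 26 kbp per degC
nac_to_basepairs <- function(percent, group, anchors = genome_anchors()) {
  if (!all(group %in% names(anchors))) {
    rlang::abort(paste0("unknown group(s): ",
                        paste(setdiff(group, names(anchors)), collapse = ", ")))
  }
  if (any(!is.finite(percent))) rlang::abort("`percent` must be finite")
  percent / 100 * unname(anchors[group]) * 1000
}

#' Annual summary of temperature-response slopes
#'
#' Mean and standard error of the monthly slopes per group, treatment and
#' response (the Table-1-style annual summary).
#'
#' @param slopes Output of [temperature_slopes()].
#' @return A tibble keyed by `treatment`, `group`, `response` with
#'   `mean_slope`, `se_slope`, `n_months`.
#' @export
annual_slope_summary <- function(slopes) {
  slopes |>
    dplyr::group_by(.data$treatment, .data$group, .data$response) |>
    dplyr::summarise(
      mean_slope = mean(.data$slope),
      se_slope = stats::sd(.data$slope) / sqrt(dplyr::n()),
      n_months = dplyr::n(),
      .groups = "drop"
    )
}

#' Correlation matrix of monthly temperature responses
#'
#' Assembles the monthly slope series for every response x group x treatment
#' combination and computes all pairwise Pearson correlations with two-sided
#' p values (t approximation), the Table-2-style matrix.
#'
#' @param slopes Output of [temperature_slopes()] (needs `month`,
#'   `treatment`, `group`, `response`, `slope`).
#' @return A tibble with `series_a`, `series_b`, `r`, `p_value`, `n`; pairs
#'   with zero variance in either series have `r = NA`. The full symmetric
#'   matrix is attached as `attr(, "matrix")`.
#' @export
correlate_responses <- function(slopes) {
  wide <- slopes |>
    dplyr::mutate(series = paste(.data$response, .data$group, .data$treatment,
                                 sep = "_")) |>
    dplyr::select("month", "series", "slope") |>
    tidyr::pivot_wider(names_from = "series", values_from = "slope") |>
    dplyr::arrange(.data$month)
  series <- setdiff(names(wide), "month")
  if (nrow(wide) < 3) rlang::abort("need >= 3 months of paired slopes")
  pairs <- tidyr::expand_grid(series_a = series, series_b = series) |>
    dplyr::filter(.data$series_a < .data$series_b)
  out <- purrr::pmap_dfr(pairs, function(series_a, series_b) {
    a <- wide[[series_a]]; b <- wide[[series_b]]
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(tibble::tibble(series_a = series_a, series_b = series_b,
                            r = NA_real_, p_value = NA_real_,
                            n = length(a), degenerate = TRUE))
    }
    ct <- stats::cor.test(a, b)
    tibble::tibble(series_a = series_a, series_b = series_b,
                   r = unname(ct$estimate), p_value = ct$p.value,
                   n = length(a), degenerate = FALSE)
  })
  m <- diag(1, length(series))
  dimnames(m) <- list(series, series)
  for (i in seq_len(nrow(out))) {
    m[out$series_a[i], out$series_b[i]] <- out$r[i]
    m[out$series_b[i], out$series_a[i]] <- out$r[i]
  }
  attr(out, "matrix") <- m
  out
}
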