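# broom-style tidiers for the fitted-object classes

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_temperature_slope Tidy the slope fit (term-level table).
#' @param x An `mt_tslope` object.
#' @param ... Unused.
#' @export
tidy.mt_tslope <- function(x, ...) {
  tibble::tibble(
    term = "temperature",
    estimate = x$slope,
    std.error = x$se,
    conf.low = x$ci_lo,
    conf.high = x$ci_hi,
    p.value = x$p_value
  )
}

#' @describeIn fit_temperature_slope One-row model summary.
#' @export
glance.mt_tslope <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n,
                 significant = x$significant)
}

#' @describeIn fit_growth_rate Tidy the growth fit.
#' @param x An `mt_growth` object.
#' @param ... Unused.
#' @export
tidy.mt_growth <- function(x, ...) {
  tibble::tibble(term = "time", estimate = x$rate,
                 window.start = x$t_start, window.end = x$t_end)
}

#' @describeIn fit_growth_rate One-row fit summary.
#' @export
glance.mt_growth <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n_window,
                 r2.ok = x$r2_ok, positive = x$positive)
}

#' @describeIn activation_energy Tidy the Arrhenius fit.
#' @param x An `mt_arrhenius` object.
#' @param ... Unused.
#' @export
tidy.mt_arrhenius <- function(x, ...) {
  tibble::tibble(term = "inverse_kT", estimate = x$slope,
                 std.error = x$se, activation.energy = x$e_ev)
}

#' @describeIn activation_energy One-row fit summary.
#' @export
glance.mt_arrhenius <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n)
}

#' Tidy a dissimilarity matrix into pair rows
#'
#' @param x A `dist` object.
#' @param ... Unused.
#' @return A tibble with `item1`, `item2`, `distance`.
#' @export
tidy_dist <- function(x, ...) {
  stopifnot(inherits(x, "dist"))
  labs <- attr(x, "Labels")
  n <- attr(x, "Size")
  if (is.null(labs)) labs <- as.character(seq_len(n))
  idx <- utils::combn(n, 2)
  tibble::tibble(item1 = labs[idx[1, ]], item2 = labs[idx[2, ]],
                 distance = as.numeric(x))
}
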