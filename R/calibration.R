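#' Side-scatter to cell-diameter calibration model
#'
#' Empirical calibrations between bead-relative side scatter (SSC, ru) and
#' cell diameter are instrument- and site-specific; the model here is a
#' strictly increasing power law `d = a * ssc^b` (equivalently linear on
#' log-log axes), with coefficients supplied by the user. The defaults map
#' the bead-relative scatter of small heterotrophic bacteria onto spherical
#' volumes in the 0.035-0.091 um^3 range typical of coastal assemblages.
#'
#' @param a Multiplier (um at ssc = 1 ru), > 0.
#' @param b Exponent, > 0 (monotonicity requirement).
#' @param range Valid SSC input range (ru); values outside are still
#'   converted but flagged as extrapolated.
#' @param form Either `"power"` (coefficients `a`, `b` on linear signals) or
#'   `"loglog"`, in which case `a` and `b` are the intercept and slope of
#'   `log(d) ~ log(ssc)` (natural logs) and are converted internally.
#' @return An object of class `mt_calibration`, kind `"ssc_to_diameter"`.
#' @export
#' @examples
#' cal <- ssc_calibration(a = 1, b = 0.5)
#' ssc_to_diameter(4, cal) # 2 um
ssc_calibration <- function(a = 1, b = 0.25, range = c(1e-4, 2),
                            form = c("power", "loglog")) {
  form <- match.arg(form)
  if (form == "loglog") {
    a <- exp(a)
    # slope unchanged
  }
  if (!is.finite(a) || a <= 0) rlang::abort("`a` must be > 0")
  if (!is.finite(b) || b <= 0) {
    rlang::abort("non-monotone calibration rejected: exponent must be > 0")
  }
  if (length(range) != 2 || range[1] <= 0 || range[2] <= range[1]) {
    rlang::abort("`range` must be positive and increasing")
  }
  structure(
    list(kind = "ssc_to_diameter", form = "power", a = a, b = b, range = range),
    class = "mt_calibration"
  )
}

#' Convert bead-relative side scatter to cell diameter
#'
#' @param ssc_ru Positive SSC values in bead-relative units.
#' @param model An [ssc_calibration()] model.
#' @return Numeric diameters in um, with a logical attribute `extrapolated`
#'   marking inputs outside the model's valid range.
#' @export
ssc_to_diameter <- function(ssc_ru, model) {
  stopifnot(inherits(model, "mt_calibration"), model$kind == "ssc_to_diameter")
  stop_if_not_positive(ssc_ru, "ssc_ru")
  d <- model$a * ssc_ru^model$b
  extra <- ssc_ru < model$range[1] | ssc_ru > model$range[2]
  if (any(extra)) {
    rlang::warn(paste0(sum(extra), " SSC value(s) outside the calibration range; ",
                       "extrapolated"))
  }
  attr(d, "extrapolated") <- extra
  d
}

#' Invert an SSC calibration (diameter to expected SSC)
#'
#' Used by the synthetic-data generator to position event clouds so that a
#' target mean diameter maps back through the calibration.
#'
#' @param d Diameters in um, > 0.
#' @inheritParams ssc_to_diameter
#' @return SSC in bead-relative units.
#' @export
ssc_from_diameter <- function(d, model) {
  stopifnot(inherits(model, "mt_calibration"), model$kind == "ssc_to_diameter")
  stop_if_not_positive(d, "d")
  (d / model$a)^(1 / model$b)
}

#' Sphere volume from diameter
#'
#' Cells are treated as spheres: `V = (pi/6) d^3`.
#'
#' @param d Diameter in um, > 0.
#' @return Volume in um^3.
#' @export
#' @examples
#' diameter_to_volume(1) # pi/6 = 0.5236
diameter_to_volume <- function(d) {
  stop_if_not_positive(d, "d")
  pi / 6 * d^3
}

#' Diameter from sphere volume
#'
#' @param v Volume in um^3, > 0.
#' @return Diameter in um.
#' @export
volume_to_diameter <- function(v) {
  stop_if_not_positive(v, "v")
  (6 * v / pi)^(1 / 3)
}

#' Fit a between-fluorochrome calibration
#'
#' Different nucleic-acid stains (e.g. Syto 13 vs Sybr-Green I) give
#' different green-fluorescence scales; running a set of samples with both
#' stains gives paired values from which a linear conversion is fitted by
#' OLS.
#'
#' @param pairs Data frame with the paired per-sample fluorescence values.
#' @param from,to Column names holding the source-dye and target-dye values.
#' @return An `mt_calibration` of kind `"syto_to_sybr"` with the fitted lm in
#'   `$fit` and `intercept`/`slope` coefficients.
#' @export
fit_dye_calibration <- function(pairs, from = "syto", to = "sybr") {
  stopifnot(is.data.frame(pairs))
  if (!all(c(from, to) %in% names(pairs))) {
    rlang::abort(paste0("`pairs` must contain columns `", from, "` and `", to, "`"))
  }
  if (nrow(pairs) < 3) rlang::abort("need >= 3 paired samples")
  fit <- stats::lm(stats::reformulate(from, to), data = pairs)
  co <- stats::coef(fit)
  if (co[[2]] <= 0) {
    rlang::abort("non-monotone calibration rejected: fitted slope must be > 0")
  }
  structure(
    list(kind = "syto_to_sybr", form = "linear",
         intercept = unname(co[[1]]), slope = unname(co[[2]]),
         r_squared = summary(fit)$r.squared,
         range = range(pairs[[from]]), fit = fit),
    class = "mt_calibration"
  )
}

#' Convert Syto 13 fluorescence to the Sybr-Green I scale
#'
#' @param gf_syto Fluorescence values (fru) measured with the source dye.
#' @param model A fitted [fit_dye_calibration()] model; converting without a
#'   model is an error.
#' @return Converted fluorescence (fru) on the target-dye scale.
#' @export
syto_to_sybr <- function(gf_syto, model) {
  if (missing(model) || is.null(model)) {
    rlang::abort("no dye calibration model supplied; fit one with fit_dye_calibration()")
  }
  stopifnot(inherits(model, "mt_calibration"), model$kind == "syto_to_sybr")
  model$intercept + model$slope * gf_syto
}

#' @export
print.mt_calibration <- function(x, ...) {
  if (x$kind == "ssc_to_diameter") {
    cat("<mt_calibration> d[um] =", x$a, "* ssc^", x$b,
        " valid ssc range [", x$range[1], ",", x$range[2], "] ru\n")
  } else {
    cat("<mt_calibration> sybr =", x$intercept, "+", x$slope, "* syto",
        " (R^2 =", round(x$r_squared, 3), ")\n")
  }
  invisible(x)
}
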