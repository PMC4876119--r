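# internal helpers shared across modules

#' Boltzmann constant in electron-volts per Kelvin
#'
#' Housed here because activation energies are reported in eV throughout.
#' @return A length-one numeric, 8.617e-5 eV K^-1.
#' @export
boltzmann_ev <- function() 8.617e-5

# deg C -> K
celsius_to_kelvin <- function(x) x + 273.15

# first matching column name, or abort
pick_col <- function(df, candidates, what) {
  hit <- intersect(candidates, names(df))
  if (length(hit) == 0) {
    rlang::abort(paste0(
      "no ", what, " column found; expected one of: ",
      paste(candidates, collapse = ", ")
    ))
  }
  hit[[1]]
}

stop_if_not_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort(paste0("`", name, "` must be finite and > 0"))
  }
  invisible(x)
}

# Deterministic per-unit substreams from one master seed: draw the substream
# seeds once under the master seed so (inputs, seed) fixes every stream.
# Values stay below 2^31 - 1 (R integer range).
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(as.integer(seed))
  out <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

# simple closed-form OLS pieces, used internally for window scoring where
# calling lm() thousands of times would dominate runtime
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, sum(y^2))) 1 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r2 = r2, n = n)
}
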