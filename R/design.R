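#' Define a monthly warming-incubation design
#'
#' Describes one year of incubation experiments: each month, seawater is split
#' into a whole-community (`C`, 200 um pre-filtered) and a filtered (`F`,
#' 0.8 um pre-filtered) treatment and incubated in triplicate at the ambient
#' (collection) temperature and at fixed offsets below and above it, giving
#' 18 bottles per month at the defaults. Bottles are subsampled over roughly
#' a week while abundance moves through lag, exponential and stationary
#' phases.
#'
#' @param months Character vector of experiment labels (default the twelve
#'   month abbreviations).
#' @param ambient_temperature Numeric, ambient (collection) temperature in
#'   deg C for each month; recycled if length one. The default is a mid-
#'   latitude coastal seasonal cycle spanning ~13-20 deg C.
#' @param temperature_offsets Offsets in deg C applied to the ambient value,
#'   strictly increasing, at least two distinct values. Default `c(-3, 0, 3)`.
#' @param treatments Treatment codes. Default `c("C", "F")`.
#' @param replicates Bottles per month x treatment x temperature cell.
#' @param sampling_times Strictly increasing sampling times in days, starting
#'   at 0. Default covers 0-6 d at one to two samples per day.
#' @param photoperiod_h Optional per-month photoperiod metadata (hours);
#'   carried along, not used by any computation.
#' @return An object of class `mt_design`.
#' @seealso [design_grid()], [truth_params()], [simulate_experiment()]
#' @export
#' @examples
#' d <- experiment_design()
#' design_grid(d)
experiment_design <- function(months = month.abb,
                              ambient_temperature = c(13.2, 12.8, 13.1, 13.9,
                                                      15.2, 16.8, 18.9, 19.8,
                                                      19.2, 17.6, 15.8, 14.1),
                              temperature_offsets = c(-3, 0, 3),
                              treatments = c("C", "F"),
                              replicates = 3,
                              sampling_times = c(0, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6),
                              photoperiod_h = NULL) {
  months <- as.character(months)
  if (length(months) < 1) rlang::abort("at least one month is required")
  if (anyDuplicated(months)) rlang::abort("month labels must be unique")
  if (length(ambient_temperature) == 1) {
    ambient_temperature <- rep(ambient_temperature, length(months))
  }
  if (length(ambient_temperature) != length(months)) {
    rlang::abort("`ambient_temperature` must have one value per month")
  }
  if (length(temperature_offsets) < 2 || any(diff(temperature_offsets) <= 0)) {
    rlang::abort("`temperature_offsets` must be strictly increasing with >= 2 values")
  }
  if (!(0 %in% temperature_offsets)) {
    rlang::abort("`temperature_offsets` must include 0 (the ambient bottle)")
  }
  if (replicates < 1) rlang::abort("`replicates` must be >= 1")
  if (length(sampling_times) < 2 || any(diff(sampling_times) <= 0) ||
      sampling_times[1] != 0) {
    rlang::abort("`sampling_times` must be strictly increasing and start at 0")
  }
  structure(
    list(
      months = months,
      ambient_temperature = ambient_temperature,
      temperature_offsets = temperature_offsets,
      treatments = as.character(treatments),
      replicates = as.integer(replicates),
      sampling_times = as.numeric(sampling_times),
      photoperiod_h = photoperiod_h
    ),
    class = "mt_design"
  )
}

#' Expand a design into its bottle grid
#'
#' @param design An [experiment_design()] object.
#' @return A tibble with one row per bottle: `month`, `ambient_temperature`,
#'   `treatment`, `offset`, `temperature`, `replicate`, `bottle`.
#' @export
design_grid <- function(design) {
  stopifnot(inherits(design, "mt_design"))
  amb <- tibble::tibble(
    month = factor(design$months, levels = design$months),
    ambient_temperature = design$ambient_temperature
  )
  grid <- tidyr::expand_grid(
    amb,
    treatment = design$treatments,
    offset = design$temperature_offsets,
    replicate = seq_len(design$replicates)
  )
  grid <- dplyr::mutate(grid,
    temperature = .data$ambient_temperature + .data$offset,
    bottle = paste(.data$month, .data$treatment,
                   sprintf("%+d", .data$offset), .data$replicate, sep = "_")
  )
  grid
}

#' @export
print.mt_design <- function(x, ...) {
  cat("<mt_design> ", length(x$months), " months x {",
      paste(x$treatments, collapse = ","), "} x offsets {",
      paste(x$temperature_offsets, collapse = ","), "} degC x ",
      x$replicates, " replicates; ",
      length(x$sampling_times), " sampling times over ",
      max(x$sampling_times), " d\n", sep = "")
  invisible(x)
}
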