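# HNA/LNA gating and bead-relative normalisation.

# local maxima / minima indices of a density estimate
turning_points <- function(y) {
  d <- diff(y)
  s <- sign(d)
  # collapse flat runs
  s[s == 0] <- 1
  ch <- diff(s)
  list(maxima = which(ch < 0) + 1L, minima = which(ch > 0) + 1L)
}

#' Gate a cytogram into bead, LNA and HNA populations
#'
#' Beads are identified first, as events within a log-space window of the
#' known nominal bead position. The remaining (bacterial) events are split by
#' a threshold on log green fluorescence placed at the deepest minimum of a
#' kernel density estimate between the two highest modes -- the automated
#' analogue of drawing a gate between the two clusters on the fluorescence
#' vs. scatter plot. Events above the threshold are HNA, below are LNA, so
#' the HNA mean fluorescence always exceeds the LNA mean. If the fluorescence
#' distribution is unimodal the gate cannot be placed: all bacterial events
#' are labelled as a single population (HNA) and the result is flagged.
#'
#' @param events Data frame with raw signal columns `ssc_raw` and `gf_raw`
#'   (positive; log-transformable).
#' @param bead Nominal bead position, a list with `ssc` and `gf` in raw
#'   units, or `NULL` if the acquisition contains no beads.
#' @param bead_window Half-width (natural-log units) of the bead gate around
#'   the nominal position, applied to both channels.
#' @param bw Bandwidth rule or value passed to [stats::density()].
#' @return The events with a `label` factor column (`bead`, `LNA`, `HNA`),
#'   of class `mt_gated`; the gate parameters are stored in
#'   `attr(, "gate")`: `threshold_log_gf`, `threshold_gf`, `unimodal`,
#'   `n` per label.
#' @export
gate_populations <- function(events, bead = NULL, bead_window = 1,
                             bw = "nrd0") {
  stopifnot(is.data.frame(events))
  ssc_col <- pick_col(events, c("ssc_raw", "ssc_ru", "ssc"), "side scatter")
  gf_col <- pick_col(events, c("gf_raw", "gf_fru", "gf"), "green fluorescence")
  if (nrow(events) < 1) rlang::abort("at least one event is required")
  ssc <- events[[ssc_col]]
  gf <- events[[gf_col]]
  stop_if_not_positive(ssc, ssc_col)
  stop_if_not_positive(gf, gf_col)

  is_bead <- rep(FALSE, nrow(events))
  if (!is.null(bead)) {
    is_bead <- abs(log(ssc) - log(bead$ssc)) <= bead_window &
      abs(log(gf) - log(bead$gf)) <= bead_window
  }
  x <- log(gf[!is_bead])

  unimodal <- FALSE
  thr <- NA_real_
  label <- factor(rep("HNA", nrow(events)), levels = c("bead", "LNA", "HNA"))
  label[is_bead] <- "bead"

  if (length(x) >= 2 && stats::sd(x) > 0) {
    den <- stats::density(x, bw = bw, n = 512)
    tp <- turning_points(den$y)
    # ignore spurious tail wiggles: a mode must carry real density, and the
    # valley between the two modes must actually dip below the lower peak
    peaks <- tp$maxima[den$y[tp$maxima] >= 0.05 * max(den$y)]
    if (length(peaks) >= 2) {
      top2 <- sort(peaks[order(den$y[peaks], decreasing = TRUE)][1:2])
      mins <- tp$minima[tp$minima > top2[1] & tp$minima < top2[2]]
      if (length(mins) >= 1) {
        deepest <- mins[which.min(den$y[mins])]
        if (den$y[deepest] <= 0.9 * min(den$y[top2])) {
          thr <- den$x[deepest]
        }
      }
    }
  }
  if (is.na(thr)) {
    unimodal <- TRUE
    rlang::warn("unimodal fluorescence distribution: single-population gate")
  } else {
    bac <- !is_bead
    label[bac & log(gf) <= thr] <- "LNA"
  }

  out <- tibble::as_tibble(events)
  out$label <- label
  structure(out,
    class = c("mt_gated", class(tibble::tibble())),
    gate = list(threshold_log_gf = thr,
                threshold_gf = if (is.na(thr)) NA_real_ else exp(thr),
                unimodal = unimodal,
                bead_window = bead_window,
                n = table(label))
  )
}

#' Normalise signals to the internal bead standard
#'
#' Divides each raw signal by the arithmetic mean of the bead-labelled
#' events' signal in that channel, so the bead mean maps to exactly 1.0
#' relative unit. The output is therefore invariant to any common rescaling
#' of the raw signals (instrument gain).
#'
#' @param events Gated events (see [gate_populations()]) with `ssc_raw`,
#'   `gf_raw` and a `label` column, or supply `labels` separately.
#' @param labels Optional label vector overriding `events$label`.
#' @param min_beads Minimum number of bead events required for a stable
#'   denominator.
#' @param acquisition Optional acquisition identifier used in error messages.
#' @return The events with added `ssc_ru` and `gf_fru` columns.
#' @export
normalize_to_beads <- function(events, labels = NULL, min_beads = 20,
                               acquisition = NULL) {
  stopifnot(is.data.frame(events))
  if (is.null(labels)) {
    if (!"label" %in% names(events)) {
      rlang::abort("`events` has no `label` column; gate first or pass `labels`")
    }
    labels <- events$label
  }
  beads <- labels == "bead"
  if (sum(beads) < min_beads) {
    rlang::abort(paste0(
      "too few bead events (", sum(beads), " < ", min_beads, ")",
      if (!is.null(acquisition)) paste0(" in acquisition ", acquisition)
    ))
  }
  gate <- attr(events, "gate")
  out <- dplyr::mutate(tibble::as_tibble(events),
    ssc_ru = .data$ssc_raw / mean(.data$ssc_raw[beads]),
    gf_fru = .data$gf_raw / mean(.data$gf_raw[beads])
  )
  attr(out, "gate") <- gate
  out
}

#' Per-population summaries of one acquisition
#'
#' Abundance is the labelled-event count divided by the acquired volume;
#' scatter and fluorescence are averaged in bead-relative units; cell volume
#' is computed per event (SSC -> diameter -> sphere volume) and then
#' averaged, since the mean cell volume of the population -- not the volume
#' at the mean scatter -- is the biological quantity of interest.
#'
#' @param events Gated, bead-normalised events (columns `ssc_ru`, `gf_fru`,
#'   `label`).
#' @param acquired_volume_mL Acquired sample volume in mL, > 0.
#' @param calibration An [ssc_calibration()].
#' @param groups Population labels to summarise.
#' @return A tibble with one row per group: `n_events`, `abundance`
#'   (cells mL^-1), `mean_ssc_ru`, `mean_gf_fru`, `mean_diameter` (um),
#'   `mean_volume` (um^3) and an `empty` flag (zero events: abundance 0,
#'   means `NA`).
#' @export
population_stats <- function(events, acquired_volume_mL,
                             calibration = ssc_calibration(),
                             groups = c("LNA", "HNA")) {
  stopifnot(is.data.frame(events))
  if (!is.finite(acquired_volume_mL) || acquired_volume_mL <= 0) {
    rlang::abort("`acquired_volume_mL` must be > 0")
  }
  if (!all(c("ssc_ru", "gf_fru", "label") %in% names(events))) {
    rlang::abort("`events` must be gated and normalised (ssc_ru, gf_fru, label)")
  }
  purrr::map_dfr(groups, function(g) {
    sel <- events$label == g
    n <- sum(sel)
    if (n == 0) {
      return(tibble::tibble(group = g, n_events = 0L, abundance = 0,
                            mean_ssc_ru = NA_real_, mean_gf_fru = NA_real_,
                            mean_diameter = NA_real_, mean_volume = NA_real_,
                            empty = TRUE))
    }
    d <- suppressWarnings(ssc_to_diameter(events$ssc_ru[sel], calibration))
    tibble::tibble(
      group = g,
      n_events = n,
      abundance = n / acquired_volume_mL,
      mean_ssc_ru = mean(events$ssc_ru[sel]),
      mean_gf_fru = mean(events$gf_fru[sel]),
      mean_diameter = mean(d),
      mean_volume = mean(diameter_to_volume(as.numeric(d))),
      empty = FALSE
    )
  })
}
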