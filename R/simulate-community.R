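#' Simulate CARD-FISH count tables and ARISA peak tables
#'
#' Each month gets its own community: a CARD-FISH probe composition (jittered
#' around the global proportions, with total probe coverage of DAPI held
#' near its target) and an ARISA fragment profile (a fixed set of fragment
#' lengths with skewed intensities). Samples within a month share the month
#' community up to small sample-level noise, so that same-month samples are
#' expected to cluster together downstream. ARISA peak lengths are jittered
#' by a small measurement error so fragment binning is non-trivial, and
#' nuisance peaks below the intensity cutoff and outside the 100-1000 bp
#' range are added to exercise the filters.
#'
#' @param samples Tibble with one row per community sample; must contain
#'   `month`, `treatment`, `offset` (and optionally `temperature`).
#' @param community Community settings, see [truth_params()].
#' @param month_props Optional named list: month -> named probe proportions
#'   (each summing to <= 1). Generated if `NULL`. Proportions summing to
#'   more than 1 are rejected.
#' @param month_profiles Optional named list: month -> tibble with
#'   `fragment_length` (bp) and `intensity`. Generated if `NULL`.
#' @param seed Optional seed.
#' @return A list with `cardfish` (tibble: sample keys, one count column per
#'   probe, `dapi_total`), `arisa` (tibble: sample keys, `fragment_length`,
#'   `rfi`), and `truth` (the month-level compositions and profiles used).
#' @export
simulate_community_tables <- function(samples,
                                      community = truth_params()$community,
                                      month_props = NULL,
                                      month_profiles = NULL,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(is.data.frame(samples))
  need <- c("month", "treatment", "offset")
  if (!all(need %in% names(samples))) {
    rlang::abort(paste("`samples` needs columns:", paste(need, collapse = ", ")))
  }
  months <- unique(as.character(samples$month))
  probes <- names(community$cardfish_props)

  if (is.null(month_props)) {
    month_props <- lapply(months, function(m) {
      p <- community$cardfish_props *
        exp(stats::rnorm(length(probes), 0, community$month_sd))
      # between-month mixes differ but total probe coverage of DAPI stays
      # near its target
      cov <- min(0.98, sum(community$cardfish_props) *
                   exp(stats::rnorm(1, 0, community$coverage_sd)))
      p / sum(p) * cov
    })
    names(month_props) <- months
  }
  for (p in month_props) {
    if (any(p < 0) || sum(p) > 1) {
      rlang::abort("probe proportions must be >= 0 and sum to <= 1")
    }
  }

  if (is.null(month_profiles)) {
    # a few dominant fragments carry most of the intensity (they survive the
    # downstream RFI cutoff); the rare tail exercises the filters
    anchors <- seq(110, 990, by = 8)
    month_profiles <- lapply(months, function(m) {
      nf <- community$n_fragments
      nd <- min(community$n_dominant, nf)
      len <- sort(sample(anchors, nf)) + stats::runif(nf, -2, 2)
      dom <- sample.int(nf, nd)
      w_dom <- stats::rgamma(nd, shape = 8)
      w_rare <- stats::rgamma(nf - nd, shape = 0.5)
      intensity <- numeric(nf)
      intensity[dom] <- community$dominant_mass * w_dom / sum(w_dom)
      intensity[-dom] <- (1 - community$dominant_mass) * w_rare / sum(w_rare)
      tibble::tibble(fragment_length = len, intensity = intensity)
    })
    names(month_profiles) <- months
  }

  keys <- dplyr::mutate(
    tibble::as_tibble(samples),
    sample = paste(.data$month, .data$treatment,
                   sprintf("%+d", .data$offset), sep = "_")
  )

  sdl <- sqrt(log(1 + community$prop_cv^2))
  card <- purrr::pmap(keys, function(...) {
    row <- list(...)
    p <- month_props[[as.character(row$month)]]
    p <- p * exp(stats::rnorm(length(p), -sdl^2 / 2, sdl))
    if (sum(p) > 0.99) p <- p / sum(p) * 0.99
    counts <- stats::rmultinom(1, community$dapi_cells, c(p, 1 - sum(p)))[, 1]
    out <- as.list(counts[seq_along(probes)])
    names(out) <- probes
    tibble::tibble(!!!out, dapi_total = community$dapi_cells)
  })
  cardfish <- dplyr::bind_cols(keys, dplyr::bind_rows(card))

  sdr <- sqrt(log(1 + community$rfi_cv^2))
  arisa <- purrr::pmap(keys, function(...) {
    row <- list(...)
    prof <- month_profiles[[as.character(row$month)]]
    main <- tibble::tibble(
      fragment_length = prof$fragment_length +
        stats::rnorm(nrow(prof), 0, community$length_jitter_bp),
      rfi = prof$intensity * exp(stats::rnorm(nrow(prof), -sdr^2 / 2, sdr))
    )
    nz <- community$n_noise_peaks
    noise <- tibble::tibble(
      fragment_length = stats::runif(nz, 105, 995),
      rfi = stats::runif(nz, 0.002, 0.01)
    )
    no <- community$n_outside_peaks
    outside <- tibble::tibble(
      fragment_length = c(stats::runif(ceiling(no / 2), 60, 95),
                          stats::runif(floor(no / 2), 1005, 1150)),
      rfi = stats::runif(no, 0.02, 0.1)
    )
    dplyr::arrange(dplyr::bind_rows(main, noise, outside),
                   .data$fragment_length)
  })
  arisa <- dplyr::bind_cols(
    keys[rep(seq_len(nrow(keys)), vapply(arisa, nrow, 1L)), ],
    dplyr::bind_rows(arisa)
  )

  list(cardfish = cardfish, arisa = arisa,
       truth = list(month_props = month_props, month_profiles = month_profiles))
}
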