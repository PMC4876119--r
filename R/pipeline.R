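# End-to-end drivers: simulate -> gate -> temperature response -> community.

#' Gate and summarise every acquisition of an experiment
#'
#' Runs bead identification, HNA/LNA gating, bead-relative normalisation and
#' population summaries over every acquisition of a (simulated or imported)
#' experiment.
#'
#' @param experiment An `mt_experiment` from [simulate_experiment()], or any
#'   tibble shaped like its `acquisitions` element.
#' @param calibration [ssc_calibration()] used for volume conversion;
#'   defaults to the experiment's own calibration when available.
#' @param bead Nominal bead position; defaults to the experiment's truth.
#' @param min_beads Passed to [normalize_to_beads()].
#' @return A tidy per-acquisition, per-group table of [population_stats()]
#'   rows keyed by `month`, `treatment`, `offset`, `temperature`,
#'   `replicate`, `time`.
#' @export
gate_experiment <- function(experiment, calibration = NULL, bead = NULL,
                            min_beads = 20) {
  acq <- if (inherits(experiment, "mt_experiment")) {
    if (is.null(calibration)) calibration <- experiment$truth$calibration
    if (is.null(bead)) bead <- experiment$truth$params$bead
    experiment$acquisitions
  } else {
    experiment
  }
  if (is.null(calibration)) calibration <- ssc_calibration()
  keys <- intersect(c("month", "ambient_temperature", "treatment", "offset",
                      "temperature", "replicate", "bottle", "time"),
                    names(acq))
  stats_list <- purrr::map(seq_len(nrow(acq)), function(i) {
    ev <- gate_populations(acq$events[[i]], bead = bead)
    ev <- normalize_to_beads(ev, min_beads = min_beads,
                             acquisition = paste(unlist(acq[i, keys[1:min(3, length(keys))]]),
                                                 collapse = "/"))
    st <- population_stats(ev, acq$acquired_volume_mL[i], calibration)
    dplyr::bind_cols(acq[rep(i, nrow(st)), keys], st)
  })
  dplyr::bind_rows(stats_list)
}

#' Temperature-response analysis of gated summaries
#'
#' Chains [bottle_means()], [temperature_slopes()], percent-per-degC and
#' base-pair conversion, growth-rate and activation-energy estimation, the
#' annual summaries and the cross-correlation matrix of monthly responses.
#'
#' @param stats Output of [gate_experiment()].
#' @param abundance Optional tidy abundance table (e.g.
#'   `experiment$abundance`) for growth fits; when `NULL`, the
#'   cytometry-derived abundances in `stats` are used.
#' @return A list: `summaries`, `ambient`, `slopes` (with `percent_per_degc`
#'   and, for NAC, `kbp_per_degc`), `annual`, `percent_summary`,
#'   `correlations`, `growth`, `arrhenius`.
#' @export
analyze_temperature <- function(stats, abundance = NULL) {
  summaries <- bottle_means(stats)
  ambient <- ambient_reference(stats)
  slopes <- temperature_slopes(summaries) |>
    dplyr::left_join(ambient, by = c("month", "treatment", "group")) |>
    dplyr::mutate(
      ambient_value = ifelse(.data$response == "volume",
                             .data$ambient_volume, .data$ambient_nac),
      percent_per_degc = percent_per_degc(.data$slope, .data$ambient_value),
      kbp_per_degc = ifelse(
        .data$response == "nac",
        nac_to_basepairs(.data$percent_per_degc, .data$group),
        NA_real_
      )
    ) |>
    dplyr::select(-"ambient_volume", -"ambient_nac")
  annual <- annual_slope_summary(slopes)
  percent_summary <- slopes |>
    dplyr::group_by(.data$treatment, .data$group, .data$response) |>
    dplyr::summarise(
      mean_percent = mean(.data$percent_per_degc),
      se_percent = stats::sd(.data$percent_per_degc) / sqrt(dplyr::n()),
      mean_kbp = mean(.data$kbp_per_degc),
      .groups = "drop"
    )
  correlations <- if (dplyr::n_distinct(slopes$month) >= 3) {
    correlate_responses(slopes)
  } else {
    rlang::inform("fewer than 3 months: correlation matrix skipped")
    NULL
  }
  if (is.null(abundance)) {
    abundance <- dplyr::select(stats, dplyr::any_of(c(
      "month", "treatment", "offset", "temperature", "replicate", "group",
      "time", "abundance"
    )))
  }
  growth <- growth_rates(abundance)
  arrhenius <- activation_energies(growth)
  list(summaries = summaries, ambient = ambient, slopes = slopes,
       annual = annual, percent_summary = percent_summary,
       correlations = correlations, growth = growth, arrhenius = arrhenius)
}

#' Community-structure analysis
#'
#' CARD-FISH counts become percentages of DAPI and ARISA peak tables are
#' filtered and binned into OTUs; each is turned into a Bray-Curtis
#' dissimilarity matrix and a UPGMA dendrogram, and the tendency of samples
#' from the same month to cluster together is quantified per treatment.
#'
#' @param cardfish Probe-count table (see [simulate_community_tables()]).
#' @param arisa Peak table with `sample`, `fragment_length`, `rfi`.
#' @param group_by Sample metadata column used for the concordance check.
#' @return A list with `cardfish` (percentages), `otu` (binned ARISA table),
#'   and per-treatment `trees` and `concordance` for both fingerprints.
#' @export
analyze_community <- function(cardfish, arisa, group_by = "month") {
  card_pct <- relative_abundance(cardfish)
  arisa_f <- filter_peaks(arisa)
  per_treatment <- function(df, fun) {
    split(df, df$treatment) |> purrr::map(fun)
  }
  card_res <- per_treatment(card_pct, function(df) {
    m <- as.matrix(df[, grep("^pct_", names(df))])
    rownames(m) <- df$sample
    hc <- cluster_dendrogram(bray_curtis(m))
    labs <- as.character(df[[group_by]])
    names(labs) <- df$sample
    list(tree = hc, newick = as_newick(hc),
         concordance = cluster_concordance(hc, labs))
  })
  arisa_res <- per_treatment(arisa_f, function(df) {
    otu <- bin_fragments(df)
    hc <- cluster_dendrogram(bray_curtis(otu))
    meta <- dplyr::distinct(
      dplyr::inner_join(tibble::tibble(sample = otu$sample),
                        dplyr::distinct(arisa, .data$sample,
                                        .data$month, .data$treatment),
                        by = "sample"))
    labs <- as.character(meta[[group_by]])
    names(labs) <- meta$sample
    list(otu = otu, tree = hc, newick = as_newick(hc),
         concordance = cluster_concordance(hc, labs))
  })
  list(cardfish = card_pct, arisa_filtered = arisa_f,
       cardfish_trees = card_res, arisa_trees = arisa_res)
}

#' Run the full pipeline on a synthetic experiment
#'
#' `simulate -> gate -> temperature response -> community`, optionally
#' writing every result table to delimited files.
#'
#' @inheritParams simulate_experiment
#' @param out_dir Optional directory; when given, results are written with
#'   [write_results()].
#' @return A list: `experiment`, `stats`, `temperature`, `community`.
#' @export
run_pipeline <- function(design = experiment_design(), truth = truth_params(),
                         seed = 1, n_events = 2000,
                         calibration = ssc_calibration(), out_dir = NULL) {
  experiment <- simulate_experiment(design, truth, seed = seed,
                                    n_events = n_events,
                                    calibration = calibration)
  stats <- gate_experiment(experiment)
  temperature <- analyze_temperature(stats, abundance = experiment$abundance)
  community <- analyze_community(experiment$cardfish, experiment$arisa)
  res <- list(experiment = experiment, stats = stats,
              temperature = temperature, community = community)
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' Write pipeline results as delimited text files
#'
#' Tables go to TSV, dendrograms to Newick, and the ground-truth record to
#' JSON. Output is plain text and reproducible: identical results give
#' byte-identical files.
#'
#' @param results Output of [run_pipeline()] (or a compatible list).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_tsv(df, path)
    files <<- c(files, path)
  }
  wr(results$stats, "population_stats.tsv")
  tr <- results$temperature
  wr(tr$summaries, "bottle_means.tsv")
  wr(tr$slopes, "temperature_slopes.tsv")
  wr(tr$annual, "annual_slopes.tsv")
  wr(tr$percent_summary, "percent_summary.tsv")
  if (!is.null(tr$correlations)) wr(tr$correlations, "slope_correlations.tsv")
  wr(tr$growth, "growth_rates.tsv")
  wr(tr$arrhenius, "activation_energies.tsv")
  co <- results$community
  wr(co$cardfish, "cardfish_percentages.tsv")
  wr(co$arisa_filtered, "arisa_filtered_peaks.tsv")
  for (tre in names(co$arisa_trees)) {
    wr(co$arisa_trees[[tre]]$otu, paste0("otu_table_", tre, ".tsv"))
    writeLines(co$arisa_trees[[tre]]$newick,
               file.path(dir, paste0("arisa_dendrogram_", tre, ".nwk")))
    files <- c(files, file.path(dir, paste0("arisa_dendrogram_", tre, ".nwk")))
  }
  for (tre in names(co$cardfish_trees)) {
    writeLines(co$cardfish_trees[[tre]]$newick,
               file.path(dir, paste0("cardfish_dendrogram_", tre, ".nwk")))
    files <- c(files, file.path(dir, paste0("cardfish_dendrogram_", tre, ".nwk")))
  }
  if (!is.null(results$experiment)) {
    truth <- results$experiment$truth
    truth_json <- list(
      seed = truth$seed, n_events = truth$n_events,
      design = truth$design[c("months", "ambient_temperature",
                              "temperature_offsets", "treatments",
                              "replicates", "sampling_times")],
      groups = truth$params$groups,
      growth = truth$params$growth,
      bead = truth$params$bead,
      event_correlation = truth$params$event_correlation,
      bottles = truth$bottles
    )
    path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth_json, path, auto_unbox = TRUE, digits = NA)
    files <- c(files, path)
  }
  invisible(files)
}

#' Write per-acquisition event tables
#'
#' One TSV per acquisition (rows: `ssc_raw`, `gf_raw`, `truth_label`),
#' named by bottle and time point.
#'
#' @param experiment An `mt_experiment`.
#' @param dir Output directory.
#' @param max_acquisitions Optional cap on the number of files written.
#' @return Invisibly, the files written.
#' @export
write_event_tables <- function(experiment, dir, max_acquisitions = Inf) {
  stopifnot(inherits(experiment, "mt_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acq <- experiment$acquisitions
  n <- min(nrow(acq), max_acquisitions)
  files <- character(n)
  for (i in seq_len(n)) {
    nm <- paste0("events_", acq$bottle[i], "_t", acq$time[i], ".tsv")
    files[i] <- file.path(dir, nm)
    readr::write_tsv(acq$events[[i]], files[i])
  }
  invisible(files)
}
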