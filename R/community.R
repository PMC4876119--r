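# CARD-FISH relative abundances, ARISA filtering and shifting-window
# binning, Bray-Curtis dissimilarity and UPGMA dendrograms.

#' CARD-FISH relative abundances
#'
#' Converts probe counts to percentages of the total DAPI count per sample,
#' and reports the summed coverage of the probe set.
#'
#' @param counts Tibble with one row per sample: one count column per probe
#'   and a `dapi_total` column.
#' @param probes Probe column names; defaults to the four broad groups
#'   (SAR11, Rhodobacteraceae, Gammaproteobacteria, Bacteroidetes)
#'   intersected with the available columns.
#' @return The input with added `pct_<probe>` columns and `coverage` (summed
#'   probe percentage of DAPI).
#' @export
relative_abundance <- function(counts, probes = NULL) {
  stopifnot(is.data.frame(counts))
  if (!"dapi_total" %in% names(counts)) {
    rlang::abort("`counts` must contain a `dapi_total` column")
  }
  if (is.null(probes)) {
    probes <- intersect(c("SAR11", "Rhodobacteraceae", "Gammaproteobacteria",
                          "Bacteroidetes"), names(counts))
  }
  if (length(probes) == 0) rlang::abort("no probe columns found")
  stop_if_not_positive(counts$dapi_total, "dapi_total")
  for (p in probes) {
    if (any(counts[[p]] < 0)) rlang::abort(paste0("negative counts in ", p))
    if (any(counts[[p]] > counts$dapi_total)) {
      rlang::abort(paste0("probe count exceeds DAPI total in ", p))
    }
  }
  pct <- purrr::map_dfc(probes, function(p) {
    tibble::tibble(!!paste0("pct_", p) := 100 * counts[[p]] / counts$dapi_total)
  })
  dplyr::bind_cols(tibble::as_tibble(counts), pct) |>
    dplyr::mutate(coverage = rowSums(pct))
}

#' Filter ARISA peak profiles
#'
#' Per sample: intensities are first normalised to sum 1 over all raw peaks,
#' then peaks outside the fragment-size range or with normalised intensity
#' below the cutoff (inclusive: values equal to the cutoff are retained) are
#' removed, and the surviving intensities are renormalised to sum 1. Samples
#' left empty are dropped with a warning and listed in
#' `attr(, "flagged_samples")`.
#'
#' @param peaks Tibble with `fragment_length` (bp), `rfi` and optionally a
#'   `sample` column (a single profile is assumed otherwise).
#' @param min_bp,max_bp Retained fragment-size range (inclusive).
#' @param rfi_cutoff Relative fluorescence intensity cutoff on the
#'   normalised scale.
#' @return Filtered, renormalised peak tibble.
#' @export
filter_peaks <- function(peaks, min_bp = 100, max_bp = 1000,
                         rfi_cutoff = 0.09) {
  stopifnot(is.data.frame(peaks))
  if (!all(c("fragment_length", "rfi") %in% names(peaks))) {
    rlang::abort("`peaks` needs `fragment_length` and `rfi` columns")
  }
  peaks <- tibble::as_tibble(peaks)
  if (!"sample" %in% names(peaks)) peaks$sample <- "sample_1"
  out <- peaks |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(rfi = .data$rfi / sum(.data$rfi)) |>
    dplyr::filter(.data$fragment_length >= min_bp,
                  .data$fragment_length <= max_bp,
                  .data$rfi >= rfi_cutoff) |>
    dplyr::mutate(rfi = .data$rfi / sum(.data$rfi)) |>
    dplyr::ungroup()
  flagged <- setdiff(unique(peaks$sample), unique(out$sample))
  if (length(flagged) > 0) {
    rlang::warn(paste0("sample(s) empty after filtering: ",
                       paste(flagged, collapse = ", ")))
  }
  attr(out, "flagged_samples") <- flagged
  out
}

# bin start for each fragment under one frame offset
bin_start <- function(len, anchor, offset, window) {
  anchor + offset + window * floor((len - anchor - offset) / window)
}

# samples x bins matrix of summed rfi for one frame
frame_table <- function(profiles, anchor, offset, window) {
  b <- bin_start(profiles$fragment_length, anchor, offset, window)
  agg <- profiles |>
    dplyr::mutate(bin = b) |>
    dplyr::group_by(.data$sample, .data$bin) |>
    dplyr::summarise(rfi = sum(.data$rfi), .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = "bin", values_from = "rfi",
                             values_fill = 0, names_sort = TRUE)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample
  m
}

#' Bin ARISA fragments into OTUs with a shifting window
#'
#' Fragments are assigned to fixed-width bins `[start, start + window)`;
#' candidate binning frames are generated by shifting the bin anchor in
#' steps of `shift` across one full window, and the frame whose resulting
#' sample x bin table has the highest mean pairwise sample similarity
#' (1 - Bray-Curtis) is selected. Each occupied bin is an OTU. Every
#' retained fragment lands in exactly one bin per frame, so per-sample
#' intensity row sums are preserved.
#'
#' @param profiles Filtered peak tibble (see [filter_peaks()]) with
#'   `sample`, `fragment_length`, `rfi`; at least 2 samples.
#' @param window Bin width in bp.
#' @param shift Frame shift step in bp.
#' @param anchor Base position (bp) the frames are anchored at.
#' @return An OTU table of class `mt_otu`: a tibble with a `sample` column
#'   and one numeric column per occupied bin (named by bin start). The
#'   selected frame offset and the per-frame scores are in
#'   `attr(, "offset")` / `attr(, "frame_scores")`.
#' @export
bin_fragments <- function(profiles, window = 3, shift = 0.1, anchor = 100) {
  stopifnot(is.data.frame(profiles))
  if (!all(c("sample", "fragment_length", "rfi") %in% names(profiles))) {
    rlang::abort("`profiles` needs `sample`, `fragment_length`, `rfi` columns")
  }
  n_samples <- dplyr::n_distinct(profiles$sample)
  if (n_samples < 2) rlang::abort("need >= 2 samples to select a frame")
  offsets <- seq(0, window - shift, by = shift)
  scores <- vapply(offsets, function(o) {
    m <- frame_table(profiles, anchor, o, window)
    if (ncol(m) == 1) return(1)
    mean(1 - vegan::vegdist(m, method = "bray"))
  }, numeric(1))
  best <- offsets[which.max(scores)]
  m <- frame_table(profiles, anchor, best, window)
  out <- dplyr::bind_cols(tibble::tibble(sample = rownames(m)),
                          tibble::as_tibble(m))
  class(out) <- c("mt_otu", class(out))
  attr(out, "offset") <- best
  attr(out, "window") <- window
  attr(out, "frame_scores") <- tibble::tibble(offset = offsets, score = scores)
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over bins/taxa, computed
#' with `vegan::vegdist`. Pairs of all-zero samples have undefined distance
#' and are flagged with a warning.
#'
#' @param table An OTU table from [bin_fragments()], or any data frame /
#'   matrix of non-negative abundances with samples in rows (a `sample`
#'   column is used for labels if present).
#' @return A `dist` object with sample labels.
#' @export
#' @examples
#' bray_curtis(rbind(a = c(1, 1, 0), b = c(0, 1, 1)))[1] # 0.5
bray_curtis <- function(table) {
  if (is.data.frame(table)) {
    labs <- if ("sample" %in% names(table)) table$sample else rownames(table)
    m <- as.matrix(dplyr::select(tibble::as_tibble(table),
                                 dplyr::where(is.numeric)))
    rownames(m) <- labs
  } else {
    m <- as.matrix(table)
  }
  if (nrow(m) < 2) rlang::abort("need >= 2 samples")
  if (any(m < 0)) rlang::abort("abundances must be non-negative")
  zero <- rowSums(m) == 0
  if (sum(zero) >= 2) {
    rlang::warn("pairs of all-zero samples have undefined Bray-Curtis distance")
  }
  vegan::vegdist(m, method = "bray")
}

#' Agglomerative dendrogram from a dissimilarity matrix
#'
#' UPGMA (average linkage) by default, matching common practice for
#' community fingerprint dendrograms; complete and single linkage are
#' available as options.
#'
#' @param dm A `dist` object (e.g. from [bray_curtis()]).
#' @param method Linkage method.
#' @return An `hclust` tree. Use [as_newick()] to serialise and
#'   [stats::cophenetic()] for cophenetic distances.
#' @export
cluster_dendrogram <- function(dm, method = c("average", "complete", "single")) {
  method <- match.arg(method)
  stopifnot(inherits(dm, "dist"))
  if (attr(dm, "Size") < 3) {
    rlang::warn("fewer than 3 samples: trivial tree")
  }
  stats::hclust(dm, method = method)
}

#' Serialise a dendrogram as Newick
#'
#' @param tree An `hclust` or `phylo` tree.
#' @return A Newick string with branch lengths.
#' @export
as_newick <- function(tree) {
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Fraction of label groups forming exclusive clades
#'
#' Quantifies how strongly a grouping (e.g. month of sampling) is reflected
#' in a dendrogram: a group is concordant when its leaves form an exclusive
#' subtree (some internal node contains exactly that group's leaves).
#' Singleton groups are trivially concordant and reported separately.
#'
#' @param tree An `hclust` tree.
#' @param labels Group labels, one per leaf, in the order of
#'   `tree$labels` (or a named vector matching the leaf labels).
#' @return A list of class `mt_concordance`: `groups` (tibble with `group`,
#'   `size`, `concordant`, `singleton`), `fraction` (all groups, singletons
#'   counted as concordant) and `fraction_multi` (non-singleton groups
#'   only).
#' @export
cluster_concordance <- function(tree, labels) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (!is.null(names(labels)) && !is.null(tree$labels)) {
    labels <- labels[tree$labels]
  }
  if (length(labels) != n) {
    rlang::abort("`labels` must have one entry per leaf")
  }
  merge <- tree$merge
  sets <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    left <- if (merge[k, 1] < 0) -merge[k, 1] else sets[[merge[k, 1]]]
    right <- if (merge[k, 2] < 0) -merge[k, 2] else sets[[merge[k, 2]]]
    sets[[k]] <- sort(c(left, right))
  }
  groups <- purrr::map_dfr(unique(as.character(labels)), function(g) {
    idx <- sort(which(as.character(labels) == g))
    singleton <- length(idx) == 1
    conc <- singleton ||
      any(vapply(sets, function(s) identical(s, idx), logical(1)))
    tibble::tibble(group = g, size = length(idx),
                   concordant = conc, singleton = singleton)
  })
  multi <- groups[!groups$singleton, ]
  structure(
    list(groups = groups,
         fraction = mean(groups$concordant),
         fraction_multi = if (nrow(multi)) mean(multi$concordant) else NA_real_),
    class = "mt_concordance"
  )
}

#' @export
print.mt_concordance <- function(x, ...) {
  cat("<mt_concordance> ", round(100 * x$fraction, 1), "% of groups exclusive",
      if (!is.na(x$fraction_multi)) {
        paste0(" (", round(100 * x$fraction_multi, 1), "% of multi-leaf groups)")
      }, "\n", sep = "")
  invisible(x)
}
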