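test_that("CARD-FISH percentages divide by DAPI and report coverage", {
  counts <- tibble::tibble(
    sample = "s1", SAR11 = 10, Rhodobacteraceae = 10,
    Gammaproteobacteria = 10, Bacteroidetes = 10, dapi_total = 100
  )
  ra <- relative_abundance(counts)
  expect_equal(ra$pct_SAR11, 10)
  expect_equal(ra$coverage, 40)
  counts$Bacteroidetes <- 0
  expect_equal(relative_abundance(counts)$pct_Bacteroidetes, 0)
  counts$SAR11 <- 150
  expect_error(relative_abundance(counts), "exceeds DAPI")
})

test_that("generator proportions reappear as summed coverage downstream", {
  s <- tidyr::expand_grid(month = month.abb[1:4], treatment = c("C", "F"),
                          offset = c(-3, 0, 3))
  ct <- simulate_community_tables(s, seed = 61)
  ra <- relative_abundance(ct$cardfish)
  expect_lt(abs(mean(ra$coverage) - 70.4), 1.5)
})

test_that("peak filtering honours range, inclusive cutoff and renormalisation", {
  prof <- tibble::tibble(
    fragment_length = c(150, 1005, 400, 600),
    rfi = c(0.5, 0.3, 0.41, 0.09)
  )
  # normalised over all 4 peaks: 0.5/1.3, 0.3/1.3, 0.41/1.3, 0.09/1.3
  f <- filter_peaks(prof, rfi_cutoff = 0.09 / 1.3)
  expect_false(1005 %in% f$fragment_length)   # out of range
  expect_true(600 %in% f$fragment_length)     # exactly at cutoff: retained
  expect_equal(sum(f$rfi), 1)
  # hand renormalisation over the three survivors
  expect_equal(sort(f$rfi), sort(c(0.5, 0.41, 0.09) / 1.0), tolerance = 1e-12)

  expect_warning(
    empty <- filter_peaks(tibble::tibble(fragment_length = c(200, 300),
                                         rfi = c(0.5, 0.5)),
                          rfi_cutoff = 0.6),
    "empty after filtering"
  )
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "flagged_samples"), "sample_1")
})

test_that("toy fragments bin as forced by the 3-bp window", {
  prof <- tibble::tibble(
    sample = rep(c("a", "b"), each = 3),
    fragment_length = rep(c(100.0, 101.0, 104.5), 2),
    rfi = rep(1 / 3, 6)
  )
  otu <- bin_fragments(prof)
  bins <- setdiff(names(otu), "sample")
  expect_equal(length(bins), 2)   # {100, 101} co-binned; 104.5 separate
  expect_equal(unname(rowSums(otu[, bins])), c(1, 1), tolerance = 1e-12)
})

test_that("selected frame equals the brute-force optimum on random toy sets", {
  set.seed(62)
  for (rep in 1:25) {
    n_samp <- sample(2:5, 1)
    n_frag <- sample(3:20, 1)
    prof <- tidyr::expand_grid(sample = paste0("s", seq_len(n_samp)),
                               idx = seq_len(n_frag))
    prof$fragment_length <- rep(runif(n_frag, 100, 1000), times = n_samp) +
      rnorm(nrow(prof), 0, 0.4)
    prof$rfi <- runif(nrow(prof), 0.1, 1)
    prof <- dplyr::select(prof, -idx)
    got <- bin_fragments(prof)
    want <- binning_oracle(prof)
    expect_equal(attr(got, "offset"), want$offset)
    # selected frame's score is maximal over every enumerated frame
    sc <- attr(got, "frame_scores")
    expect_true(all(max(sc$score) >= sc$score - 1e-12))
    # partition property: per-sample totals preserved
    sums <- rowSums(got[, setdiff(names(got), "sample")])
    want_sums <- tapply(prof$rfi, prof$sample, sum)
    expect_equal(unname(sums), as.numeric(want_sums[got$sample]),
                 tolerance = 1e-12)
  }
})

test_that("jittered fragments of a true OTU are co-binned in most replicates", {
  set.seed(63)
  hits <- replicate(40, {
    s <- tidyr::expand_grid(month = "Jan", treatment = c("C", "F"),
                            offset = c(-3, 0, 3))
    ct <- quietly(simulate_community_tables(s, seed = sample.int(1e6, 1)))
    f <- quietly(filter_peaks(ct$arisa))
    otu <- bin_fragments(f)
    off <- attr(otu, "offset")
    # map each retained peak back to its generating true fragment
    true_len <- ct$truth$month_profiles$Jan$fragment_length
    nearest <- true_len[vapply(f$fragment_length,
                               function(x) which.min(abs(true_len - x)), 1L)]
    keep <- abs(nearest - f$fragment_length) < 2
    starts <- 100 + off +
      3 * floor((f$fragment_length[keep] - 100 - off) / 3)
    ok <- tapply(starts, nearest[keep],
                 function(b) length(unique(b)) == 1)
    mean(ok)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Bray-Curtis matches hand arithmetic and its metric properties", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0), d = c(2, 2, 0))
  dm <- bray_curtis(m)
  md <- as.matrix(dm)
  expect_equal(md["a", "b"], 0.5)            # (1+0+1)/(1+2+1)
  expect_equal(md["a", "c"], 0)              # identical rows
  expect_equal(md["a", "d"], 1 / 3)          # joint rescaling is not identity
  disj <- bray_curtis(rbind(x = c(1, 2, 0, 0), y = c(0, 0, 3, 1)))
  expect_equal(as.numeric(disj), 1)          # disjoint supports
  expect_true(all(md >= 0 & md <= 1))
  expect_equal(md, t(md))
  expect_true(all(diag(md) == 0))
  # random cross-check against the hand formula
  set.seed(64)
  r <- matrix(runif(5 * 7), 5)
  dr <- as.matrix(bray_curtis(r))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(dr[i, j], bc_oracle(r[i, ], r[j, ]), tolerance = 1e-12)
  }
})

test_that("UPGMA dendrogram: forced topology, monotone heights, Newick round trip", {
  dm <- as.dist(matrix(c(0, 0.1, 0.9,
                         0.1, 0, 0.9,
                         0.9, 0.9, 0), 3,
                       dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  hc <- cluster_dendrogram(dm)
  expect_true(all(diff(hc$height) >= 0))
  ph <- ape::read.tree(text = as_newick(hc))
  expect_true(ape::is.monophyletic(ph, c("A", "B")))
  # cophenetic distances consistent with merge heights
  cp <- as.matrix(stats::cophenetic(hc))
  expect_equal(cp["A", "B"], 0.1)
  expect_equal(cp["A", "C"], 0.9)
  # Newick round trip preserves topology and branch lengths
  ph2 <- ape::read.tree(text = ape::write.tree(ph))
  expect_equal(ape::dist.topo(ph, ph2)[1], 0)
  expect_equal(sort(ph2$edge.length), sort(ph$edge.length), tolerance = 1e-9)
})

test_that("UPGMA heights are monotone on random dissimilarities", {
  set.seed(65)
  for (i in 1:10) {
    m <- matrix(runif(8 * 6), 8)
    hc <- cluster_dendrogram(bray_curtis(m))
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("concordance: blocked groups score 1, planted outlier flagged", {
  m <- matrix(0.9, 6, 6)
  m[1:2, 1:2] <- 0.05; m[3:4, 3:4] <- 0.05; m[5:6, 5:6] <- 0.05
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
  hc <- cluster_dendrogram(stats::as.dist(m))
  cc <- cluster_concordance(hc, rep(c("g1", "g2", "g3"), each = 2))
  expect_equal(cc$fraction, 1)

  # planted outlier: one sample of g1 sits inside the g3 block
  labs <- c("g1", "g2", "g2", "g3", "g3", "g1")
  cc2 <- cluster_concordance(hc, labs)
  expect_false(cc2$groups$concordant[cc2$groups$group == "g1"])
})

test_that("random labels on a star-like tree match the permutation null", {
  set.seed(66)
  n <- 10
  m <- matrix(0.8, n, n) + matrix(runif(n * n, 0, 0.02), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  hc <- cluster_dendrogram(stats::as.dist(m))
  labs <- rep(c("a", "b", "c", "d", "e"), each = 2)
  obs <- replicate(300, cluster_concordance(hc, sample(labs))$fraction)
  perm <- replicate(1000, cluster_concordance(hc, sample(labs))$fraction)
  expect_lt(abs(mean(obs) - mean(perm)),
            3 * sqrt(var(obs) / 300 + var(perm) / 1000))
})

test_that("month-planted communities cluster by month", {
  set.seed(67)
  fr <- replicate(10, {
    s <- tidyr::expand_grid(month = month.abb[1:4], treatment = "C",
                            offset = c(-3, 0, 3))
    ct <- quietly(simulate_community_tables(s, seed = sample.int(1e6, 1)))
    f <- quietly(filter_peaks(ct$arisa))
    otu <- bin_fragments(f)
    hc <- cluster_dendrogram(bray_curtis(otu))
    meta <- dplyr::distinct(ct$arisa[, c("sample", "month")])
    labs <- stats::setNames(as.character(meta$month), meta$sample)
    cluster_concordance(hc, labs)$fraction
  })
  expect_gte(mean(fr), 0.95)
})
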