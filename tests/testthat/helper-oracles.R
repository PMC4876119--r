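# Independent oracles and fixture builders used across the suite.

# textbook OLS closed forms, independent of lm()
ols_oracle <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sigma2 <- sum(res^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 2)
  list(slope = slope, intercept = intercept, se = se,
       ci = slope + c(-1, 1) * tcrit * se,
       r2 = 1 - sum(res^2) / sum((y - my)^2))
}

# hand Bray-Curtis for two non-negative vectors
bc_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)

# brute-force shifting-window binning: enumerate frames with naive loops and
# score each by mean pairwise similarity using the hand BC formula
binning_oracle <- function(profiles, window = 3, shift = 0.1, anchor = 100) {
  offsets <- seq(0, window - shift, by = shift)
  samples <- sort(unique(profiles$sample))
  score_frame <- function(o) {
    starts <- anchor + o +
      window * floor((profiles$fragment_length - anchor - o) / window)
    bins <- sort(unique(starts))
    mat <- matrix(0, length(samples), length(bins),
                  dimnames = list(samples, as.character(bins)))
    for (i in seq_len(nrow(profiles))) {
      s <- as.character(profiles$sample[i])
      b <- as.character(starts[i])
      mat[s, b] <- mat[s, b] + profiles$rfi[i]
    }
    sims <- c()
    for (i in seq_along(samples)) {
      for (j in seq_len(i - 1)) {
        sims <- c(sims, 1 - bc_oracle(mat[i, ], mat[j, ]))
      }
    }
    list(score = mean(sims), mat = mat)
  }
  scores <- vapply(offsets, function(o) score_frame(o)$score, numeric(1))
  best <- offsets[which.max(scores)]
  list(offset = best, scores = scores, table = score_frame(best)$mat)
}

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

small_design <- function(n_months = 2, sampling_times = c(0, 1, 2, 3, 4, 5, 6)) {
  experiment_design(
    months = month.abb[seq_len(n_months)],
    ambient_temperature = seq(13, by = 1, length.out = n_months),
    sampling_times = sampling_times
  )
}

# truth with every stochastic dial at zero (point-mass event clouds)
zero_noise_truth <- function(groups = NULL, growth = list(), bead = list(), ...) {
  truth_params(
    groups = groups,
    sdlog_ssc = 0, sdlog_gf = 0,
    bottle_sd_volume = 0, bottle_sd_nac = 0,
    drift_lag = 0, drift_exponential = 0,
    growth = utils::modifyList(list(rate_cv = 0, abundance_cv = 0), growth),
    bead = utils::modifyList(list(cv = 0), bead),
    ...
  )
}
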