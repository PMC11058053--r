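# shared fixtures: tiny recordings and rasters built in code

# recording with given value matrix and metadata defaults
tiny_recording <- function(values, frame_interval = 1, stimulus_onset = 0,
                           labels = NULL) {
  fluorescence_recording(values, frame_interval = frame_interval,
                         stimulus_onset = stimulus_onset, labels = labels)
}

# wrap a 0/1 matrix as a binary_raster (cells x frames)
tiny_raster <- function(active, frame_interval = 1, stimulus_onset = 0) {
  structure(list(active = active, frame_interval = frame_interval,
                 stimulus_onset = stimulus_onset,
                 labels = rep("unknown", nrow(active)),
                 threshold_params = list()),
            class = "binary_raster")
}

# normalised_traces wrapper for direct unit tests
tiny_traces <- function(values, frame_interval = 1, stimulus_onset = 0) {
  structure(list(values = values, frame_interval = frame_interval,
                 stimulus_onset = stimulus_onset,
                 labels = rep("unknown", nrow(values)),
                 provenance = list()),
            class = "normalised_traces")
}

# brute-force Pearson correlation: textbook sums, no cor()
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (den == 0) return(NA_real_)
  num / den
}

# brute-force exact two-sided Wilcoxon signed-rank p by 2^n enumeration
brute_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W_plus <- sum(r[d > 0])
  S <- sum(r)
  W <- min(W_plus, S - W_plus)
  all_wplus <- vapply(0:(2^n - 1), function(bits) {
    signs <- bitwAnd(bits, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  min(1, mean(all_wplus <= W + 1e-9) + mean(all_wplus >= S - W - 1e-9))
}

# independent bursty binary rasters: renewal bursts, no coupling
independent_raster <- function(n_cells, n_frames, burst_len = 6,
                               gap_mean = 40, seed = 1) {
  set.seed(seed)
  act <- matrix(0L, n_cells, n_frames)
  for (c in seq_len(n_cells)) {
    t <- 1 + stats::rgeom(1, 1 / gap_mean)
    while (t <= n_frames) {
      act[c, t:min(n_frames, t + burst_len - 1L)] <- 1L
      t <- t + burst_len + stats::rgeom(1, 1 / gap_mean)
    }
  }
  tiny_raster(act)
}
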