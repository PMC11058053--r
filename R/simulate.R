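#' Configuration for the synthetic islet generator
#'
#' Defines the study conditions the generator emulates: a glucose-step
#' recording in which a minority of planted hub cells drive islet-wide
#' oscillatory Ca2+ waves, a labelled subpopulation (e.g. NNAT-positive cells,
#' about 15% of beta cells) whose hub membership can be biased, and imaging
#' noise.
#'
#' The generative model: after `glucose_step_frame`, each hub initiates
#' oscillations as a gamma-renewal process (`event_rate` per minute,
#' shape `renewal_shape`; irregular on purpose -- strictly periodic trains
#' would re-align under the circular-shift null used downstream). Each
#' oscillation is a sustained activity plateau of `plateau_s` seconds in the
#' hub itself. Every other cell is wired to the hub with probability
#' `hub_coupling`; a wired cell responds to each oscillation with probability
#' `response_reliability`, as a brief stereotyped transient (instant rise of
#' amplitude 1, exponential decay `decay_s`) placed at a uniform random delay
#' within the plateau -- the wave reaches different cells at different times,
#' so followers coincide with their hub but only rarely with one another.
#' Followers additionally fire private transients at
#' `event_rate * follower_coupling` per minute. Baseline is 1 a.u. plus
#' linear drift; Gaussian noise `noise_sd` is added everywhere.
#'
#' @param n_cells number of cells (default 50, a typical imaged field).
#' @param n_frames total frames (default 3000).
#' @param frame_interval seconds per frame (default 1).
#' @param hub_fraction fraction of cells planted as hubs (default 0.1).
#' @param hub_coupling probability that a given cell is wired to a hub
#'   (default 0.6).
#' @param follower_coupling multiplier on `event_rate` for followers' private
#'   events; must be < `hub_coupling` (default 0.05).
#' @param event_rate oscillations per minute per hub (default 60/165, one
#'   slow glucose-induced oscillation every ~2.75 min).
#' @param label_fraction expected fraction of label-positive cells
#'   (default 0.15).
#' @param label_hub_odds odds multiplier for a hub being label-positive;
#'   values < 1 de-enrich hubs from the positive subpopulation (default 1).
#' @param glucose_step_frame 0-based frame of stimulation onset (default 120).
#' @param noise_sd fluorescence noise s.d. in a.u. (default 0.2).
#' @param drift_per_frame linear baseline drift in a.u./frame (default 0).
#' @param seed integer seed; one stream per islet.
#' @param response_reliability per-oscillation response probability of wired
#'   cells (default 0.95).
#' @param plateau_s hub oscillation plateau duration in seconds (default 55).
#' @param decay_s transient decay constant in seconds (default 4).
#' @param renewal_shape gamma shape of inter-oscillation intervals
#'   (default 2).
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 50, n_frames = 3000,
                              frame_interval = 1, hub_fraction = 0.1,
                              hub_coupling = 0.6, follower_coupling = 0.05,
                              event_rate = 60 / 165, label_fraction = 0.15,
                              label_hub_odds = 1, glucose_step_frame = 120,
                              noise_sd = 0.2, drift_per_frame = 0, seed = 1,
                              response_reliability = 0.95, plateau_s = 55,
                              decay_s = 4, renewal_shape = 2) {
  cfg <- list(n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
              frame_interval = frame_interval, hub_fraction = hub_fraction,
              hub_coupling = hub_coupling,
              follower_coupling = follower_coupling, event_rate = event_rate,
              label_fraction = label_fraction,
              label_hub_odds = label_hub_odds,
              glucose_step_frame = as.integer(glucose_step_frame),
              noise_sd = noise_sd, drift_per_frame = drift_per_frame,
              seed = as.integer(seed),
              response_reliability = response_reliability,
              plateau_s = plateau_s, decay_s = decay_s,
              renewal_shape = renewal_shape)
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what)
  chk(cfg$n_cells >= 1, "n_cells must be a positive integer")
  chk(cfg$n_frames >= 1, "n_frames must be a positive integer")
  chk(cfg$frame_interval > 0, "frame_interval must be > 0 seconds")
  for (p in c("hub_fraction", "hub_coupling", "follower_coupling",
              "label_fraction", "response_reliability"))
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1,
        sprintf("%s must be a proportion in [0, 1]", p))
  chk(cfg$follower_coupling < cfg$hub_coupling || cfg$hub_coupling == 0,
      "follower_coupling must be < hub_coupling")
  chk(cfg$hub_fraction == 0 || cfg$hub_fraction * cfg$n_cells >= 1,
      "hub_fraction * n_cells must be >= 1 when hub_fraction > 0")
  chk(cfg$event_rate >= 0, "event_rate must be >= 0 events per minute")
  chk(cfg$label_hub_odds > 0, "label_hub_odds must be a positive real")
  chk(cfg$glucose_step_frame >= 0 && cfg$glucose_step_frame < cfg$n_frames,
      "glucose_step_frame must be < n_frames")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$plateau_s > 0, "plateau_s must be > 0 seconds")
  chk(cfg$decay_s > 0, "decay_s must be > 0 seconds")
  invisible(cfg)
}

#' Simulate one islet recording with planted hubs and exported ground truth
#'
#' Draws, in a fixed stream order (hub identities; wiring per hub; labels;
#' oscillation onsets and responses per hub; follower private events; noise),
#' a glucose-step recording under the model described in
#' [simulation_config()]. Identical configs give identical output.
#'
#' @param config a [simulation_config()].
#' @return A list with components `recording` (a
#'   [fluorescence_recording()]) and `truth` (class `islet_ground_truth`:
#'   `hub_ids` -- 1-based planted hub indices, `labels`, `event_times` --
#'   per-hub 0-based onset frames, `adjacency` -- symmetric 0/1 matrix of
#'   planted hub--cell wiring).
#' @export
simulate_islet <- function(config) {
  validate_config(config)
  with(config, {
    set.seed(seed)
    dt <- frame_interval
    n_hubs <- if (hub_fraction > 0) max(1L, round(hub_fraction * n_cells)) else 0L
    hubs <- if (n_hubs > 0) sort(sample.int(n_cells, n_hubs)) else integer(0)
    adj <- matrix(0L, n_cells, n_cells)
    wired <- vector("list", length(hubs))
    names(wired) <- as.character(hubs)
    for (i in seq_along(hubs)) {
      h <- hubs[i]
      others <- setdiff(seq_len(n_cells), h)
      w <- others[stats::runif(length(others)) < hub_coupling]
      wired[[i]] <- w
      adj[h, w] <- 1L; adj[w, h] <- 1L
    }
    p_lab <- rep(label_fraction, n_cells)
    if (length(hubs) > 0 && label_fraction > 0 && label_fraction < 1) {
      odds <- label_fraction / (1 - label_fraction) * label_hub_odds
      p_lab[hubs] <- min(1, max(0, odds / (1 + odds)))
    }
    labels <- ifelse(stats::runif(n_cells) < p_lab, "pos", "neg")

    Tpost_s <- (n_frames - glucose_step_frame) * dt
    per_s <- if (event_rate > 0) 60 / event_rate else Inf
    dec <- exp(-(seq_len(ceiling(6 * decay_s / dt))) * dt / decay_s)
    ker_hub <- c(rep(1, max(1L, round(plateau_s / dt))),
                 exp(-seq_len(ceiling(6 / dt)) * dt))
    ker_fol <- c(1, dec)
    onset_resp <- matrix(0, n_cells, n_frames)
    onset_hub <- matrix(0, n_cells, n_frames)
    event_times <- vector("list", length(hubs))
    names(event_times) <- as.character(hubs)
    to_frame <- function(t_s) glucose_step_frame + 1L + floor(t_s / dt)
    for (i in seq_along(hubs)) {
      h <- hubs[i]
      on <- numeric(0)
      if (is.finite(per_s)) {
        t_s <- stats::runif(1, 0, per_s)
        while (t_s < Tpost_s) {
          on <- c(on, t_s)
          t_s <- t_s + stats::rgamma(1, renewal_shape, renewal_shape / per_s)
        }
      }
      f <- to_frame(on); f <- f[f <= n_frames]
      event_times[[i]] <- f - 1L   # 0-based
      onset_hub[h, f] <- onset_hub[h, f] + 1
      for (c in wired[[i]]) {
        resp <- on[stats::runif(length(on)) < response_reliability]
        fr <- to_frame(resp + stats::runif(length(resp), 0, plateau_s))
        fr <- fr[fr <= n_frames]
        if (length(fr) > 0)
          onset_resp[c, ] <- onset_resp[c, ] + tabulate(fr, n_frames)
      }
    }
    followers <- setdiff(seq_len(n_cells), hubs)
    priv_rate <- event_rate * follower_coupling
    for (c in followers) {
      n_ev <- stats::rpois(1, priv_rate * Tpost_s / 60)
      if (n_ev > 0) {
        fr <- to_frame(stats::runif(n_ev, 0, Tpost_s))
        fr <- fr[fr <= n_frames]
        if (length(fr) > 0)
          onset_resp[c, ] <- onset_resp[c, ] + tabulate(fr, n_frames)
      }
    }
    tr <- matrix(1, n_cells, n_frames) +
      matrix(drift_per_frame * (seq_len(n_frames) - 1L),
             n_cells, n_frames, byrow = TRUE)
    pre <- seq_len(glucose_step_frame)
    tr <- tr + batch_causal_conv(onset_hub, ker_hub, pre) +
      batch_causal_conv(onset_resp, ker_fol, pre)
    if (noise_sd > 0)
      tr <- tr + matrix(stats::rnorm(n_cells * n_frames, 0, noise_sd),
                        n_cells, n_frames)
    tr <- pmax(tr, 0.01)
    theta <- stats::runif(n_cells, 0, 2 * pi)
    rad <- 100 * sqrt(stats::runif(n_cells))
    rec <- fluorescence_recording(
      tr, frame_interval = dt, labels = labels,
      stimulus_onset = glucose_step_frame,
      islet_id = sprintf("islet_seed%d", seed),
      coords = cbind(rad * cos(theta), rad * sin(theta)))
    truth <- structure(
      list(hub_ids = hubs, labels = labels, event_times = event_times,
           adjacency = adj),
      class = "islet_ground_truth")
    list(recording = rec, truth = truth)
  })
}

# causal convolution of every row of `onsets` with kernel `ker`, batched as
# zero-padded FFTs; `pre` columns (pre-stimulus, onset-free by construction)
# are zeroed to remove FFT round-off
batch_causal_conv <- function(onsets, ker, pre) {
  n_frames <- ncol(onsets)
  use <- rowSums(onsets) > 0
  out <- matrix(0, nrow(onsets), n_frames)
  if (!any(use)) return(out)
  L <- stats::nextn(n_frames + length(ker), factors = c(2, 3, 5))
  Z <- matrix(0, L, sum(use))
  Z[seq_len(n_frames), ] <- t(onsets[use, , drop = FALSE])
  K <- stats::fft(c(ker, numeric(L - length(ker))))
  conv <- Re(stats::mvfft(stats::mvfft(Z) * K, inverse = TRUE)) / L
  res <- t(conv[seq_len(n_frames), , drop = FALSE])
  res[, pre] <- 0
  out[use, ] <- res
  out
}

#' Simulate a cohort of islets
#'
#' Islet `i` uses seed `base_seed + i - 1`, so the first islet reproduces
#' `simulate_islet` at `base_seed`; islet ids are distinct.
#'
#' @param config a [simulation_config()]; its `seed` field is overridden.
#' @param n_islets number of islets (>= 1).
#' @param base_seed integer seed for the first islet.
#' @return A list of `simulate_islet` results.
#' @export
simulate_cohort <- function(config, n_islets, base_seed = config$seed) {
  if (n_islets < 1) stop("n_islets must be >= 1")
  lapply(seq_len(n_islets), function(i) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i - 1L)
    simulate_islet(cfg)
  })
}

#' Write ground truth as a JSON sidecar
#'
#' Exports `hub_ids` (1-based), per-cell labels, per-hub 0-based event onset
#' frames and the planted adjacency as an edge list.
#'
#' @param truth an `islet_ground_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  ut <- which(upper.tri(truth$adjacency) & truth$adjacency == 1L,
              arr.ind = TRUE)
  jsonlite::write_json(
    list(hub_ids = truth$hub_ids, labels = truth$labels,
         event_times = truth$event_times,
         adjacency_edges = list(from = as.integer(ut[, 1]),
                                to = as.integer(ut[, 2]))),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Simulate a bisulphite clone methylation matrix
#'
#' Each clone x CpG call is independently methylated with the site's
#' probability, then masked as missing with probability `missing_prob`.
#'
#' @param n_clones number of clones (>= 1).
#' @param cpg_positions strictly increasing 1-based genomic positions.
#' @param per_cpg_prob per-site methylation probabilities, same length as
#'   `cpg_positions`.
#' @param missing_prob probability a call is missing (default 0).
#' @param seed integer seed.
#' @param region_id,sample_id identifiers stored on the result.
#' @return A [clone_methylation()] matrix.
#' @export
simulate_clone_matrix <- function(n_clones, cpg_positions, per_cpg_prob,
                                  missing_prob = 0, seed = 1,
                                  region_id = "region",
                                  sample_id = "sample") {
  if (length(cpg_positions) != length(per_cpg_prob))
    stop("cpg_positions and per_cpg_prob must have equal length")
  if (any(per_cpg_prob < 0 | per_cpg_prob > 1) ||
      missing_prob < 0 || missing_prob > 1)
    stop("probabilities must lie in [0, 1]")
  if (n_clones < 1) stop("n_clones must be >= 1")
  set.seed(seed)
  n_sites <- length(cpg_positions)
  m <- matrix(ifelse(stats::runif(n_clones * n_sites) <
                       rep(per_cpg_prob, each = n_clones), "M", "U"),
              n_clones, n_sites)
  if (missing_prob > 0)
    m[stats::runif(n_clones * n_sites) < missing_prob] <- "."
  clone_methylation(m, cpg_positions, region_id = region_id,
                    sample_id = sample_id)
}
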