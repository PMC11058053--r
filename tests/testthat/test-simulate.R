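test_that("invalid configurations are rejected naming the violated invariant", {
  expect_error(simulation_config(hub_fraction = 1.2), "proportion")
  expect_error(simulation_config(follower_coupling = 0.7), "hub_coupling")
  expect_error(simulation_config(glucose_step_frame = 3000), "n_frames")
  expect_error(simulation_config(hub_fraction = 0.001), "hub_fraction")
  expect_error(simulation_config(label_hub_odds = 0), "positive")
})

test_that("identical seeds give identical recordings and ground truth", {
  cfg <- simulation_config(n_cells = 12, n_frames = 500, seed = 21)
  a <- simulate_islet(cfg)
  b <- simulate_islet(cfg)
  expect_identical(a$recording$values, b$recording$values)
  expect_identical(a$truth$hub_ids, b$truth$hub_ids)
  expect_identical(a$truth$adjacency, b$truth$adjacency)
})

test_that("pre-step frames are baseline plus noise only; event_rate 0 stays silent", {
  cfg <- simulation_config(n_cells = 6, n_frames = 400, hub_fraction = 0.2,
                           noise_sd = 0, seed = 2)
  sim <- simulate_islet(cfg)
  expect_true(all(sim$recording$values[, 1:120] == 1))
  cfg0 <- simulation_config(n_cells = 6, n_frames = 400, hub_fraction = 0.2,
                            event_rate = 0, noise_sd = 0, seed = 2)
  sim0 <- simulate_islet(cfg0)
  expect_true(all(sim0$recording$values == 1))
})

test_that("with full coupling and reliability every cell responds within each oscillation", {
  cfg <- simulation_config(n_cells = 5, n_frames = 900, hub_fraction = 0.2,
                           hub_coupling = 1, follower_coupling = 0,
                           response_reliability = 1, noise_sd = 0, seed = 4)
  sim <- simulate_islet(cfg)
  h <- sim$truth$hub_ids
  expect_length(h, 1)
  expect_true(all(sim$truth$adjacency[h, -h] == 1))
  plateau_f <- round(cfg$plateau_s / cfg$frame_interval)
  v <- sim$recording$values
  for (ev in sim$truth$event_times[[as.character(h)]]) {
    if (ev + plateau_f + 2 > ncol(v)) next  # responses clipped at the end
    win <- (ev + 1):(ev + plateau_f + 2)    # 1-based columns
    for (c in setdiff(1:5, h))
      expect_gt(max(v[c, win]), 1.5)  # a transient fired inside the window
  }
})

test_that("adjacency is symmetric with zero diagonal and hubs are in range", {
  sim <- simulate_islet(simulation_config(n_cells = 15, n_frames = 400,
                                          seed = 8))
  expect_identical(sim$truth$adjacency, t(sim$truth$adjacency))
  expect_true(all(diag(sim$truth$adjacency) == 0))
  expect_true(all(sim$truth$hub_ids %in% 1:15))
})

test_that("label marginals match the configured expectation over 10^4 cells", {
  cfg <- simulation_config(n_cells = 2500, n_frames = 130,
                           glucose_step_frame = 120, event_rate = 0,
                           noise_sd = 0, label_fraction = 0.15, seed = 31)
  frac <- vapply(0:3, function(k) {
    c2 <- cfg; c2$seed <- 31L + k
    mean(simulate_islet(c2)$truth$labels == "pos")
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.15), 0.02)
})

test_that("label_hub_odds biases hub labels in the expected direction", {
  cfg <- simulation_config(n_cells = 400, n_frames = 130,
                           glucose_step_frame = 120, event_rate = 0,
                           noise_sd = 0, label_hub_odds = 0.2, seed = 1)
  hub_pos <- fol_pos <- c()
  for (s in 1:25) {
    c2 <- cfg; c2$seed <- s
    sim <- simulate_islet(c2)
    hub_pos <- c(hub_pos, sim$truth$labels[sim$truth$hub_ids] == "pos")
    fol_pos <- c(fol_pos, sim$truth$labels[-sim$truth$hub_ids] == "pos")
  }
  expect_lt(mean(hub_pos), mean(fol_pos))
  # expected hub-positive probability: odds 0.15/0.85 * 0.2
  p_exp <- (0.15 / 0.85 * 0.2) / (1 + 0.15 / 0.85 * 0.2)
  expect_lt(abs(mean(hub_pos) - p_exp), 0.025)
})

test_that("cohorts use consecutive seeds and distinct islet ids", {
  cfg <- simulation_config(n_cells = 8, n_frames = 300, hub_fraction = 0.25,
                           seed = 99)
  coh <- simulate_cohort(cfg, n_islets = 3, base_seed = 50)
  ids <- vapply(coh, function(x) x$recording$islet_id, character(1))
  expect_length(unique(ids), 3)
  single <- simulate_islet(simulation_config(n_cells = 8, n_frames = 300,
                                             hub_fraction = 0.25, seed = 50))
  expect_identical(coh[[1]]$recording$values, single$recording$values)
  coh2 <- simulate_cohort(cfg, n_islets = 3, base_seed = 50)
  expect_identical(coh[[2]]$recording$values, coh2[[2]]$recording$values)
})

test_that("ground-truth JSON sidecar round-trips the planted structure", {
  sim <- simulate_islet(simulation_config(n_cells = 10, n_frames = 400,
                                          seed = 3))
  td <- withr::local_tempdir()
  p <- file.path(td, "gt.json")
  write_ground_truth(sim$truth, p)
  gt <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_setequal(gt$hub_ids, sim$truth$hub_ids)
  expect_equal(length(gt$adjacency_edges$from),
               sum(sim$truth$adjacency[upper.tri(sim$truth$adjacency)]))
})

test_that("clone matrices honour per-site probabilities and missingness", {
  m1 <- simulate_clone_matrix(20, c(5, 9, 14), c(1, 1, 1), seed = 2)
  expect_true(all(m1$calls == "M"))
  m0 <- simulate_clone_matrix(20, c(5, 9), c(0, 0), missing_prob = 0.3,
                              seed = 2)
  expect_true(all(m0$calls %in% c("U", ".")))
  expect_gt(sum(m0$calls == "."), 0)
  expect_error(simulate_clone_matrix(5, c(1, 2), c(0.5)), "equal length")
  # determinism
  expect_identical(simulate_clone_matrix(8, c(1, 5), c(.4, .6), seed = 7)$calls,
                   simulate_clone_matrix(8, c(1, 5), c(.4, .6), seed = 7)$calls)
})
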