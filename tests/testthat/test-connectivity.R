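test_that("Pearson matrix matches hand values on binary vectors", {
  ras <- tiny_raster(rbind(c(1, 1, 0, 0),
                           c(1, 1, 0, 0),
                           c(0, 1, 0, 1),
                           c(1, 0, 1, 0)))
  r <- pearson_matrix(ras, c(0, 4))
  expect_equal(r[1, 2], 1)
  expect_equal(r[3, 4], -1)
  expect_equal(r[1, 4], 0)   # 1100 vs 1010
  expect_identical(r, t(r))
  expect_equal(diag(r), rep(1, 4))
})

test_that("zero-variance cells give undefined correlations", {
  ras <- tiny_raster(rbind(c(0, 0, 0, 0), c(1, 0, 1, 0)))
  r <- pearson_matrix(ras, c(0, 4))
  expect_true(is.na(r[1, 2]) && is.na(r[1, 1]))
  expect_equal(r[2, 2], 1)
})

test_that("Pearson matrix agrees with a brute-force oracle to 1e-12", {
  set.seed(100)
  for (k in 1:20) {
    n <- sample(3:10, 1); Tn <- sample(10:50, 1)
    act <- matrix(rbinom(n * Tn, 1, runif(1, 0.2, 0.8)), n, Tn)
    r <- pearson_matrix(tiny_raster(act), c(0, Tn))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      expect_equal(r[i, j], brute_pearson(act[i, ], act[j, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("circular-shift null table equals directly shifted correlations", {
  set.seed(5)
  act <- matrix(rbinom(3 * 30, 1, 0.4), 3, 30)
  ras <- tiny_raster(act)
  tab <- hubnet:::shift_r_table(t(act))
  for (k in c(0, 1, 7, 29)) {
    shifted <- act[2, c((k + 1):30, seq_len(k))[1:30]]
    expect_equal(tab$Rk[k + 1, 1], brute_pearson(act[1, ], shifted),
                 tolerance = 1e-9)
  }
})

test_that("identical bursty vectors are significant; an all-zero cell never is", {
  set.seed(12)
  v <- rep(0L, 200)
  starts <- seq(5, 195, by = 33) + sample(-3:3, 6, replace = TRUE)
  for (s in starts) v[s:(s + 9)] <- 1L   # ~30% active, 200 frames
  act <- rbind(v, v, rep(0L, 200))
  sig <- permutation_significance(tiny_raster(act), c(0, 200),
                                  method = "exact", alpha = 0.01)
  expect_true(sig[1, 2])
  expect_false(any(sig[3, ]))
  expect_false(any(diag(sig)))
})

test_that("independent sparse vectors are rarely significant", {
  hits <- 0
  for (s in 1:40) {
    set.seed(s)
    act <- matrix(0L, 2, 100)
    act[1, sample(100, 5)] <- 1L
    act[2, sample(100, 5)] <- 1L
    sig <- permutation_significance(tiny_raster(act), c(0, 100),
                                    n_permutations = 200, alpha = 0.01,
                                    seed = s, method = "sample")
    hits <- hits + sig[1, 2]
  }
  expect_lte(hits / 40, 0.05)
})

test_that("sampled significance is deterministic under a seed", {
  ras <- independent_raster(8, 300, seed = 3)
  s1 <- permutation_significance(ras, c(0, 300), seed = 11,
                                 n_permutations = 300)
  s2 <- permutation_significance(ras, c(0, 300), seed = 11,
                                 n_permutations = 300)
  expect_identical(as.logical(s1), as.logical(s2))
  expect_identical(attr(s1, "p_values"), attr(s2, "p_values"))
})

test_that("connectivity percentages count significant partners", {
  full <- matrix(TRUE, 5, 5); diag(full) <- FALSE
  expect_equal(cell_connectivity(full), rep(100, 5))
  expect_equal(cell_connectivity(matrix(FALSE, 4, 4)), rep(0, 4))
  star <- matrix(FALSE, 11, 11)
  star[1, 2:11] <- star[2:11, 1] <- TRUE
  expect_equal(cell_connectivity(star), c(100, rep(10, 10)))
  expect_error(cell_connectivity(matrix(FALSE, 1, 1)), "2 cells")
})

test_that("node categories use lower-edge-inclusive boundaries", {
  got <- categorise_cells(c(80, 79.9, 60, 59.9, 40, 39.9, 0, 100))
  expect_equal(as.character(got),
               c(">=80", ">=60", ">=60", ">=40", ">=40", "<40", "<40",
                 ">=80"))
  expect_error(categorise_cells(c(50, 101)), "\\[0, 100\\]")
  expect_setequal(names(category_palette()),
                  c(">=80", ">=60", ">=40", "<40"))
})

test_that("hub classification is inclusive at the threshold and monotone", {
  pct <- c(30, 29.9, 0, 55.5, 100)
  expect_identical(classify_hubs(pct, 30), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  set.seed(2)
  p <- runif(50, 0, 100)
  for (k in 1:10) {
    t1 <- runif(1, 1, 99); t2 <- t1 + runif(1, 0, 100 - t1)
    expect_true(all(classify_hubs(p, t2) <= classify_hubs(p, t1)))
  }
  expect_error(classify_hubs(pct, 0), "\\(0, 100\\]")
})

test_that("degree distribution recovers a planted power-law exponent", {
  set.seed(77)
  d <- 1:100
  pmf <- d^-2 / sum(d^-2)
  pct <- sample(d, 10000, replace = TRUE, prob = pmf)
  dist <- degree_distribution(pct, n_bins = 10)
  expect_false(dist$degenerate)
  expect_lt(abs(dist$slope - (-2)), 0.15)
  expect_gt(dist$fit_r2, 0.9)
  expect_equal(sum(dist$proportion), 1)
})

test_that("two-bin distribution matches the closed-form slope", {
  pct <- c(rep(1, 9), rep(10, 1))
  dist <- degree_distribution(pct, n_bins = 2)
  w <- diff(dist$bins)
  expected <- (log10(0.1 / w[2]) - log10(0.9 / w[1])) /
    (log10(dist$centres[2]) - log10(dist$centres[1]))
  expect_equal(dist$slope, expected, tolerance = 1e-12)
})

test_that("degenerate connectivity distributions are flagged or rejected", {
  dist <- degree_distribution(rep(25, 40))
  expect_true(dist$degenerate)
  expect_true(is.na(dist$slope))
  expect_error(degree_distribution(rep(0, 10)), "zero connectivity")
})

test_that("islet summaries separate hub and follower coactivity by construction", {
  sim <- simulate_islet(simulation_config(n_cells = 30, n_frames = 2000,
                                          seed = 14))
  res <- analyse_islet(sim$recording)
  s <- summarise_islet(res)
  expect_true(s$hub_fraction > 0)
  expect_gt(s$mean_hub_coactivity_pct, s$mean_follower_coactivity_pct)
  # complete-graph degenerate cases
  full <- matrix(TRUE, 4, 4); diag(full) <- FALSE
  fake <- structure(list(hub_flags = rep(TRUE, 4), mean_r = 1,
                         connectivity_pct = cell_connectivity(full)),
                    class = "connectivity_result")
  s2 <- summarise_islet(fake)
  expect_equal(s2$hub_fraction, 1)
  expect_equal(s2$mean_hub_coactivity_pct, 100)
})

test_that("planted wiring is recovered and unrelated cells stay unconnected", {
  # clean regime: low noise, no private follower events, <= 20 cells.
  # Planted hub-cell links must be significant; cells sharing no driver are
  # independent by construction, so links between them appear at most at
  # chance level. (Cells co-driven by a shared hub are genuinely coactive,
  # so some extra edges among them are expected and not counted as errors.)
  ok_edges <- total <- unrelated_hits <- unrelated_total <- 0
  for (s in 1:4) {
    sim <- simulate_islet(simulation_config(
      n_cells = 18, n_frames = 3000, noise_sd = 0.05,
      follower_coupling = 0, seed = s))
    res <- analyse_islet(sim$recording, alpha = 0.01)
    adj <- sim$truth$adjacency
    hubs <- sim$truth$hub_ids
    hub_edges <- which(adj == 1 & row(adj) %in% hubs & upper.tri(adj))
    ok_edges <- ok_edges + sum(res$sig_mask[hub_edges])
    total <- total + length(hub_edges)
    drives <- adj[hubs, , drop = FALSE]
    shared <- t(drives) %*% drives        # cells x cells shared-driver count
    unrelated <- shared == 0 & adj == 0 & upper.tri(adj) &
      !(row(adj) %in% hubs) & !(col(adj) %in% hubs)
    unrelated_hits <- unrelated_hits + sum(res$sig_mask[unrelated])
    unrelated_total <- unrelated_total + sum(unrelated)
  }
  expect_gte(ok_edges / total, 0.9)
  if (unrelated_total > 0)
    expect_lte(unrelated_hits / unrelated_total, 0.05)
})

test_that("GraphML and delimited exports round-trip the network", {
  sim <- simulate_islet(simulation_config(n_cells = 12, n_frames = 1200,
                                          seed = 6))
  res <- analyse_islet(sim$recording)
  td <- withr::local_tempdir()
  gpath <- file.path(td, "net.graphml")
  export_graphml(res, gpath)
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::vcount(g), 12)
  expect_equal(igraph::ecount(g), sum(res$sig_mask) / 2)
  expect_true(all(c("label", "category", "hub", "connectivity_pct") %in%
                    igraph::vertex_attr_names(g)))
  write_connectivity(res, td)
  cells <- utils::read.delim(file.path(td, "cells.tsv"))
  expect_equal(nrow(cells), 12)
  expect_equal(cells$hub, as.integer(res$hub_flags))
})
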