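#' Pairwise Pearson coactivity of binarised cells
#'
#' Textbook Pearson correlation between each pair of cells' binary activity
#' vectors over an analysis window. Pairs involving a zero-variance (silent
#' or saturated) cell are undefined and returned as `NA`; the diagonal is 1
#' for defined cells and `NA` otherwise.
#'
#' @param raster a [binarise()] result.
#' @param window 0-based half-open frame window; defaults to
#'   `[stimulus_onset, n_frames)`.
#' @return Symmetric cells x cells matrix of correlations in `[-1, 1]`.
#' @export
pearson_matrix <- function(raster, window = NULL) {
  X <- raster_window(raster, window)
  if (ncol(X) < 2) stop("need at least 2 cells")
  if (nrow(X) < 2) stop("window must contain at least 2 frames")
  sds <- apply(X, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  r
}

# extract window as frames x cells numeric matrix
raster_window <- function(raster, window = NULL) {
  n <- ncol(raster$active)
  if (is.null(window)) window <- c(raster$stimulus_onset, n)
  idx <- window_index(window, n)
  t(raster$active[, idx, drop = FALSE])
}

# Circular cross-correlation machinery. For binary vectors with fixed
# margins, the Pearson r at a circular offset is a strictly increasing
# function of the overlap count O(k) = sum_t x_i(t) x_j(t+k), so null
# exceedance counts can be taken on the integer overlaps directly.
# Returns overlaps (T x npairs), pair indices, observed r, validity.
shift_overlap_table <- function(X) {
  Tn <- nrow(X); n <- ncol(X)
  m <- colMeans(X)
  v <- colMeans(X^2) - m^2
  ok <- v > 0
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pair_i <- idx[, 1]; pair_j <- idx[, 2]
  Fx <- stats::mvfft(X)
  Cs <- Conj(Fx[, pair_i, drop = FALSE]) * Fx[, pair_j, drop = FALSE]
  O <- round(Re(stats::mvfft(Cs, inverse = TRUE)) / Tn)
  denom <- sqrt(v[pair_i] * v[pair_j]) * Tn
  denom[denom == 0] <- NA_real_
  robs <- (O[1, ] - Tn * m[pair_i] * m[pair_j]) / denom
  list(O = O, pair_i = pair_i, pair_j = pair_j, robs = robs, ok = ok)
}

# r values at every offset for one pair (used by tests and diagnostics)
shift_r_table <- function(X) {
  tab <- shift_overlap_table(X)
  Tn <- nrow(X)
  m <- colMeans(X)
  v <- colMeans(X^2) - m^2
  denom <- sqrt(v[tab$pair_i] * v[tab$pair_j]) * Tn
  denom[denom == 0] <- NA_real_
  Rk <- sweep(tab$O, 2, Tn * m[tab$pair_i] * m[tab$pair_j]) /
    rep(denom, each = Tn)
  list(Rk = Rk, pair_i = tab$pair_i, pair_j = tab$pair_j, ok = tab$ok)
}

#' Permutation significance of pairwise coactivity
#'
#' For each defined cell pair, a null distribution of the Pearson coefficient
#' is built by circularly shifting one cell's binary vector (which preserves
#' each cell's burst structure while destroying alignment); a connection is
#' significant iff the observed coefficient strictly exceeds the
#' `(1 - alpha)` quantile of the pair's null. With `method = "sample"`
#' (the default) each permutation draws a random non-zero offset; with
#' `method = "exact"` the null enumerates all `T - 1` offsets, which is
#' deterministic and needs no seed. Circular-shift correlations at all
#' offsets are computed in one pass by FFT cross-correlation, so both methods
#' cost about the same.
#'
#' @param raster a [binarise()] result.
#' @param window 0-based half-open frame window (default: post-stimulus).
#' @param n_permutations permutations per pair for `method = "sample"`
#'   (>= 100; default 1000).
#' @param alpha per-pair significance level (default 0.01).
#' @param seed integer seed for `method = "sample"`.
#' @param method `"sample"` or `"exact"`.
#' @return Logical cells x cells significance mask (symmetric, zero
#'   diagonal), with attribute `p_values` (matrix of permutation p-values,
#'   `(count >= observed + 1) / (m + 1)`).
#' @export
permutation_significance <- function(raster, window = NULL,
                                     n_permutations = 1000, alpha = 0.01,
                                     seed = 1,
                                     method = c("sample", "exact")) {
  method <- match.arg(method)
  X <- raster_window(raster, window)
  if (nrow(X) < 3) stop("window must contain at least 3 frames")
  if (method == "sample" && n_permutations < 100)
    stop("n_permutations must be >= 100")
  tab <- shift_overlap_table(X)
  Tn <- nrow(X); n <- ncol(X); npairs <- length(tab$pair_i)
  robs <- tab$robs
  obs_O <- tab$O[1, ]
  if (method == "exact") {
    m <- Tn - 1L
    count <- colSums(tab$O >= rep(obs_O, each = Tn)) - 1L
  } else {
    m <- as.integer(n_permutations)
    set.seed(seed)
    count <- integer(npairs)
    block <- max(1L, floor(2e6 / m))
    for (s in seq(1L, npairs, by = block)) {
      e <- min(s + block - 1L, npairs)
      cols <- s:e
      off <- matrix(sample.int(Tn - 1L, m * length(cols), replace = TRUE),
                    m, length(cols))
      nullv <- matrix(tab$O[cbind(as.vector(off) + 1L,
                                  rep(cols, each = m))],
                      m, length(cols))
      count[cols] <- colSums(nullv >= rep(obs_O[cols], each = m))
    }
  }
  # observed > (1-alpha) quantile (type 1)  <=>  count <= m - ceil((1-alpha) m)
  allow <- m - as.integer(ceiling((1 - alpha) * m))
  sigv <- count <= allow & !is.na(robs) &
    tab$ok[tab$pair_i] & tab$ok[tab$pair_j]
  sig <- matrix(FALSE, n, n)
  sig[cbind(tab$pair_i, tab$pair_j)] <- sigv
  sig <- sig | t(sig)
  pv <- matrix(NA_real_, n, n)
  pvals <- (count + 1) / (m + 1)
  pv[cbind(tab$pair_i, tab$pair_j)] <- pvals
  pv[cbind(tab$pair_j, tab$pair_i)] <- pvals
  attr(sig, "p_values") <- pv
  attr(sig, "method") <- method
  sig
}

#' Per-cell connectivity percentage
#'
#' `100 * degree / (n_cells - 1)`: the percentage of the remaining cells to
#' which each cell is significantly connected.
#'
#' @param sig_mask symmetric logical/0-1 matrix with zero diagonal.
#' @return Numeric vector in `[0, 100]`.
#' @export
cell_connectivity <- function(sig_mask) {
  sig_mask <- as.matrix(sig_mask)
  n <- nrow(sig_mask)
  if (n < 2) stop("need at least 2 cells")
  if (!isTRUE(all.equal(sig_mask * 1, t(sig_mask) * 1)))
    stop("sig_mask must be symmetric")
  if (any(diag(sig_mask) != 0)) stop("sig_mask diagonal must be zero")
  100 * rowSums(sig_mask) / (n - 1)
}

#' Node categories from connectivity percentages
#'
#' Category boundaries are inclusive at the lower edge, matching the
#' Cartesian-map convention: `[80, 100]` black, `[60, 80)` grey, `[40, 60)`
#' white, `[0, 40)` orange.
#'
#' @param connectivity_pct numeric vector in `[0, 100]`.
#' @return Factor with levels `">=80" ">=60" ">=40" "<40"`; see
#'   [category_palette()] for the node colours.
#' @export
categorise_cells <- function(connectivity_pct) {
  if (any(connectivity_pct < 0 | connectivity_pct > 100, na.rm = TRUE))
    stop("connectivity percentages must lie in [0, 100]")
  cut(connectivity_pct, breaks = c(-Inf, 40, 60, 80, Inf), right = FALSE,
      labels = c("<40", ">=40", ">=60", ">=80")) |>
    factor(levels = c(">=80", ">=60", ">=40", "<40"))
}

#' Node colours for connectivity categories
#' @return Named character vector mapping category to map colour.
#' @export
category_palette <- function() {
  c(">=80" = "black", ">=60" = "grey", ">=40" = "white", "<40" = "orange")
}

#' Classify hub cells
#'
#' A cell is a hub iff its connectivity percentage is at least
#' `hub_threshold_pct` (inclusive, default 30); all other cells are
#' followers.
#'
#' @param connectivity_pct numeric vector in `[0, 100]`.
#' @param hub_threshold_pct threshold in `(0, 100]`.
#' @return Logical vector, `TRUE` for hubs.
#' @export
classify_hubs <- function(connectivity_pct, hub_threshold_pct = 30) {
  if (hub_threshold_pct <= 0 || hub_threshold_pct > 100)
    stop("hub_threshold_pct must lie in (0, 100]")
  connectivity_pct >= hub_threshold_pct
}

#' Log-log connectivity distribution and power-law fit
#'
#' Cells with positive connectivity are binned on logarithmically spaced
#' bins; the fitted exponent is the least-squares slope of
#' `log10(proportion / bin width)` on `log10(bin centre)` over non-empty
#' bins (the width normalisation makes the slope estimate the exponent of
#' the underlying frequency law rather than the bin-mass law). With fewer
#' than two non-empty bins the slope is undefined and flagged.
#'
#' @param connectivity_pct numeric vector in `[0, 100]`.
#' @param n_bins number of logarithmic bins (default 8).
#' @return Object of class `degree_distribution`: `bins` (edges), `centres`
#'   (geometric), `proportion`, `density`, `slope`, `fit_r2`, `n_positive`,
#'   `degenerate`.
#' @export
degree_distribution <- function(connectivity_pct, n_bins = 8) {
  pos <- connectivity_pct[connectivity_pct > 0 & !is.na(connectivity_pct)]
  if (length(pos) == 0)
    stop("all cells have zero connectivity; distribution undefined")
  lo <- min(pos); hi <- max(pos)
  if (lo == hi) {
    out <- list(bins = c(lo, hi), centres = lo, proportion = 1,
                density = NA_real_, slope = NA_real_, fit_r2 = NA_real_,
                n_positive = length(pos), degenerate = TRUE)
    return(structure(out, class = "degree_distribution"))
  }
  edges <- 10^seq(log10(lo), log10(hi), length.out = n_bins + 1)
  edges[length(edges)] <- hi * (1 + 1e-9)
  cnt <- as.integer(table(cut(pos, edges, right = FALSE,
                              include.lowest = TRUE)))
  prop <- cnt / length(pos)
  width <- diff(edges)
  centres <- sqrt(edges[-length(edges)] * edges[-1])
  keep <- cnt > 0
  dens <- prop / width
  if (sum(keep) < 2) {
    slope <- NA_real_; r2 <- NA_real_; degen <- TRUE
  } else {
    fit <- stats::lm(log10(dens[keep]) ~ log10(centres[keep]))
    slope <- unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
    degen <- FALSE
  }
  structure(list(bins = edges, centres = centres, proportion = prop,
                 density = dens, slope = slope, fit_r2 = r2,
                 n_positive = length(pos), degenerate = degen),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf(
    "<degree_distribution> %d cells with positive connectivity; slope %s (R2 %s)\n",
    x$n_positive,
    if (is.na(x$slope)) "undefined" else sprintf("%.3f", x$slope),
    if (is.na(x$fit_r2)) "-" else sprintf("%.3f", x$fit_r2)))
  invisible(x)
}

#' Full connectivity analysis of one islet recording
#'
#' Runs the whole pipeline: F/Fmin normalisation, moving-average smoothing,
#' robust binarisation against the pre-stimulus baseline, pairwise Pearson
#' coactivity over the post-stimulus window, circular-shift permutation
#' significance, connectivity percentages, node categories and hub
#' classification.
#'
#' @param rec a [fluorescence_recording()].
#' @param smooth_seconds moving-average window (default 3 s).
#' @param k_mad binarisation threshold height (default 3).
#' @param alpha per-pair significance level (default 0.01).
#' @param hub_threshold_pct hub threshold (default 30).
#' @param method significance null: `"exact"` (all circular shifts; default)
#'   or `"sample"`.
#' @param n_permutations permutations for `method = "sample"`.
#' @param seed seed for `method = "sample"`.
#' @return Object of class `connectivity_result`: `r_matrix`, `sig_mask`,
#'   `connectivity_pct`, `categories`, `hub_flags`, `mean_r`,
#'   `n_permutations`, `alpha`, `seed`, `labels`, `coords`, `islet_id`,
#'   `hub_threshold_pct`.
#' @export
analyse_islet <- function(rec, smooth_seconds = 3, k_mad = 3, alpha = 0.01,
                          hub_threshold_pct = 30,
                          method = c("exact", "sample"),
                          n_permutations = 1000, seed = 1) {
  method <- match.arg(method)
  tr <- normalise_fmin(rec)
  if (smooth_seconds > 0) tr <- smooth_traces(tr, smooth_seconds)
  raster <- binarise(tr, k_mad = k_mad)
  r <- pearson_matrix(raster)
  sig <- permutation_significance(raster, alpha = alpha, seed = seed,
                                  n_permutations = n_permutations,
                                  method = method)
  pct <- cell_connectivity(sig)
  ut <- upper.tri(r)
  structure(
    list(r_matrix = r, sig_mask = sig, connectivity_pct = pct,
         categories = categorise_cells(pct),
         hub_flags = classify_hubs(pct, hub_threshold_pct),
         mean_r = mean(r[ut], na.rm = TRUE),
         n_permutations = if (method == "sample") n_permutations
                          else ncol(raster$active) - rec$stimulus_onset - 1L,
         alpha = alpha, seed = seed, labels = rec$labels,
         coords = rec$coords, islet_id = rec$islet_id,
         hub_threshold_pct = hub_threshold_pct),
    class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  n <- length(x$connectivity_pct)
  cat(sprintf("<connectivity_result '%s'> %d cells; mean r %.3f; %d hubs (>=%g%%)\n",
              x$islet_id, n, x$mean_r, sum(x$hub_flags), x$hub_threshold_pct))
  invisible(x)
}

#' Scalar summaries of a connectivity analysis
#'
#' @param result a `connectivity_result`.
#' @return Named list: `mean_r` (over defined off-diagonal pairs),
#'   `hub_fraction`, `mean_hub_coactivity_pct`,
#'   `mean_follower_coactivity_pct`.
#' @export
summarise_islet <- function(result) {
  hubs <- result$hub_flags
  list(mean_r = result$mean_r,
       hub_fraction = mean(hubs),
       mean_hub_coactivity_pct =
         if (any(hubs)) mean(result$connectivity_pct[hubs]) else NA_real_,
       mean_follower_coactivity_pct =
         if (any(!hubs)) mean(result$connectivity_pct[!hubs]) else NA_real_)
}

#' Export the significant-connection network as GraphML
#'
#' Nodes carry label, connectivity percentage, category, hub flag and (when
#' available) map coordinates; edges carry the Pearson coefficient, for
#' rendering Cartesian coactivity maps.
#'
#' @param result a `connectivity_result`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(result, path) {
  n <- length(result$connectivity_pct)
  g <- igraph::graph_from_adjacency_matrix(result$sig_mask * 1,
                                           mode = "undirected")
  igraph::V(g)$name <- sprintf("cell%03d", seq_len(n) - 1L)
  igraph::V(g)$label <- result$labels
  igraph::V(g)$connectivity_pct <- result$connectivity_pct
  igraph::V(g)$category <- as.character(result$categories)
  igraph::V(g)$hub <- as.integer(result$hub_flags)
  if (!is.null(result$coords)) {
    igraph::V(g)$x <- result$coords[, 1]
    igraph::V(g)$y <- result$coords[, 2]
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0)
    igraph::E(g)$r <- result$r_matrix[el]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write connectivity outputs as delimited text
#'
#' Writes the r matrix and significance mask as square CSVs with cell-id
#' headers, and the per-cell table (connectivity percentage, category, hub
#' flag, label) as TSV.
#'
#' @param result a `connectivity_result`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_connectivity <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(result$connectivity_pct)
  ids <- sprintf("cell%03d", seq_len(n) - 1L)
  rm <- result$r_matrix; dimnames(rm) <- list(ids, ids)
  sm <- result$sig_mask * 1L; dimnames(sm) <- list(ids, ids)
  utils::write.csv(rm, file.path(dir, "r_matrix.csv"))
  utils::write.csv(sm, file.path(dir, "sig_mask.csv"))
  utils::write.table(
    data.frame(cell_id = ids, label = result$labels,
               connectivity_pct = result$connectivity_pct,
               category = as.character(result$categories),
               hub = as.integer(result$hub_flags)),
    file.path(dir, "cells.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}
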