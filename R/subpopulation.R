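#' Hub/follower composition of labelled subpopulations in one islet
#'
#' Counts hubs and followers within the label-positive and label-negative
#' cells of an islet (cells labelled `"unknown"` are excluded). The
#' hub:follower ratio is `NA` (undefined) when a class has hubs but no
#' followers, and 0 when it has no hubs; an islet missing one label class
#' entirely is flagged `incomplete` and later excluded from paired tests.
#'
#' @param result a `connectivity_result` (from [analyse_islet()]).
#' @param labels per-cell labels; defaults to the labels carried by `result`.
#' @return Object of class `islet_hub_comparison` with one row per label in
#'   `$counts` (n_cells, n_hubs, n_followers, hub_follower_ratio, hub_pct).
#' @export
hub_follower_by_label <- function(result, labels = result$labels) {
  if (length(labels) != length(result$hub_flags))
    stop("labels do not align with cells")
  keep <- labels %in% c("pos", "neg")
  lab <- labels[keep]
  hub <- result$hub_flags[keep]
  one <- function(l) {
    n <- sum(lab == l)
    h <- sum(hub[lab == l])
    f <- n - h
    ratio <- if (n == 0) NA_real_
             else if (f == 0 && h == 0) NA_real_
             else if (f == 0) NA_real_
             else h / f
    data.frame(label = l, n_cells = n, n_hubs = h, n_followers = f,
               hub_follower_ratio = ratio,
               hub_pct = if (n > 0) 100 * h / n else NA_real_)
  }
  counts <- rbind(one("pos"), one("neg"))
  structure(list(islet_id = result$islet_id, counts = counts,
                 incomplete = any(counts$n_cells == 0)),
            class = "islet_hub_comparison")
}

#' @export
print.islet_hub_comparison <- function(x, ...) {
  cat(sprintf("<islet_hub_comparison '%s'>%s\n", x$islet_id,
              if (x$incomplete) " [incomplete: a label class is empty]" else ""))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Differences `d = x - y` are formed, zero differences dropped (Wilcoxon's
#' convention), `|d|` ranked with midranks for ties, and
#' `W = min(W+, W-)` reported. For `n_effective <= 25` the two-sided p-value
#' is exact, from the full distribution of the signed-rank sum over all
#' `2^n` sign assignments (computed by convolution over the doubled ranks so
#' midranks stay integral); otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return Object of class `paired_test_result`: `statistic` (W), `p_value`,
#'   `n_effective`, `method` (`"exact"` or `"normal"`), `W_plus`, `W_minus`,
#'   `all_zero` flag.
#' @export
wilcoxon_matched_pairs <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(structure(list(statistic = NA_real_, p_value = 1,
                          n_effective = 0L, method = "exact",
                          W_plus = 0, W_minus = 0, all_zero = TRUE),
                     class = "paired_test_result"))
  r <- rank(abs(d))
  W_plus <- sum(r[d > 0])
  W_minus <- sum(r[d < 0])
  W <- min(W_plus, W_minus)
  S <- n * (n + 1) / 2
  if (n <= 25) {
    w2 <- as.integer(round(2 * r))            # doubled ranks are integers
    f <- c(1, numeric(sum(w2)))               # gf coefficients over 2*W+
    for (w in w2) {
      shifted <- c(numeric(w), f[seq_len(length(f) - w)])
      f <- f + shifted
    }
    p_all <- f / 2^n
    twoW <- as.integer(round(2 * W))
    twoS <- as.integer(round(2 * S))
    p <- sum(p_all[seq_len(twoW + 1L)]) +
      sum(p_all[(twoS - twoW + 1L):(twoS + 1L)])
    p <- min(1, p)
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- S / 2
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(W_plus - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal"
  }
  structure(list(statistic = W, p_value = p, n_effective = n,
                 method = method, W_plus = W_plus, W_minus = W_minus,
                 all_zero = FALSE),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "<paired_test_result> W = %s, p = %.4g (%s, n_effective = %d)\n",
    format(x$statistic), x$p_value, x$method, x$n_effective))
  invisible(x)
}

#' Paired cohort comparison of hub:follower composition between labels
#'
#' Builds the per-islet table of the chosen metric for label-positive and
#' label-negative cells and applies the Wilcoxon matched-pairs signed-rank
#' test across islets (the islet, never the cell, is the paired unit).
#' Islets flagged incomplete, or with an undefined ratio in either class,
#' are excluded from the test (undefined ratios are treated as missing, not
#' coerced to 0) and reported.
#'
#' @param comparisons list of `islet_hub_comparison` objects (or of
#'   `connectivity_result`s, which are converted with their own labels).
#' @param metric `"hub_follower_ratio"` (default) or `"hub_pct"`.
#' @return List: `per_islet` data frame, `test` (a `paired_test_result`),
#'   `metric`, `excluded` (islet ids).
#' @export
cohort_hub_comparison <- function(comparisons,
                                  metric = c("hub_follower_ratio",
                                             "hub_pct")) {
  metric <- match.arg(metric)
  comparisons <- lapply(comparisons, function(x)
    if (inherits(x, "connectivity_result")) hub_follower_by_label(x) else x)
  rows <- lapply(comparisons, function(cmp) {
    v <- cmp$counts[[metric]]
    data.frame(islet_id = cmp$islet_id,
               pos = v[cmp$counts$label == "pos"],
               neg = v[cmp$counts$label == "neg"],
               incomplete = cmp$incomplete)
  })
  d <- do.call(rbind, rows)
  usable <- !d$incomplete & !is.na(d$pos) & !is.na(d$neg)
  excluded <- d$islet_id[!usable]
  if (sum(usable) < 2)
    stop("fewer than 2 islets with both labels defined; paired test needs >= 2")
  test <- wilcoxon_matched_pairs(d$pos[usable], d$neg[usable])
  list(per_islet = d, test = test, metric = metric,
       excluded = as.character(excluded))
}

#' Paired comparison of glucose-response AUC between labels across a cohort
#'
#' Per islet, the mean response AUC (trapezoidal integral of `F/Fmin - 1`
#' over the post-stimulus window) is computed for label-positive and
#' label-negative cells; islets missing a label are excluded and reported.
#' A Wilcoxon matched-pairs signed-rank test is applied across islets.
#'
#' @param recordings list of [fluorescence_recording()]s (elements may also
#'   be `simulate_islet` results, whose `$recording` is used).
#' @param window 0-based half-open frame window for the AUC; default
#'   `[stimulus_onset, n_frames - 1)` per recording.
#' @param smooth_seconds moving-average window before integration
#'   (default 3 s; 0 for none).
#' @return List: `per_islet` data frame (islet_id, mean_auc_pos,
#'   mean_auc_neg), `test`, `excluded`.
#' @export
compare_auc_by_label <- function(recordings, window = NULL,
                                 smooth_seconds = 3) {
  recordings <- lapply(recordings, function(x)
    if (!inherits(x, "fluorescence_recording") && !is.null(x$recording))
      x$recording else x)
  rows <- lapply(recordings, function(rec) {
    tr <- normalise_fmin(rec)
    if (smooth_seconds > 0) tr <- smooth_traces(tr, smooth_seconds)
    auc <- response_auc(tr, window)
    data.frame(islet_id = rec$islet_id,
               mean_auc_pos = if (any(rec$labels == "pos"))
                 mean(auc[rec$labels == "pos"]) else NA_real_,
               mean_auc_neg = if (any(rec$labels == "neg"))
                 mean(auc[rec$labels == "neg"]) else NA_real_)
  })
  d <- do.call(rbind, rows)
  usable <- !is.na(d$mean_auc_pos) & !is.na(d$mean_auc_neg)
  if (sum(usable) < 2)
    stop("fewer than 2 islets with both labels present; paired test needs >= 2")
  test <- wilcoxon_matched_pairs(d$mean_auc_pos[usable],
                                 d$mean_auc_neg[usable])
  list(per_islet = d, test = test,
       excluded = as.character(d$islet_id[!usable]))
}
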