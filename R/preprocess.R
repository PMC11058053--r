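#' Normalise traces to each cell's minimum (F/Fmin)
#'
#' Divides every cell's trace by that cell's minimum, so the per-cell minimum
#' of the output is exactly 1. By default the minimum is taken over the whole
#' recording (the usual reading of an F/Fmin axis); `baseline = "prestim"`
#' instead uses the mean over the pre-stimulus window.
#'
#' @param rec a [fluorescence_recording()].
#' @param baseline `"global"` (per-cell minimum over all frames) or
#'   `"prestim"` (per-cell mean over `[0, stimulus_onset)`).
#' @return An object of class `normalised_traces`: `values` (cells x frames,
#'   dimensionless), `frame_interval`, `stimulus_onset`, `labels`,
#'   `provenance` (normalisation and any smoothing applied).
#' @export
normalise_fmin <- function(rec, baseline = c("global", "prestim")) {
  baseline <- match.arg(baseline)
  v <- if (inherits(rec, "normalised_traces")) rec$values else rec$values
  ref <- switch(baseline,
    global = apply(v, 1, min),
    prestim = {
      if (rec$stimulus_onset < 1)
        stop("prestim baseline needs a non-empty pre-stimulus window")
      rowMeans(v[, seq_len(rec$stimulus_onset), drop = FALSE])
    })
  if (any(ref <= 0)) stop("per-cell reference must be positive")
  structure(
    list(values = v / ref, frame_interval = rec$frame_interval,
         stimulus_onset = rec$stimulus_onset, labels = rec$labels,
         islet_id = rec$islet_id,
         provenance = list(normalisation = baseline, smoothing = NULL)),
    class = "normalised_traces")
}

#' @export
print.normalised_traces <- function(x, ...) {
  sm <- x$provenance$smoothing
  cat(sprintf("<normalised_traces> %d cells x %d frames; smoothing: %s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(sm)) "none" else sprintf("%g s moving average", sm)))
  invisible(x)
}

#' Smooth traces with a centred moving average
#'
#' The window is `round(window_seconds / frame_interval)` frames, forced odd;
#' edges use shrinking windows (no padding values are invented), so a
#' one-frame window is the identity and constant traces are unchanged.
#'
#' @param traces a `normalised_traces` object.
#' @param window_seconds window length in seconds (>= one frame interval).
#' @return `traces` with smoothed values and updated provenance.
#' @export
smooth_traces <- function(traces, window_seconds = 3) {
  if (window_seconds <= 0) stop("window_seconds must be positive")
  if (window_seconds < traces$frame_interval)
    stop("window_seconds must be at least one frame interval")
  w <- round(window_seconds / traces$frame_interval)
  if (w %% 2 == 0) w <- w + 1L
  traces$values <- moving_average(traces$values, w)
  traces$provenance$smoothing <- window_seconds
  traces
}

# centred moving average over matrix rows, shrinking windows at the edges
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- ncol(x)
  cs <- cbind(0, t(apply(x, 1, cumsum)))
  half <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  out <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(x))
  dimnames(out) <- dimnames(x)
  out
}

#' Binarise smoothed traces against a robust baseline threshold
#'
#' Per cell, the threshold is `median(baseline) + k_mad * MAD(baseline)` with
#' the MAD scaled to estimate an s.d. (constant 1.4826); a frame is active iff
#' the trace strictly exceeds the threshold. Cells whose baseline MAD is zero
#' borrow the islet median of the positive MADs, so constant traces stay
#' inactive. Because the median and MAD are equivariant under positive affine
#' maps, uniformly rescaling or shifting a cell's trace leaves the raster
#' unchanged.
#'
#' @param traces a `normalised_traces` object (smooth first; binarisation is
#'   applied to the values as given).
#' @param k_mad threshold height in robust s.d. units (default 3).
#' @param baseline_frames half-open 0-based frame window `c(start, end)` used
#'   as baseline; defaults to `[0, stimulus_onset)`.
#' @return An object of class `binary_raster`: `active` (cells x frames 0/1
#'   matrix), `threshold_params`, `frame_interval`, `stimulus_onset`,
#'   `labels`.
#' @export
binarise <- function(traces, k_mad = 3, baseline_frames = NULL) {
  if (k_mad <= 0) stop("k_mad must be positive")
  if (is.null(baseline_frames))
    baseline_frames <- c(0L, traces$stimulus_onset)
  idx <- window_index(baseline_frames, ncol(traces$values))
  if (length(idx) < 1) stop("baseline window is empty")
  base <- traces$values[, idx, drop = FALSE]
  med <- apply(base, 1, stats::median)
  madv <- apply(base, 1, stats::mad)
  if (all(madv == 0)) {
    fallback <- 0
  } else {
    fallback <- stats::median(madv[madv > 0])
  }
  madv[madv == 0] <- fallback
  thr <- med + k_mad * madv
  structure(
    list(active = (traces$values > thr) * 1L,
         threshold_params = list(k_mad = k_mad,
                                 baseline_frames = baseline_frames,
                                 thresholds = thr),
         frame_interval = traces$frame_interval,
         stimulus_onset = traces$stimulus_onset,
         labels = traces$labels, islet_id = traces$islet_id),
    class = "binary_raster")
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf("<binary_raster> %d cells x %d frames; active fraction %.3f\n",
              nrow(x$active), ncol(x$active), mean(x$active)))
  invisible(x)
}

#' Glucose-response area under the curve
#'
#' Trapezoidal integral of `(F/Fmin - 1)` over a half-open window `[a, b)`,
#' in units of seconds. Each frame pair `(i, i+1)` with `a <= i < b`
#' contributes one trapezoid, so the closing frame `b` is used as the right
#' edge and the integral is additive over adjacent half-open windows:
#' `auc([a,b)) + auc([b,c)) == auc([a,c))`. Requires `b <= n_frames - 1`.
#' Negative values are possible when the smoothed trace dips below 1.
#'
#' @param traces a `normalised_traces` object.
#' @param window 0-based half-open frame window `c(start, end)`; defaults to
#'   `[stimulus_onset, n_frames - 1)`.
#' @return Numeric vector of per-cell areas (dimensionless x seconds).
#' @export
response_auc <- function(traces, window = NULL) {
  n <- ncol(traces$values)
  if (is.null(window)) window <- c(traces$stimulus_onset, n - 1L)
  a <- window[1]; b <- window[2]
  if (b <= a) stop("response window is empty")
  if (a < 0 || b > n - 1L)
    stop("window must satisfy 0 <= start < end <= n_frames - 1")
  v <- traces$values - 1
  cols <- (a + 1L):(b + 1L)   # frames a..b, 1-based
  seg <- (v[, cols[-length(cols)], drop = FALSE] +
            v[, cols[-1], drop = FALSE]) / 2
  unname(rowSums(seg)) * traces$frame_interval
}

# half-open 0-based window -> 1-based column indices
window_index <- function(window, n) {
  a <- window[1]; b <- window[2]
  if (a < 0 || b > n || b <= a) stop("invalid frame window [", a, ", ", b, ")")
  (a + 1L):b
}
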