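#' Islet fluorescence recording
#'
#' Container for one imaged islet: a cells x frames matrix of raw Cal-590/
#' Cal-520 style fluorescence values (arbitrary units), per-cell subpopulation
#' labels, optional cell centroid coordinates and the stimulation onset.
#'
#' Frame indices throughout the package are 0-based and windows are half-open
#' `[start, end)`, matching the `f0, f1, ...` column naming of the trace CSV
#' dialect. `stimulus_onset` is the first frame of the glucose step, so
#' `[0, stimulus_onset)` is the baseline window and
#' `[stimulus_onset, n_frames)` the response window.
#'
#' @param values numeric matrix, cells x frames; all entries finite and > 0.
#' @param frame_interval frame spacing in seconds (> 0).
#' @param labels per-cell labels, one of `"pos"`, `"neg"`, `"unknown"`.
#'   Defaults to all `"unknown"`.
#' @param stimulus_onset 0-based frame index at which stimulation begins.
#' @param islet_id character identifier.
#' @param coords optional cells x 2 matrix of (x, y) centroids in micrometres;
#'   `NA` rows allowed.
#'
#' @return An object of class `fluorescence_recording`.
#' @export
fluorescence_recording <- function(values, frame_interval, labels = NULL,
                                   stimulus_onset = 0L, islet_id = "islet",
                                   coords = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("fluorescence values must be finite numbers")
  bad <- which(values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive fluorescence at cell %d, frame %d",
                 bad[1, 1], bad[1, 2] - 1L))
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      frame_interval <= 0)
    stop("frame_interval must be a single positive number of seconds")
  n_cells <- nrow(values)
  if (is.null(labels)) labels <- rep("unknown", n_cells)
  if (length(labels) != n_cells)
    stop(sprintf("labels length (%d) does not match cell count (%d)",
                 length(labels), n_cells))
  if (!all(labels %in% c("pos", "neg", "unknown")))
    stop("labels must be 'pos', 'neg' or 'unknown'")
  stimulus_onset <- as.integer(stimulus_onset)
  if (stimulus_onset < 0 || stimulus_onset >= ncol(values))
    stop("stimulus_onset must be a frame index within the recording")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n_cells || ncol(coords) != 2)
      stop("coords must be a cells x 2 matrix")
  }
  structure(
    list(values = values, frame_interval = frame_interval,
         labels = labels, stimulus_onset = stimulus_onset,
         islet_id = islet_id, coords = coords),
    class = "fluorescence_recording")
}

#' @export
print.fluorescence_recording <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_recording '%s'> %d cells x %d frames (%.3g s/frame)\n",
    x$islet_id, nrow(x$values), ncol(x$values), x$frame_interval))
  cat(sprintf("  stimulus onset: frame %d (%.1f s); labels: %s\n",
              x$stimulus_onset, x$stimulus_onset * x$frame_interval,
              paste(sprintf("%s=%d", names(table(x$labels)),
                            table(x$labels)), collapse = " ")))
  invisible(x)
}

#' Number of cells / frames in a recording
#' @param rec a `fluorescence_recording`.
#' @return integer count.
#' @export
n_cells <- function(rec) nrow(rec$values)

#' @rdname n_cells
#' @export
n_frames <- function(rec) ncol(rec$values)

#' Read an islet trace CSV (plus its JSON metadata sidecar)
#'
#' The trace dialect is one row per cell with header
#' `cell_id,label,x,y,f0,f1,...,fN`; fluorescence values must be positive
#' numbers, `x`/`y` may be empty. The sidecar (default: same path with a
#' `.json` extension) carries `islet_id`, `frame_interval_s` and
#' `stimulus_onset_frame`.
#'
#' @param path CSV file path.
#' @param meta_path JSON sidecar path; defaults to `path` with `.json`
#'   substituted for its extension.
#' @return A [fluorescence_recording()] with cell order as in the file.
#' @export
read_traces <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.[^.]*$", ".json", path)
  if (!file.exists(path)) stop("trace file not found: ", path)
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("islet_id", "frame_interval_s", "stimulus_onset_frame"))
    if (is.null(meta[[f]])) stop("metadata sidecar missing field: ", f)
  d <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("cell_id", "label", "x", "y")
  if (!all(need %in% names(d)[1:4]))
    stop("trace header must start with: ", paste(need, collapse = ","))
  fcols <- grep("^f[0-9]+$", names(d), value = TRUE)
  if (length(fcols) == 0) stop("no fluorescence columns (f0...) found")
  if (!identical(fcols, paste0("f", seq_along(fcols) - 1L)))
    stop("fluorescence columns must be consecutive f0..fN")
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(d[, fcols])), nrow = nrow(d)))
  nn <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(nn) > 0)
    stop(sprintf("non-numeric fluorescence for cell '%s', frame %d",
                 d$cell_id[nn[1, 1]], nn[1, 2] - 1L))
  neg <- which(vals <= 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("non-positive fluorescence for cell '%s', frame %d",
                 d$cell_id[neg[1, 1]], neg[1, 2] - 1L))
  coords <- cbind(suppressWarnings(as.numeric(d$x)),
                  suppressWarnings(as.numeric(d$y)))
  if (all(is.na(coords))) coords <- NULL
  rec <- fluorescence_recording(
    vals, frame_interval = meta$frame_interval_s, labels = d$label,
    stimulus_onset = meta$stimulus_onset_frame, islet_id = meta$islet_id,
    coords = coords)
  rec$cell_ids <- d$cell_id
  rec
}

#' Write an islet recording as trace CSV + JSON sidecar
#'
#' Inverse of [read_traces()]; values are written with 15 significant digits
#' so a read/write round trip preserves them to at least 12.
#'
#' @param rec a `fluorescence_recording`.
#' @param path output CSV path; the sidecar goes to the same path with a
#'   `.json` extension unless `meta_path` is given.
#' @param meta_path optional sidecar path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(rec, path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.[^.]*$", ".json", path)
  ids <- rec$cell_ids
  if (is.null(ids)) ids <- sprintf("cell%03d", seq_len(n_cells(rec)) - 1L)
  co <- rec$coords
  if (is.null(co)) co <- matrix(NA_real_, n_cells(rec), 2)
  vals <- format(rec$values, digits = 15, trim = TRUE, scientific = FALSE)
  d <- data.frame(cell_id = ids, label = rec$labels,
                  x = ifelse(is.na(co[, 1]), "", format(co[, 1])),
                  y = ifelse(is.na(co[, 2]), "", format(co[, 2])),
                  matrix(vals, nrow = n_cells(rec)),
                  check.names = FALSE, stringsAsFactors = FALSE)
  names(d)[-(1:4)] <- paste0("f", seq_len(n_frames(rec)) - 1L)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(islet_id = rec$islet_id, frame_interval_s = rec$frame_interval,
         stimulus_onset_frame = rec$stimulus_onset),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
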