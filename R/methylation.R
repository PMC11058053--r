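#' Bisulphite clone methylation matrix
#'
#' Clones x CpG sites call matrix with states `"M"` (methylated), `"U"`
#' (unmethylated) and `"."` (missing), plus strictly increasing 1-based
#' genomic positions -- the per-molecule representation behind lollipop
#' plots of amplicon bisulphite sequencing.
#'
#' @param calls character matrix (clones x sites) of `"M"`, `"U"`, `"."`.
#' @param cpg_positions strictly increasing integer positions, one per site.
#' @param region_id,sample_id identifiers (e.g. amplicon name and sorted
#'   population).
#' @return Object of class `clone_methylation`.
#' @export
clone_methylation <- function(calls, cpg_positions, region_id = "region",
                              sample_id = "sample") {
  calls <- as.matrix(calls)
  if (nrow(calls) < 1) stop("need at least one clone")
  if (ncol(calls) != length(cpg_positions))
    stop("number of call columns must match number of CpG positions")
  bad <- which(matrix(!(calls %in% c("M", "U", ".")), nrow(calls)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("unknown call state '%s' at clone %d, site %d",
                 calls[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]))
  if (any(diff(cpg_positions) <= 0))
    stop("cpg_positions must be strictly increasing")
  structure(list(calls = calls, cpg_positions = as.integer(cpg_positions),
                 region_id = region_id, sample_id = sample_id),
            class = "clone_methylation")
}

#' @export
print.clone_methylation <- function(x, ...) {
  cat(sprintf("<clone_methylation '%s'/'%s'> %d clones x %d CpGs (%d-%d)\n",
              x$region_id, x$sample_id, nrow(x$calls), ncol(x$calls),
              min(x$cpg_positions), max(x$cpg_positions)))
  invisible(x)
}

#' Read a clone-call TSV
#'
#' Dialect: header `clone_id` followed by one column per CpG named by its
#' genomic position; cell values `M`, `U` or `.`. An optional JSON sidecar
#' supplies `region_id` and `sample_id`.
#'
#' @param path TSV file path.
#' @param meta_path optional JSON sidecar path; defaults to `path` with a
#'   `.json` extension, used only if the file exists.
#' @return A [clone_methylation()] with clone order preserved.
#' @export
read_clone_calls <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.[^.]*$", ".json", path)
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = "character")
  if (names(d)[1] != "clone_id")
    stop("first column must be 'clone_id'")
  pos <- suppressWarnings(as.integer(names(d)[-1]))
  if (any(is.na(pos)))
    stop("CpG columns must be named by integer genomic position")
  region_id <- "region"; sample_id <- "sample"
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$region_id)) region_id <- meta$region_id
    if (!is.null(meta$sample_id)) sample_id <- meta$sample_id
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$clone_id
  bad <- which(matrix(!(m %in% c("M", "U", ".")), nrow(m)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("unknown call state '%s' for clone '%s' at position %d",
                 m[bad[1, 1], bad[1, 2]], d$clone_id[bad[1, 1]],
                 pos[bad[1, 2]]))
  clone_methylation(m, pos, region_id = region_id, sample_id = sample_id)
}

#' Write a clone-call TSV (inverse of [read_clone_calls()])
#' @param mat a `clone_methylation`.
#' @param path output TSV path.
#' @param meta_path optional JSON sidecar path (region and sample ids);
#'   defaults to `path` with `.json` extension.
#' @return `path`, invisibly.
#' @export
write_clone_calls <- function(mat, path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.[^.]*$", ".json", path)
  ids <- rownames(mat$calls)
  if (is.null(ids)) ids <- sprintf("clone%02d", seq_len(nrow(mat$calls)))
  d <- data.frame(clone_id = ids, mat$calls, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[-1] <- mat$cpg_positions
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(region_id = mat$region_id,
                            sample_id = mat$sample_id),
                       meta_path, auto_unbox = TRUE)
  invisible(path)
}

#' Percent methylation per CpG and for the region
#'
#' Per site: `methylated / (methylated + unmethylated) * 100`, missing calls
#' excluded; sites with no informative call are `NA` and flagged. The region
#' percentage pools all informative calls across sites (not the mean of site
#' percentages), so it is robust to unequal missingness; `region_mean_of_sites`
#' is also reported for comparison.
#'
#' @param mat a `clone_methylation`.
#' @return Object of class `methylation_summary`: `per_cpg_pct`,
#'   `n_informative` (per site), `region_pct`, `region_mean_of_sites`,
#'   `n_clones`, `cpg_positions`, `undefined_sites`.
#' @export
percent_methylation <- function(mat) {
  meth <- colSums(mat$calls == "M")
  unmeth <- colSums(mat$calls == "U")
  info <- meth + unmeth
  if (sum(info) == 0) stop("no informative calls in the matrix")
  pct <- ifelse(info > 0, 100 * meth / info, NA_real_)
  structure(
    list(per_cpg_pct = pct, n_informative = info,
         region_pct = 100 * sum(meth) / sum(info),
         region_mean_of_sites = mean(pct, na.rm = TRUE),
         n_clones = nrow(mat$calls), cpg_positions = mat$cpg_positions,
         undefined_sites = which(info == 0),
         region_id = mat$region_id, sample_id = mat$sample_id),
    class = "methylation_summary")
}

#' @export
print.methylation_summary <- function(x, ...) {
  cat(sprintf(
    "<methylation_summary '%s'/'%s'> %d clones, %d CpGs; region %.1f%% methylated\n",
    x$region_id, x$sample_id, x$n_clones, length(x$per_cpg_pct),
    x$region_pct))
  invisible(x)
}

#' Paired comparison of per-CpG methylation between two populations
#'
#' Paired Student's t test on per-site percentage differences, pairing by
#' CpG site (both summaries must cover identical positions). The t statistic
#' is computed from the textbook closed form; when all differences are equal
#' the variance is zero and the result is flagged instead of reporting an
#' infinite statistic (p is 1 when the common difference is zero).
#'
#' @param a,b `methylation_summary` objects over the same CpG positions.
#' @return List: `t`, `p_value`, `df`, `n_sites` (jointly defined sites),
#'   `mean_difference` (a - b, percentage points), `region_difference`,
#'   `zero_variance` flag.
#' @export
compare_methylation <- function(a, b) {
  if (!identical(a$cpg_positions, b$cpg_positions))
    stop("CpG positions differ between the two summaries")
  ok <- !is.na(a$per_cpg_pct) & !is.na(b$per_cpg_pct)
  if (sum(ok) < 2)
    stop("need at least 2 CpG sites with defined values in both populations")
  d <- a$per_cpg_pct[ok] - b$per_cpg_pct[ok]
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = if (m == 0) 0 else NA_real_,
                p_value = if (m == 0) 1 else NA_real_,
                df = n - 1L, n_sites = n, mean_difference = m,
                region_difference = a$region_pct - b$region_pct,
                zero_variance = TRUE))
  }
  tval <- m / (s / sqrt(n))
  list(t = tval, p_value = 2 * stats::pt(-abs(tval), n - 1),
       df = n - 1L, n_sites = n, mean_difference = m,
       region_difference = a$region_pct - b$region_pct,
       zero_variance = FALSE)
}

#' Text lollipop rendering of a clone matrix
#'
#' One row per clone, one glyph per CpG: filled (`*`) methylated, open (`o`)
#' unmethylated, gap (`.`) missing; deterministic layout in position order.
#'
#' @param mat a `clone_methylation`.
#' @param glyphs named character vector mapping `M`, `U`, `.` to glyphs.
#' @return Character vector, one string per clone, with the position header
#'   as attribute `header`.
#' @export
lollipop_text <- function(mat, glyphs = c(M = "*", U = "o", "." = ".")) {
  if (ncol(mat$calls) == 0) stop("empty region: no CpG sites")
  g <- matrix(glyphs[mat$calls], nrow(mat$calls))
  out <- apply(g, 1, paste, collapse = " ")
  ids <- rownames(mat$calls)
  if (!is.null(ids)) names(out) <- ids
  attr(out, "header") <- paste(mat$cpg_positions, collapse = " ")
  out
}

#' Lollipop plot of a clone matrix
#'
#' Base-graphics rendering of the classic bisulphite diagram: clones as
#' rows, CpGs at their genomic positions, closed circles methylated, open
#' circles unmethylated, gaps missing.
#'
#' @param mat a `clone_methylation`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_lollipop <- function(mat, ...) {
  if (ncol(mat$calls) == 0) stop("empty region: no CpG sites")
  nc <- nrow(mat$calls); ns <- ncol(mat$calls)
  pos <- mat$cpg_positions
  graphics::plot(range(pos), c(0.5, nc + 0.5), type = "n", yaxt = "n",
                 xlab = "genomic position", ylab = "clone",
                 main = sprintf("%s / %s", mat$region_id, mat$sample_id),
                 ...)
  graphics::axis(2, at = seq_len(nc), labels = rev(seq_len(nc)), las = 1)
  for (i in seq_len(nc)) {
    y <- nc - i + 1
    graphics::segments(min(pos), y, max(pos), y, col = "grey80")
    filled <- mat$calls[i, ] == "M"
    open <- mat$calls[i, ] == "U"
    graphics::points(pos[filled], rep(y, sum(filled)), pch = 19)
    graphics::points(pos[open], rep(y, sum(open)), pch = 21, bg = "white")
  }
  invisible(NULL)
}
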