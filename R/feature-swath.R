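#' Build an equal-width m/z window grid
#'
#' The m/z axis is divided into contiguous equal-width windows. Each window
#' is half-open `[lo, hi)` except the last, which is closed at `mz_max` so
#' the windows tile `[mz_min, mz_max]` exactly. A size spec of the form
#' `"NxN"` (also accepted: `"N x N"`, `"N×N"`) yields `N^2` windows: the
#' square notation is a display convention for heat maps, but the feature
#' vector handed to the classifier is always the flat 1-D sequence of bins.
#' An integer spec yields exactly that many windows.
#'
#' @param mz_min,mz_max Range of the grid in Thomson; `mz_min < mz_max`.
#' @param size_spec Either an integer window count or a string like
#'   `"32x32"`.
#' @return A `WindowGrid` with fields `mz_min`, `mz_max`, `n_windows`,
#'   `window_width` and `breaks` (length `n_windows + 1`).
#' @examples
#' build_window_grid(400, 1400, "32x32")$n_windows  # 1024
#' @export
build_window_grid <- function(mz_min, mz_max, size_spec) {
  if (!is.numeric(mz_min) || !is.numeric(mz_max) || mz_min >= mz_max)
    stop("need mz_min < mz_max")
  n <- parse_window_spec(size_spec)
  breaks <- seq(mz_min, mz_max, length.out = n + 1L)
  structure(
    list(mz_min = as.numeric(mz_min), mz_max = as.numeric(mz_max),
         n_windows = n, window_width = (mz_max - mz_min) / n,
         breaks = breaks, size_spec = as.character(size_spec)),
    class = "WindowGrid"
  )
}

#' Parse a window-size spec into a window count
#'
#' @param size_spec Integer count or `"NxN"` string (N^2 windows).
#' @return Integer number of windows.
#' @export
parse_window_spec <- function(size_spec) {
  if (is.numeric(size_spec)) {
    n <- as.integer(size_spec)
    if (is.na(n) || n < 1L) stop("window count must be a positive integer")
    return(n)
  }
  s <- gsub("\\s", "", as.character(size_spec))
  if (grepl("^[0-9]+[xX×][0-9]+$", s)) {
    parts <- as.integer(strsplit(s, "[xX×]")[[1]])
    if (parts[1] != parts[2])
      stop("window spec must be square, e.g. '32x32'; got '", size_spec, "'")
    if (parts[1] < 1L) stop("window count must be positive")
    return(parts[1]^2L)
  }
  if (grepl("^[0-9]+$", s)) return(parse_window_spec(as.numeric(s)))
  stop("cannot parse window spec '", size_spec,
       "'; use an integer or 'NxN'")
}

#' @export
print.WindowGrid <- function(x, ...) {
  cat(sprintf("WindowGrid: %d windows of %.4f Th over [%.2f, %.2f]\n",
              x$n_windows, x$window_width, x$mz_min, x$mz_max))
  invisible(x)
}

#' Infer a shared m/z range from a set of runs
#'
#' Training and test runs must share one feature space, so a single grid
#' range is inferred across the whole pool: the floor of the global minimum
#' m/z and the ceiling of the global maximum. A degenerate range (single
#' m/z value) is widened by 1 Th.
#'
#' @param runs List of `SpectraRun`.
#' @return Numeric `c(mz_min, mz_max)`.
#' @export
infer_mz_range <- function(runs) {
  if (inherits(runs, "SpectraRun")) runs <- list(runs)
  mzs <- unlist(lapply(runs, function(r)
    lapply(r$scans, function(s) s$peaks[, 1L])), use.names = FALSE)
  if (length(mzs) == 0L) stop("cannot infer m/z range: all scans are empty")
  lo <- floor(min(mzs)); hi <- ceiling(max(mzs))
  if (hi <= lo) hi <- lo + 1
  c(lo, hi)
}

new_intensity_matrix <- function(values, row_ids, grid, normalized,
                                 n_dropped = 0L) {
  colnames(values) <- paste0("w", seq_len(ncol(values)))
  structure(list(values = values, row_ids = row_ids, grid = grid,
                 normalized = isTRUE(normalized), n_dropped = n_dropped),
            class = "IntensityMatrix")
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  cat(sprintf("IntensityMatrix: %d scans x %d windows (%s)%s\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw summed intensities",
              if (x$n_dropped > 0)
                sprintf(", %d out-of-range peaks dropped", x$n_dropped)
              else ""))
  invisible(x)
}

#' @export
dim.IntensityMatrix <- function(x) dim(x$values)

#' Feature swath extraction: bin one run into an intensity matrix
#'
#' For every scan, the intensities of all peaks falling inside the same m/z
#' window are summed, giving one fixed-length feature row per scan
#' (including empty scans, which become all-zero rows). Peaks outside the
#' grid range are dropped; the dropped count is kept on the matrix and
#' reported via a message.
#'
#' @param run A `SpectraRun`.
#' @param grid A `WindowGrid` shared across all runs of the experiment.
#' @return An unnormalized `IntensityMatrix` with one row per scan.
#' @export
extract_feature_swath <- function(run, grid) {
  stopifnot(inherits(run, "SpectraRun"), inherits(grid, "WindowGrid"))
  ns <- length(run$scans)
  if (ns == 0L) stop("run '", run$run_id, "' has no scans")
  nw <- grid$n_windows
  vals <- matrix(0, nrow = ns, ncol = nw)
  counts <- vapply(run$scans, function(s) nrow(s$peaks), integer(1))
  scan_of <- rep.int(seq_len(ns), counts)
  mz <- unlist(lapply(run$scans, function(s) s$peaks[, 1L]), use.names = FALSE)
  intens <- unlist(lapply(run$scans, function(s) s$peaks[, 2L]), use.names = FALSE)
  n_dropped <- 0L
  if (length(mz) > 0L) {
    # half-open [lo, hi) bins, last bin closed at mz_max
    bin <- findInterval(mz, grid$breaks, rightmost.closed = TRUE)
    inrange <- bin >= 1L & bin <= nw
    n_dropped <- sum(!inrange)
    if (any(inrange)) {
      cell <- (scan_of[inrange] - 1L) * nw + bin[inrange]
      acc <- rowsum(intens[inrange], group = cell)
      tv <- t(vals)  # cell index is column-major in the transposed layout
      tv[as.integer(rownames(acc))] <- acc[, 1L]
      vals <- t(tv)
    }
  }
  if (n_dropped > 0L)
    message(n_dropped, " peak(s) outside [", grid$mz_min, ", ", grid$mz_max,
            "] dropped for run ", run$run_id)
  new_intensity_matrix(
    vals,
    row_ids = data.frame(
      run_id = rep(run$run_id, ns),
      scan_index = vapply(run$scans, function(s) s$scan_index, integer(1))),
    grid = grid, normalized = FALSE, n_dropped = n_dropped)
}

#' Normalize each scan row by its own maximum
#'
#' Each row of the intensity matrix is divided by that row's maximum summed
#' intensity, so every nonzero row has maximum exactly 1. This cancels
#' per-scan and per-run intensity-scale differences. All-zero rows (empty
#' scans) are left as zero; double normalization is refused.
#'
#' @param matrix An unnormalized `IntensityMatrix`.
#' @return The normalized `IntensityMatrix`.
#' @export
normalize_rows <- function(matrix) {
  stopifnot(inherits(matrix, "IntensityMatrix"))
  if (matrix$normalized) stop("matrix is already normalized")
  rmax <- apply(matrix$values, 1L, max)
  div <- ifelse(rmax > 0, rmax, 1)
  out <- matrix$values / div
  new_intensity_matrix(out, matrix$row_ids, matrix$grid, normalized = TRUE,
                       n_dropped = matrix$n_dropped)
}

#' Label vector for a run's matrix rows
#'
#' Every scan of a run inherits the run's sample label, so the label vector
#' is simply the label repeated once per matrix row.
#'
#' @param run A `SpectraRun` with a non-`NA` `sample_label`.
#' @param n_rows Expected row count; must equal the run's scan count.
#' @return Integer vector of length `n_rows`.
#' @export
make_label_vector <- function(run, n_rows = n_scans(run)) {
  if (is.na(run$sample_label))
    stop("run '", run$run_id, "' has no sample label")
  if (n_rows != n_scans(run))
    stop("n_rows (", n_rows, ") does not match the run's scan count (",
         n_scans(run), ")")
  rep(run$sample_label, n_rows)
}

#' Extract, normalize and stack several runs on one shared grid
#'
#' Convenience wrapper used by the cross-prediction driver: each run is
#' binned on the shared grid, row-normalized, and the rows stacked with the
#' matching label vector.
#'
#' @param runs List of labelled `SpectraRun`.
#' @param grid Shared `WindowGrid`.
#' @return List with `features` (normalized `IntensityMatrix`) and `labels`
#'   (integer vector, one per row).
#' @export
pool_features <- function(runs, grid) {
  mats <- lapply(runs, function(r) normalize_rows(extract_feature_swath(r, grid)))
  labels <- unlist(lapply(runs, make_label_vector), use.names = FALSE)
  values <- do.call(rbind, lapply(mats, `[[`, "values"))
  row_ids <- do.call(rbind, lapply(mats, `[[`, "row_ids"))
  list(features = new_intensity_matrix(values, row_ids, grid, TRUE),
       labels = labels)
}
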