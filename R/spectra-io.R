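#' Construct a spectra run
#'
#' A `SpectraRun` bundles one raw file's scans (of a single MS level) with an
#' integer sample label. Scans are ordered by acquisition; each scan holds a
#' two-column peak matrix (`mz`, `intensity`) sorted by ascending m/z.
#'
#' @param run_id Character scalar identifying the run (usually the source
#'   filename stem).
#' @param scans List of scans. Each scan is a list with fields `scan_index`
#'   (1-based ordinal within the source file), `ms_level` (1 or 2),
#'   `retention_time` (seconds) and `peaks` (numeric matrix with columns
#'   `mz`, `intensity`; zero rows allowed).
#' @param sample_label Integer class code for the whole run (e.g. 0 = benign,
#'   1 = tumor). `NA` when unknown.
#' @param ms_level MS level of all scans, or `NA` if mixed (pre-filtering).
#' @return An object of class `SpectraRun`.
#' @export
spectra_run <- function(run_id, scans, sample_label = NA_integer_,
                        ms_level = NA_integer_) {
  stopifnot(is.character(run_id), length(run_id) == 1L, is.list(scans))
  idx <- vapply(scans, function(s) as.integer(s$scan_index), integer(1))
  if (length(idx) > 1L && any(diff(idx) <= 0L))
    stop("scan_index values must be strictly increasing within a run")
  for (s in scans) {
    pk <- s$peaks
    if (!is.matrix(pk) || ncol(pk) != 2L)
      stop("each scan's peaks must be a two-column (mz, intensity) matrix")
    if (nrow(pk) > 0L) {
      if (any(pk[, 1L] <= 0)) stop("peak m/z values must be positive")
      if (any(pk[, 2L] < 0)) stop("peak intensities must be non-negative")
      if (is.unsorted(pk[, 1L])) stop("peaks must be sorted ascending by m/z")
    }
  }
  structure(
    list(run_id = run_id, scans = scans,
         sample_label = as.integer(sample_label),
         ms_level = as.integer(ms_level)),
    class = "SpectraRun"
  )
}

#' @export
print.SpectraRun <- function(x, ...) {
  np <- sum(vapply(x$scans, function(s) nrow(s$peaks), integer(1)))
  cat(sprintf("SpectraRun '%s': %d scans (MS level %s), %d peaks, label %s\n",
              x$run_id, length(x$scans),
              ifelse(is.na(x$ms_level), "mixed", x$ms_level), np,
              ifelse(is.na(x$sample_label), "NA", x$sample_label)))
  invisible(x)
}

#' Number of scans in a run
#' @param run A `SpectraRun`.
#' @return Integer scan count.
#' @export
n_scans <- function(run) length(run$scans)

#' Keep only scans of one MS level
#'
#' @param run A `SpectraRun` (possibly with mixed MS levels).
#' @param ms_level 1 or 2.
#' @return A `SpectraRun` containing only the requested level, in the
#'   original acquisition order.
#' @export
filter_ms_level <- function(run, ms_level) {
  stopifnot(ms_level %in% c(1L, 2L))
  keep <- vapply(run$scans, function(s) s$ms_level == ms_level, logical(1))
  spectra_run(run$run_id, run$scans[keep], run$sample_label,
              ms_level = as.integer(ms_level))
}

#' Read an mzML or mzXML file into a SpectraRun
#'
#' Parses a centroided (or profile; peaks are taken as stored) run via the
#' proteowizard bindings and keeps only scans of the requested MS level, in
#' acquisition order. Retention times are reported in seconds regardless of
#' the unit stored in the file; peaks within each scan are sorted by m/z.
#' The dialect (mzML 1.1 vs mzXML 3.x) is auto-detected from the file.
#'
#' Scans with zero peaks are retained: they later become all-zero rows of the
#' intensity matrix, and their count is reported in a message.
#'
#' @param path Path to an mzML or mzXML file.
#' @param ms_level Which scans to keep: 1 (precursor/survey) or 2 (fragment).
#' @param sample_label Optional integer class label to attach to the run.
#' @return A `SpectraRun` whose `run_id` is the filename stem.
#' @export
read_spectra <- function(path, ms_level = 1L, sample_label = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(ms_level %in% c(1L, 2L))
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("cannot parse '", path,
                                          "' as mzML/mzXML: ",
                                          conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(ms), add = TRUE)
  hd <- mzR::header(ms)
  keep <- which(hd$msLevel == ms_level)
  if (length(keep) == 0L)
    stop("'", path, "' contains no scans at MS level ", ms_level)
  scans <- vector("list", length(keep))
  n_empty <- 0L
  for (i in seq_along(keep)) {
    k <- keep[i]
    pk <- mzR::peaks(ms, k)
    if (is.null(dim(pk))) pk <- matrix(pk, ncol = 2L)
    if (nrow(pk) > 0L && is.unsorted(pk[, 1L]))
      pk <- pk[order(pk[, 1L]), , drop = FALSE]
    if (nrow(pk) == 0L) n_empty <- n_empty + 1L
    colnames(pk) <- c("mz", "intensity")
    scans[[i]] <- list(scan_index = as.integer(hd$seqNum[k]),
                       ms_level = as.integer(hd$msLevel[k]),
                       retention_time = as.numeric(hd$retentionTime[k]),
                       peaks = pk)
  }
  if (n_empty > 0L)
    message(n_empty, " empty scan(s) retained in ", basename(path))
  spectra_run(tools::file_path_sans_ext(basename(path)), scans,
              sample_label = sample_label, ms_level = as.integer(ms_level))
}

#' Load a sample manifest
#'
#' The manifest is delimited text with columns `file`, `label` and optionally
#' `group`. Relative paths are resolved against the manifest's directory;
#' every referenced file must exist and paths must be unique. Labels are
#' parsed as integer class codes. Fewer than two distinct labels triggers a
#' warning at load time (classification will refuse such input later).
#'
#' @param path Path to the manifest CSV/TSV.
#' @return A data.frame of class `sample_manifest` with columns `file`,
#'   `label`, `group`, plus attribute `single_class` (logical).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- data.table::fread(path, data.table = FALSE, colClasses = list(character = "file"))
  if (!all(c("file", "label") %in% names(m)))
    stop("manifest must have columns 'file' and 'label'")
  if (!"group" %in% names(m)) m$group <- NA_character_
  lab <- suppressWarnings(as.integer(m$label))
  if (anyNA(lab)) stop("manifest labels must be integers")
  m$label <- lab
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", m$file), m$file,
                file.path(base, m$file))
  if (anyDuplicated(abs))
    stop("duplicate file paths in manifest: ",
         paste(unique(abs[duplicated(abs)]), collapse = ", "))
  missing <- !file.exists(abs)
  if (any(missing))
    stop("manifest row ", which(missing)[1L], " references a missing file: ",
         m$file[which(missing)[1L]])
  m$file <- abs
  single <- length(unique(m$label)) < 2L
  if (single)
    warning("manifest contains fewer than 2 distinct labels; ",
            "classification will not be possible")
  structure(m[, c("file", "label", "group")],
            single_class = single, class = c("sample_manifest", "data.frame"))
}

#' Read every run of a manifest
#'
#' @param manifest A `sample_manifest` (or path to one).
#' @param ms_level MS level to extract from each file.
#' @return List of `SpectraRun`, labels attached from the manifest.
#' @export
read_manifest_runs <- function(manifest, ms_level = 1L) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i)
    read_spectra(manifest$file[i], ms_level = ms_level,
                 sample_label = manifest$label[i]))
}

#' Write an intensity matrix to CSV
#'
#' One row per scan, prefixed by `run_id` and `scan_index` identifier
#' columns, then one column per m/z window named `w<j>`. Values round-trip
#' losslessly at full double precision.
#'
#' @param matrix An `IntensityMatrix` (see [extract_feature_swath()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_matrix_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "IntensityMatrix"))
  if (nrow(matrix$values) == 0L) stop("refusing to write an empty matrix")
  df <- data.frame(run_id = matrix$row_ids$run_id,
                   scan_index = matrix$row_ids$scan_index,
                   matrix$values, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read an intensity matrix back from CSV
#'
#' Inverse of [write_matrix_csv()]. The window grid is reconstructed from
#' the supplied `grid` argument (the CSV stores only window identifiers).
#'
#' @param path CSV written by [write_matrix_csv()].
#' @param grid The `WindowGrid` the matrix was built with (optional).
#' @param normalized Whether the stored values were normalized.
#' @return An `IntensityMatrix`.
#' @export
read_matrix_csv <- function(path, grid = NULL, normalized = FALSE) {
  df <- data.table::fread(path, data.table = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  new_intensity_matrix(vals,
                       row_ids = data.frame(run_id = df$run_id,
                                            scan_index = df$scan_index),
                       grid = grid, normalized = normalized)
}
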