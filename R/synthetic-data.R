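#' Configuration for the synthetic DDA cohort generator
#'
#' The generator emulates data-dependent-acquisition runs at desk scale:
#' each run is a few hundred survey scans, each scan a Poisson number of
#' background peaks uniform in m/z with log-normal intensities, plus
#' class-signature peaks at a fixed set of m/z loci. Class identity enters
#' only through the signature loci: every class shares the same base locus
#' positions, and a class displaces each locus by `signature_shift` times a
#' class-specific offset (in Th) and scales its intensity by
#' `exp(signature_shift * class-specific log-multiplier)`. At
#' `signature_shift = 0` all classes are therefore distributionally
#' identical by construction. Each run additionally draws one global
#' intensity scale factor, which per-scan row-max normalization must
#' cancel downstream.
#'
#' @param n_runs_per_class Runs (samples) per class.
#' @param n_classes Number of classes; labels are `0 .. n_classes - 1`.
#' @param scans_per_run Survey scans per run.
#' @param mz_range Numeric `c(min, max)` of the scan range, Th.
#' @param rt_range Numeric `c(min, max)` retention-time range, seconds.
#' @param n_background_peaks Poisson mean of background peaks per scan.
#' @param n_signature_loci Signature m/z loci per class.
#' @param signature_shift Effect size >= 0 scaling both the Th displacement
#'   and the log-intensity multiplier of class signatures; 0 = no class
#'   signal, 1 = strong separation (default).
#' @param intensity_noise Log-normal sigma of peak intensities.
#' @param run_scale_jitter Range of the per-run multiplicative intensity
#'   factor.
#' @param ms2 If `TRUE`, each survey scan is followed by one fragment
#'   (MS2) scan built from a randomly chosen signature locus, with noisier
#'   signatures so MS1 carries more class signal than MS2.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the config.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_runs_per_class = 5L, n_classes = 2L,
                             scans_per_run = 300L,
                             mz_range = c(400, 1400),
                             rt_range = c(0, 3600),
                             n_background_peaks = 150,
                             n_signature_loci = 8L,
                             signature_shift = 1,
                             intensity_noise = 0.5,
                             run_scale_jitter = c(0.5, 2),
                             ms2 = FALSE,
                             seed = 1L) {
  stopifnot(n_runs_per_class >= 1L, n_classes >= 1L, scans_per_run >= 1L,
            length(mz_range) == 2L, mz_range[1] < mz_range[2],
            length(rt_range) == 2L, rt_range[1] < rt_range[2],
            n_background_peaks > 0, n_signature_loci >= 1L,
            signature_shift >= 0, intensity_noise >= 0,
            length(run_scale_jitter) == 2L,
            run_scale_jitter[1] > 0,
            run_scale_jitter[1] <= run_scale_jitter[2])
  structure(as.list(environment()), class = "SyntheticConfig")
}

#' Generate a synthetic labelled cohort
#'
#' See [synthetic_config()] for the generative model. Runs are named
#' `class<label>_run<r>`; labels are `0 .. n_classes - 1`.
#'
#' @param config A `SyntheticConfig`.
#' @return List of `SpectraRun` (MS1-only unless `config$ms2`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)

  mzr <- config$mz_range
  span <- diff(mzr)
  # base loci shared by all classes; class-specific displacement and
  # intensity log-multiplier scale with signature_shift
  base_loci <- sort(stats::runif(config$n_signature_loci,
                                 mzr[1] + 0.05 * span, mzr[2] - 0.05 * span))
  delta <- matrix(stats::runif(config$n_classes * config$n_signature_loci,
                               -5, 5),
                  config$n_classes, config$n_signature_loci)
  logmult <- matrix(stats::rnorm(config$n_classes * config$n_signature_loci,
                                 0, 0.8),
                    config$n_classes, config$n_signature_loci)

  runs <- vector("list", config$n_classes * config$n_runs_per_class)
  i <- 0L
  for (cls in seq_len(config$n_classes) - 1L) {
    loci <- base_loci + config$signature_shift * delta[cls + 1L, ]
    lmul <- config$signature_shift * logmult[cls + 1L, ]
    for (r in seq_len(config$n_runs_per_class)) {
      i <- i + 1L
      scale <- stats::runif(1, config$run_scale_jitter[1],
                            config$run_scale_jitter[2])
      rt <- sort(stats::runif(config$scans_per_run,
                              config$rt_range[1], config$rt_range[2]))
      scans <- vector("list",
                      config$scans_per_run * (1L + as.integer(config$ms2)))
      si <- 0L
      for (sc in seq_len(config$scans_per_run)) {
        nbg <- stats::rpois(1, config$n_background_peaks)
        bg_mz <- stats::runif(nbg, mzr[1], mzr[2])
        bg_int <- stats::rlnorm(nbg, log(1e4), max(config$intensity_noise, 1e-8))
        sig_mz <- loci + stats::rnorm(length(loci), 0, 0.05)
        sig_int <- stats::rlnorm(length(loci), log(8e4) + lmul,
                                 max(config$intensity_noise, 1e-8))
        mz <- c(bg_mz, sig_mz); it <- c(bg_int, sig_int) * scale
        ord <- order(mz)
        si <- si + 1L
        scans[[si]] <- list(scan_index = si, ms_level = 1L,
                            retention_time = rt[sc],
                            peaks = cbind(mz = mz[ord], intensity = it[ord]))
        if (config$ms2) {
          # fragment scan from one signature precursor: fragments at fixed
          # fractional offsets, doubled noise so MS2 carries less signal
          prec <- sample.int(length(loci), 1L)
          frag_mz <- loci[prec] * c(0.35, 0.5, 0.65, 0.8) +
            stats::rnorm(4, 0, 0.5)
          frag_int <- stats::rlnorm(4, log(4e4) + 0.5 * lmul[prec],
                                    max(2 * config$intensity_noise, 1e-8))
          nbg2 <- stats::rpois(1, config$n_background_peaks)
          b2_mz <- stats::runif(nbg2, mzr[1], mzr[2])
          b2_int <- stats::rlnorm(nbg2, log(2e4),
                                  max(2 * config$intensity_noise, 1e-8))
          mz2 <- c(b2_mz, frag_mz); it2 <- c(b2_int, frag_int) * scale
          ord2 <- order(mz2)
          si <- si + 1L
          scans[[si]] <- list(scan_index = si, ms_level = 2L,
                              retention_time = rt[sc] + 0.1,
                              peaks = cbind(mz = mz2[ord2],
                                            intensity = it2[ord2]))
        }
      }
      runs[[i]] <- spectra_run(sprintf("class%d_run%02d", cls, r),
                               scans[seq_len(si)], sample_label = cls,
                               ms_level = if (config$ms2) NA_integer_ else 1L)
    }
  }
  runs
}

#' Binned intensity pattern of one run over (retention time, m/z)
#'
#' Sums peak intensities on a 2-D grid of equal retention-time and m/z
#' bins, with the marginal intensity profile along each axis. This is the
#' fingerprint view used to eyeball class differences; the classifier
#' itself never sees retention time.
#'
#' @param run A nonempty `SpectraRun`.
#' @param rt_bins,mz_bins Number of bins per axis.
#' @param mz_range Optional `c(min, max)` to pin the m/z bin edges (so the
#'   m/z marginal matches a `WindowGrid` of the same bounds and count).
#' @return A `PatternSummary` with `grid` (rt_bins x mz_bins matrix),
#'   `rt_breaks`, `mz_breaks`, `rt_marginal` (row sums) and `mz_marginal`
#'   (column sums).
#' @export
pattern_summary <- function(run, rt_bins = 32L, mz_bins = 32L,
                            mz_range = NULL) {
  stopifnot(inherits(run, "SpectraRun"), rt_bins >= 1L, mz_bins >= 1L)
  if (length(run$scans) == 0L) stop("run '", run$run_id, "' has no scans")
  counts <- vapply(run$scans, function(s) nrow(s$peaks), integer(1))
  if (sum(counts) == 0L) stop("run '", run$run_id, "' has no peaks")
  rt <- rep.int(vapply(run$scans, `[[`, numeric(1), "retention_time"), counts)
  mz <- unlist(lapply(run$scans, function(s) s$peaks[, 1L]), use.names = FALSE)
  it <- unlist(lapply(run$scans, function(s) s$peaks[, 2L]), use.names = FALSE)
  rtr <- range(rt)
  if (rtr[1] == rtr[2]) rtr[2] <- rtr[1] + 1
  if (is.null(mz_range)) {
    mz_range <- c(floor(min(mz)), ceiling(max(mz)))
    if (mz_range[1] == mz_range[2]) mz_range[2] <- mz_range[1] + 1
  }
  rt_breaks <- seq(rtr[1], rtr[2], length.out = rt_bins + 1L)
  mz_breaks <- seq(mz_range[1], mz_range[2], length.out = mz_bins + 1L)
  ri <- findInterval(rt, rt_breaks, rightmost.closed = TRUE)
  mi <- findInterval(mz, mz_breaks, rightmost.closed = TRUE)
  keep <- ri >= 1L & ri <= rt_bins & mi >= 1L & mi <= mz_bins
  grid <- matrix(0, rt_bins, mz_bins)
  if (any(keep)) {
    cell <- (mi[keep] - 1L) * rt_bins + ri[keep]  # column-major
    acc <- rowsum(it[keep], group = cell)
    grid[as.integer(rownames(acc))] <- acc[, 1L]
  }
  structure(list(run_id = run$run_id, grid = grid,
                 rt_breaks = rt_breaks, mz_breaks = mz_breaks,
                 rt_marginal = rowSums(grid), mz_marginal = colSums(grid)),
            class = "PatternSummary")
}

#' Write a pattern summary as CSV
#'
#' Long-format CSV with one row per (rt bin, mz bin) cell plus the bin
#' midpoints; marginals are appended as separate files with suffixes
#' `_rt.csv` and `_mz.csv`.
#'
#' @param ps A `PatternSummary`.
#' @param path Output CSV path for the grid.
#' @return `path`, invisibly.
#' @export
write_pattern_csv <- function(ps, path) {
  stopifnot(inherits(ps, "PatternSummary"))
  rt_mid <- (utils::head(ps$rt_breaks, -1) + utils::tail(ps$rt_breaks, -1)) / 2
  mz_mid <- (utils::head(ps$mz_breaks, -1) + utils::tail(ps$mz_breaks, -1)) / 2
  df <- data.frame(rt = rep(rt_mid, times = length(mz_mid)),
                   mz = rep(mz_mid, each = length(rt_mid)),
                   intensity = as.vector(ps$grid))
  data.table::fwrite(df, path)
  stem <- sub("\\.csv$", "", path)
  data.table::fwrite(data.frame(rt = rt_mid, intensity = ps$rt_marginal),
                     paste0(stem, "_rt.csv"))
  data.table::fwrite(data.frame(mz = mz_mid, intensity = ps$mz_marginal),
                     paste0(stem, "_mz.csv"))
  invisible(path)
}

#' Heat-map plot of a pattern summary
#'
#' @param ps A `PatternSummary`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_pattern <- function(ps) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_pattern needs the ggplot2 package")
  rt_mid <- (utils::head(ps$rt_breaks, -1) + utils::tail(ps$rt_breaks, -1)) / 2
  mz_mid <- (utils::head(ps$mz_breaks, -1) + utils::tail(ps$mz_breaks, -1)) / 2
  df <- data.frame(rt = rep(rt_mid, times = length(mz_mid)),
                   mz = rep(mz_mid, each = length(rt_mid)),
                   intensity = as.vector(ps$grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rt, y = .data$mz,
                                   fill = log1p(.data$intensity))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log(1+intensity)") +
    ggplot2::labs(x = "retention time (s)", y = "m/z (Th)",
                  title = ps$run_id)
}

#' Write a run as a peak-table CSV
#'
#' Columns `scan_index`, `ms_level`, `retention_time`, `mz`, `intensity`,
#' one row per peak (empty scans appear with NA mz/intensity so they
#' survive the round trip).
#'
#' @param run A `SpectraRun`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(run, path) {
  rows <- lapply(run$scans, function(s) {
    if (nrow(s$peaks) == 0L)
      data.frame(scan_index = s$scan_index, ms_level = s$ms_level,
                 retention_time = s$retention_time,
                 mz = NA_real_, intensity = NA_real_)
    else
      data.frame(scan_index = s$scan_index, ms_level = s$ms_level,
                 retention_time = s$retention_time,
                 mz = s$peaks[, 1L], intensity = s$peaks[, 2L])
  })
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}

#' Read a peak-table CSV back into a SpectraRun
#'
#' @param path CSV written by [write_run_csv()].
#' @param sample_label Optional label to attach.
#' @return A `SpectraRun`.
#' @export
read_run_csv <- function(path, sample_label = NA_integer_) {
  df <- data.table::fread(path, data.table = FALSE)
  idx <- sort(unique(df$scan_index))
  scans <- lapply(idx, function(i) {
    d <- df[df$scan_index == i, , drop = FALSE]
    pk_df <- d[!is.na(d$mz), c("mz", "intensity"), drop = FALSE]
    pk <- as.matrix(pk_df[order(pk_df$mz), , drop = FALSE])
    storage.mode(pk) <- "double"
    colnames(pk) <- c("mz", "intensity")
    list(scan_index = as.integer(i), ms_level = as.integer(d$ms_level[1]),
         retention_time = as.numeric(d$retention_time[1]), peaks = pk)
  })
  lvls <- unique(df$ms_level)
  spectra_run(tools::file_path_sans_ext(basename(path)), scans,
              sample_label = sample_label,
              ms_level = if (length(lvls) == 1L) as.integer(lvls) else NA_integer_)
}

#' Write a cohort to disk with a manifest
#'
#' Each run is written in the requested format and a `manifest.csv`
#' (`file,label,group`) referencing the files is placed beside them.
#'
#' @param runs List of labelled `SpectraRun`.
#' @param dir Output directory (created if needed).
#' @param format `"mzml"`, `"mzxml"` or `"csv"`.
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(runs, dir, format = c("mzml", "csv", "mzxml")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- switch(format, mzml = ".mzML", mzxml = ".mzXML", csv = ".csv")
  files <- character(length(runs))
  for (i in seq_along(runs)) {
    files[i] <- file.path(dir, paste0(runs[[i]]$run_id, ext))
    switch(format,
           mzml = write_mzml(runs[[i]], files[i]),
           mzxml = write_mzxml(runs[[i]], files[i]),
           csv = write_run_csv(runs[[i]], files[i]))
  }
  man <- data.frame(file = basename(files),
                    label = vapply(runs, `[[`, integer(1), "sample_label"),
                    group = vapply(runs, `[[`, character(1), "run_id"))
  mpath <- file.path(dir, "manifest.csv")
  data.table::fwrite(man, mpath)
  invisible(mpath)
}
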