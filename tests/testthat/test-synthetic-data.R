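test_that("cohort generation is a pure function of its config", {
  cfg <- small_cohort_config(seed = 101)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_length(a, 6L)
  expect_equal(vapply(a, `[[`, integer(1), "sample_label"),
               rep(0:1, each = 3))
  expect_equal(n_scans(a[[1]]), cfg$scans_per_run)
})

test_that("zero signature shift makes the classes distributionally identical", {
  runs <- generate_cohort(synthetic_config(n_runs_per_class = 2,
                                           scans_per_run = 30,
                                           signature_shift = 0,
                                           run_scale_jitter = c(1, 1),
                                           seed = 7))
  pool <- function(cls) {
    v <- unlist(lapply(runs[vapply(runs, `[[`, integer(1),
                                   "sample_label") == cls],
                       function(r) lapply(r$scans, function(s)
                         s$peaks[, "intensity"])), use.names = FALSE)
    sample(v, 2000)
  }
  set.seed(1)
  ks <- suppressWarnings(stats::ks.test(log(pool(0)), log(pool(1))))
  expect_gt(ks$p.value, 0.01)
})

test_that("a global intensity rescale cannot change normalized features or predictions", {
  runs <- generate_cohort(small_cohort_config(seed = 5, scans = 15))
  scaled <- lapply(runs, function(r) {
    r$scans <- lapply(r$scans, function(s) {
      s$peaks[, "intensity"] <- s$peaks[, "intensity"] * 1e3
      s
    })
    r
  })
  rng <- infer_mz_range(runs)
  grid <- build_window_grid(rng[1], rng[2], "6x6")
  nm1 <- normalize_rows(extract_feature_swath(runs[[1]], grid))
  nm2 <- normalize_rows(extract_feature_swath(scaled[[1]], grid))
  expect_equal(nm1$values, nm2$values, tolerance = 1e-12)

  p <- pool_features(runs[-1], grid)
  m <- train_model(p$features, p$labels, model_spec(36, c(8, 4), 2),
                   training_config(epochs = 3, seed = 2))
  expect_equal(predict_scans(m, nm1), predict_scans(m, nm2),
               tolerance = 1e-12)
})

test_that("class signal raises leave-one-out accuracy above the null", {
  accs <- vapply(1:3, function(s) {
    shifted <- generate_cohort(small_cohort_config(seed = s, shift = 1,
                                                   scans = 30))
    rng <- infer_mz_range(shifted)
    run_loo(shifted, build_window_grid(rng[1], rng[2], "10x10"),
            config = fast_training(seed = s))$accuracy
  }, numeric(1))
  null_accs <- vapply(1:3, function(s) {
    null <- generate_cohort(small_cohort_config(seed = s, shift = 0,
                                                scans = 30))
    rng <- infer_mz_range(null)
    run_loo(null, build_window_grid(rng[1], rng[2], "10x10"),
            config = fast_training(seed = s))$accuracy
  }, numeric(1))
  expect_gte(mean(accs), mean(null_accs))
  expect_gte(mean(accs), 0.8)  # strong separation at desk scale
})

test_that("MS2 emulation produces fragment scans tied to the survey cycle", {
  cfg <- synthetic_config(n_runs_per_class = 1, scans_per_run = 10,
                          ms2 = TRUE, seed = 3)
  runs <- generate_cohort(cfg)
  lv <- vapply(runs[[1]]$scans, `[[`, integer(1), "ms_level")
  expect_equal(sum(lv == 1L), 10L)
  expect_equal(sum(lv == 2L), 10L)
  expect_equal(lv[1:4], c(1L, 2L, 1L, 2L))
  ms1 <- filter_ms_level(runs[[1]], 1L)
  expect_equal(n_scans(ms1), 10L)
  expect_true(all(vapply(ms1$scans, `[[`, integer(1), "ms_level") == 1L))
})

test_that("pattern grids put intensity where the peaks are", {
  one <- spectra_run("one", list(make_scan(1, 500, 42, rt = 100)), 0L, 1L)
  ps <- pattern_summary(one, rt_bins = 4, mz_bins = 4, mz_range = c(400, 600))
  expect_equal(sum(ps$grid > 0), 1L)
  expect_equal(sum(ps$grid), 42)
  expect_error(pattern_summary(spectra_run("e", list(), 0L, 1L), 4, 4),
               "no scans")
})

test_that("pattern marginals are consistent with the grid and the swath bins", {
  set.seed(8)
  run <- random_run(15, max_peaks = 100, mz_range = c(150, 1050))
  rng <- infer_mz_range(list(run))
  ps <- pattern_summary(run, rt_bins = 5, mz_bins = 12, mz_range = rng)
  expect_equal(ps$rt_marginal, rowSums(ps$grid))
  expect_equal(ps$mz_marginal, colSums(ps$grid))

  # the m/z marginal equals the column sums of the matching window grid
  grid <- build_window_grid(rng[1], rng[2], 12)
  m <- suppressMessages(extract_feature_swath(run, grid))
  expect_equal(ps$mz_marginal, unname(colSums(m$values)), tolerance = 1e-9)

  # with a single RT bin the marginal IS the total binned spectrum
  ps1 <- pattern_summary(run, rt_bins = 1, mz_bins = 12, mz_range = rng)
  expect_equal(as.numeric(ps1$grid[1, ]), ps1$mz_marginal)
})

test_that("peak-table CSV and cohort exports round-trip through the readers", {
  run <- toy_run(label = 1L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_run_csv(run, f)
  back <- read_run_csv(f, sample_label = 1L)
  expect_equal(n_scans(back), 3L)
  for (i in 1:3)
    expect_equal(back$scans[[i]]$peaks, run$scans[[i]]$peaks,
                 tolerance = 1e-9, ignore_attr = TRUE)

  dir <- withr::local_tempdir()
  runs <- generate_cohort(synthetic_config(n_runs_per_class = 1,
                                           scans_per_run = 3,
                                           n_background_peaks = 10, seed = 2))
  man <- write_cohort(runs, dir, format = "mzml")
  m <- load_manifest(man)
  expect_equal(nrow(m), 2L)
  reread <- read_manifest_runs(m, ms_level = 1)
  expect_equal(vapply(reread, n_scans, integer(1)), c(3L, 3L))
  expect_equal(vapply(reread, `[[`, integer(1), "sample_label"), 0:1)
})

test_that("pattern CSV export writes the grid and both marginals", {
  run <- toy_run()
  ps <- pattern_summary(run, rt_bins = 2, mz_bins = 3, mz_range = c(100, 600))
  f <- file.path(withr::local_tempdir(), "pattern.csv")
  write_pattern_csv(ps, f)
  grid_df <- read.csv(f)
  expect_equal(nrow(grid_df), 6L)
  expect_equal(sum(grid_df$intensity), sum(ps$grid))
  expect_true(file.exists(sub("\\.csv$", "_rt.csv", f)))
  expect_true(file.exists(sub("\\.csv$", "_mz.csv", f)))
})
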