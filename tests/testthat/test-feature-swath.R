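test_that("NxN specs expand to N^2 one-dimensional windows", {
  expect_equal(build_window_grid(400, 1400, "5x5")$n_windows, 25L)
  expect_equal(build_window_grid(400, 1400, "10×10")$n_windows, 100L)
  g <- build_window_grid(400, 1400, "28 x 28")
  expect_equal(g$n_windows, 784L)
  expect_equal(g$window_width, 1000 / 784)
  expect_equal(build_window_grid(400, 1400, "32x32")$n_windows, 1024L)

  g1 <- build_window_grid(100, 200, 1)
  expect_equal(g1$n_windows, 1L)
  expect_equal(g1$breaks, c(100, 200))

  expect_error(build_window_grid(200, 100, 5), "mz_min < mz_max")
  expect_error(build_window_grid(100, 200, 0), "positive")
  expect_error(parse_window_spec("3x4"), "square")
  expect_error(parse_window_spec("banana"), "cannot parse")
})

test_that("window grids tile the m/z range exactly", {
  for (n in c(1L, 7L, 25L, 128L)) {
    g <- build_window_grid(350.5, 1249.5, n)
    expect_length(g$breaks, n + 1L)
    expect_equal(g$breaks[1], g$mz_min)
    expect_equal(g$breaks[n + 1L], g$mz_max)
    expect_equal(diff(g$breaks), rep(g$window_width, n), tolerance = 1e-9)
  }
})

test_that("m/z range inference floors, ceils and widens degenerate ranges", {
  r1 <- spectra_run("a", list(make_scan(1, c(350.2, 800), c(1, 1))), 0L, 1L)
  r2 <- spectra_run("b", list(make_scan(1, 1249.8, 1)), 1L, 1L)
  expect_equal(infer_mz_range(list(r1, r2)), c(350, 1250))

  single <- spectra_run("c", list(make_scan(1, 500.0, 1)), 0L, 1L)
  expect_equal(infer_mz_range(list(single)), c(500, 501))

  empty <- spectra_run("d", list(make_scan(1, numeric(0), numeric(0))), 0L, 1L)
  expect_error(infer_mz_range(list(empty)), "empty")
})

test_that("swath extraction sums in-range peaks per window", {
  run <- spectra_run("x", list(
    make_scan(1, c(100.5, 100.9, 350.0), c(10, 5, 7))), 0L, 1L)
  grid <- build_window_grid(100, 600, 5)
  m <- extract_feature_swath(run, grid)
  expect_equal(as.numeric(m$values[1, ]), c(15, 0, 7, 0, 0))
  expect_false(m$normalized)
})

test_that("a peak on an interior boundary lands in the window starting there", {
  run <- spectra_run("b", list(make_scan(1, 200.0, 4)), 0L, 1L)
  grid <- build_window_grid(100, 600, 5)  # boundaries at 200, 300, ...
  m <- extract_feature_swath(run, grid)
  expect_equal(as.numeric(m$values[1, ]), c(0, 4, 0, 0, 0))
  # and the very last boundary is closed
  top <- spectra_run("t", list(make_scan(1, 600.0, 9)), 0L, 1L)
  expect_equal(as.numeric(extract_feature_swath(top, grid)$values[1, ]),
               c(0, 0, 0, 0, 9))
})

test_that("out-of-range peaks are dropped and counted", {
  run <- spectra_run("o", list(make_scan(1, c(50, 150, 700), c(1, 2, 3))),
                     0L, 1L)
  grid <- build_window_grid(100, 600, 5)
  expect_message(m <- extract_feature_swath(run, grid), "2 peak")
  expect_equal(m$n_dropped, 2L)
  expect_equal(sum(m$values), 2)
})

test_that("vectorized binning matches the brute-force per-peak oracle", {
  set.seed(31)
  for (rep in 1:4) {
    run <- random_run(n_scans = 12, max_peaks = 400)
    nw <- sample(2:128, 1)
    rng <- infer_mz_range(list(run))
    grid <- build_window_grid(rng[1], rng[2], nw)
    fast <- suppressMessages(extract_feature_swath(run, grid))
    expect_equal(unname(fast$values), brute_force_swath(run, grid),
                 tolerance = 1e-12)
  }
})

test_that("row sums conserve total in-range intensity", {
  set.seed(17)
  run <- random_run(n_scans = 20, max_peaks = 300)
  rng <- infer_mz_range(list(run))
  grid <- build_window_grid(rng[1], rng[2], 64)
  m <- suppressMessages(extract_feature_swath(run, grid))
  for (i in seq_along(run$scans)) {
    pk <- run$scans[[i]]$peaks
    inr <- pk[, 1] >= rng[1] & pk[, 1] <= rng[2]
    expect_equal(sum(m$values[i, ]), sum(pk[inr, 2]),
                 tolerance = 1e-9 * max(1, sum(pk[inr, 2])))
  }
})

test_that("binning is invariant to peak order within a scan", {
  set.seed(5)
  mz <- runif(200, 100, 1100); it <- rexp(200, 1e-3)
  run1 <- spectra_run("p", list(make_scan(1, mz, it)), 0L, 1L)
  perm <- sample(200)
  run2 <- spectra_run("p", list(make_scan(1, mz[perm], it[perm])), 0L, 1L)
  grid <- build_window_grid(100, 1100, 50)
  expect_equal(extract_feature_swath(run1, grid)$values,
               extract_feature_swath(run2, grid)$values)
})

test_that("row normalization divides by the row max and is single-shot", {
  run <- spectra_run("n", list(
    make_scan(1, c(150, 250, 350), c(2, 4, 8)),
    make_scan(2, numeric(0), numeric(0))), 0L, 1L)
  grid <- build_window_grid(100, 600, 5)
  raw <- extract_feature_swath(run, grid)
  nm <- normalize_rows(raw)
  expect_equal(as.numeric(nm$values[1, 1:3]), c(0.25, 0.5, 1.0))
  expect_equal(as.numeric(nm$values[2, ]), rep(0, 5))
  expect_true(nm$normalized)
  expect_error(normalize_rows(nm), "already normalized")
})

test_that("every normalized row max is 0 or 1", {
  set.seed(23)
  run <- random_run(n_scans = 25, max_peaks = 200)
  rng <- infer_mz_range(list(run))
  nm <- suppressMessages(
    normalize_rows(extract_feature_swath(
      run, build_window_grid(rng[1], rng[2], 40))))
  rmax <- apply(nm$values, 1, max)
  expect_true(all(abs(rmax - 1) < 1e-12 | rmax == 0))
  expect_true(all(nm$values >= 0 & nm$values <= 1))
})

test_that("label vectors repeat the run label once per scan", {
  run4 <- spectra_run("l", lapply(1:4, function(i) make_scan(i, 500, 1)),
                      sample_label = 1L, ms_level = 1L)
  expect_equal(make_label_vector(run4), c(1L, 1L, 1L, 1L))
  run3 <- spectra_run("m", lapply(1:3, function(i) make_scan(i, 500, 1)),
                      sample_label = 0L, ms_level = 1L)
  expect_equal(make_label_vector(run3), c(0L, 0L, 0L))
  expect_error(make_label_vector(run3, 5), "does not match")
  empty <- spectra_run("e", list(), sample_label = 0L, ms_level = 1L)
  expect_length(make_label_vector(empty, 0), 0L)
})
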