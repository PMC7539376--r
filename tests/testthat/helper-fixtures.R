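# Fixture builders and independent oracles shared by the test files.

make_scan <- function(idx, mz, intensity, rt = idx, level = 1L) {
  ord <- order(mz)
  list(scan_index = as.integer(idx), ms_level = as.integer(level),
       retention_time = as.numeric(rt),
       peaks = cbind(mz = mz[ord], intensity = intensity[ord]))
}

# a hand-built run with known peak content
toy_run <- function(label = 0L, id = "toy") {
  spectra_run(id, list(
    make_scan(1, c(100.5, 100.9, 350.0), c(10, 5, 7), rt = 1.0),
    make_scan(2, c(250.0, 420.5), c(3, 2), rt = 2.0),
    make_scan(3, numeric(0), numeric(0), rt = 3.0)
  ), sample_label = label, ms_level = 1L)
}

# mixed-level run: 3 MS1 + 5 MS2 scans
mixed_run <- function(id = "mixed") {
  scans <- list()
  k <- 0L
  for (i in 1:8) {
    lvl <- if (i %in% c(1, 4, 7)) 1L else 2L
    k <- k + 1L
    scans[[k]] <- make_scan(i, c(100 + i, 200 + i), c(i, 2 * i),
                            rt = 10 * i, level = lvl)
  }
  spectra_run(id, scans, sample_label = 1L, ms_level = NA_integer_)
}

random_run <- function(n_scans, max_peaks = 1000, mz_range = c(100, 1100),
                       label = 0L, id = "rand") {
  scans <- lapply(seq_len(n_scans), function(i) {
    np <- sample.int(max_peaks, 1L)
    make_scan(i, runif(np, mz_range[1] - 50, mz_range[2] + 50),
              rexp(np, 1 / 1000), rt = i)
  })
  spectra_run(id, scans, sample_label = label, ms_level = 1L)
}

# brute-force binning oracle: loop every peak, linear-search its window
brute_force_swath <- function(run, grid) {
  nw <- grid$n_windows
  out <- matrix(0, length(run$scans), nw)
  for (i in seq_along(run$scans)) {
    pk <- run$scans[[i]]$peaks
    for (k in seq_len(nrow(pk))) {
      mz <- pk[k, 1]
      for (j in seq_len(nw)) {
        lo <- grid$breaks[j]; hi <- grid$breaks[j + 1]
        inside <- if (j < nw) (mz >= lo && mz < hi) else (mz >= lo && mz <= hi)
        if (inside) {
          out[i, j] <- out[i, j] + pk[k, 2]
          break
        }
      }
    }
  }
  out
}

# O(n^2) concordant-pair AUC oracle, ties counted one half
pair_auc <- function(labels, scores, positive_class = max(labels)) {
  pos <- scores[labels == positive_class]
  neg <- scores[labels != positive_class]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force trainable-parameter count by walking consecutive layer pairs
hand_count_params <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden, spec$output_units)
  total <- 0
  for (l in seq_len(length(dims) - 1))
    total <- total + dims[l] * dims[l + 1] + dims[l + 1]
  total
}

# small fast cohort for unit tests (acceptance tests use the real defaults)
small_cohort_config <- function(seed, shift = 1, runs_per_class = 3,
                                scans = 40) {
  synthetic_config(n_runs_per_class = runs_per_class, scans_per_run = scans,
                   n_background_peaks = 40, signature_shift = shift,
                   seed = seed)
}

fast_training <- function(seed = 1) {
  # small fixtures mean few rows per epoch; keep enough optimizer steps
  training_config(epochs = 25, batch_size = 32, learning_rate = 5e-3,
                  seed = seed)
}

# predictors injectable into run_loo: the per-iteration seed is
# master_seed + k, so the run index is recoverable inside the closure
oracle_predictor <- function(runs, master_seed) {
  function(train_x, train_labels, test_x, seed) {
    k <- seed - master_seed
    lab <- runs[[k]]$sample_label
    classes <- sort(unique(vapply(runs, `[[`, integer(1), "sample_label")))
    probs <- matrix(0, nrow(test_x), length(classes),
                    dimnames = list(NULL, classes))
    probs[, as.character(lab)] <- 1
    list(labels = rep(lab, nrow(test_x)), probs = probs)
  }
}

adversary_predictor <- function(runs, master_seed) {
  function(train_x, train_labels, test_x, seed) {
    k <- seed - master_seed
    classes <- sort(unique(vapply(runs, `[[`, integer(1), "sample_label")))
    wrong <- setdiff(classes, runs[[k]]$sample_label)[1L]
    probs <- matrix(0, nrow(test_x), length(classes),
                    dimnames = list(NULL, classes))
    probs[, as.character(wrong)] <- 1
    list(labels = rep(wrong, nrow(test_x)), probs = probs)
  }
}

# separable 2-class feature matrix in the [0, 1] normalized range
separable_features <- function(n_per_class = 100, d = 20, seed = 99) {
  set.seed(seed)
  x0 <- matrix(pmin(1, pmax(0, rnorm(n_per_class * d, 0.25, 0.08))),
               n_per_class, d)
  x1 <- matrix(pmin(1, pmax(0, rnorm(n_per_class * d, 0.75, 0.08))),
               n_per_class, d)
  list(x = rbind(x0, x1),
       y = rep(c(0L, 1L), each = n_per_class))
}
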