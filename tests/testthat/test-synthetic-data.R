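test_that("config validation enforces the generator invariants", {
  expect_error(synthetic_config(P = 0, n_per = 1, d = 1), "P must be")
  expect_error(synthetic_config(P = 2, n_per = 1, d = 1, delta = -1),
               "non-negative")
  expect_error(synthetic_config(P = 3, n_per = 1, d = 1, mode = "condition"),
               "even participant count")
  expect_silent(synthetic_config(P = 4, n_per = 1, d = 1, mode = "condition"))
})

test_that("all variance sources at zero give exactly zero features", {
  cfg <- synthetic_config(P = 2, n_per = 1, d = 1, delta = 0,
                          sigma_participant = 0, sigma_noise = 0, seed = 1)
  ds <- generate_feature_dataset(cfg)
  expect_equal(ds$n, 4L)            # 2 participants x 2 classes x 1
  expect_true(all(ds$features == 0))
})

test_that("state-mode shape matches the configured design", {
  cfg <- synthetic_config(P = 12, n_per = 300, d = 90, delta = 1,
                          sigma_participant = 1, sigma_noise = 1, seed = 7)
  ds <- generate_feature_dataset(cfg)
  expect_equal(ds$n, 7200L)
  tab <- table(ds$participant, ds$label)
  expect_true(all(tab == 300L))
})

test_that("condition mode assigns one constant label per participant, balanced", {
  cfg <- synthetic_config(P = 6, n_per = 10, d = 4, mode = "condition", seed = 2)
  ds <- generate_feature_dataset(cfg)
  lab_per <- tapply(ds$label, ds$participant, function(l) unique(l))
  expect_true(all(lengths(lab_per) == 1L))
  expect_equal(sum(unlist(lab_per)), 3L)   # half the participants in class 1
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- synthetic_config(P = 4, n_per = 15, d = 6, seed = 42)
  expect_identical(generate_feature_dataset(cfg)$features,
                   generate_feature_dataset(cfg)$features)
  raw1 <- generate_raw_epochs(synthetic_config(P = 2, n_per = 3, d = 1, seed = 5),
                              fs = 64, channels = 2, epoch_seconds = 1)
  raw2 <- generate_raw_epochs(synthetic_config(P = 2, n_per = 3, d = 1, seed = 5),
                              fs = 64, channels = 2, epoch_seconds = 1)
  expect_identical(raw1$epochs, raw2$epochs)
})

test_that("per-participant empirical means recover the configured offsets", {
  cfg <- synthetic_config(P = 5, n_per = 250, d = 4, delta = 0,
                          sigma_participant = 3, sigma_noise = 1, seed = 11)
  ds <- generate_feature_dataset(cfg)
  offsets <- attr(ds, "offsets")
  tol <- 5 * cfg$sigma_noise / sqrt(2 * cfg$n_per)   # 5-sd tolerance
  for (p in seq_len(cfg$P)) {
    emp <- colMeans(ds$features[ds$participant == levels(ds$participant)[p], ])
    expect_true(all(abs(emp - offsets[p, ]) < tol))
  }
})

test_that("with no participant effect, between-participant location tests reject at the nominal rate", {
  rejections <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(P = 2, n_per = 30, d = 1, delta = 0,
                            sigma_participant = 0, sigma_noise = 1, seed = s)
    ds <- generate_feature_dataset(cfg)
    pv <- stats::t.test(ds$features[ds$participant == "P01", 1],
                        ds$features[ds$participant == "P02", 1])$p.value
    if (pv < 0.05) rejections <- rejections + 1L
  }
  expected <- n_seeds * 0.05
  tol <- 3 * sqrt(n_seeds * 0.05 * 0.95)
  expect_true(abs(rejections - expected) <= tol)
})

test_that("clustered configurations produce high participant purity", {
  cfg <- synthetic_config(P = 6, n_per = 20, d = 10, delta = 1,
                          sigma_participant = 10, sigma_noise = 1, seed = 1)
  ds <- generate_feature_dataset(cfg)
  expect_gt(participant_purity(ds$features, ds$participant, k = 10), 0.9)
})

test_that("raw epochs have the configured shape and carry the class band effect", {
  cfg <- synthetic_config(P = 2, n_per = 10, d = 1, seed = 3)
  raw <- generate_raw_epochs(cfg, fs = 128, channels = 30, epoch_seconds = 1)
  expect_length(raw$epochs, 40L)    # 2 participants x 2 classes x 10
  expect_true(all(vapply(raw$epochs, function(e)
    all(dim(e) == c(30L, 128L)), logical(1))))

  # doubling the class-1 alpha amplitude quadruples its band power
  raw2 <- generate_raw_epochs(synthetic_config(P = 4, n_per = 30, d = 1, seed = 9),
                              fs = 128, channels = 1, epoch_seconds = 1,
                              bands = list(alpha = c(12, 15)),
                              amplitudes = rbind(1, 2),
                              noise_sd = 0, participant_amp_sd = 0)
  bp <- vapply(raw2$epochs, function(e) fft_band_power(e[1, ], 128, c(12, 15)),
               numeric(1))
  ratio <- mean(bp[raw2$label == 1]) / mean(bp[raw2$label == 0])
  expect_lt(abs(ratio - 4) / 4, 0.1)
})

test_that("raw generator rejects invalid signal configurations", {
  cfg <- synthetic_config(P = 2, n_per = 2, d = 1, seed = 1)
  expect_error(generate_raw_epochs(cfg, fs = 128, epoch_seconds = 0.1),
               "at least 32 samples")
  expect_error(generate_raw_epochs(cfg, fs = 64,
                                   bands = list(bad = c(30, 40)),
                                   amplitudes = rbind(1, 1)),
               "Nyquist")
})

test_that("dataset CSV round-trip preserves the data", {
  cfg <- synthetic_config(P = 3, n_per = 4, d = 5, seed = 8)
  ds <- generate_feature_dataset(cfg)
  path <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path, mode = "state")
  expect_equal(back$features, ds$features, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.character(back$participant), as.character(ds$participant))
  expect_equal(back$label, ds$label)
})
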