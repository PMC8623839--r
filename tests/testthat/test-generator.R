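# Synthetic sEMG generator: configuration contracts, prototype geometry,
# subject derivation, session synthesis and the domain-shift dials.

test_that("generator config validates its invariants", {
  expect_error(generator_config(n_subjects = 0), "n_subjects")
  expect_error(generator_config(fs = 800), "carrier band")
  expect_error(generator_config(movement_s = 1, ramp_s = 0.6), "ramp_s")
  expect_error(generator_config(noise_floor = -1), "noise_floor")
  cfg <- generator_config(seed = 3)
  expect_s3_class(cfg, "emg_generator_config")
  expect_identical(cfg$n_gestures, 7L)
})

test_that("prototypes are normalized circular bumps, deterministic in seed", {
  cfg1 <- tiny_config(n_gestures = 1, seed = 5)
  P <- make_prototypes(cfg1, floor = 0)
  expect_equal(dim(P), c(1, 8))
  expect_equal(max(P), 1)
  expect_gt(P[1, 1], 0)  # bump centre sits at ring coordinate 0 -> channel 1
  expect_true(all(P >= 0))

  cfg <- tiny_config(seed = 5)
  expect_identical(make_prototypes(cfg), make_prototypes(cfg))
  expect_equal(unname(apply(make_prototypes(cfg), 1, max)), rep(1, 3))
})

test_that("equal-width prototypes 4 channels apart are circular shifts", {
  cfg <- tiny_config(n_gestures = 2)
  P <- make_prototypes(cfg, floor = 0.1, centers = c(0, 4), widths = c(1.3, 1.3))
  shifted <- P[1, c(5:8, 1:4)]  # row 1 rotated by 4 ring positions
  expect_equal(unname(P[2, ]), unname(shifted), tolerance = 1e-9)
})

test_that("activation shifting interpolates circularly", {
  A <- matrix(runif(16), 2, 8)
  expect_equal(shift_activation(A, 0), A)
  expect_equal(shift_activation(A, 1), A[, c(2:8, 1)])   # integer = permutation
  expect_equal(shift_activation(A, -3), A[, c(6:8, 1:5)])
  half <- shift_activation(A, 0.5)
  expect_equal(half[, 1], 0.5 * A[, 1] + 0.5 * A[, 2])
})

test_that("subject derivation reduces to prototypes in the zero-noise limit", {
  cfg0 <- tiny_config(subject_sigma = 0, subject_rot = 0, gain_sigma = 0,
                      noise_sigma = 0, session_shift_sigma = 0)
  P <- make_prototypes(cfg0)
  s1 <- derive_subject(P, 1, cfg0)
  expect_equal(s1$activation, P, tolerance = 1e-12)
  expect_equal(s1$channel_gain, rep(1, 8))
  expect_equal(s1$electrode_offset, 0)

  cfg <- tiny_config()
  P2 <- make_prototypes(cfg)
  a <- derive_subject(P2, 1, cfg)
  b <- derive_subject(P2, 2, cfg)
  expect_false(isTRUE(all.equal(a$activation, b$activation)))
  expect_equal(a$electrode_offset[1], 0)  # session 1 is the reference
  expect_equal(unname(apply(a$activation, 1, max)), rep(1, 3))
})

test_that("session synthesis obeys the block and label structure", {
  cfg <- generator_config(n_subjects = 1, n_sessions = 1, n_gestures = 1,
                          n_repetitions = 1, n_channels = 2, fs = 2000,
                          movement_s = 5, rest_s = 3, seed = 9)
  rec <- synthesize_session(derive_subject(make_prototypes(cfg), 1, cfg),
                            1, cfg)
  expect_equal(nrow(rec$emg), 16000)            # (5 + 3) s at 2 kHz
  expect_equal(sum(rec$label == 1), 10000)      # movement samples
  expect_identical(rec$label == 0, rec$repetition == 0)

  cfg2 <- tiny_config(n_gestures = 2, n_repetitions = 3)
  rec2 <- synthesize_session(derive_subject(make_prototypes(cfg2), 1, cfg2),
                             1, cfg2)
  for (g in 1:2) {
    expect_equal(sum(rec2$label == g),
                 3 * round(cfg2$movement_s * cfg2$fs))
  }
  # each (gesture, repetition) pair is one contiguous movement block
  for (g in 1:2) {
    for (r in 1:3) {
      idx <- which(rec2$label == g & rec2$repetition == r)
      expect_equal(idx, seq(min(idx), max(idx)))
    }
  }
})

test_that("zero activation with no noise yields a silent recording", {
  cfg <- tiny_config(noise_floor = 0, interference_amp = 0, noise_sigma = 0)
  subj <- derive_subject(make_prototypes(cfg), 1, cfg)
  subj$activation[] <- 0
  rec <- synthesize_session(subj, 1, cfg)
  expect_equal(max(abs(rec$emg)), 0)
})

test_that("power-line interference shows up as a 50 Hz spectral peak", {
  cfg <- tiny_config(interference_amp = 0.5)
  rec <- synthesize_session(derive_subject(make_prototypes(cfg), 1, cfg),
                            1, cfg)
  x <- rec$emg[, 1]
  n <- length(x)
  p <- Mod(fft(x))[2:(n %/% 2)]^2
  freq <- (1:(n %/% 2 - 1)) * cfg$fs / n
  bin50 <- which.min(abs(freq - 50))
  win <- p[(bin50 - 25):(bin50 + 25)]
  expect_equal(which.max(win), 26, tolerance = 1)  # local max at 50 Hz +- 1 bin
})

test_that("identical config and seed give bit-identical recordings", {
  cfg <- tiny_config(seed = 21)
  d1 <- synthesize_dataset(cfg)
  d2 <- synthesize_dataset(cfg)
  expect_identical(d1, d2)
})

test_that("session shift dial increases inter-session activation distance", {
  mean_l2 <- function(sigma) {
    d <- vapply(1:20, function(s) {
      cfg <- tiny_config(n_sessions = 2, session_shift_sigma = sigma,
                         seed = 100 + s)
      subj <- derive_subject(make_prototypes(cfg), 1, cfg)
      A1 <- shift_activation(subj$activation, subj$electrode_offset[1])
      A2 <- shift_activation(subj$activation, subj$electrode_offset[2])
      sqrt(sum((A1 - A2)^2))
    }, numeric(1))
    mean(d)
  }
  d0 <- mean_l2(0)
  d1 <- mean_l2(0.25)
  d2 <- mean_l2(0.75)
  expect_equal(d0, 0)
  expect_gt(d1, d0)
  expect_gt(d2, d1)
})

test_that("a forest separates gestures within one session without shift", {
  cfg <- tiny_config(n_gestures = 4, subject_sigma = 0, subject_rot = 0,
                     session_shift_sigma = 0, gain_sigma = 0, noise_sigma = 0,
                     rep_sigma = 0, noise_floor = 0.05, seed = 31)
  rec <- synthesize_session(derive_subject(make_prototypes(cfg), 1, cfg),
                            1, cfg)
  feats <- extract_features(rec)
  train <- features_at_rep(feats, c(1, 3, 4, 6))
  test <- features_at_rep(feats, c(2, 5))
  fit <- train_forest(train$X, train$y, classes = 0:4, n_trees = 100,
                      seed = 1)
  acc <- balanced_accuracy(test$y, predict(fit, test$X))
  expect_gte(acc, 0.9)
})
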