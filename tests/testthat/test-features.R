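# Signal conditioning and windowed feature extraction.

make_recording <- function(emg, fs = 1000, label = NULL, repetition = NULL) {
  n <- nrow(emg)
  emgadapt:::new_recording(emg, label %||% integer(n),
                           repetition %||% integer(n),
                           subject_id = 1, session_id = 1, fs = fs)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("hampel filter removes a power-line tone and little else", {
  expect_equal(hampel_powerline(matrix(0, 1000, 2), 1000),
               matrix(0, 1000, 2))

  set.seed(1)
  fs <- 1000
  n <- 8000
  t <- (0:(n - 1)) / fs
  noise <- rnorm(n)
  x <- noise + 4 * sin(2 * pi * 50 * t + 0.3)
  y <- hampel_powerline(matrix(x, ncol = 1), fs)[, 1]
  band_power <- function(z) {
    p <- Mod(fft(z))^2
    f <- (0:(n - 1)) * fs / n
    sum(p[f >= 49 & f <= 51])
  }
  expect_lt(band_power(y), 0.1 * band_power(x))  # >= 90% reduction

  # white noise alone passes through nearly untouched
  y2 <- hampel_powerline(matrix(noise, ncol = 1), fs)[, 1]
  expect_lt(sqrt(mean((y2 - noise)^2)) / sqrt(mean(noise^2)), 0.05)

  expect_error(hampel_powerline(matrix(noise, ncol = 1), fs,
                                n_harmonics = 12), "Nyquist")
})

test_that("standardization uses training statistics only", {
  set.seed(2)
  A <- matrix(rnorm(4000, mean = 3, sd = 2), ncol = 4)
  Z <- standardize(A, A)
  expect_equal(unname(colMeans(Z)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 4), tolerance = 1e-9)

  const <- cbind(A[, 1], 5)
  expect_equal(standardize(const, const)[, 2], rep(0, 1000))

  B <- 2 * A  # doubled gain in the applied session
  expect_equal(unname(apply(standardize(A, B), 2, sd)), rep(2, 4),
               tolerance = 1e-9)
  expect_error(standardize(A[0, , drop = FALSE], A), "empty")
})

test_that("window counts follow floor((n - W)/S) + 1", {
  rec <- make_recording(matrix(rnorm(20000), ncol = 2), fs = 2000)
  w <- sliding_windows(rec)  # W = 400, S = 20
  expect_equal(w$n_windows, 481)

  rec2 <- make_recording(matrix(rnorm(400), ncol = 2), fs = 1000)
  expect_equal(sliding_windows(rec2)$n_windows, 1)  # n == W exactly
  rec3 <- make_recording(matrix(rnorm(100), ncol = 2), fs = 1000)
  expect_equal(sliding_windows(rec3)$n_windows, 0)

  for (case in list(c(5000, 1000), c(7777, 1000), c(12345, 2000))) {
    n <- case[1]; fs <- case[2]
    W <- round(200 * fs / 1000); S <- round(10 * fs / 1000)
    rec <- make_recording(matrix(0, n, 1), fs = fs)
    expect_equal(sliding_windows(rec)$n_windows,
                 if (n >= W) floor((n - W) / S) + 1 else 0)
  }
})

test_that("window labels are majority votes with ties to rest", {
  lab <- c(rep(1L, 200), rep(0L, 200))
  rec <- make_recording(matrix(0, 400, 1), fs = 2000, label = lab,
                        repetition = lab)
  w <- sliding_windows(rec)  # single 400-sample window, 200/200 split
  expect_equal(w$label, 0L)

  lab2 <- c(rep(2L, 300), rep(0L, 100))
  rec2 <- make_recording(matrix(0, 400, 1), fs = 2000, label = lab2,
                         repetition = lab2)
  expect_equal(sliding_windows(rec2)$label, 2L)
})

test_that("MAV and VAR match their definitions", {
  expect_equal(unname(mav(matrix(c(1, -1, 2, -2), 4, 1))), 1.5)
  expect_equal(unname(mav(matrix(0, 10, 3))), c(0, 0, 0))
  expect_error(mav(matrix(0, 0, 2)), "empty")

  expect_equal(unname(win_var(matrix(7, 5, 1))), 0)
  expect_equal(unname(win_var(matrix(c(1, -1, 1, -1), 4, 1))), 4 / 3)
  expect_error(win_var(matrix(1, 1, 2)), "2 samples")

  set.seed(3)
  Wm <- matrix(rnorm(800), 100, 8)
  expect_equal(mav(Wm), colMeans(abs(Wm)), tolerance = 1e-12)
  expect_equal(win_var(Wm), apply(Wm, 2, function(v) {
    sum((v - mean(v))^2) / (length(v) - 1)
  }), tolerance = 1e-10)
})

test_that("mDWT marginals match a direct cascade-convolution oracle", {
  filt <- emgadapt:::db_filters("db7")
  expect_equal(mdwt(matrix(0, 64, 2)), rep(0, 8))

  set.seed(4)
  x <- matrix(rnorm(128), 128, 1)
  m1 <- mdwt(x)
  expect_equal(mdwt(3.5 * x), 3.5 * m1, tolerance = 1e-10)  # homogeneity
  expect_true(all(m1 >= 0))

  imp <- matrix(0, 64, 1)
  imp[17, 1] <- 1
  expect_equal(mdwt(imp),
               oracle_mdwt_channel(imp[, 1], filt$lo, filt$hi, 3),
               tolerance = 1e-8)
  x2 <- matrix(rnorm(200), 200, 1)
  expect_equal(mdwt(x2),
               oracle_mdwt_channel(x2[, 1], filt$lo, filt$hi, 3),
               tolerance = 1e-8)

  expect_error(mdwt(matrix(0, 8, 1)), "support")
  expect_error(mdwt(matrix(0, 16, 1), levels = 6), "levels")
})

test_that("feature extraction has the documented layout and dimensions", {
  cfg <- tiny_config(seed = 11)
  rec <- synthesize_session(derive_subject(make_prototypes(cfg), 1, cfg),
                            1, cfg)
  f <- extract_features(rec)
  expect_equal(ncol(f$X), 8 * (2 + 4))  # C * (2 + levels + 1) = 48
  expect_equal(f$feature_names[1:2], c("mav_ch1", "mav_ch2"))
  expect_equal(f$feature_names[17], "mdwt_ch1_d1")
  expect_false(anyNA(f$X))
  expect_true(all(f$X[, grepl("mdwt|var|mav", f$feature_names)] >= 0))
  expect_identical(extract_features(rec)$X, f$X)  # deterministic

  rest <- rec
  rest$label[] <- 0L
  rest$repetition[] <- 0L
  expect_true(all(extract_features(rest)$y == 0))
})

test_that("feature extraction commutes with channel permutation", {
  cfg <- tiny_config(seed = 12)
  rec <- synthesize_session(derive_subject(make_prototypes(cfg), 1, cfg),
                            1, cfg)
  rec$emg <- rec$emg[1:3000, ]
  rec$label <- rec$label[1:3000]
  rec$repetition <- rec$repetition[1:3000]
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  rec_p <- rec
  rec_p$emg <- rec$emg[, perm]
  f <- extract_features(rec)
  fp <- extract_features(rec_p)
  col_perm <- c(perm, 8 + perm,
                as.vector(vapply(perm, function(ch) 16 + (ch - 1) * 4 + 1:4,
                                 numeric(4))))
  expect_equal(unname(fp$X), unname(f$X[, col_perm]), tolerance = 1e-12)
})

test_that("training subsampling keeps every factor-th row", {
  cfg <- tiny_config(seed = 13)
  rec <- synthesize_session(derive_subject(make_prototypes(cfg), 1, cfg),
                            1, cfg)
  f <- extract_features(rec)
  n <- nrow(f$X)
  s10 <- subsample_train(f, 10)
  expect_equal(nrow(s10$X), ceiling(n / 10))
  expect_equal(s10$X[2, ], f$X[11, ])
  expect_identical(subsample_train(f, 1)$X, f$X)

  f101 <- emgadapt:::features_subset(f, 1:101)
  expect_equal(nrow(subsample_train(f101, 10)$X), 11)
})

test_that("coarse-step extraction equals extract-then-subsample", {
  cfg <- tiny_config(seed = 14)
  rec <- synthesize_session(derive_subject(make_prototypes(cfg), 1, cfg),
                            1, cfg)
  a <- subsample_train(extract_features(rec, step_ms = 10), 10)
  b <- extract_features(rec, step_ms = 100)
  expect_equal(a$X, b$X)
  expect_equal(a$y, b$y)
  expect_equal(a$repetition, b$repetition)
})
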