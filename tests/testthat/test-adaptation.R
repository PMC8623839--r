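# SER / STRUT tree surgery, threshold selection and the voting ensembles.

# two-class source tree on a 1-D feature, trained on separable data
blob_data <- function(n_per, shift = 0, seed = 1, sd = 0.5) {
  set.seed(seed)
  X <- cbind(c(rnorm(n_per, 0, sd), rnorm(n_per, 4, sd)) + shift,
             rnorm(2 * n_per))
  list(X = X, y = rep(0:1, each = n_per))
}

test_that("divergence gain is calibrated at its extremes", {
  # a candidate inducing exactly the source child distributions has DG = 1
  values <- c(1, 2, 3, 4)
  labels <- c(0, 0, 1, 1)
  res <- select_threshold(values, labels, QL = c(1, 0), QR = c(0, 1))
  expect_equal(res$dg, 1, tolerance = 1e-12)
  expect_equal(res$threshold, 2.5)
  expect_equal(res$ig, res$ig_max, tolerance = 1e-12)

  # flipped child distributions are maximally divergent: DG = 0
  i <- which(abs(res$candidates - 2.5) < 1e-9)
  res2 <- select_threshold(values, labels, QL = c(0, 1), QR = c(1, 0))
  expect_equal(res2$candidate_dg[i], 0, tolerance = 1e-12)

  expect_error(select_threshold(rep(2, 5), c(0, 0, 1, 1, 0),
                                QL = c(1, 0), QR = c(0, 1)), "identical")
})

test_that("selected threshold maximizes DG over the admissible set", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(10:60, 1)
    K <- sample(2:4, 1)
    values <- sample(1:12, n, replace = TRUE)
    labels <- sample(0:(K - 1), n, replace = TRUE)
    if (length(unique(values)) < 2) next
    QL <- as.numeric(stats::rmultinom(1, 20, rep(1, K))) / 20
    QR <- as.numeric(stats::rmultinom(1, 20, rep(1, K))) / 20
    res <- select_threshold(values, labels, QL, QR)
    orc <- oracle_dg_scan(values, labels, K, QL, QR)
    expect_equal(res$candidates, orc$cand, tolerance = 1e-12)
    expect_equal(res$candidate_ig, orc$ig, tolerance = 1e-10)
    # returned optimum equals the brute-force maximum over admissible
    # candidates, and no admissible candidate beats it
    adm_dg <- orc$dg[res$admissible]
    expect_equal(res$dg, max(adm_dg), tolerance = 1e-10)
    expect_true(all(adm_dg <= res$dg + 1e-10))
  }
})

test_that("SER leaves a perfectly-fitting tree structurally unchanged", {
  d <- blob_data(40)
  src <- induce_tree(d$X, d$y, classes = 0:1)
  adapted <- ser_tree(src, d$X, d$y)
  expect_equal(adapted$feature, src$feature)
  expect_equal(adapted$threshold, src$threshold)
  expect_equal(mean(predict(adapted, d$X) != d$y), 0)
})

test_that("SER expansion grows a working tree out of a single leaf", {
  leaf <- new_emg_tree(0L, 0, 0L, 0L, matrix(c(10, 2), 1), 0:1)
  d <- blob_data(30, seed = 2)
  adapted <- ser_tree(leaf, d$X, d$y)
  expect_gt(length(adapted$feature), 1)
  expect_equal(mean(predict(adapted, d$X) != d$y), 0)
  expect_error(ser_tree(leaf, d$X[0, , drop = FALSE], integer(0)),
               "non-empty")
})

test_that("SER replaces reached leaf counts with target counts and keeps source counts elsewhere", {
  # stump at 1.5; target data reaches only the left branch
  stump <- new_emg_tree(c(1L, 0L, 0L), c(1.5, 0, 0), c(2L, 0L, 0L),
                        c(3L, 0L, 0L),
                        matrix(c(6, 6, 5, 1, 1, 5), 3, 2, byrow = TRUE), 0:1)
  X_T <- matrix(c(0, 1, 1, 0), 4, 1)
  X_T <- cbind(X_T, 0)
  y_T <- c(1, 1, 1, 0)
  adapted <- ser_tree(stump, X_T, y_T)
  expect_equal(adapted$feature[1], 1L)
  right_leaf <- adapted$right[1]
  expect_equal(adapted$counts[right_leaf, ], c(1, 5))  # untouched source
  left_root <- adapted$left[1]
  left_nodes <- setdiff(seq_along(adapted$feature), c(1, right_leaf))
  expect_equal(sum(adapted$counts[left_root, ]), 4)    # target counts
})

test_that("post-SER audit: subtree error never exceeds leaf error", {
  for (seed in 1:5) {
    d0 <- random_cart_dataset(seed)
    dT <- random_cart_dataset(seed + 100)
    dcom <- min(ncol(d0$X), ncol(dT$X))
    K <- max(length(d0$classes), length(dT$classes))
    src <- induce_tree(d0$X[, 1:dcom, drop = FALSE],
                       d0$y %% K, classes = 0:(K - 1))
    XT <- dT$X[, 1:dcom, drop = FALSE]
    yT <- dT$y %% K
    adapted <- ser_tree(src, XT, yT)
    mem <- route(adapted, XT)
    pred <- predict(adapted, XT)
    worst <- -Inf
    for (v in which(adapted$feature != 0L)) {
      rows <- mem[[v]]
      if (length(rows) == 0) next
      e_s <- mean(pred[rows] != yT[rows])
      maj <- (0:(K - 1))[which.max(tabulate(yT[rows] + 1, K))]
      e_l <- mean(yT[rows] != maj)
      worst <- max(worst, e_s - e_l)
    }
    expect_lte(worst, 1e-12)
  }
})

test_that("STRUT on identical data recovers IG-maximal thresholds", {
  d <- blob_data(50, seed = 3)
  src <- induce_tree(d$X, d$y, classes = 0:1)
  adapted <- strut_tree(src, d$X, d$y)
  ig <- attr(adapted, "diag_ig")
  igm <- attr(adapted, "diag_ig_max")
  ok <- !is.na(ig)
  expect_true(any(ok))
  expect_equal(ig[ok], igm[ok], tolerance = 1e-9)
  expect_equal(mean(predict(adapted, d$X) != d$y),
               mean(predict(src, d$X) != d$y), tolerance = 0.01)
})

test_that("STRUT restores a covariate-shifted stump threshold", {
  d <- blob_data(60, seed = 4)
  src <- induce_tree(d$X, d$y, classes = 0:1)
  shift <- 3
  d_shift <- blob_data(60, shift = shift, seed = 5)
  adapted <- strut_tree(src, d_shift$X, d_shift$y)
  # root threshold moves by about the shift (within one inter-sample gap)
  gap <- max(diff(sort(d_shift$X[, 1])))
  expect_lt(abs(adapted$threshold[1] - (src$threshold[1] + shift)), gap + 0.2)
  expect_lte(mean(predict(adapted, d_shift$X) != d_shift$y), 0.02)
})

test_that("STRUT prunes branches the target cannot reach", {
  # root splits feature 1; its right child splits feature 2; target rows all
  # share one value of feature 2, so that node cannot separate them and is
  # contracted away
  tr <- new_emg_tree(feature = c(1L, 0L, 2L, 0L, 0L),
                     threshold = c(0.5, 0, 0.5, 0, 0),
                     left = c(2L, 0L, 4L, 0L, 0L),
                     right = c(3L, 0L, 5L, 0L, 0L),
                     counts = matrix(c(4, 4, 4, 0, 0, 4, 0, 2, 0, 2),
                                     5, 2, byrow = TRUE),
                     classes = 0:1)
  X_T <- cbind(c(0, 0, 1, 1, 1, 1), c(0, 0, 0, 0, 0, 0))
  y_T <- c(0, 0, 1, 1, 0, 1)
  adapted <- strut_tree(tr, X_T, y_T)
  expect_false(2L %in% adapted$feature)  # feature-2 node contracted
  expect_lt(length(adapted$feature), 5)
})

test_that("forest adaptation is per-tree, order-independent and pure", {
  d <- blob_data(40, seed = 6)
  src <- train_forest(d$X, d$y, n_trees = 8, seed = 7)
  src_snapshot <- unserialize(serialize(src, NULL))
  dT <- blob_data(25, shift = 1, seed = 8)

  fser <- ser_forest(src, dT$X, dT$y)
  fstrut <- strut_forest(src, dT$X, dT$y)
  expect_identical(src, src_snapshot)  # source forests never mutated
  expect_equal(length(fser$trees), 8)
  expect_equal(length(fstrut$trees), 8)

  # per-tree independence: adapting each tree alone gives the same result
  solo <- lapply(src$trees, ser_tree, X_T = dT$X, y_T = dT$y)
  expect_equal(fser$trees, solo)

  # SER never increases the forest's target training error
  expect_lte(forest_error(fser, dT$X, dT$y),
             forest_error(src, dT$X, dT$y) + 1e-12)
})

test_that("MIX and vote_union pool trees with the majority tie rule", {
  d <- blob_data(40, seed = 9)
  f1 <- train_forest(d$X, d$y, n_trees = 5, seed = 1)
  f2 <- train_forest(d$X, d$y, n_trees = 5, seed = 2)
  u <- vote_union(f1, f2)
  expect_equal(u$n_trees, 10)
  expect_equal(mix_forests(f1, f2)$n_trees, 10)
  m3 <- vote_union(u, f1)
  expect_equal(m3$n_trees, 15)

  # identical inputs predict like either input
  uu <- vote_union(f1, f1)
  probe <- matrix(rnorm(40), 20, 2)
  expect_identical(predict(uu, probe), predict(f1, probe))

  # agreement set: where both forests agree, the union agrees
  p1 <- predict(f1, probe)
  p2 <- predict(f2, probe)
  pu <- predict(u, probe)
  agree <- p1 == p2
  expect_identical(pu[agree], p1[agree])

  # explicit vote-count oracle with hand-built leaf trees
  leaf_tree <- function(counts) {
    new_emg_tree(0L, 0, 0L, 0L, matrix(counts, 1), 0:1)
  }
  fa <- structure(list(trees = replicate(3, leaf_tree(c(1, 0)),
                                         simplify = FALSE),
                       classes = 0:1, n_trees = 3L, d = 2L),
                  class = "emg_forest")
  fb <- structure(list(trees = replicate(2, leaf_tree(c(0, 1)),
                                         simplify = FALSE),
                       classes = 0:1, n_trees = 2L, d = 2L),
                  class = "emg_forest")
  X <- matrix(0, 4, 2)
  expect_equal(predict(vote_union(fa, fb), X), rep(0, 4))  # 3 vs 2
  fb3 <- structure(list(trees = c(fb$trees, fb$trees[1]), classes = 0:1,
                        n_trees = 3L, d = 2L), class = "emg_forest")
  expect_equal(predict(vote_union(fa, fb3), X), rep(0, 4))  # 3 vs 3 tie -> 0

  fc <- structure(list(trees = fb$trees, classes = c(0, 2), n_trees = 2L,
                       d = 2L), class = "emg_forest")
  expect_error(vote_union(fa, fc), "class sets")
})
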