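# Experiment protocols: splits, repetition folds, the eight-method grid and
# the leakage audit.

small_dataset <- function(seed = 1, n_subjects = 3, n_sessions = 1, ...) {
  synthesize_dataset(tiny_config(n_subjects = n_subjects,
                                 n_sessions = n_sessions, seed = seed, ...))
}

small_spec <- function(...) {
  args <- list(target_subject = 2, n_trees = 20, seed = 5)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(experiment_spec, args)
}

test_that("experiment specs validate repetition disjointness and methods", {
  expect_error(experiment_spec(train_repetitions = c(1, 2),
                               test_repetitions = c(2, 5)), "disjoint")
  expect_error(experiment_spec(methods = "bagging"), "unknown method")
  expect_s3_class(small_spec(), "emg_experiment_spec")
})

test_that("rest periods inherit the preceding movement repetition", {
  r <- c(0L, 1L, 1L, 0L, 0L, 2L, 0L, 3L, 3L, 0L)
  expect_equal(carry_forward_repetition(r),
               c(0L, 1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L))
})

test_that("the split isolates the target and keeps repetitions disjoint", {
  ds <- small_dataset()
  spec <- small_spec()
  split <- split_source_target(ds, spec)
  expect_setequal(unique(split$source$subject), c(1, 3))
  expect_setequal(unique(split$target_train$repetition), c(1, 3, 4, 6))
  expect_setequal(unique(split$target_test$repetition), c(2, 5))
  expect_length(intersect(unique(split$target_train$repetition),
                          unique(split$target_test$repetition)), 0)
  expect_true(leakage_audit(split)$ok)

  expect_error(split_source_target(ds, small_spec(test_repetitions = 9)),
               "absent")
})

test_that("target training windows are restricted then subsampled", {
  ds <- small_dataset()
  spec <- small_spec()
  split <- split_source_target(ds, spec)
  # honest path: full-rate extraction, restriction, then stride subsampling
  rec <- ds[["s2_sess1"]]
  rep_eff <- carry_forward_repetition(rec$repetition)
  std_rows <- which(rep_eff %in% spec$train_repetitions)
  emg_h <- hampel_powerline(rec$emg, rec$fs)
  std <- standardizer_fit(emg_h[std_rows, , drop = FALSE])
  full <- extract_features(rec, hampel = TRUE, standardizer = std,
                           repetition = rep_eff)
  restricted <- features_at_rep(full, spec$train_repetitions)
  honest <- subsample_train(restricted, 10)
  expect_equal(unname(split$target_train$X), unname(honest$X),
               tolerance = 1e-12)
  expect_equal(split$target_train$y, honest$y)
  expect_equal(nrow(split$target_train$X), ceiling(nrow(restricted$X) / 10))
  # test windows stay at the full window rate
  test_full <- features_at_rep(full, spec$test_repetitions)
  expect_equal(nrow(split$target_test$X), nrow(test_full$X))
})

test_that("multi-session inter-subject splits include the target's other sessions", {
  ds <- small_dataset(n_subjects = 2, n_sessions = 2)
  spec <- small_spec(target_session = 2)
  split <- split_source_target(ds, spec)
  src_pairs <- unique(paste(split$source$subject, split$source$session))
  expect_setequal(src_pairs, c("1 1", "1 2", "2 1"))

  intra <- small_spec(mode = "intra_subject", target_session = 2)
  split2 <- split_source_target(ds, intra)
  expect_setequal(unique(paste(split2$source$subject,
                               split2$source$session)), "2 1")
})

test_that("leakage audit flags overlapping triples", {
  ds <- small_dataset()
  split <- split_source_target(ds, small_spec())
  bad <- split
  bad$target_train <- split$target_test  # inject test windows into training
  expect_false(leakage_audit(bad)$ok)
  expect_gt(length(leakage_audit(bad)$overlap), 0)
})

test_that("k-fold by repetition partitions labeled windows", {
  ds <- small_dataset()
  f <- split_source_target(ds, small_spec())$target_train
  folds <- kfold_by_repetition(f)
  expect_length(folds, 4)
  val_all <- sort(unname(unlist(lapply(folds, `[[`, "validation"))))
  expect_equal(val_all, which(f$repetition > 0))
  for (r in names(folds)) {
    expect_setequal(f$repetition[folds[[r]]$validation], as.integer(r))
    expect_length(intersect(folds[[r]]$train, folds[[r]]$validation), 0)
  }
  one_rep <- features_at_rep(f, 1)
  expect_error(kfold_by_repetition(one_rep), "at least 2")
})

test_that("run_experiment produces a complete deterministic grid", {
  ds <- small_dataset()
  spec <- small_spec()
  tab <- run_experiment(ds, spec)
  expect_s3_class(tab, "emg_experiment_table")
  expect_equal(nrow(tab), 8 * 4)  # methods x repetition sweep
  expect_true(all(tab$balanced_accuracy >= 0 & tab$balanced_accuracy <= 1))
  expect_equal(length(unique(tab$balanced_accuracy[
    tab$method == "source_only"])), 1)  # flat by construction

  tab2 <- run_experiment(ds, spec)
  expect_identical(tab, tab2)
})

test_that("identical source and target domains make transfer benign", {
  # all shift dials at zero: every subject/session is an i.i.d. draw from one
  # domain, so source-only is competitive and no adapted forest falls far
  # below it
  accs <- lapply(1:4, function(s) {
    ds <- small_dataset(seed = 200 + s, subject_sigma = 0, subject_rot = 0,
                        session_shift_sigma = 0, gain_sigma = 0,
                        noise_sigma = 0, noise_floor = 0.3, rep_sigma = 0.2)
    run_experiment(ds, small_spec(seed = s))
  })
  tab <- do.call(rbind, accs)
  s <- summarize_experiment(tab)
  pick <- function(m, k) {
    s$mean_balanced_accuracy[s$method == m & s$n_target_reps == k]
  }
  expect_lte(abs(pick("source_only", 4) - pick("target_only", 4)), 0.05)
  for (m in c("ser", "strut", "mix")) {
    expect_gte(mean(vapply(1:4, function(k) pick(m, k), numeric(1))),
               mean(vapply(1:4, function(k) pick("source_only", k),
                           numeric(1))) - 0.03)
  }
})

test_that("strong domain shift collapses direct source transfer", {
  ds <- small_dataset(seed = 300, subject_sigma = 2, subject_rot = 2,
                      session_shift_sigma = 1.5, noise_sigma = 1.2)
  tab <- run_experiment(ds, small_spec(seed = 17,
                                       methods = c("source_only",
                                                   "target_only")))
  src <- tab$balanced_accuracy[tab$method == "source_only"][1]
  tgt <- tab$balanced_accuracy[tab$method == "target_only" &
                                 tab$n_target_reps == 4]
  expect_lt(src, 0.5 * tgt)
})

test_that("leave-one-target-out covers every subject and aggregates means", {
  ds <- small_dataset()
  spec <- small_spec(methods = c("source_only", "target_only"))
  tabs <- leave_one_target_out(ds, spec)
  expect_length(tabs, 3)
  expect_setequal(vapply(tabs, function(t) t$target_id[1], character(1)),
                  c("1", "2", "3"))
  s <- attr(tabs, "summary")
  cell <- s$mean_balanced_accuracy[s$method == "target_only" &
                                     s$n_target_reps == 2]
  manual <- mean(vapply(tabs, function(t) {
    t$balanced_accuracy[t$method == "target_only" & t$n_target_reps == 2]
  }, numeric(1)))
  expect_equal(cell, manual)

  # subject order in the dataset list does not change the aggregate
  tabs2 <- leave_one_target_out(rev(ds), spec)
  expect_equal(attr(tabs2, "summary"), s)
})
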