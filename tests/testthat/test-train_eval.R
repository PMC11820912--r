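test_that("subject-wise split partitions subjects at the requested ratio", {
  segs <- toy_segments(n_subjects = 10L, per_subject = 3L)
  sp <- split_by_subject(segs, 0.8, seed = 1)
  expect_equal(length(sp$train_subjects), 8L)
  expect_equal(length(sp$test_subjects), 2L)
  expect_equal(length(intersect(sp$train_subjects, sp$test_subjects)), 0L)
  expect_equal(length(sp$train) + length(sp$test), length(segs))

  # same seed -> identical split; different seed -> different assignment
  sp2 <- split_by_subject(segs, 0.8, seed = 1)
  expect_identical(sp$train_subjects, sp2$train_subjects)
  alt <- vapply(2:20, function(s) {
    !setequal(split_by_subject(segs, 0.8, seed = s)$test_subjects,
              sp$test_subjects)
  }, logical(1))
  expect_true(any(alt))
})

test_that("learning rate decays linearly from lr0 to zero", {
  tc <- train_config(lr0 = 1e-3, max_epochs = 100L)
  expect_equal(lr_schedule(0, tc), 1e-3)
  expect_equal(lr_schedule(50, tc), 5e-4)
  expect_equal(lr_schedule(100, tc), 0)
})

test_that("early stopping fires exactly at patience on a flat trace", {
  trace <- c(0.5, rep(0.6, 11))
  st <- stopping_epoch(trace, patience = 10L)
  expect_equal(st$stop_epoch, 12L)
  expect_equal(st$best_epoch, 2L)
  # an improving trace never triggers
  st2 <- stopping_epoch(seq(0.1, 0.9, length.out = 20), patience = 10L)
  expect_equal(st2$stop_epoch, 20L)
  expect_equal(st2$best_epoch, 20L)
})

test_that("training histories are bit-identical under a shared seed", {
  segs <- toy_segments(n_subjects = 5L, per_subject = 4L, T = 24L)
  cfg <- micro_model_config(2L, dropout = 0.2)
  tc <- micro_train_config(seed = 9L, max_epochs = 4L)
  f1 <- train(cfg, tc, segs, "panas_binary")
  f2 <- train(cfg, tc, segs, "panas_binary")
  expect_identical(f1$history, f2$history)
  expect_identical(flatten_params(f1$params), flatten_params(f2$params))
  f3 <- train(cfg, micro_train_config(seed = 10L, max_epochs = 4L), segs,
              "panas_binary")
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("evaluation metrics match hand-computed values", {
  # binary confusion [[2,0],[1,1]] (rows = truth)
  r <- evaluate_predictions(truth = c(1, 1, 2, 2), pred = c(1, 1, 1, 2),
                            n_classes = 2)
  expect_equal(r$accuracy, 75.0)
  expect_equal(r$macro_precision, mean(c(2 / 3, 1)) * 100, tolerance = 1e-10)
  expect_equal(r$macro_f1, mean(c(0.8, 2 / 3)) * 100, tolerance = 1e-10)
  expect_equal(round(r$macro_precision, 2), 83.33)
  expect_equal(round(r$macro_f1, 2), 73.33)

  # all-one-class predictor on balanced binary data
  r2 <- suppressWarnings(
    evaluate_predictions(truth = c(1, 1, 2, 2), pred = c(1, 1, 1, 1),
                         n_classes = 2))
  expect_equal(r2$accuracy, 50)
  expect_equal(r2$macro_f1, mean(c(2 / 3, 0)) * 100, tolerance = 1e-10)
  expect_equal(round(r2$macro_f1, 2), 33.33)
  # the never-predicted class is skipped in macro precision (with warning),
  # or scored zero under the alternative convention
  expect_warning(evaluate_predictions(c(1, 1, 2, 2), c(1, 1, 1, 1), 2),
                 "never predicted")
  r2z <- evaluate_predictions(c(1, 1, 2, 2), c(1, 1, 1, 1), 2,
                              na_class = "zero")
  expect_equal(r2z$macro_precision, 25)

  # perfect predictions
  r3 <- evaluate_predictions(1:5, 1:5, 5)
  expect_equal(r3$accuracy, 100)
  expect_equal(r3$macro_f1, 100)
  expect_equal(r3$confusion, diag(5), ignore_attr = TRUE)
})

test_that("metrics equal brute-force per-class computation on random pairs", {
  brute <- function(truth, pred, C) {
    acc <- mean(truth == pred)
    prec <- rec <- f1 <- rep(NA_real_, C)
    for (k in seq_len(C)) {
      tp <- sum(truth == k & pred == k)
      fp <- sum(truth != k & pred == k)
      fn <- sum(truth == k & pred != k)
      prec[k] <- if (tp + fp > 0) tp / (tp + fp) else NA
      rec[k] <- if (tp + fn > 0) tp / (tp + fn) else NA
      p0 <- if (is.na(prec[k])) 0 else prec[k]
      r0 <- if (is.na(rec[k])) 0 else rec[k]
      f1[k] <- if (is.na(prec[k]) && is.na(rec[k])) NA
               else if (p0 + r0 > 0) 2 * p0 * r0 / (p0 + r0) else 0
    }
    present <- vapply(seq_len(C), function(k) any(truth == k) || any(pred == k),
                      logical(1))
    list(acc = 100 * acc,
         mp = 100 * mean(prec[present], na.rm = TRUE),
         mf = 100 * mean(f1[present], na.rm = TRUE))
  }
  set.seed(77)
  for (i in 1:200) {
    C <- sample(2:5, 1)
    n <- sample(5:60, 1)
    truth <- sample(seq_len(C), n, replace = TRUE)
    pred <- sample(seq_len(C), n, replace = TRUE)
    r <- suppressWarnings(evaluate_predictions(truth, pred, C))
    b <- brute(truth, pred, C)
    expect_equal(r$accuracy, b$acc)
    expect_equal(r$macro_precision, b$mp)
    expect_equal(r$macro_f1, b$mf)
    # consistency: accuracy recomputed from the confusion counts
    expect_equal(sum(diag(r$counts)) / sum(r$counts) * 100, r$accuracy)
    # row-normalised confusion rows sum to 1 for observed true classes
    rs <- rowSums(r$counts) > 0
    expect_equal(unname(rowSums(r$confusion)[rs]), rep(1, sum(rs)))
  }
})

test_that("ablation runner covers all 7 modality subsets per task in order", {
  segs <- toy_segments(n_subjects = 6L, per_subject = 4L, T = 24L)
  tab <- suppressWarnings(
    run_modality_ablation(segs, c("panas_binary", "valence_binary",
                                  "arousal_binary"),
                          micro_model_config(2L), micro_train_config(),
                          split_seed = 3))
  expect_equal(nrow(tab), 21L)
  # declared row order: HR, GSR, ACCEL, HR+GSR, GSR+ACCEL, HR+ACCEL, all
  first7 <- tab[tab$task == "panas_binary", c("hr", "gsr", "accel")]
  expect_equal(unname(as.matrix(first7)),
               matrix(c(TRUE, FALSE, FALSE,
                        FALSE, TRUE, FALSE,
                        FALSE, FALSE, TRUE,
                        TRUE, TRUE, FALSE,
                        FALSE, TRUE, TRUE,
                        TRUE, FALSE, TRUE,
                        TRUE, TRUE, TRUE), 7, 3, byrow = TRUE))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 100))
})

test_that("ablation recovers a planted single-modality effect", {
  # only HR carries class signal; HR-containing subsets must clearly beat
  # the ACCEL-only model
  segs <- toy_segments(n_subjects = 8L, per_subject = 8L, T = 40L, shift = 2,
                       channels = "HR", seed = 5)
  tab <- suppressWarnings(
    run_modality_ablation(segs, "panas_binary", micro_model_config(2L),
                          micro_train_config(seed = 5, max_epochs = 30L),
                          split_seed = 5))
  hr_rows <- tab$hr
  accel_only <- !tab$hr & !tab$gsr & tab$accel
  expect_gt(min(tab$accuracy[hr_rows]) - tab$accuracy[accel_only], 20)
})

test_that("grid runner crosses batch sizes and head counts on a shared split", {
  segs <- toy_segments(n_subjects = 6L, per_subject = 4L, T = 24L)
  tab <- suppressWarnings(
    run_grid(segs, batch_sizes = c(8, 16), inner_dims = c(2, 4),
             tasks = "panas_binary", micro_model_config(2L),
             micro_train_config(), split_seed = 4))
  expect_equal(nrow(tab), 4L)
  expect_setequal(paste(tab$batch_size, tab$inner_dim),
                  c("8 2", "8 4", "16 2", "16 4"))
  expect_true(all(c("accuracy", "macro_f1", "n_test") %in% names(tab)))
})
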