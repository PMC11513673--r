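fake_manifest <- function(counts) {
  do.call(rbind, lapply(names(counts), function(cl)
    data.frame(path = sprintf("%s_%03d.png", cl, seq_len(counts[[cl]])),
               label = cl,
               subject_id = sprintf("%s%02d", tolower(cl),
                                    rep(1:2, length.out = counts[[cl]])),
               record_index = seq_len(counts[[cl]]))))
}

test_that("task relabeling pools, excludes and preserves counts", {
  man <- fake_manifest(c(ALS = 2, HD = 2, PD = 2, CONTROL = 2))
  ndd <- apply_task(man, "NDD_VS_CONTROL")
  expect_equal(as.vector(attr(ndd, "counts")), c(6L, 2L))
  expect_setequal(unique(ndd$label), c("NDD", "CONTROL"))

  als <- apply_task(man, "ALS_VS_CONTROL")
  expect_equal(nrow(als), 4L)
  expect_false(any(als$subject_id %in% c("hd01", "pd01")))

  four <- apply_task(man, "FOUR_GROUP")
  expect_equal(four$label, man$label)  # identity relabeling

  # CLI aliases resolve to the same tasks
  expect_equal(task_spec("ndd")$task_id, "NDD_VS_CONTROL")
  expect_error(task_spec("alzheimer"))
})

test_that("record-mode folds partition the data with balanced class counts", {
  labels <- rep(c("A", "B", "C", "D"), each = 25)
  split <- stratified_folds(labels, k = 10, seed = 4)
  expect_equal(sort(unlist(lapply(1:10, function(f) which(split$fold == f)))),
               seq_along(labels))
  # 25 per class over 10 folds: every fold gets 2 or 3 of each class
  expect_true(all(split$counts %in% 2:3))
  # exact divisibility gives identical per-fold counts
  even <- stratified_folds(rep(c("A", "B"), each = 50), k = 10, seed = 4)
  expect_true(all(even$counts == 5L))

  again <- stratified_folds(labels, k = 10, seed = 4)
  expect_identical(split$fold, again$fold)
  other <- stratified_folds(labels, k = 10, seed = 5)
  expect_false(identical(split$fold, other$fold))
  expect_equal(other$counts, split$counts)  # same count profile

  expect_error(stratified_folds(rep(c("A", "B"), c(5, 50)), k = 10),
               "smallest class")
})

test_that("subject-mode folds keep each subject's records together", {
  labels <- rep(c("ALS", "CONTROL"), each = 40)
  subjects <- paste0(rep(c("a", "c"), each = 40), rep(rep(1:4, each = 10), 2))
  split <- stratified_folds(labels, k = 4, seed = 1, grouping = "subject",
                            subject_ids = subjects)
  per_subject <- tapply(split$fold, subjects, function(f) length(unique(f)))
  expect_true(all(per_subject == 1L))
  expect_equal(sort(unique(split$fold)), 1:4)
})

test_that("confusion counts reconstruct hand-built TP/FP/FN/TN", {
  # binary construction with TP=3, FP=1, FN=2, TN=4 (positive = "POS")
  true <- c(rep("POS", 5), rep("NEG", 5))
  pred <- c("POS", "POS", "POS", "NEG", "NEG", "POS", rep("NEG", 4))
  cm <- confusion(true, pred, c("POS", "NEG"))
  expect_equal(sum(cm), 10L)
  ovr <- attr(cm, "ovr")
  expect_equal(unname(ovr["POS", ]), c(3, 1, 2, 4))

  perfect <- confusion(c("A", "B", "C"), c("A", "B", "C"), c("A", "B", "C"))
  expect_true(all(perfect == diag(1, 3)))
  expect_error(confusion(c("A", "X"), c("A", "A"), c("A", "B")), "class_order")
})

test_that("the four metrics reproduce the hand-computed reference cases", {
  true <- c(rep("POS", 5), rep("NEG", 5))
  pred <- c("POS", "POS", "POS", "NEG", "NEG", "POS", rep("NEG", 4))
  cm <- confusion(true, pred, c("POS", "NEG"))
  m <- metrics(cm, positive = "POS")
  expect_equal(m$accuracy, 70.0)
  expect_equal(m$precision, 75.0)
  expect_equal(m$sensitivity, 60.0)
  expect_equal(m$f1, 66.67, tolerance = 1e-3)

  perfect <- metrics(confusion(true, true, c("POS", "NEG")), positive = "POS")
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$sensitivity,
                 perfect$f1), rep(100, 4))

  # all-one-class predictor on a balanced set: accuracy 50, one sensitivity 0
  degenerate <- suppressWarnings(
    metrics(confusion(true, rep("POS", 10), c("POS", "NEG"))))
  expect_equal(degenerate$accuracy, 50)
  expect_equal(degenerate$per_class$sensitivity[2], 0)
  expect_warning(metrics(confusion(true, rep("POS", 10), c("POS", "NEG"))),
                 "zero denominator")
})

test_that("metrics agree with a brute-force recount on random label sets", {
  set.seed(64)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    classes <- LETTERS[1:k]
    n <- sample(10:40, 1)
    true <- sample(classes, n, replace = TRUE)
    # ensure every class appears as a true label
    true[seq_len(k)] <- classes
    pred <- sample(classes, n, replace = TRUE)
    cm <- confusion(true, pred, classes)
    got <- suppressWarnings(metrics(cm))
    want <- oracle_metrics(true, pred, classes)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$precision, want$precision)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$f1, want$f1)
  }
})

test_that("micro and weighted averaging modes behave as defined", {
  true <- c("A", "A", "A", "B", "B", "C")
  pred <- c("A", "B", "A", "B", "A", "C")
  cm <- confusion(true, pred, c("A", "B", "C"))
  micro <- metrics(cm, averaging = "micro")
  expect_equal(micro$precision, micro$accuracy)   # single-label micro == accuracy
  wtd <- metrics(cm, averaging = "weighted")
  prec_c <- metrics(cm)$per_class$precision
  expect_equal(wtd$precision, sum(c(3, 2, 1) / 6 * prec_c))
})

test_that("cross-validation on a separable toy task is perfect and well-formed", {
  toy <- toy_separable_images(30, side = 100L)
  dir <- withr::local_tempdir()
  man <- data.frame(path = file.path(dir, sprintf("img%02d.png", 1:30)),
                    label = ifelse(toy$labels == "dark", "ALS", "CONTROL"),
                    subject_id = rep(c("als01", "control01"), length.out = 30),
                    record_index = 1:30)
  rep_out <- cross_validate(man, "als",
                            model_config(epochs = 3, batch_size = 8),
                            k = 3, seed = 2, images = toy$x, verbose = FALSE)
  expect_equal(nrow(rep_out), 4L)          # 3 folds + mean
  expect_equal(rep_out$fold, c("1", "2", "3", "mean"))
  expect_equal(rep_out$accuracy, rep(100, 4))
  # mean row is the exact arithmetic mean of the fold rows
  expect_equal(rep_out$f1[4], mean(rep_out$f1[1:3]))
  expect_equal(sum(rep_out$n_test[1:3]), 30L)

  out <- file.path(dir, "report")
  write_report(rep_out, out, config_hash = "abc")
  expect_true(file.exists(paste0(out, ".csv")))
  parsed <- jsonlite::read_json(paste0(out, ".json"), simplifyVector = TRUE)
  expect_equal(parsed$task, "ALS_VS_CONTROL")
  expect_equal(nrow(parsed$folds), 4L)
})
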