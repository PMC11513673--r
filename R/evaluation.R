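# Classification tasks, stratified k-fold protocol, confusion matrices and
# the accuracy / precision / sensitivity / F1 metrics, per fold and
# averaged.

TASK_IDS <- c("FOUR_GROUP", "NDD_VS_CONTROL", "ALS_VS_CONTROL",
              "HD_VS_CONTROL", "PD_VS_CONTROL")

#' Define a classification task
#'
#' The five tasks of the study: the 4-group problem (ALS vs HD vs PD vs
#' control), all neurodegenerative diseases pooled against control, and
#' the three single-disease-versus-control problems (which exclude the
#' other two diseases entirely). For binary tasks the disease class is the
#' positive class and is listed first in the class order.
#'
#' @param task_id One of `"FOUR_GROUP"`, `"NDD_VS_CONTROL"`,
#'   `"ALS_VS_CONTROL"`, `"HD_VS_CONTROL"`, `"PD_VS_CONTROL"` (or their
#'   lowercase CLI aliases `four_group`, `ndd`, `als`, `hd`, `pd`).
#' @return A `task_spec` with the label mapping, included classes, class
#'   order and positive class.
#' @export
task_spec <- function(task_id) {
  alias <- c(four_group = "FOUR_GROUP", ndd = "NDD_VS_CONTROL",
             als = "ALS_VS_CONTROL", hd = "HD_VS_CONTROL",
             pd = "PD_VS_CONTROL")
  if (tolower(task_id) %in% names(alias)) task_id <- alias[[tolower(task_id)]]
  task_id <- match.arg(task_id, TASK_IDS)
  spec <- switch(task_id,
    FOUR_GROUP = list(
      mapping = c(ALS = "ALS", HD = "HD", PD = "PD", CONTROL = "CONTROL"),
      class_order = c("ALS", "HD", "PD", "CONTROL"), positive = NA_character_),
    NDD_VS_CONTROL = list(
      mapping = c(ALS = "NDD", HD = "NDD", PD = "NDD", CONTROL = "CONTROL"),
      class_order = c("NDD", "CONTROL"), positive = "NDD"),
    ALS_VS_CONTROL = list(
      mapping = c(ALS = "ALS", CONTROL = "CONTROL"),
      class_order = c("ALS", "CONTROL"), positive = "ALS"),
    HD_VS_CONTROL = list(
      mapping = c(HD = "HD", CONTROL = "CONTROL"),
      class_order = c("HD", "CONTROL"), positive = "HD"),
    PD_VS_CONTROL = list(
      mapping = c(PD = "PD", CONTROL = "CONTROL"),
      class_order = c("PD", "CONTROL"), positive = "PD")
  )
  structure(c(list(task_id = task_id), spec), class = "task_spec")
}

#' Relabel a dataset manifest for a task
#'
#' Maps the four source labels onto the task's classes and drops rows of
#' excluded classes (e.g. HD and PD rows for the ALS-versus-control task).
#'
#' @param manifest Data frame with a `label` column of source classes.
#' @param task A [task_spec()] or task id.
#' @return The filtered, relabeled manifest; per-class counts in the
#'   `"counts"` attribute.
#' @export
apply_task <- function(manifest, task) {
  if (!inherits(task, "task_spec")) task <- task_spec(task)
  keep <- manifest$label %in% names(task$mapping)
  out <- manifest[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no samples left after applying task ", task$task_id)
  out$label <- unname(task$mapping[out$label])
  rownames(out) <- NULL
  attr(out, "counts") <- table(factor(out$label, levels = task$class_order))
  attr(out, "task") <- task
  out
}

#' Stratified k-fold assignment
#'
#' Record mode assigns records round-robin to folds within each class
#' after a seeded shuffle, so per-fold class counts differ by at most one
#' from exact proportionality. Subject mode assigns whole subjects to
#' folds, stratified by class — the leakage-safe option, since record
#' mode lets strides of one subject appear in both the training and test
#' portions.
#'
#' @param labels Character vector of class labels, one per record.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param grouping `"record"` (default) or `"subject"`.
#' @param subject_ids Required for subject grouping.
#' @return A `fold_split`: integer fold id (1..k) per record, plus the
#'   per-fold class count table.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L,
                             grouping = c("record", "subject"),
                             subject_ids = NULL) {
  grouping <- match.arg(grouping)
  k <- as.integer(k)
  labels <- as.character(labels)
  n <- length(labels)
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (grouping == "record") {
      cls_counts <- table(labels)
      if (k > min(cls_counts))
        stop(sprintf("cannot stratify: k = %d exceeds the smallest class count (%d)",
                     k, min(cls_counts)))
      for (cl in names(cls_counts)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      if (is.null(subject_ids))
        stop("subject grouping requires subject_ids")
      subj <- unique(subject_ids)
      subj_label <- labels[match(subj, subject_ids)]
      if (k > min(table(subj_label)))
        stop(sprintf("cannot stratify: k = %d exceeds the smallest per-class subject count (%d)",
                     k, min(table(subj_label))))
      sfold <- integer(length(subj))
      for (cl in unique(subj_label)) {
        idx <- sample(which(subj_label == cl))
        sfold[idx] <- rep_len(seq_len(k), length(idx))
      }
      fold <- sfold[match(subject_ids, subj)]
    }
  })
  structure(list(fold = fold, k = k, seed = as.integer(seed),
                 grouping = grouping,
                 counts = table(fold = fold, label = labels)),
            class = "fold_split")
}

#' Confusion matrix with one-vs-rest counts
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param class_order Row/column order of the matrix (rows = true class).
#' @return A `confusion_matrix`: K x K integer `table` plus per-class TP,
#'   FP, FN, TN in the `"ovr"` attribute.
#' @export
confusion <- function(true_labels, predicted_labels, class_order) {
  stopifnot(length(true_labels) == length(predicted_labels))
  t_f <- factor(as.character(true_labels), levels = class_order)
  p_f <- factor(as.character(predicted_labels), levels = class_order)
  if (anyNA(t_f) || anyNA(p_f))
    stop("labels outside class_order")
  m <- table(true = t_f, predicted = p_f)
  total <- sum(m)
  ovr <- t(vapply(class_order, function(cl) {
    tp <- m[cl, cl]
    fp <- sum(m[, cl]) - tp
    fn <- sum(m[cl, ]) - tp
    c(TP = tp, FP = fp, FN = fn, TN = total - tp - fp - fn)
  }, c(TP = 0, FP = 0, FN = 0, TN = 0)))
  structure(m, class = c("confusion_matrix", class(m)), ovr = ovr)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the proportion of correctly classified samples
#' ((TP + TN) over all cases); precision is TP / (TP + FP); sensitivity is
#' TP / (TP + FN); the F1 score is the harmonic mean
#' 2 x precision x sensitivity / (precision + sensitivity). All reported
#' in percent. For multi-class problems the per-class one-vs-rest
#' precision and sensitivity are averaged (macro by default; micro and
#' weighted available) and the report-level F1 combines the averaged pair;
#' per-class F1 values are also returned. For binary tasks `positive`
#' selects single-class reporting for precision/sensitivity/F1 (the
#' disease class, by the pipeline's convention). A zero denominator yields
#' 0 with a warning.
#'
#' @param cm A [confusion()] matrix.
#' @param averaging `"macro"` (default), `"micro"` or `"weighted"`.
#' @param positive Optional class name for binary-style reporting.
#' @return A `metrics_report` row: list with accuracy, precision,
#'   sensitivity, f1 (percent) and the per-class table.
#' @export
metrics <- function(cm, averaging = c("macro", "micro", "weighted"),
                    positive = NULL) {
  averaging <- match.arg(averaging)
  ovr <- attr(cm, "ovr")
  total <- sum(cm)
  safe_div <- function(num, den, what) {
    out <- ifelse(den == 0, 0, num / den)
    if (any(den == 0))
      warning("zero denominator in ", what, "; reporting 0 for the affected class")
    out
  }
  prec_c <- safe_div(ovr[, "TP"], ovr[, "TP"] + ovr[, "FP"], "precision")
  sens_c <- safe_div(ovr[, "TP"], ovr[, "TP"] + ovr[, "FN"], "sensitivity")
  f1_c <- ifelse(prec_c + sens_c == 0, 0,
                 2 * prec_c * sens_c / (prec_c + sens_c))
  accuracy <- sum(diag(cm)) / total

  if (!is.null(positive)) {
    stopifnot(positive %in% rownames(ovr))
    precision <- prec_c[[positive]]
    sensitivity <- sens_c[[positive]]
  } else if (averaging == "macro") {
    precision <- mean(prec_c)
    sensitivity <- mean(sens_c)
  } else if (averaging == "micro") {
    precision <- safe_div(sum(ovr[, "TP"]), sum(ovr[, "TP"] + ovr[, "FP"]),
                          "micro precision")
    sensitivity <- safe_div(sum(ovr[, "TP"]), sum(ovr[, "TP"] + ovr[, "FN"]),
                            "micro sensitivity")
  } else {
    w <- rowSums(cm) / total
    precision <- sum(w * prec_c)
    sensitivity <- sum(w * sens_c)
  }
  f1 <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)

  structure(list(
    accuracy = 100 * accuracy,
    precision = 100 * precision,
    sensitivity = 100 * sensitivity,
    f1 = 100 * f1,
    averaging = if (is.null(positive)) averaging else paste0("positive:", positive),
    per_class = data.frame(class = rownames(ovr),
                           precision = 100 * unname(prec_c),
                           sensitivity = 100 * unname(sens_c),
                           f1 = 100 * unname(f1_c),
                           row.names = NULL)
  ), class = "metrics_entry")
}

#' @export
print.metrics_entry <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  sensitivity %.2f%%  F1 %.2f%%  [%s]\n",
              x$accuracy, x$precision, x$sensitivity, x$f1, x$averaging))
  invisible(x)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Runs the stratified k-fold protocol on an image dataset manifest for
#' one task: per fold, a fresh model is trained on the other k-1 portions
#' and evaluated on the held-out portion; the report carries the four
#' metrics per fold and their arithmetic mean across folds.
#'
#' @param manifest Dataset manifest ([build_dataset()] /
#'   [read_manifest()]); its labels are relabeled via [apply_task()].
#' @param task A [task_spec()] or task id.
#' @param model_config A [model_config()]; `n_classes` is overridden by
#'   the task.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment and the per-fold model seeds.
#' @param grouping Passed to [stratified_folds()].
#' @param averaging Passed to [metrics()] (binary tasks report the
#'   positive/disease class regardless).
#' @param images Optional preloaded image array matching `manifest` rows
#'   (loaded from the manifest paths when omitted).
#' @param verbose Print per-fold progress.
#' @return A `metrics_report`: data frame of k fold rows plus one `mean`
#'   row, with the per-fold confusion matrices attached.
#' @export
cross_validate <- function(manifest, task, model_config = NULL, k = 10L,
                           seed = 1L, grouping = "record",
                           averaging = "macro", images = NULL,
                           verbose = TRUE) {
  if (!inherits(task, "task_spec")) task <- task_spec(task)
  keep <- manifest$label %in% names(task$mapping)
  if (!is.null(images)) {
    stopifnot(dim(images)[3L] == nrow(manifest))
    images <- images[, , keep, drop = FALSE]
  }
  manifest <- apply_task(manifest[keep, , drop = FALSE], task)
  if (is.null(images)) images <- load_images(manifest)
  images <- normalize_images(images)

  cfg <- model_config %||% gaitqr::model_config()
  cfg$n_classes <- length(task$class_order)

  split <- stratified_folds(manifest$label, k = k, seed = seed,
                            grouping = grouping,
                            subject_ids = manifest$subject_id)
  positive <- if (!is.na(task$positive)) task$positive else NULL

  fold_rows <- vector("list", split$k)
  cms <- vector("list", split$k)
  t0 <- proc.time()[["elapsed"]]
  for (f in seq_len(split$k)) {
    test_idx <- which(split$fold == f)
    train_idx <- which(split$fold != f)
    fold_cfg <- cfg
    fold_cfg$seed <- as.integer((as.numeric(seed) * 131 + f) %% 2147483629)
    model <- build_model(fold_cfg, input_side = dim(images)[1L])
    model$class_order <- task$class_order
    model <- train_model(model, images[, , train_idx, drop = FALSE],
                         manifest$label[train_idx])
    pred <- predict(model, images[, , test_idx, drop = FALSE])
    cm <- confusion(manifest$label[test_idx], pred$labels, task$class_order)
    entry <- metrics(cm, averaging = averaging, positive = positive)
    cms[[f]] <- cm
    fold_rows[[f]] <- data.frame(fold = as.character(f),
                                 n_test = length(test_idx),
                                 accuracy = entry$accuracy,
                                 precision = entry$precision,
                                 sensitivity = entry$sensitivity,
                                 f1 = entry$f1)
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.2f%% (n_test=%d, %.1fs elapsed)",
                      f, split$k, entry$accuracy, length(test_idx),
                      proc.time()[["elapsed"]] - t0))
  }
  report <- do.call(rbind, fold_rows)
  mean_row <- data.frame(fold = "mean", n_test = sum(report$n_test),
                         accuracy = mean(report$accuracy),
                         precision = mean(report$precision),
                         sensitivity = mean(report$sensitivity),
                         f1 = mean(report$f1))
  report <- rbind(report, mean_row)
  structure(report,
            class = c("metrics_report", "data.frame"),
            task = task$task_id, k = split$k, seed = seed,
            grouping = grouping, confusion = cms)
}

#' Write a metrics report as JSON and CSV
#'
#' @param report A `metrics_report` from [cross_validate()].
#' @param path Output path prefix (`<path>.json`, `<path>.csv`).
#' @param config_hash Optional configuration fingerprint recorded in the
#'   JSON for reproducibility.
#' @export
write_report <- function(report, path, config_hash = NULL) {
  df <- as.data.frame(report)
  write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(task = attr(report, "task"), k = attr(report, "k"),
         seed = attr(report, "seed"), grouping = attr(report, "grouping"),
         config_hash = config_hash, folds = df),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
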