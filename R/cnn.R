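# R surface of the convolutional classifier: configuration, shape
# arithmetic, construction, training, prediction, and checkpointing.

#' Configure the convolutional classifier
#'
#' Defaults reproduce the reference architecture for 100x100 single-channel
#' QR images: a 64-filter 3x3 same-padding convolution, 3x3 max pooling
#' with stride 3, a 64-filter 3x3 valid convolution, a second 3x3/3 max
#' pool, then a flatten of 6400 units feeding the N-way output layer
#' directly. `hidden_dense_units = 6400` instead inserts an explicit 6400-
#' unit dense layer between the flatten and the output, the other reading
#' of a "6400-unit dense layer"; both are supported. Unstated training
#' hyperparameters are package choices: ReLU activations, softmax output,
#' cross-entropy loss, Adam with learning rate 1e-3, batch size 32,
#' 30 epochs.
#'
#' @param n_classes Number of output classes (>= 2).
#' @param conv_filters,kernel_side,pool_side,pool_stride Architecture
#'   constants (defaults 64, 3, 3, 3).
#' @param conv1_padding,conv2_padding `"same"` and `"valid"` respectively.
#' @param hidden_dense_units 0 (flatten feeds the output directly) or a
#'   positive unit count for an inserted hidden dense layer.
#' @param learning_rate,batch_size,epochs,seed Training hyperparameters.
#' @return A `model_config`.
#' @export
model_config <- function(n_classes = 2L, conv_filters = 64L, kernel_side = 3L,
                         pool_side = 3L, pool_stride = 3L,
                         conv1_padding = "same", conv2_padding = "valid",
                         hidden_dense_units = 0L, learning_rate = 1e-3,
                         batch_size = 32L, epochs = 30L, seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes),
              conv_filters = as.integer(conv_filters),
              kernel_side = as.integer(kernel_side),
              pool_side = as.integer(pool_side),
              pool_stride = as.integer(pool_stride),
              conv1_padding = match.arg(conv1_padding, c("same", "valid")),
              conv2_padding = match.arg(conv2_padding, c("valid", "same")),
              hidden_dense_units = as.integer(hidden_dense_units),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              seed = as.integer(seed))
  if (cfg$n_classes < 2L) stop("n_classes must be >= 2")
  if (any(c(cfg$conv_filters, cfg$kernel_side, cfg$pool_side, cfg$pool_stride,
            cfg$batch_size, cfg$epochs) < 1L) || cfg$learning_rate <= 0)
    stop("all architecture and training counts must be positive")
  if (cfg$hidden_dense_units < 0L) stop("hidden_dense_units must be >= 0")
  structure(cfg, class = "model_config")
}

#' Dimension chain of the network
#'
#' Pure shape arithmetic, stage by stage: a same-padding convolution
#' preserves the spatial side; 3x3 pooling with stride 3 maps side s to
#' floor(s / 3) (floor semantics, non-overlapping windows); a valid 3x3
#' convolution maps s to s - 2; the flatten size is filters times the
#' final side squared. With the defaults and a 100x100 input:
#' (1,100,100) -> (64,100,100) -> (64,33,33) -> (64,31,31) -> (64,10,10)
#' -> 6400.
#'
#' @param config A [model_config()].
#' @param input_side Input image side in pixels (default 100).
#' @return A `shape_chain`: list of per-stage `(channels, side)` plus the
#'   flatten length.
#' @export
compute_shapes <- function(config = model_config(), input_side = 100L) {
  conv_side <- function(s, padding, k)
    if (padding == "same") s else s - k + 1L
  pool_side <- function(s, p, stride) (s - p) %/% stride + 1L

  s0 <- as.integer(input_side)
  s1 <- conv_side(s0, config$conv1_padding, config$kernel_side)
  s2 <- pool_side(s1, config$pool_side, config$pool_stride)
  s3 <- conv_side(s2, config$conv2_padding, config$kernel_side)
  s4 <- pool_side(s3, config$pool_side, config$pool_stride)
  f <- config$conv_filters
  structure(list(
    input = c(channels = 1L, side = s0),
    conv1 = c(channels = f, side = s1),
    pool1 = c(channels = f, side = s2),
    conv2 = c(channels = f, side = s3),
    pool2 = c(channels = f, side = s4),
    flatten = f * s4 * s4
  ), class = "shape_chain")
}

#' @export
print.shape_chain <- function(x, ...) {
  stage <- function(nm) sprintf("(%d,%d,%d)", x[[nm]][["channels"]],
                                x[[nm]][["side"]], x[[nm]][["side"]])
  cat(sprintf("%s -> %s -> %s -> %s -> %s -> flatten %d\n",
              stage("input"), stage("conv1"), stage("pool1"),
              stage("conv2"), stage("pool2"), x$flatten))
  invisible(x)
}

#' Total trainable parameter count
#'
#' Closed form from the configuration: each convolution contributes
#' filters x (in_channels x k^2) weights plus filters biases; each dense
#' layer in_units x out_units + out_units. With the defaults and no hidden
#' layer: 64x9+64 + 64x576+64 + 6400xN+N. With a 6400-unit hidden dense
#' layer an additional 6400x6400+6400 term appears.
#'
#' @param config A [model_config()].
#' @param input_side Input side (default 100).
#' @return Integer parameter count.
#' @export
count_parameters <- function(config = model_config(), input_side = 100L) {
  sh <- compute_shapes(config, input_side)
  f <- config$conv_filters
  k2 <- config$kernel_side^2
  n <- f * (1L * k2) + f + f * (f * k2) + f
  head_in <- sh$flatten
  if (config$hidden_dense_units > 0L) {
    n <- n + head_in * config$hidden_dense_units + config$hidden_dense_units
    head_in <- config$hidden_dense_units
  }
  n + head_in * config$n_classes + config$n_classes
}

#' Build an untrained model
#'
#' Allocates seeded initial parameters (He-normal weights, zero biases)
#' for the configured architecture. Only the default 3x3 kernels and
#' 3x3/stride-3 pooling are supported by the compiled kernels; other
#' values are rejected here rather than silently approximated.
#'
#' @param config A [model_config()].
#' @param input_side Input side (default 100).
#' @return A `gaitqr_cnn` model object (untrained).
#' @export
build_model <- function(config = model_config(), input_side = 100L) {
  stopifnot(inherits(config, "model_config"))
  if (config$kernel_side != 3L || config$pool_side != 3L ||
      config$pool_stride != 3L ||
      config$conv1_padding != "same" || config$conv2_padding != "valid")
    stop("the compiled network supports 3x3 kernels, 3x3 pooling with stride 3, same+valid padding")
  params <- cnn_init_cpp(as.integer(input_side), config$conv_filters,
                         config$hidden_dense_units, config$n_classes,
                         config$seed)
  structure(list(config = config, input_side = as.integer(input_side),
                 params = params, class_order = NULL, history = NULL,
                 trained = FALSE),
            class = "gaitqr_cnn")
}

#' @export
print.gaitqr_cnn <- function(x, ...) {
  cat(sprintf("<gaitqr_cnn> %s, %d classes, %s parameters\n",
              if (x$trained) "trained" else "untrained",
              x$config$n_classes,
              format(count_parameters(x$config, x$input_side), big.mark = ",")))
  if (x$trained)
    cat(sprintf("  classes: %s; final training accuracy %.3f\n",
                paste(x$class_order, collapse = ", "),
                tail(x$history$accuracy, 1L)))
  invisible(x)
}

# images: side x side x n array; rescale {0,255} to [0,1] if needed
normalize_images <- function(images) {
  if (length(dim(images)) != 3L)
    stop("images must be a side x side x n array")
  if (dim(images)[3L] == 0L) stop("empty dataset")
  if (max(images) > 1) images <- images / 255
  images
}

#' Train the classifier
#'
#' Mini-batch Adam on the categorical cross-entropy, pixels scaled to
#' [0, 1], for `config$epochs` epochs. The label order observed in
#' `labels` (first occurrence order of factor levels) is persisted with
#' the model and fixes the column order of predicted probabilities.
#'
#' @param model An untrained (or previously trained) `gaitqr_cnn`.
#' @param images `side x side x n` array, values in \[0, 1\] or \{0, 255\}.
#' @param labels Character/factor vector of length n.
#' @param epochs,batch_size,learning_rate Optional overrides of the
#'   model's configuration.
#' @return The trained `gaitqr_cnn`, with per-epoch loss/accuracy history.
#' @export
train_model <- function(model, images, labels, epochs = NULL,
                        batch_size = NULL, learning_rate = NULL) {
  stopifnot(inherits(model, "gaitqr_cnn"))
  images <- normalize_images(images)
  n <- dim(images)[3L]
  if (n == 0L) stop("empty dataset")
  if (length(labels) != n) stop("labels must match the number of images")
  labels <- as.character(labels)
  class_order <- model$class_order
  if (is.null(class_order)) class_order <- unique(labels)
  if (!all(labels %in% class_order))
    stop("label outside the model's class set: ",
         paste(setdiff(labels, class_order), collapse = ", "))
  if (length(class_order) != model$config$n_classes)
    stop(sprintf("model expects %d classes but data has %d",
                 model$config$n_classes, length(class_order)))
  y <- match(labels, class_order) - 1L
  cfg <- model$config
  fit <- cnn_train_cpp(images, y, model$params,
                       n_classes = cfg$n_classes,
                       epochs = as.integer(epochs %||% cfg$epochs),
                       batch_size = as.integer(batch_size %||% cfg$batch_size),
                       lr = learning_rate %||% cfg$learning_rate,
                       seed = cfg$seed)
  model$params <- fit$weights
  model$history <- rbind(model$history, fit$history)
  model$class_order <- class_order
  model$trained <- TRUE
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class labels and probabilities
#'
#' @param object A trained `gaitqr_cnn`.
#' @param images `side x side x n` array.
#' @param ... Unused.
#' @return List with `labels` (argmax of the probabilities, in the model's
#'   class order) and `prob` (n x K matrix, rows summing to 1).
#' @export
predict.gaitqr_cnn <- function(object, images, ...) {
  if (!object$trained) warning("predicting with an untrained model")
  images <- normalize_images(images)
  prob <- cnn_predict_cpp(object$params, images)
  colnames(prob) <- object$class_order %||%
    paste0("class", seq_len(ncol(prob)))
  list(labels = colnames(prob)[max.col(prob, ties.method = "first")],
       prob = prob)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a JSON sidecar (configuration, class order, training
#' history) next to a plain-text parameter dump, so checkpoints survive in
#' text-only storage.
#'
#' @param model A `gaitqr_cnn`.
#' @param path Checkpoint path prefix; `<path>.json` and `<path>.params`
#'   are written.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gaitqr_cnn"))
  side <- list(config = unclass(model$config),
               input_side = model$input_side,
               class_order = model$class_order,
               history = model$history,
               trained = model$trained,
               param_shapes = lapply(model$params, function(p)
                 if (is.matrix(p)) dim(p) else length(p)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".params"), "w")
  on.exit(close(con))
  for (nm in names(model$params))
    writeLines(c(nm, paste(sprintf("%.17g", c(model$params[[nm]])),
                           collapse = " ")), con)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lines <- readLines(paste0(path, ".params"))
  params <- list()
  for (k in seq(1L, length(lines), by = 2L)) {
    nm <- lines[k]
    vals <- as.numeric(strsplit(trimws(lines[k + 1L]), " +")[[1]])
    shape <- side$param_shapes[[nm]]
    params[[nm]] <- if (length(shape) == 2L) matrix(vals, shape[1], shape[2])
                    else vals
  }
  cfg <- do.call(model_config, side$config)
  structure(list(config = cfg, input_side = side$input_side, params = params,
                 class_order = side$class_order,
                 history = as.data.frame(side$history),
                 trained = isTRUE(side$trained)),
            class = "gaitqr_cnn")
}
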