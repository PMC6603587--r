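# The patch classifier: a small 7-layer CNN (3 convolutions, 1 max
# pooling, 3 fully connected layers, 4-way softmax) and an MLP
# baseline, trained with plain mini-batch SGD + momentum on the CPU.
# Everything is seeded and bit-reproducible on a given platform.

default_layer_spec <- function(kind, class_count = 4L) {
  if (kind == "cnn") {
    # 7x7 -> conv(16) 5x5 -> conv(32) 3x3 -> pool 2x2 -> conv(64,
    # zero-padded) 2x2 -> fc 128 -> fc 64 -> fc 4; seven layers.
    list(list(type = "conv", filters = 16L, size = 3L, padding = "valid"),
         list(type = "conv", filters = 32L, size = 3L, padding = "valid"),
         list(type = "pool", size = 2L),
         list(type = "conv", filters = 64L, size = 3L, padding = "same"),
         list(type = "fc", units = 128L),
         list(type = "fc", units = 64L),
         list(type = "fc", units = class_count))
  } else {
    list(list(type = "fc", units = 128L),
         list(type = "fc", units = 64L),
         list(type = "fc", units = class_count))
  }
}

#' Configure a patch classifier
#'
#' Defaults follow the 7-layer CNN structure (convolutions for feature
#' extraction, max pooling to shrink the spatial map, fully connected
#' layers, 4-way softmax) with its published training-iteration count
#' of 180 epochs; the MLP baseline flattens the 7x7 patch into 49
#' features and uses the same fully connected head. Optimizer:
#' stochastic gradient descent with momentum 0.9, learning rate 0.01,
#' batch 128.
#'
#' @param kind `"cnn"` or `"mlp"`.
#' @param layer_spec optional list of layer descriptors
#'   (`list(type = "conv", filters = , size = 3)`,
#'   `list(type = "pool", size = 2)`, `list(type = "fc", units = )`).
#'   A CNN spec must contain at least one convolution, one pooling and
#'   one fully connected layer and total 7 weighted/pooling layers.
#' @param epochs training passes over the data (default 180).
#' @param batch_size mini-batch size.
#' @param learning_rate,momentum SGD hyper-parameters.
#' @param seed integer seed controlling weight initialization and
#'   shuffling.
#' @param class_count number of output classes (4).
#' @param input_size patch width in pixels (7).
#' @param class_weights use inverse-frequency class weights in the
#'   loss (off by default).
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("cnn", "mlp"), layer_spec = NULL,
                              epochs = 180L, batch_size = 128L,
                              learning_rate = 0.01, momentum = 0.9,
                              seed = 1L, class_count = 4L, input_size = 7L,
                              class_weights = FALSE) {
  kind <- match.arg(kind)
  if (is.null(layer_spec)) layer_spec <- default_layer_spec(kind, class_count)
  types <- vapply(layer_spec, `[[`, "", "type")
  if (kind == "cnn") {
    if (!any(types == "conv") || !any(types == "pool") ||
        !any(types == "fc") || length(layer_spec) != 7L)
      abort_config(paste("a CNN spec needs >= 1 conv, >= 1 pool, >= 1 fc",
                         "and exactly 7 weighted/pooling layers"))
  }
  last <- layer_spec[[length(layer_spec)]]
  if (last$type != "fc" || last$units != class_count)
    abort_config("final layer must be fully connected with class_count units")
  if (epochs < 1L || batch_size < 1L || learning_rate <= 0)
    abort_config("epochs, batch_size must be >= 1 and learning_rate > 0")
  structure(list(kind = kind, layer_spec = layer_spec,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed),
                 class_count = as.integer(class_count),
                 input_size = as.integer(input_size),
                 class_weights = isTRUE(class_weights)),
            class = "classifier_config")
}

#' Build an (untrained) patch classifier
#'
#' Instantiates the layer stack and initializes weights (He-normal)
#' under the config seed, so even an untrained model produces valid
#' softmax outputs.
#'
#' @param config a [classifier_config()].
#' @return object of class `csvd_classifier` with fields `config`,
#'   `layers`, `n_parameters`, `trained`, `training_log`.
#' @export
build_classifier <- function(config) {
  stopifnot(inherits(config, "classifier_config"))
  set.seed(config$seed)
  input_shape <- if (config$kind == "cnn")
    c(1L, config$input_size, config$input_size)
  else (config$input_size^2)
  layers <- nn_init_layers(config$layer_spec, input_shape,
                           config$class_count)
  structure(list(config = config, layers = layers,
                 n_parameters = nn_param_count(layers),
                 trained = FALSE, training_log = NULL),
            class = "csvd_classifier")
}

#' @export
print.csvd_classifier <- function(x, ...) {
  cat(sprintf("<csvd_classifier %s: %d layers, %d parameters, %s>\n",
              x$config$kind, length(x$layers), x$n_parameters,
              if (x$trained) sprintf("trained %d epochs", x$config$epochs)
              else "untrained"))
  invisible(x)
}

as_patch_matrix <- function(patches) {
  if (inherits(patches, "patch_set")) patches$patches
  else if (is.matrix(patches)) patches
  else abort_shape("patches must be a patch_set or matrix")
}

patch_labels_of <- function(patches, labels) {
  if (!is.null(labels)) return(as.integer(labels))
  if (inherits(patches, "patch_set") && !is.null(patches$labels))
    return(as.integer(patches$labels))
  abort_degenerate_data("no patch labels supplied")
}

# Raw intensities are kept out of the model: this is the one explicit
# rescale from native integer range to [0, 1].
scale_patches <- function(X) X / 255

#' Train a patch classifier
#'
#' Runs exactly `config$epochs` passes of mini-batch SGD with a
#' cross-entropy objective, logging loss and train/validation accuracy
#' per epoch. Fully deterministic given the config seed.
#'
#' @param model an untrained (or trained) [build_classifier()] result.
#' @param patches training patches: a [patch_set()] with labels, or a
#'   matrix plus `labels`.
#' @param labels optional integer class ids 0..3 (overrides the patch
#'   set's).
#' @param val,val_labels optional validation patches/labels for the
#'   per-epoch accuracy log.
#' @return the trained `csvd_classifier`, with `training_log` set to a
#'   data frame (epoch, loss, train_acc, val_acc).
#' @export
train_classifier <- function(model, patches, labels = NULL, val = NULL,
                             val_labels = NULL) {
  stopifnot(inherits(model, "csvd_classifier"))
  cfg <- model$config
  X <- scale_patches(as_patch_matrix(patches))
  y <- patch_labels_of(patches, labels)
  if (length(y) != nrow(X)) abort_shape("labels do not align with patches")
  if (length(unique(y)) < 2L)
    abort_degenerate_data("training set holds a single class")
  Xv <- yv <- NULL
  if (!is.null(val)) {
    Xv <- scale_patches(as_patch_matrix(val))
    yv <- patch_labels_of(val, val_labels)
  }
  n <- nrow(X)
  K <- cfg$class_count
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  w_cls <- if (cfg$class_weights) {
    freq <- tabulate(y + 1L, nbins = K)
    ifelse(freq > 0, n / (K * freq), 0)
  } else rep(1, K)
  sample_w <- w_cls[y + 1L]

  layers <- model$layers
  vel <- lapply(layers, function(l)
    if (is.null(l$W)) list() else list(W = l$W * 0, b = l$b * 0))
  set.seed(cfg$seed + 1L)   # shuffling stream, distinct from init
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    train_acc = numeric(0), val_acc = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    tot_loss <- 0; tot_correct <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      wb <- sample_w[idx]
      fwd <- nn_forward(layers, Xb, want_cache = TRUE)
      P <- nn_softmax(fwd$out)
      nb <- nrow(Xb)
      tot_loss <- tot_loss -
        sum(wb * log(pmax(P[Yb == 1], 1e-12)))
      pred <- max.col(P, ties.method = "last") - 1L
      tot_correct <- tot_correct + sum(pred == y[idx])
      dZ <- (P - Yb) * (wb / nb)
      grads <- nn_backward(layers, fwd$caches, dZ)
      st <- nn_sgd_step(layers, grads, vel, cfg$learning_rate, cfg$momentum)
      layers <- st$layers; vel <- st$vel
    }
    val_acc <- NA_real_
    if (!is.null(Xv)) {
      pv <- nn_predict_classes(layers, Xv, batch = 4096L)
      val_acc <- mean(pv == yv)
    }
    log <- rbind(log, data.frame(epoch = ep, loss = tot_loss / n,
                                 train_acc = tot_correct / n,
                                 val_acc = val_acc))
  }
  model$layers <- layers
  model$trained <- TRUE
  model$training_log <- log
  model
}

nn_predict_prob <- function(layers, X, batch = 4096L) {
  n <- nrow(X)
  out <- matrix(0, n, ncol(nn_forward(layers, X[1, , drop = FALSE])$out))
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    out[idx, ] <- nn_softmax(nn_forward(layers, X[idx, , drop = FALSE])$out)
  }
  out
}

nn_predict_classes <- function(layers, X, batch = 4096L) {
  max.col(nn_predict_prob(layers, X, batch), ties.method = "last") - 1L
}

#' Classify patches
#'
#' Produces a softmax probability vector (4 values summing to 1) and
#' the argmax class for each patch. Argmax ties break toward the
#' higher class id, i.e. lesion-favoring.
#'
#' @param model a `csvd_classifier`.
#' @param patches a [patch_set()] or matrix of raw-intensity patches.
#' @return list with `prob` (n x 4 matrix) and `class` (integer ids
#'   0..3).
#' @export
predict_patches <- function(model, patches) {
  stopifnot(inherits(model, "csvd_classifier"))
  X <- as_patch_matrix(patches)
  if (ncol(X) != model$config$input_size^2)
    abort_shape(sprintf("patches have %d pixels, model expects %d",
                        ncol(X), model$config$input_size^2))
  P <- nn_predict_prob(model$layers, scale_patches(X))
  list(prob = P, class = max.col(P, ties.method = "last") - 1L)
}

#' Segment a slice with a trained patch classifier
#'
#' Tiles the slice, assigns class 0 (non-brain) to every patch whose
#' footprint lies fully outside the brain mask without running
#' inference, classifies the remaining patches and reassembles the
#' decisions into a full-resolution label map.
#'
#' @param model a trained `csvd_classifier`.
#' @param slice a [grayscale_slice()] (typically the masked slice from
#'   [extract_brain()]).
#' @param brain a `brain_region` (or [binary_mask()]); `NULL` runs
#'   inference on every patch.
#' @param grid a [patch_grid()] matching the slice; default 7x7
#'   non-overlapping.
#' @return a [label_map()] with the slice's dimensions.
#' @export
segment_slice <- function(model, slice, brain = NULL, grid = NULL) {
  stopifnot(inherits(slice, "grayscale_slice"))
  if (is.null(grid))
    grid <- patch_grid(slice$height, slice$width,
                       model$config$input_size)
  ps <- extract_patches(slice, grid)
  n <- nrow(ps$patches)
  labels <- integer(n)
  run <- rep(TRUE, n)
  if (!is.null(brain)) {
    mask <- if (inherits(brain, "brain_region")) brain$mask
            else if (inherits(brain, "binary_mask")) brain
            else abort_shape("brain must be a brain_region or binary_mask")
    if (mask$height != slice$height || mask$width != slice$width)
      abort_shape("brain mask dimensions differ from the slice")
    overlap <- extract_patches(mask$cells, grid)
    run <- rowSums(overlap$patches) > 0
  }
  if (any(run)) {
    pred <- predict_patches(model, ps$patches[run, , drop = FALSE])
    labels[run] <- pred$class
  }
  reassemble(labels, grid)
}

#' Save / load a classifier
#'
#' The on-disk model is self-describing: config (including seed),
#' weights and a format version tag.
#'
#' @param model a `csvd_classifier`.
#' @param path destination `.rds`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "csvd_classifier"))
  saveRDS(list(format = "csvdseg-classifier-1", model = model), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "csvdseg-classifier-1"))
    abort_format("not a csvdseg classifier file")
  obj$model
}
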