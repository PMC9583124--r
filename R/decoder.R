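#' CNN decoder architecture and training hyperparameters
#'
#' The decoder is a compact convolutional network: two convolution blocks
#' (convolution, 2x2 max pooling, ReLU), then a fully connected ReLU layer
#' and a fully connected softmax layer whose width equals the dictionary
#' size. Weights use Glorot-normal initialization; training minimizes
#' categorical cross-entropy with Adam and stops early once the monitored
#' loss stops improving.
#'
#' @param conv1_filters,conv2_filters Filter counts of the two convolutions.
#' @param kernel_size Square convolution kernel side (default 3).
#' @param fc_width Width of the hidden fully connected layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum training epochs (early stopping usually ends
#'   training first).
#' @param patience Early-stopping patience, epochs.
#' @param min_delta Minimum loss improvement counted by early stopping.
#' @param val_frac Fraction of the training data held out (stratified) as
#'   the early-stopping validation set; 0 monitors training loss instead.
#' @return An `emorfi_decoder_spec`.
#' @export
decoder_spec <- function(conv1_filters = 32L, conv2_filters = 64L,
                         kernel_size = 3L, fc_width = 128L,
                         learning_rate = 1e-3, batch_size = 32L,
                         epochs = 200L, patience = 10L, min_delta = 1e-4,
                         val_frac = 0.1) {
  structure(
    list(conv1_filters = as.integer(conv1_filters),
         conv2_filters = as.integer(conv2_filters),
         kernel_size = as.integer(kernel_size),
         fc_width = as.integer(fc_width),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), patience = as.integer(patience),
         min_delta = min_delta, val_frac = val_frac),
    class = "emorfi_decoder_spec"
  )
}

dataset_to_cube <- function(images, side) {
  arr <- array(0, dim = c(side, side, length(images)))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!all(dim(img) == c(side, side))) {
      abort_emorfi(sprintf("image %d is not %dx%d", i, side, side),
                   "emorfi_validation_error")
    }
    arr[, , i] <- img
  }
  arr
}

# Stratified validation split: the last ceil(val_frac * reps) replicates of
# each class, after a seeded permutation within class.
split_validation <- function(labels, val_frac, seed) {
  if (val_frac <= 0) return(integer(0))
  val_idx <- integer(0)
  with_seed(seed, {
    for (ci in unique(labels)) {
      idx <- which(labels == ci)
      n_val <- max(1L, floor(val_frac * length(idx)))
      if (n_val >= length(idx)) n_val <- length(idx) - 1L
      if (n_val > 0) val_idx <- c(val_idx, sample(idx, n_val))
    }
  })
  sort(val_idx)
}

#' Train a CNN decoder on a balanced dataset
#'
#' @param train_set An `emorfi_dataset`.
#' @param spec An `emorfi_decoder_spec`.
#' @param seed Integer seed; fixes initialization, the validation split and
#'   shuffling, making training fully reproducible.
#' @return An `emorfi_decoder` holding the trained weights, the spec, the
#'   loss history and provenance digests.
#' @export
train_decoder <- function(train_set, spec = decoder_spec(), seed = 1L) {
  stopifnot(inherits(train_set, "emorfi_dataset"))
  n_class <- length(train_set$characters)
  side <- train_set$img_side
  cfg <- c(unclass(spec), list(n_class = n_class))
  val_idx <- split_validation(train_set$labels, spec$val_frac, seed)
  tr_idx <- setdiff(seq_along(train_set$labels), val_idx)
  Xtr <- dataset_to_cube(train_set$images[tr_idx], side)
  ytr <- train_set$labels[tr_idx] - 1L
  if (length(val_idx) > 0) {
    Xval <- dataset_to_cube(train_set$images[val_idx], side)
    yval <- train_set$labels[val_idx] - 1L
  } else {
    Xval <- array(0, dim = c(side, side, 0))
    yval <- integer(0)
  }
  fit <- cpp_cnn_train(Xtr, ytr, Xval, yval, cfg, as.integer(seed))
  structure(
    list(weights = fit$weights, spec = spec, n_class = n_class,
         img_side = side, characters = train_set$characters,
         history = fit$history, best_loss = fit$best_loss,
         stopped_epoch = fit$stopped_epoch, seed = as.integer(seed),
         dataset_digest = obj_digest(list(train_set$codebook_digest,
                                          train_set$config_digest,
                                          train_set$base_seed,
                                          train_set$seed_offset,
                                          train_set$reps_per_class))),
    class = "emorfi_decoder"
  )
}

#' @export
print.emorfi_decoder <- function(x, ...) {
  cat(sprintf(
    "<emorfi_decoder> %d classes, %dx%d input, %d+%d filters, fc %d; trained %d epochs (best loss %.4f)\n",
    x$n_class, x$img_side, x$img_side, x$spec$conv1_filters,
    x$spec$conv2_filters, x$spec$fc_width, length(x$history), x$best_loss
  ))
  invisible(x)
}

#' @export
glance.emorfi_decoder <- function(x, ...) {
  tibble(
    n_class = x$n_class, img_side = x$img_side,
    conv1_filters = x$spec$conv1_filters, conv2_filters = x$spec$conv2_filters,
    fc_width = x$spec$fc_width, epochs_run = length(x$history),
    best_loss = x$best_loss, seed = x$seed,
    weights_digest = obj_digest(x$weights)
  )
}

as_image_list <- function(images) {
  if (inherits(images, "emorfi_dataset")) return(images$images)
  if (is.matrix(images)) return(list(images))
  if (is.list(images)) return(images)
  abort_emorfi("images must be a matrix, list of matrices, or emorfi_dataset",
               "emorfi_validation_error")
}

#' Categorical class probabilities for pattern images
#'
#' @param model An `emorfi_decoder`.
#' @param images A preprocessed image matrix, list of matrices, or
#'   `emorfi_dataset` at the model's input side.
#' @return Numeric matrix, one row per image, columns named by the
#'   dictionary characters; each row sums to 1.
#' @export
predict_proba <- function(model, images) {
  stopifnot(inherits(model, "emorfi_decoder"))
  imgs <- as_image_list(images)
  X <- dataset_to_cube(imgs, model$img_side)
  p <- cpp_cnn_predict(model$weights, X, c(unclass(model$spec),
                                           list(n_class = model$n_class)))
  colnames(p) <- model$characters
  p
}

#' Decode images to characters
#'
#' @inheritParams predict_proba
#' @return Character vector: the argmax class of each image.
#' @export
decode_patterns <- function(model, images) {
  p <- predict_proba(model, images)
  model$characters[max.col(p, ties.method = "first")]
}

#' @export
predict.emorfi_decoder <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "prob") predict_proba(object, newdata)
  else decode_patterns(object, newdata)
}

#' Evaluate a decoder on a held-out test set
#'
#' Computes accuracy, the confusion matrix, per-class precision and recall,
#' per-class one-vs-rest ROC curves and their macro-averaged AUC.
#'
#' @param model An `emorfi_decoder` (or `emorfi_ensemble`).
#' @param test_set An `emorfi_dataset` with the same dictionary.
#' @return An `emorfi_eval` with fields `accuracy`, `confusion`,
#'   `per_class` (tibble), `roc` (tibble of ROC points), `macro_auc`,
#'   `n`.
#' @export
evaluate_decoder <- function(model, test_set) {
  stopifnot(inherits(test_set, "emorfi_dataset"))
  if (length(test_set$images) == 0) {
    abort_emorfi("empty test set", "emorfi_validation_error")
  }
  p <- predict_proba(model, test_set)
  eval_probs(p, test_set$labels, test_set$characters)
}

eval_probs <- function(p, labels, characters) {
  n_class <- length(characters)
  pred <- max.col(p, ties.method = "first")
  confusion <- matrix(0L, n_class, n_class,
                      dimnames = list(truth = characters,
                                      predicted = characters))
  for (i in seq_along(labels)) {
    confusion[labels[i], pred[i]] <- confusion[labels[i], pred[i]] + 1L
  }
  accuracy <- sum(diag(confusion)) / length(labels)
  precision <- diag(confusion) / pmax(colSums(confusion), 1)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  roc_pts <- list()
  aucs <- rep(NA_real_, n_class)
  for (ci in seq_len(n_class)) {
    truth <- as.integer(labels == ci)
    if (length(unique(truth)) == 2) {
      r <- pROC::roc(truth, p[, ci], quiet = TRUE, direction = "<")
      aucs[ci] <- as.numeric(pROC::auc(r))
      roc_pts[[ci]] <- tibble(
        character = characters[ci],
        fpr = rev(1 - r$specificities),
        tpr = rev(r$sensitivities)
      )
    }
  }
  structure(
    list(
      accuracy = accuracy,
      confusion = confusion,
      per_class = tibble(character = characters,
                         precision = as.numeric(precision),
                         recall = as.numeric(recall),
                         auc = aucs),
      roc = do.call(rbind, roc_pts),
      macro_auc = mean(aucs, na.rm = TRUE),
      n = length(labels)
    ),
    class = "emorfi_eval"
  )
}

#' @export
print.emorfi_eval <- function(x, ...) {
  cat(sprintf("<emorfi_eval> accuracy %.3f, macro AUC %.3f on %d items\n",
              x$accuracy, x$macro_auc, x$n))
  invisible(x)
}

#' @rdname evaluate_decoder
#' @param x An `emorfi_eval`.
#' @param ... Unused.
#' @export
tidy.emorfi_eval <- function(x, ...) x$per_class

#' @export
glance.emorfi_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_auc = x$macro_auc, n = x$n)
}
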