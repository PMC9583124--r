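#' Train independently initialized base decoders
#'
#' Trains `M` CNN decoders on the same dataset with distinct seeds. Random
#' initialization diversifies the models; stacking or voting over them
#' improves decoding, and the spread of their predictions carries
#' uncertainty information.
#'
#' @param train_set An `emorfi_dataset`.
#' @param spec An `emorfi_decoder_spec` shared by all bases.
#' @param n_models Number of base models (default 5).
#' @param seeds Distinct integer seeds, one per base; default `1:n_models`.
#' @return List of `emorfi_decoder` objects.
#' @export
train_bases <- function(train_set, spec = decoder_spec(), n_models = 5L,
                        seeds = seq_len(n_models)) {
  if (n_models < 2L) abort_emorfi("need at least 2 base models", "emorfi_validation_error")
  if (length(seeds) != n_models || anyDuplicated(seeds)) {
    abort_emorfi("seeds must be n_models distinct integers", "emorfi_validation_error")
  }
  lapply(seeds, function(s) train_decoder(train_set, spec, seed = s))
}

#' Stack base-model predictions into a meta-learning dataset
#'
#' Each item's feature vector is the concatenation of every base model's
#' probability vector on that item (length `M * n_classes`); the label is
#' unchanged. This is the standard stacked-generalization construction.
#'
#' @param bases List of `emorfi_decoder`s sharing one dictionary.
#' @param dataset An `emorfi_dataset`.
#' @return An `emorfi_stack_dataset`: list with `features` (matrix), `labels`,
#'   `characters`, `n_models`.
#' @export
make_stack_dataset <- function(bases, dataset) {
  n_class <- unique(vapply(bases, function(b) b$n_class, 0L))
  if (length(n_class) != 1L) {
    abort_emorfi("base models disagree on the number of classes",
                 "emorfi_validation_error")
  }
  features <- do.call(cbind, lapply(bases, function(b) {
    predict_proba(b, dataset)
  }))
  structure(
    list(features = unname(features), labels = dataset$labels,
         characters = dataset$characters, n_models = length(bases)),
    class = "emorfi_stack_dataset"
  )
}

#' Train a stacking meta-model
#'
#' Fits a softmax classifier on stacked base probabilities: multinomial
#' logistic regression by default (`hidden = integer(0)`), or a feedforward
#' network with ReLU hidden layers. Defaults follow the stacker protocol:
#' Glorot-uniform initialization, categorical cross-entropy, Adam with
#' learning rate 1e-4, early stopping with patience 5 and minimum
#' improvement 1e-4.
#'
#' @param stack An `emorfi_stack_dataset` (from the *training* set).
#' @param hidden Integer vector of hidden-layer widths; empty = logistic
#'   regression.
#' @param learning_rate,batch_size,epochs,patience,min_delta Training
#'   hyperparameters.
#' @param val_frac Stratified validation fraction for early stopping
#'   (0 monitors training loss).
#' @param seed Integer seed.
#' @param bases Optional list of the base decoders; if supplied they are
#'   stored so the ensemble can predict directly from images.
#' @return An `emorfi_ensemble`.
#' @export
train_stacker <- function(stack, hidden = integer(0), learning_rate = 1e-4,
                          batch_size = 32L, epochs = 400L, patience = 5L,
                          min_delta = 1e-4, val_frac = 0, seed = 1L,
                          bases = NULL) {
  stopifnot(inherits(stack, "emorfi_stack_dataset"))
  if (length(stack$labels) == 0) {
    abort_emorfi("empty stack dataset", "emorfi_validation_error")
  }
  n_class <- length(stack$characters)
  val_idx <- split_validation(stack$labels, val_frac, seed)
  tr_idx <- setdiff(seq_along(stack$labels), val_idx)
  fit <- cpp_mlp_train(
    stack$features[tr_idx, , drop = FALSE], stack$labels[tr_idx] - 1L,
    stack$features[val_idx, , drop = FALSE],
    if (length(val_idx)) stack$labels[val_idx] - 1L else integer(0),
    as.integer(hidden), n_class, learning_rate, as.integer(batch_size),
    as.integer(epochs), as.integer(patience), min_delta,
    TRUE, as.integer(seed)
  )
  structure(
    list(W = fit$W, b = fit$b, hidden = as.integer(hidden),
         characters = stack$characters, n_class = n_class,
         n_models = stack$n_models, history = fit$history,
         best_loss = fit$best_loss, seed = as.integer(seed), bases = bases),
    class = "emorfi_ensemble"
  )
}

#' @export
print.emorfi_ensemble <- function(x, ...) {
  cat(sprintf(
    "<emorfi_ensemble> %s over %d base models, %d classes\n",
    if (length(x$hidden)) paste0("mlp(", paste(x$hidden, collapse = ","), ")")
    else "logistic regression",
    x$n_models, x$n_class
  ))
  invisible(x)
}

#' @export
glance.emorfi_ensemble <- function(x, ...) {
  tibble(
    architecture = if (length(x$hidden)) paste0("mlp(", paste(x$hidden, collapse = ","), ")")
                   else "logistic",
    n_models = x$n_models, n_class = x$n_class,
    epochs_run = length(x$history), best_loss = x$best_loss, seed = x$seed
  )
}

#' Ensemble class probabilities
#'
#' @param model An `emorfi_ensemble`.
#' @param x Either an `emorfi_stack_dataset` / feature matrix, or (when the
#'   ensemble stores its base models) images / an `emorfi_dataset`.
#' @return Probability matrix, one row per item.
#' @export
predict_proba_ensemble <- function(model, x) {
  stopifnot(inherits(model, "emorfi_ensemble"))
  features <- if (inherits(x, "emorfi_stack_dataset")) {
    x$features
  } else if (is.matrix(x) && ncol(x) == model$n_models * model$n_class &&
             !inherits(x, "emorfi_pattern")) {
    x
  } else {
    if (is.null(model$bases)) {
      abort_emorfi("ensemble stores no base models; supply stacked features",
                   "emorfi_validation_error")
    }
    make_stack_dataset(model$bases, as_stack_input(x))$features
  }
  p <- cpp_mlp_predict(model$W, model$b, features)
  colnames(p) <- model$characters
  p
}

as_stack_input <- function(x) {
  if (inherits(x, "emorfi_dataset")) return(x)
  imgs <- as_image_list(x)
  structure(list(images = imgs, labels = rep(1L, length(imgs)),
                 characters = "?"), class = "emorfi_dataset")
}

#' @export
predict.emorfi_ensemble <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_proba_ensemble(object, newdata)
  if (type == "prob") p else object$characters[max.col(p, ties.method = "first")]
}

# evaluate_decoder() dispatches on predict_proba for both decoder and
# ensemble inputs; route ensembles through their base models.
#' @rdname evaluate_decoder
#' @export
evaluate_ensemble <- function(model, test_set) {
  stopifnot(inherits(model, "emorfi_ensemble"), inherits(test_set, "emorfi_dataset"))
  if (length(test_set$images) == 0) {
    abort_emorfi("empty test set", "emorfi_validation_error")
  }
  p <- predict_proba_ensemble(model, test_set)
  eval_probs(p, test_set$labels, test_set$characters)
}

#' Majority vote over replicate predictions
#'
#' Takes the modal predicted label over several ballots (replicate patterns
#' of the same message). Ties are broken by the highest summed probability
#' across ballots, then by lowest class index — deterministic and
#' confidence-aware.
#'
#' @param labels Integer or character vector of per-ballot predictions.
#' @param probs Optional matrix of per-ballot probability rows (same order),
#'   used for tie-breaking.
#' @return The winning label (same type as `labels`).
#' @export
majority_vote <- function(labels, probs = NULL) {
  if (length(labels) == 0) {
    abort_emorfi("majority_vote needs at least one ballot", "emorfi_validation_error")
  }
  counts <- table(labels)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) == 1L) {
    out <- winners
  } else if (!is.null(probs)) {
    sums <- colSums(probs[, winners, drop = FALSE])
    out <- winners[which.max(sums)] # which.max takes the first (lowest) index
  } else {
    out <- sort(winners)[1L]
  }
  if (is.integer(labels)) as.integer(out)
  else if (is.numeric(labels)) as.numeric(out)
  else out
}

#' Prediction-uncertainty metrics
#'
#' Evaluates four uncertainty metrics over `M` items and `N` classes with
#' one-hot true labels `y` and predicted probabilities `p`:
#' negative log likelihood \eqn{-M^{-1}\sum_j \sum_i y_{ij} \log p_{ij}}
#' (natural log, probabilities floored at 1e-12), mean squared error
#' \eqn{M^{-1} N^{-1} \sum_j \sum_i (y_{ij} - p_{ij})^2}, and the top-1 /
#' top-5 error rates (fraction of items whose true class is not among the 1
#' or 5 highest-probability predictions; probability ties resolve to the
#' lower class index).
#'
#' @param probs Probability matrix (rows sum to 1).
#' @param labels Integer true class indices (1-based).
#' @return An `emorfi_uncertainty`: list with `nll`, `mse`, `top1_error`,
#'   `top5_error`, `n`.
#' @export
uncertainty <- function(probs, labels) {
  probs <- as.matrix(probs)
  M <- nrow(probs); N <- ncol(probs)
  if (length(labels) != M || any(labels < 1L | labels > N)) {
    abort_emorfi("labels must index probability columns", "emorfi_validation_error")
  }
  p_true <- probs[cbind(seq_len(M), labels)]
  nll <- -mean(log(pmax(p_true, 1e-12)))
  Y <- matrix(0, M, N)
  Y[cbind(seq_len(M), labels)] <- 1
  mse <- sum((Y - probs)^2) / (M * N)
  ranks <- t(apply(-probs, 1, function(r) rank(r, ties.method = "first")))
  true_rank <- ranks[cbind(seq_len(M), labels)]
  structure(
    list(nll = nll, mse = mse,
         top1_error = mean(true_rank > 1),
         top5_error = mean(true_rank > 5),
         n = M),
    class = "emorfi_uncertainty"
  )
}

#' @export
print.emorfi_uncertainty <- function(x, ...) {
  cat(sprintf(
    "<emorfi_uncertainty> nll %.4f, mse %.4f, top-1 error %.3f, top-5 error %.3f (%d items)\n",
    x$nll, x$mse, x$top1_error, x$top5_error, x$n
  ))
  invisible(x)
}

#' @export
tidy.emorfi_uncertainty <- function(x, ...) {
  tibble(
    metric = c("nll", "mse", "top1_error", "top5_error"),
    value = c(x$nll, x$mse, x$top1_error, x$top5_error)
  )
}
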