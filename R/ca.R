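#' Elementary cellular-automaton encoder configuration
#'
#' The 1D analogue of the spot-array scheme: bits are embedded as blocks of
#' 1-cells in an initial binary sequence, each cell is independently flipped
#' with a small probability (the noise source), and the sequence evolves
#' under an elementary CA rule for a fixed number of steps. A feedforward
#' network decodes the final sequence.
#'
#' The published description does not pin down the rule; rule 54 — a
#' weakly chaotic rule with slow, structured information spread — is the
#' configurable default.
#'
#' @param rule Elementary rule number, 0-255.
#' @param width Sequence length, cells.
#' @param steps Number of rule applications.
#' @param block_width 1-block width per bit, cells.
#' @param block_spacing Center-to-center distance of adjacent blocks, cells.
#' @param flip_prob Per-cell bit-flip probability on the initial sequence.
#' @param boundary `"fixed"` (zeros beyond the ends, default) or
#'   `"periodic"`.
#' @return An `emorfi_ca_config`.
#' @export
ca_config <- function(rule = 54L, width = 64L, steps = 16L, block_width = 4L,
                      block_spacing = 8L, flip_prob = 0.05,
                      boundary = c("fixed", "periodic")) {
  rule <- as.integer(rule)
  if (rule < 0L || rule > 255L) {
    abort_emorfi("rule must be in 0..255", "emorfi_validation_error")
  }
  if (flip_prob < 0 || flip_prob > 1) {
    abort_emorfi("flip_prob must be in [0, 1]", "emorfi_validation_error")
  }
  structure(
    list(rule = rule, width = as.integer(width), steps = as.integer(steps),
         block_width = as.integer(block_width),
         block_spacing = as.integer(block_spacing), flip_prob = flip_prob,
         boundary = match.arg(boundary)),
    class = "emorfi_ca_config"
  )
}

rule_table <- function(rule) {
  # neighborhood (left, center, right) read as the binary number 4l+2c+r;
  # bit k of the rule gives the next state for neighborhood value k
  as.integer((rule %/% 2^(0:7)) %% 2)
}

#' Apply an elementary CA rule for one step
#'
#' @param cells Integer 0/1 vector.
#' @param rule Rule number 0-255.
#' @param boundary `"fixed"` or `"periodic"`.
#' @return Next 0/1 vector.
#' @export
ca_step <- function(cells, rule, boundary = "fixed") {
  n <- length(cells)
  if (boundary == "periodic") {
    left <- cells[c(n, seq_len(n - 1))]
    right <- cells[c(seq_len(n - 1) + 1, 1)]
  } else {
    left <- c(0L, cells[seq_len(n - 1)])
    right <- c(cells[seq_len(n - 1) + 1], 0L)
  }
  tab <- rule_table(rule)
  tab[4L * left + 2L * cells + right + 1L]
}

ca_initial_sequence <- function(bits, config) {
  digits <- as.integer(strsplit(bits, "")[[1]])
  n_bits <- length(digits)
  span <- (n_bits - 1L) * config$block_spacing + config$block_width
  if (span > config$width) {
    abort_emorfi("bit blocks exceed the sequence width", "emorfi_validation_error")
  }
  start <- (config$width - span) %/% 2L
  cells <- integer(config$width)
  for (k in seq_len(n_bits)) {
    if (digits[k] == 1L) {
      from <- start + (k - 1L) * config$block_spacing + 1L
      cells[from:(from + config$block_width - 1L)] <- 1L
    }
  }
  cells
}

#' Encode a bit string through the noisy CA
#'
#' Builds the block initial sequence, flips each cell independently with
#' `flip_prob`, and evolves the rule for `steps` applications.
#'
#' @param bits Binary string.
#' @param config An `emorfi_ca_config`.
#' @param seed Optional integer seed for the flips.
#' @return Integer 0/1 vector of length `width` (the final sequence).
#' @export
ca_encode <- function(bits, config = ca_config(), seed = NULL) {
  cells <- ca_initial_sequence(bits, config)
  flip <- function() {
    if (config$flip_prob > 0) {
      flips <- runif(length(cells)) < config$flip_prob
      cells[flips] <<- 1L - cells[flips]
    }
  }
  if (is.null(seed)) flip() else with_seed(seed, flip())
  for (s in seq_len(config$steps)) {
    cells <- ca_step(cells, config$rule, config$boundary)
  }
  cells
}

#' Generate a balanced CA sequence dataset
#'
#' @param codebook An `emorfi_codebook`.
#' @param config An `emorfi_ca_config`.
#' @param reps_per_class Replicates per character.
#' @param base_seed Integer seed.
#' @param seed_offset Stream offset (keep train/test disjoint).
#' @return List with `sequences` (matrix, one row per item), `labels`,
#'   `characters`.
#' @export
generate_ca_dataset <- function(codebook, config = ca_config(),
                                reps_per_class = 50L, base_seed = 1L,
                                seed_offset = 0L) {
  n_class <- length(codebook$characters)
  seqs <- matrix(0L, n_class * reps_per_class, config$width)
  labels <- integer(nrow(seqs))
  i <- 0L
  for (ci in seq_len(n_class)) {
    bits <- char_to_bits(codebook$characters[[ci]], codebook)
    for (r in seq_len(reps_per_class)) {
      i <- i + 1L
      seqs[i, ] <- ca_encode(bits, config,
                             seed = derive_seed(base_seed, seed_offset, ci, r))
      labels[i] <- ci
    }
  }
  list(sequences = seqs, labels = labels, characters = codebook$characters)
}

#' Train a feedforward decoder for CA final sequences
#'
#' A softmax feedforward network (ReLU hidden layers) on the raw 0/1 final
#' sequences.
#'
#' @param dataset From [generate_ca_dataset()].
#' @param hidden Hidden-layer widths (default 32).
#' @param learning_rate,batch_size,epochs,patience,min_delta Training
#'   hyperparameters.
#' @param seed Integer seed.
#' @return An `emorfi_seq_decoder`.
#' @export
train_seq_decoder <- function(dataset, hidden = 32L, learning_rate = 1e-3,
                              batch_size = 32L, epochs = 100L, patience = 10L,
                              min_delta = 1e-4, seed = 1L) {
  n_class <- length(dataset$characters)
  fit <- cpp_mlp_train(
    dataset$sequences * 1.0, dataset$labels - 1L,
    matrix(0, 0, ncol(dataset$sequences)), integer(0),
    as.integer(hidden), n_class, learning_rate, as.integer(batch_size),
    as.integer(epochs), as.integer(patience), min_delta, FALSE,
    as.integer(seed)
  )
  structure(
    list(W = fit$W, b = fit$b, characters = dataset$characters,
         n_class = n_class, history = fit$history, seed = as.integer(seed)),
    class = "emorfi_seq_decoder"
  )
}

#' @export
predict.emorfi_seq_decoder <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- cpp_mlp_predict(object$W, object$b, as.matrix(newdata) * 1.0)
  colnames(p) <- object$characters
  if (type == "prob") p else object$characters[max.col(p, ties.method = "first")]
}
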