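test_that("stacked features are blockwise probability vectors", {
  ds <- toy_image_dataset(n_per_class = 6)
  spec <- decoder_spec(conv1_filters = 4L, conv2_filters = 8L, fc_width = 16L,
                       epochs = 10L, val_frac = 0)
  bases <- train_bases(ds, spec, n_models = 3, seeds = c(1, 2, 3))
  expect_length(bases, 3)
  digests <- vapply(bases, function(b) obj_digest(b$weights), "")
  expect_equal(anyDuplicated(digests), 0L) # random init diversifies

  stk <- make_stack_dataset(bases, ds)
  expect_equal(dim(stk$features), c(12, 3 * 2)) # M * n_classes columns
  for (blk in 1:3) {
    block <- stk$features[, (2 * blk - 1):(2 * blk)]
    expect_lt(max(abs(rowSums(block) - 1)), 1e-6)
  }
  expect_equal(stk$labels, ds$labels)

  # identical bases give blockwise-identical features
  stk2 <- make_stack_dataset(list(bases[[1]], bases[[1]]), ds)
  expect_identical(stk2$features[, 1:2], stk2$features[, 3:4])

  expect_error(train_bases(ds, spec, n_models = 2, seeds = c(1, 1)),
               class = "emorfi_validation_error")
  expect_error(train_bases(ds, spec, n_models = 1),
               class = "emorfi_validation_error")
})

test_that("a stacker on perfect bases is perfect; architecture is flexible", {
  # hand-built stack: two bases that already emit the one-hot truth
  labels <- rep(1:3, each = 20)
  onehot <- matrix(0, 60, 3)
  onehot[cbind(1:60, labels)] <- 1
  stk <- structure(
    list(features = cbind(onehot, onehot), labels = labels,
         characters = c("x", "y", "z"), n_models = 2L),
    class = "emorfi_stack_dataset"
  )
  ens <- train_stacker(stk, epochs = 200L, learning_rate = 1e-2, seed = 1)
  p <- predict_proba_ensemble(ens, stk)
  expect_equal(mean(max.col(p) == labels), 1)

  ens_mlp <- train_stacker(stk, hidden = 8L, epochs = 200L,
                           learning_rate = 1e-2, seed = 1)
  p2 <- predict_proba_ensemble(ens_mlp, stk)
  expect_equal(mean(max.col(p2) == labels), 1)

  empty <- stk; empty$features <- stk$features[0, ]; empty$labels <- integer(0)
  expect_error(train_stacker(empty), class = "emorfi_validation_error")
})

test_that("majority voting follows the modal-then-probability rule", {
  expect_equal(majority_vote(c("A", "A", "B")), "A")
  expect_equal(majority_vote("A"), "A")
  # tie broken by summed probability
  probs <- rbind(c(A = 0.6, B = 0.4), c(A = 0.1, B = 0.9))
  expect_equal(majority_vote(c("A", "B"), probs), "B") # 1.3 > 0.7
  probs2 <- rbind(c(A = 0.9, B = 0.1), c(A = 0.2, B = 0.8))
  expect_equal(majority_vote(c("A", "B"), probs2), "A") # 1.1 > 0.9
  # without probabilities, ties fall to the lowest label
  expect_equal(majority_vote(c("B", "A")), "A")
  expect_equal(majority_vote(c(2L, 1L)), 1L)
  expect_error(majority_vote(character(0)), class = "emorfi_validation_error")
})

test_that("uncertainty metrics reproduce hand-computed values exactly", {
  # all correct with probability one: every metric is zero
  labels <- rep(1:3, 4)
  onehot <- matrix(0, 12, 3)
  onehot[cbind(1:12, labels)] <- 1
  u0 <- uncertainty(onehot, labels)
  expect_equal(u0$nll, 0)
  expect_equal(u0$mse, 0)
  expect_equal(u0$top1_error, 0)
  expect_equal(u0$top5_error, 0)

  # uniform over 15 classes: nll = ln 15, mse = 14/225
  uni <- matrix(1 / 15, 30, 15)
  u1 <- uncertainty(uni, rep(1:15, 2))
  expect_equal(u1$nll, log(15), tolerance = 1e-10)
  expect_equal(u1$mse, 14 / 225, tolerance = 1e-10)

  # single item, p = (0.5, 0.3, 0.2), true class = the 0.3 one
  u2 <- uncertainty(matrix(c(0.5, 0.3, 0.2), 1), 2L)
  expect_equal(u2$nll, -log(0.3), tolerance = 1e-10)
  expect_equal(u2$mse, (0.25 + 0.49 + 0.04) / 3, tolerance = 1e-10)
  expect_equal(u2$top1_error, 1)
  expect_equal(u2$top5_error, 0)

  # zero probability on the true class hits the declared floor, not -Inf
  u3 <- uncertainty(matrix(c(1, 0), 1), 2L)
  expect_equal(u3$nll, -log(1e-12))
})

test_that("uncertainty agrees with a brute-force evaluation on random input", {
  set.seed(31)
  for (rep in 1:5) {
    M <- sample(5:40, 1); N <- sample(3:12, 1)
    probs <- matrix(rexp(M * N), M)
    probs <- probs / rowSums(probs)
    labels <- sample(N, M, replace = TRUE)
    u <- uncertainty(probs, labels)
    nll_bf <- 0; mse_bf <- 0; top1_bf <- 0; top5_bf <- 0
    for (j in 1:M) {
      for (i in 1:N) {
        yij <- as.numeric(i == labels[j])
        nll_bf <- nll_bf - yij * log(probs[j, i])
        mse_bf <- mse_bf + (yij - probs[j, i])^2
      }
      ord <- order(probs[j, ], decreasing = TRUE)
      top1_bf <- top1_bf + as.numeric(ord[1] != labels[j])
      top5_bf <- top5_bf + as.numeric(!(labels[j] %in% ord[1:min(5, N)]))
    }
    expect_lt(abs(u$nll - nll_bf / M), 1e-10)
    expect_lt(abs(u$mse - mse_bf / (M * N)), 1e-10)
    expect_equal(u$top1_error, top1_bf / M)
    expect_equal(u$top5_error, top5_bf / M)
    expect_lte(u$top5_error, u$top1_error)
  }
})
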