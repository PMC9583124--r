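# Independent oracles, kept deliberately naive.

# Direct nested-sum evaluation of one growth step: for every pixel, sum
# kernel-weighted colonization over the neighborhood (zero outside the
# field), add weighted influence, threshold at zero, apply the mask.
direct_step <- function(colony, kernel, influence = NULL, mask = NULL,
                        influence_weight = 0.002) {
  n <- nrow(colony); m <- ncol(colony)
  kc <- (nrow(kernel) - 1L) / 2L
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc <- 0
      for (di in -kc:kc) {
        for (dj in -kc:kc) {
          ii <- i - di; jj <- j - dj
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= m) {
            acc <- acc + kernel[di + kc + 1, dj + kc + 1] * colony[ii, jj]
          }
        }
      }
      if (!is.null(influence)) acc <- acc + influence_weight * influence[i, j]
      out[i, j] <- as.numeric(acc > 1e-9) # same tie guard as the implementation
    }
  }
  if (!is.null(mask)) out[!mask] <- 0
  out
}

# Raw convolution oracle (no threshold), for comparing the linear part of
# the update at full numerical precision.
direct_conv <- function(field, kernel) {
  n <- nrow(field); m <- ncol(field)
  kc <- (nrow(kernel) - 1L) / 2L
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc <- 0
      for (di in -kc:kc) {
        for (dj in -kc:kc) {
          ii <- i - di; jj <- j - dj
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= m) {
            acc <- acc + kernel[di + kc + 1, dj + kc + 1] * field[ii, jj]
          }
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Elementary-CA oracle: explicit 8-entry lookup, one cell at a time.
ca_step_oracle <- function(cells, rule, boundary = "fixed") {
  n <- length(cells)
  out <- integer(n)
  for (i in seq_len(n)) {
    l <- if (i == 1) { if (boundary == "periodic") cells[n] else 0L } else cells[i - 1]
    r <- if (i == n) { if (boundary == "periodic") cells[1] else 0L } else cells[i + 1]
    neigh <- 4L * l + 2L * cells[i] + r
    out[i] <- as.integer((rule %/% 2^neigh) %% 2)
  }
  out
}

# 1-nearest-neighbour decoder over raw pixels (the simplest possible
# decoder, used for degenerate noiseless cases).
nn1_decode <- function(train_images, train_labels, images) {
  tr <- do.call(rbind, lapply(train_images, as.vector))
  vapply(images, function(img) {
    d <- rowSums((tr - matrix(as.vector(img), nrow(tr), ncol(tr), byrow = TRUE))^2)
    train_labels[which.min(d)]
  }, integer(1))
}

# Small separable image dataset for decoder tests (class = location of a
# bright block), built in code.
toy_image_dataset <- function(n_per_class = 20, side = 20, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(ci) {
      lapply(seq_len(n_per_class), function(i) {
        m <- matrix(stats::runif(side * side) * 0.1, side)
        if (ci == 1) m[3:8, 3:8] <- m[3:8, 3:8] + 0.8
        else m[(side - 7):(side - 2), (side - 7):(side - 2)] <-
            m[(side - 7):(side - 2), (side - 7):(side - 2)] + 0.8
        pmin(m, 1)
      })
    }
    structure(
      list(images = c(mk(1), mk(2)), labels = rep(1:2, each = n_per_class),
           characters = c("A", "B"), reps_per_class = as.integer(n_per_class),
           img_side = as.integer(side), codebook_digest = "toy",
           config_digest = "toy", base_seed = as.integer(seed),
           seed_offset = 0L,
           seeds = matrix(0L, 2 * n_per_class, 2,
                          dimnames = list(NULL, c("seeding", "growth")))),
      class = "emorfi_dataset"
    )
  })
}
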