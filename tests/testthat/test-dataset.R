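st <- reduced_study(snr = 3.5, max_steps = 10) # tiny sims: shape checks only

test_that("generated datasets are balanced, deterministic and reproducible", {
  ds <- generate_dataset(st$codebook, st$layout, st$params, st$geometry,
                         reps_per_class = 4, base_seed = 5)
  expect_length(ds$images, 12)
  expect_equal(as.vector(table(ds$labels)), rep(4, 3))
  expect_true(all(vapply(ds$images, function(m) all(dim(m) == c(80, 80)), TRUE)))
  expect_true(all(vapply(ds$images, function(m) all(m >= 0 & m <= 1), TRUE)))

  ds2 <- generate_dataset(st$codebook, st$layout, st$params, st$geometry,
                          reps_per_class = 4, base_seed = 5)
  expect_identical(ds$images, ds2$images)

  # any single item regenerates exactly from its recorded seeds
  i <- 7L
  ci <- ds$labels[i]
  bits <- char_to_bits(st$codebook$characters[ci], st$codebook)
  seeding <- bits_to_seeding(bits, st$layout, seeding_noise(),
                             seed = ds$seeds[i, "seeding"])
  pat <- simulate_pattern(seeding, st$params, st$geometry,
                          seed = ds$seeds[i, "growth"])
  expect_equal(preprocess_pattern(pat, 80), ds$images[[i]])
})

test_that("train and test seed streams never overlap", {
  tr <- generate_dataset(st$codebook, st$layout, st$params, st$geometry,
                         reps_per_class = 3, base_seed = 5, seed_offset = 0)
  te <- make_test_set(st$codebook, st$layout, st$params, st$geometry,
                      reps_per_class = 3, base_seed = 5, seed_offset = 1,
                      train = tr)
  expect_length(intersect(as.vector(tr$seeds), as.vector(te$seeds)), 0)
  expect_error(
    make_test_set(st$codebook, st$layout, st$params, st$geometry,
                  reps_per_class = 3, base_seed = 5, seed_offset = 0,
                  train = tr),
    class = "emorfi_validation_error"
  )
})

test_that("preprocessing handles degenerate images and the identity case", {
  expect_true(all(preprocess_pattern(matrix(0L, 96, 96), 80) == 0))
  expect_equal(preprocess_pattern(matrix(255L, 96, 96), 80),
               matrix(1, 80, 80))
  m <- matrix(seq(0, 255, length.out = 6400), 80, 80)
  expect_equal(preprocess_pattern(m, 80), m / 255) # same side: rescale only
  expect_error(preprocess_pattern(matrix(0, 10, 20)),
               class = "emorfi_validation_error")
  # downscaling averages: a constant block stays constant
  half <- matrix(128, 96, 96)
  out <- preprocess_pattern(half, 80)
  expect_equal(range(out), c(128 / 255, 128 / 255), tolerance = 1e-6)
})

test_that("replicate subsetting is nested and consistent", {
  ds <- generate_dataset(st$codebook, st$layout, st$params, st$geometry,
                         reps_per_class = 4, base_seed = 5)
  sub <- subset_replicates(ds, 2)
  expect_equal(sub$reps_per_class, 2L)
  expect_equal(as.vector(table(sub$labels)), rep(2, 3))
  direct <- generate_dataset(st$codebook, st$layout, st$params, st$geometry,
                             reps_per_class = 2, base_seed = 5)
  expect_identical(sub$images, direct$images)
  expect_error(subset_replicates(ds, 9), class = "emorfi_validation_error")
})

test_that("datasets round-trip through the PNG + manifest directory format", {
  ds <- generate_dataset(st$codebook, st$layout, st$params, st$geometry,
                         reps_per_class = 2, base_seed = 5)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_dataset(dir)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$characters, ds$characters)
  expect_equal(back$codebook_digest, ds$codebook_digest)
  # PNG storage is 8-bit: images agree to quantization
  for (i in seq_along(ds$images)) {
    expect_lt(max(abs(back$images[[i]] - ds$images[[i]])), 1 / 255 + 1e-9)
  }
})

test_that("dataset summaries expose provenance", {
  ds <- generate_dataset(st$codebook, st$layout, st$params, st$geometry,
                         reps_per_class = 2, base_seed = 5)
  td <- tidy(ds)
  expect_equal(nrow(td), 6)
  expect_equal(td$replicate, rep(1:2, 3))
  g <- glance(ds)
  expect_equal(g$n_classes, 3L)
  expect_equal(g$reps_per_class, 2L)
  expect_match(g$config_digest, "^[0-9a-f]{16}$")
})
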