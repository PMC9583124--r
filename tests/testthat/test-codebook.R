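test_that("codebook assigns binary indices in order and round-trips", {
  cb <- build_codebook(c(LETTERS[1:5], 0:9), 4)
  expect_length(cb$characters, 15)
  expect_equal(char_to_bits("A", cb), "0001")
  expect_equal(char_to_bits("9", cb), "1111")
  for (ch in cb$characters) {
    expect_equal(bits_to_char(char_to_bits(ch, cb), cb), ch)
  }
  td <- tidy(cb)
  expect_equal(td$index, 1:15)
  expect_false(any(td$bits == "0000")) # the empty seeding is never assigned

  single <- build_codebook("A", 1)
  expect_equal(char_to_bits("A", single), "1")
})

test_that("capacity and validity are enforced", {
  expect_error(build_codebook(LETTERS[1:4], 2), class = "emorfi_capacity_error")
  expect_error(build_codebook(c("A", "A"), 2), class = "emorfi_validation_error")
  cb <- build_codebook(c("A", "B"), 2)
  expect_error(char_to_bits("Z", cb), class = "emorfi_lookup_error")
  expect_error(bits_to_char("11", cb), class = "emorfi_lookup_error")
  # 100 printable ASCII characters fit a 7-bit array
  printable <- vapply(32:131, function(i) rawToChar(as.raw(i %% 127 + 1)), "")
  printable <- unique(printable)[1:100]
  cb7 <- build_codebook(printable, 7)
  expect_length(cb7$characters, 100)
})

test_that("explicit index assignment is validated and honoured", {
  cb <- build_codebook(c("A", "B", "C"), 4, indices = c(3, 5, 6))
  expect_equal(char_to_bits("B", cb), "0101")
  expect_equal(bits_to_char("0110", cb), "C")
  expect_error(build_codebook(c("A", "B"), 2, indices = c(1, 1)),
               class = "emorfi_validation_error")
  expect_error(build_codebook(c("A", "B"), 2, indices = c(0, 1)),
               class = "emorfi_validation_error")
})

test_that("spot centers form the documented braille-like grids", {
  lay4 <- seeding_layout(4, spacing = 15, spot_radius = 5, field_side = 451)
  ctr <- spot_centers(lay4)
  expect_equal(nrow(ctr), 4)
  # 2x2 square of side 15 centered on the field
  expect_equal(sort(unique(ctr[, "row"])), 226 + c(-7.5, 7.5))
  expect_equal(sort(unique(ctr[, "col"])), 226 + c(-7.5, 7.5))
  expect_equal(colMeans(ctr), c(row = 226, col = 226))

  lay1 <- seeding_layout(1, field_side = 451)
  expect_equal(spot_centers(lay1), cbind(row = 226, col = 226),
               ignore_attr = TRUE)

  lay6 <- seeding_layout(6, spacing = 15, spot_radius = 5, field_side = 451)
  ctr6 <- spot_centers(lay6)
  expect_equal(nrow(ctr6), 6)
  expect_equal(dist_adjacent <- abs(diff(sort(unique(ctr6[, "col"])))),
               c(15, 15))
  expect_error(seeding_layout(4, spacing = 300, field_side = 96),
               class = "emorfi_geometry_error")
  expect_error(seeding_layout(4, spacing = 8, spot_radius = 5),
               class = "emorfi_geometry_error") # overlapping spots refused
})

test_that("seeding fields obey the bit string, bounds and determinism", {
  lay <- seeding_layout(4, spacing = 15, spot_radius = 5, field_side = 96)
  zero <- bits_to_seeding("0000", lay)
  expect_true(all(zero == 0))

  flat <- bits_to_seeding("1111", lay, seeding_noise(enabled = FALSE))
  expect_setequal(unique(as.vector(flat)), c(0, 0.5))
  # four disks of radius 5: pi*r^2 each, discretized
  expect_equal(sum(flat > 0), 4 * sum(outer((-5:5)^2, (-5:5)^2, `+`) <= 25))

  noisy1 <- bits_to_seeding("1010", lay, seeding_noise(deviation = 0.4), seed = 7)
  noisy2 <- bits_to_seeding("1010", lay, seeding_noise(deviation = 0.4), seed = 7)
  expect_identical(noisy1, noisy2) # bit-reproducible under a fixed seed
  expect_true(all(noisy1 >= 0 & noisy1 <= 1)) # truncation holds at large sd
  # nonzero values only inside 1-spots
  mask1 <- bits_to_seeding("1010", lay, seeding_noise(enabled = FALSE)) > 0
  expect_true(all(noisy1[!mask1] == 0))

  expect_error(bits_to_seeding("101", lay), class = "emorfi_validation_error")
})

test_that("in-spot intensities follow the truncated Gaussian", {
  # mean 0.5 with symmetric truncation at [0,1] keeps the mean at 0.5
  lay <- seeding_layout(1, spacing = 15, spot_radius = 20, field_side = 96)
  f <- bits_to_seeding("1", lay, seeding_noise(mean = 0.5, deviation = 0.3),
                       seed = 11)
  vals <- f[f > 0]
  expect_gt(length(vals), 1000)
  expect_equal(mean(vals), 0.5, tolerance = 0.02)
  expect_lt(sd(vals), 0.3) # truncation shrinks the spread
})

test_that("codebook + layout round-trip through JSON", {
  cb <- build_codebook(c("A", "B", "C"), 4, indices = c(3, 5, 6))
  path <- withr::local_tempfile(fileext = ".json")
  write_codebook(cb, path, layout = seeding_layout(4), noise = seeding_noise())
  r <- read_codebook(path)
  expect_identical(r$codebook$characters, cb$characters)
  expect_identical(as.integer(r$codebook$index), c(3L, 5L, 6L))
  expect_equal(r$layout$spacing, 15)
  expect_equal(r$noise$mean, 0.5)
})

test_that("noiseless encoding is injective across a whole codebook", {
  cb <- build_codebook(c(LETTERS[1:5], 0:9), 4)
  lay <- seeding_layout(4, spacing = 15, spot_radius = 5, field_side = 96)
  fields <- lapply(cb$characters, function(ch) {
    char_to_seeding(ch, cb, lay, seeding_noise(enabled = FALSE))
  })
  digests <- vapply(fields, function(f) obj_digest(unclass(f)), "")
  expect_equal(anyDuplicated(digests), 0L)
})
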