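test_that("kernel takes its analytic values at the default parameters", {
  p <- growth_params() # b = 6.5, d1 = 4, d2 = 10, h1 = 1000, h2 = 2000
  k <- build_kernel(p)
  cut <- attr(k, "cutoff")
  expect_equal(k[cut + 1, cut + 1], 6.5 - 1) # K(0) = b*2^0 - 2^0 = 5.5
  expect_equal(k[cut + 1, cut + 1 + 7], -1, tolerance = 1e-12) # d1 << 7 << d2
  expect_equal(k[cut + 1, cut + 1 + 15], 0, tolerance = 1e-12) # d = 1.5*d2
  # radial symmetry in the noiseless case
  km <- matrix(k, nrow(k))
  expect_equal(km, t(km))
  expect_equal(km, km[rev(seq_len(nrow(km))), rev(seq_len(ncol(km)))])
  expect_error(growth_params(d1 = 12, d2 = 10), class = "emorfi_validation_error")
  expect_error(growth_params(b = -1), class = "emorfi_validation_error")
})

test_that("kernel noise has the stated standard deviation and is per-step", {
  p <- growth_params(snr = 3.5)
  k <- build_kernel(p)
  expect_identical(sample_kernel_noise(k, NULL), k) # snr absent: identity
  support <- attr(k, "support")
  set.seed(42)
  devs <- replicate(200, {
    noisy <- sample_kernel_noise(k, 3.5)
    (noisy - k)[support]
  })
  expect_equal(sd(as.vector(devs)), attr(k, "rms") / 3.5, tolerance = 0.02)
  # fresh draw each call
  set.seed(1); a <- sample_kernel_noise(k, 3.5)
  b <- sample_kernel_noise(k, 3.5)
  expect_false(identical(a, b))
})

test_that("plate influence matches its closed form", {
  expect_equal(plate_influence(0, R = 100), -1000)
  expect_equal(plate_influence(100, R = 100, epsilon = 1), -500)
  expect_lt(abs(plate_influence(50, R = 100, epsilon = 2000)), 1e-290)
  g <- domain_geometry("circle", field_side = 96, epsilon = 1)
  I <- boundary_influence_field(g)
  expect_true(all(I <= 0))
  expect_equal(min(I[g$mask]), -1000 * 2^(-1 / g$R), tolerance = 1e-10)
  # monotone toward 0 with boundary distance
  ord <- order(g$dist[g$mask])
  expect_true(all(diff(I[g$mask][ord]) >= -1e-12))
})

test_that("domain geometries have equal areas and sane distance fields", {
  geos <- equal_area_geometries(field_side = 121, area_frac = 0.35)
  areas <- vapply(geos, function(g) sum(g$mask), 0)
  target <- 0.35 * 121^2
  expect_true(all(abs(areas - target) / target < 0.03))
  for (g in geos) {
    expect_gt(g$R, 0)
    expect_true(all(g$dist[!g$mask] == 0))
    expect_equal(max(g$dist), g$R)
    # boundary pixels are within one pixel of the outside
    boundary <- g$mask & g$dist <= 1.5
    expect_gt(sum(boundary), 0)
  }
  # circle R approximates the geometric radius
  gc <- geos$circle
  expect_equal(gc$R, sqrt(0.35 * 121^2 / pi), tolerance = 0.03)
})

test_that("FFT stepping equals the direct nested-sum oracle", {
  set.seed(7)
  p <- growth_params(d2 = 4, kernel_cutoff = 6)
  k <- build_kernel(p)
  g <- domain_geometry("circle", field_side = 32, area_frac = 0.6)
  I <- boundary_influence_field(g)
  for (rep in 1:3) {
    colony <- matrix(runif(32 * 32), 32, 32) * g$mask
    # linear part at full precision
    expect_lt(max(abs(conv2_fft(colony, unclass(k)) -
                        direct_conv(colony, unclass(k)))), 1e-8)
    # full update including influence, threshold and mask
    expect_equal(
      growth_step(colony, k, I, g$mask, influence_weight = 0.002),
      direct_step(colony, unclass(k), I, g$mask, influence_weight = 0.002)
    )
  }
  # a noisy kernel goes through the same path
  set.seed(8)
  kn <- sample_kernel_noise(k, 2)
  colony <- matrix(runif(32 * 32), 32, 32) * g$mask
  expect_lt(max(abs(conv2_fft(colony, unclass(kn)) -
                      direct_conv(colony, unclass(kn)))), 1e-8)
})

test_that("growth conserves bounds and the domain mask at every step", {
  st <- reduced_study(snr = 2, max_steps = 12)
  s <- bits_to_seeding("11", st$layout, seeding_noise(), seed = 3)
  k <- build_kernel(st$params)
  I <- boundary_influence_field(st$geometry)
  colony <- unclass(s)
  set.seed(9)
  for (t in 1:12) {
    colony <- growth_step(colony, sample_kernel_noise(k, st$params$snr), I,
                          st$geometry$mask)
    expect_true(all(colony >= 0 & colony <= 1))
    expect_true(all(colony[!st$geometry$mask] == 0))
  }
})

test_that("simulation is deterministic and terminates sensibly", {
  st <- reduced_study(snr = 3.5, max_steps = 15)
  s <- bits_to_seeding("10", st$layout, seeding_noise(), seed = 5)
  a <- simulate_pattern(s, st$params, st$geometry, seed = 6)
  b <- simulate_pattern(s, st$params, st$geometry, seed = 6)
  expect_identical(unclass(a), unclass(b))
  expect_true(all(a %in% 0:255))

  zero <- bits_to_seeding("00", st$layout)
  z <- simulate_pattern(zero, st$params, st$geometry, seed = 1)
  expect_true(all(z == 0))
  expect_true(attr(z, "converged"))
  expect_lte(attr(z, "steps"), st$params$stop_patience + 1L)
})

test_that("noiseless growth preserves four-fold symmetry", {
  # symmetric seeding (all four spots) on a circular domain, no noise
  lay <- seeding_layout(4, spacing = 14, spot_radius = 3, field_side = 95)
  geo <- domain_geometry("circle", field_side = 95, area_frac = pi / 4)
  p <- growth_params(d2 = 5, max_steps = 25)
  s <- bits_to_seeding("1111", lay, seeding_noise(enabled = FALSE))
  pat <- matrix(simulate_pattern(s, p, geo), 95)
  expect_identical(pat, pat[rev(seq_len(95)), ])   # mirror rows
  expect_identical(pat, pat[, rev(seq_len(95))])   # mirror cols
  expect_identical(pat, t(pat))                    # transpose
})

test_that("morphology phases follow the expansion/inhibition balance", {
  st <- reduced_study(snr = NULL, max_steps = 25)
  s <- bits_to_seeding("11", st$layout, seeding_noise(), seed = 42)
  geo <- st$geometry

  branching <- simulate_pattern(s, st$params, geo, seed = 7)
  expect_equal(classify_morphology(branching, s, geo$mask), "branching")

  disk <- simulate_pattern(s, growth_params(b = 30, d2 = 5, max_steps = 25),
                           geo, seed = 7)
  expect_equal(classify_morphology(disk, s, geo$mask), "disk")

  # degenerate checks of the classifier itself
  expect_equal(
    classify_morphology(matrix(255L, 96, 96), matrix(1, 96, 96), geo$mask),
    "disk"
  )
  seed_img <- matrix(as.integer(round(255 * pmin(unclass(s), 1))), 96, 96)
  expect_equal(classify_morphology(seed_img, s, geo$mask), "trivial")
})

test_that("center cropping zeroes outside the circle and nothing else", {
  st <- reduced_study(max_steps = 10)
  s <- bits_to_seeding("11", st$layout, seeding_noise(), seed = 2)
  pat <- simulate_pattern(s, st$params, st$geometry, seed = 3)

  big <- crop_center(pat, 1000)
  expect_identical(unclass(big)[, ], unclass(pat)[, ])

  zero <- crop_center(matrix(0L, 96, 96), 10)
  expect_true(all(zero == 0))

  r <- 20
  cc <- crop_center(pat, r)
  mid <- (96 + 1) / 2
  d2 <- outer((1:96 - mid)^2, (1:96 - mid)^2, `+`)
  expect_true(all(cc[d2 > r^2] == 0))
  expect_identical(cc[d2 <= r^2], unclass(pat)[d2 <= r^2])

  # identical masks regardless of the domain the pattern grew on
  gsq <- domain_geometry("square", field_side = 96, area_frac = 0.4)
  psq <- simulate_pattern(s, st$params, gsq, seed = 3)
  csq <- crop_center(psq, r)
  expect_true(all(csq[d2 > r^2] == 0))

  expect_error(crop_center(pat, 0), class = "emorfi_validation_error")
})
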