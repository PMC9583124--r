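# Shared tiny generator + decoder for codec tests (built once per file).
codec_env <- local({
  st <- reduced_study(snr = 3.5, max_steps = 15, epochs = 15)
  tr <- generate_dataset(st$codebook, st$layout, st$params, st$geometry,
                         reps_per_class = 8, base_seed = 31, seed_offset = 0)
  model <- train_decoder(tr, st$spec, seed = 2)
  list(st = st, model = model)
})

test_that("frame sequences count and order ballots correctly", {
  st <- codec_env$st
  fr <- encode_text("AB", st$codebook, st$layout, st$params, st$geometry,
                    frames_per_char = 5, base_seed = 7)
  expect_length(fr$frames, 10)
  expect_equal(fr$frames_per_char, 5L)
  # first five frames encode the first character: regenerate frame 3 directly
  bits <- char_to_bits("A", st$codebook)
  s <- bits_to_seeding(bits, st$layout, seeding_noise(),
                       seed = derive_seed(7, 1, 3, 1))
  pat <- simulate_pattern(s, st$params, st$geometry,
                          seed = derive_seed(7, 1, 3, 2))
  expect_equal(fr$frames[[3]], preprocess_pattern(pat, 80))

  empty <- encode_text("", st$codebook, st$layout, st$params, st$geometry,
                       frames_per_char = 5, base_seed = 7)
  expect_length(empty$frames, 0)

  expect_error(
    encode_text("AZ!", st$codebook, st$layout, st$params, st$geometry),
    class = "emorfi_encoding_error"
  )
})

test_that("lossless video round-trips frames bit-exactly", {
  st <- codec_env$st
  fr <- encode_text("CAB", st$codebook, st$layout, st$params, st$geometry,
                    frames_per_char = 2, base_seed = 8)
  dir <- withr::local_tempdir()
  frames_to_video(fr, dir)
  back <- video_to_frames(dir)
  expect_length(back$frames, length(fr$frames))
  expect_equal(back$frames_per_char, fr$frames_per_char)
  # 8-bit quantized content is preserved exactly
  q <- function(m) floor(255 * m + 0.5)
  for (i in seq_along(fr$frames)) {
    expect_identical(q(back$frames[[i]]), q(fr$frames[[i]]))
  }
})

test_that("lossy export round-trips approximately and stays decodable", {
  st <- codec_env$st
  fr <- encode_text("BC", st$codebook, st$layout, st$params, st$geometry,
                    frames_per_char = 3, base_seed = 9)
  dir <- withr::local_tempdir()
  frames_to_video(fr, dir, lossless = FALSE, quality = 90)
  back <- video_to_frames(dir)
  # not exact, but close (PSNR well above 20 dB)
  for (i in seq_along(fr$frames)) {
    mse <- mean((back$frames[[i]] - fr$frames[[i]])^2)
    expect_lt(mse, 0.01)
  }
  dec_lossy <- decode_frames(back, codec_env$model)
  dec_exact <- decode_frames(fr, codec_env$model)
  # mild compression does not change most voted decisions
  expect_gte(mean(dec_lossy$decoded == dec_exact$decoded), 0.5)
})

test_that("decoding is a pure function of frames and model", {
  st <- codec_env$st
  fr <- encode_text("BAC", st$codebook, st$layout, st$params, st$geometry,
                    frames_per_char = 3, base_seed = 10)
  d1 <- decode_frames(fr, codec_env$model)
  d2 <- decode_frames(fr, codec_env$model)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 3)
  expect_true(all(d1$confidence >= 0 & d1$confidence <= 1))

  # scrambling ballot groups permutes the decoded message accordingly
  perm <- fr
  perm$frames <- fr$frames[c(7:9, 1:3, 4:6)]
  d3 <- decode_frames(perm, codec_env$model)
  expect_equal(d3$decoded, d1$decoded[c(3, 1, 2)])

  bad <- fr
  bad$frames <- fr$frames[1:8]
  expect_error(decode_frames(bad, codec_env$model),
               class = "emorfi_framing_error")
})

test_that("a noiseless generator round-trips text exactly", {
  st <- reduced_study(snr = NULL, max_steps = 15, epochs = 60)
  # without any noise every replicate of a character is identical
  tr <- generate_dataset(st$codebook, st$layout, st$params, st$geometry,
                         reps_per_class = 1, base_seed = 41,
                         noise = seeding_noise(enabled = FALSE))
  expect_identical(tr$images[[1]],
                   generate_dataset(st$codebook, st$layout, st$params,
                                    st$geometry, reps_per_class = 1,
                                    base_seed = 99,
                                    noise = seeding_noise(enabled = FALSE))$images[[1]])
  model <- train_decoder(tr, st$spec, seed = 3)
  fr <- encode_text("CAB", st$codebook, st$layout, st$params, st$geometry,
                    frames_per_char = 1, base_seed = 55,
                    noise = seeding_noise(enabled = FALSE))
  dec <- decode_frames(fr, model)
  expect_equal(attr(dec, "text"), "CAB")
})
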