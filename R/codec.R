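#' Encode text as a sequence of pattern frames
#'
#' Each character of the message is simulated `frames_per_char` times
#' (fresh seeding and growth noise per frame) and the frames are arranged in
#' message order: frames `1..frames_per_char` encode the first character,
#' the next `frames_per_char` the second, and so on. The replicate frames
#' are the ballots for majority-vote decoding.
#'
#' @param text Character scalar; every character must be in the codebook.
#' @param codebook An `emorfi_codebook`.
#' @param layout,params,geometry Generator configuration (see
#'   [generate_dataset()]).
#' @param frames_per_char Ballots per character (default 5).
#' @param base_seed Integer seed for the whole message.
#' @param noise Seeding noise.
#' @param img_side Frame side after preprocessing (default 80).
#' @param crop_radius Optional center-crop before preprocessing.
#' @param influence_weight Passed to [simulate_pattern()].
#' @return An `emorfi_frames`: list of `img_side` x `img_side` matrices in
#'   `[0, 1]` with fields `text`, `frames_per_char`, `codebook_digest`.
#' @export
encode_text <- function(text, codebook, layout, params = growth_params(),
                        geometry = NULL, frames_per_char = 5L,
                        base_seed = 1L, noise = seeding_noise(),
                        img_side = 80L, crop_radius = NULL,
                        influence_weight = 0.002) {
  chars <- strsplit(text, "")[[1]]
  unknown <- setdiff(unique(chars), codebook$characters)
  if (length(unknown) > 0) {
    abort_emorfi(
      sprintf("characters not in codebook: %s",
              paste(vapply(unknown, deparse, ""), collapse = ", ")),
      "emorfi_encoding_error"
    )
  }
  if (is.null(geometry)) {
    geometry <- domain_geometry("circle", field_side = layout$field_side,
                                area_frac = pi / 4)
  }
  frames <- vector("list", length(chars) * frames_per_char)
  i <- 0L
  for (pos in seq_along(chars)) {
    bits <- char_to_bits(chars[pos], codebook)
    for (b in seq_len(frames_per_char)) {
      i <- i + 1L
      seeding <- bits_to_seeding(bits, layout, noise,
                                 seed = derive_seed(base_seed, pos, b, 1L))
      pat <- simulate_pattern(seeding, params, geometry,
                              seed = derive_seed(base_seed, pos, b, 2L),
                              influence_weight = influence_weight)
      if (!is.null(crop_radius)) pat <- crop_center(pat, crop_radius)
      frames[[i]] <- preprocess_pattern(pat, img_side)
    }
  }
  structure(
    list(frames = frames, text = text,
         frames_per_char = as.integer(frames_per_char),
         codebook_digest = obj_digest(unclass(codebook))),
    class = "emorfi_frames"
  )
}

#' @export
print.emorfi_frames <- function(x, ...) {
  cat(sprintf("<emorfi_frames> %d frames (%d chars x %d ballots)\n",
              length(x$frames),
              length(x$frames) %/% x$frames_per_char, x$frames_per_char))
  invisible(x)
}

#' Write frames as a numbered-image "video" directory
#'
#' The default container is a directory of numbered frames plus a sidecar
#' JSON (`frames.json`) with the ballot count and codebook digest. Lossless
#' mode writes PNG and round-trips bit-exactly at 8-bit depth; lossy mode
#' writes JPEG at the given quality and round-trips only approximately (the
#' decoder tolerates mild compression).
#'
#' @param frames An `emorfi_frames`.
#' @param dir Output directory.
#' @param lossless Write PNG (`TRUE`, default) or JPEG.
#' @param quality JPEG quality in (0, 100], lossy mode only.
#' @return `dir`, invisibly.
#' @export
frames_to_video <- function(frames, dir, lossless = TRUE, quality = 90) {
  stopifnot(inherits(frames, "emorfi_frames"))
  if (length(frames$frames) == 0) {
    abort_emorfi("no frames to write", "emorfi_validation_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (lossless) "png" else "jpg"
  if (!lossless && !requireNamespace("EBImage", quietly = TRUE)) {
    abort_emorfi("lossy frame export needs the EBImage JPEG writer",
                 "emorfi_codec_error")
  }
  files <- sprintf("frame%05d.%s", seq_along(frames$frames), ext)
  for (i in seq_along(frames$frames)) {
    # quantize to 8-bit explicitly so lossless round-trips are bit-exact
    img <- floor(255 * frames$frames[[i]] + 0.5) / 255
    path <- file.path(dir, files[i])
    if (lossless) {
      png::writePNG(img, path)
    } else {
      EBImage::writeImage(EBImage::Image(img), path, quality = quality)
    }
  }
  jsonlite::write_json(
    list(frames_per_char = frames$frames_per_char,
         codebook_digest = frames$codebook_digest,
         n_frames = length(frames$frames), files = files,
         lossless = lossless),
    file.path(dir, "frames.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' Read frames back from a video directory
#'
#' @param dir Directory written by [frames_to_video()].
#' @return An `emorfi_frames` (with `text = NA`, to be recovered by
#'   [decode_frames()]).
#' @export
video_to_frames <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "frames.json"),
                              simplifyVector = TRUE)
  frames <- lapply(meta$files, function(f) {
    path <- file.path(dir, f)
    img <- if (grepl("\\.png$", f)) {
      png::readPNG(path)
    } else {
      as.matrix(EBImage::imageData(EBImage::readImage(path)))
    }
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
  structure(
    list(frames = frames, text = NA_character_,
         frames_per_char = as.integer(meta$frames_per_char),
         codebook_digest = meta$codebook_digest),
    class = "emorfi_frames"
  )
}

#' Decode a frame sequence back to text
#'
#' Groups frames into consecutive ballots of `frames_per_char`, decodes each
#' frame with the model, and majority-votes within each group (ties broken
#' by summed probability).
#'
#' @param frames An `emorfi_frames`, or plain list of image matrices.
#' @param model An `emorfi_decoder` or `emorfi_ensemble` (with stored bases).
#' @param frames_per_char Ballots per character; defaults to the value
#'   stored in `frames`.
#' @return A tibble with one row per character: `position`, `decoded`, and
#'   `confidence` (mean winning-class probability across ballots); the
#'   decoded text is in `attr(, "text")`.
#' @export
decode_frames <- function(frames, model, frames_per_char = NULL) {
  imgs <- if (inherits(frames, "emorfi_frames")) frames$frames else frames
  fpc <- frames_per_char %||%
    (if (inherits(frames, "emorfi_frames")) frames$frames_per_char else 1L)
  if (length(imgs) %% fpc != 0) {
    abort_emorfi(sprintf(
      "%d frames do not divide into ballots of %d", length(imgs), fpc
    ), "emorfi_framing_error")
  }
  if (length(imgs) == 0) {
    out <- tibble(position = integer(0), decoded = character(0),
                  confidence = numeric(0))
    attr(out, "text") <- ""
    return(out)
  }
  p <- if (inherits(model, "emorfi_ensemble")) {
    predict_proba_ensemble(model, imgs)
  } else {
    predict_proba(model, imgs)
  }
  characters <- colnames(p)
  n_chars <- length(imgs) %/% fpc
  decoded <- character(n_chars)
  confidence <- numeric(n_chars)
  for (g in seq_len(n_chars)) {
    rows <- ((g - 1L) * fpc + 1L):(g * fpc)
    ballots <- characters[max.col(p[rows, , drop = FALSE], ties.method = "first")]
    decoded[g] <- majority_vote(ballots, p[rows, , drop = FALSE])
    confidence[g] <- mean(p[rows, decoded[g]])
  }
  out <- tibble(position = seq_len(n_chars), decoded = decoded,
                confidence = confidence)
  attr(out, "text") <- paste(decoded, collapse = "")
  out
}
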