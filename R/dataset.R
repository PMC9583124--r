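#' Preprocess a pattern image for decoding
#'
#' Anti-aliased bilinear downscale of a square 8-bit pattern to
#' `side x side` (default 80), rescaled to `[0, 1]`. An input already at the
#' target side is only rescaled.
#'
#' @param pattern An `emorfi_pattern` or square numeric matrix (0..255).
#' @param side Output side in pixels.
#' @return A `side x side` numeric matrix in `[0, 1]`.
#' @export
preprocess_pattern <- function(pattern, side = 80L) {
  m <- unclass(pattern)
  attributes(m) <- list(dim = dim(m))
  if (nrow(m) != ncol(m)) {
    abort_emorfi("pattern must be square", "emorfi_validation_error")
  }
  m <- m / 255
  if (nrow(m) != side) {
    m <- as.matrix(EBImage::imageData(
      EBImage::resize(EBImage::Image(m), w = side, h = side,
                      filter = "bilinear", antialias = TRUE)
    ))
  }
  pmin(pmax(m, 0), 1)
}

#' Generate a balanced labeled pattern dataset
#'
#' For every codebook character, runs `reps_per_class` independent
#' simulations (fresh seeding noise and kernel-noise stream per replicate),
#' preprocesses each final pattern to `img_side`, and returns a balanced
#' labeled dataset. Replicate seeds are derived from
#' `(base_seed, seed_offset, class, replicate)`, so the whole dataset — or
#' any single item — is reproducible, and datasets built with different
#' `seed_offset`s (e.g. train vs test) share no seeds.
#'
#' @param codebook An `emorfi_codebook`.
#' @param layout An `emorfi_layout` with matching `n_bits`.
#' @param params An `emorfi_growth_params`.
#' @param geometry An `emorfi_geometry`, or `NULL` for the default full-field
#'   circular plate.
#' @param reps_per_class Replicates per character (>= 1).
#' @param base_seed Integer base seed.
#' @param noise An `emorfi_seeding_noise`.
#' @param img_side Preprocessed image side (default 80).
#' @param crop_radius Optional center-crop radius applied to each raw
#'   pattern before preprocessing (used for shape-key encryption).
#' @param seed_offset Integer stream offset; keep it distinct between train
#'   and test sets.
#' @param influence_weight Passed to [simulate_pattern()].
#' @return An `emorfi_dataset`: list with `images` (list of matrices),
#'   `labels` (integer class indices), `characters`, `reps_per_class`, and
#'   provenance (`codebook_digest`, `config_digest`, `base_seed`,
#'   `seed_offset`, per-item `seeds`).
#' @export
generate_dataset <- function(codebook, layout, params = growth_params(),
                             geometry = NULL, reps_per_class = 10L,
                             base_seed = 1L, noise = seeding_noise(),
                             img_side = 80L, crop_radius = NULL,
                             seed_offset = 0L, influence_weight = 0.002) {
  stopifnot(inherits(codebook, "emorfi_codebook"))
  if (reps_per_class < 1L) {
    abort_emorfi("reps_per_class must be >= 1", "emorfi_validation_error")
  }
  if (is.null(geometry)) {
    geometry <- domain_geometry("circle", field_side = layout$field_side,
                                area_frac = pi / 4)
  }
  n_class <- length(codebook$characters)
  images <- vector("list", n_class * reps_per_class)
  labels <- integer(length(images))
  seeds <- matrix(0L, length(images), 2,
                  dimnames = list(NULL, c("seeding", "growth")))
  i <- 0L
  for (ci in seq_len(n_class)) {
    bits <- char_to_bits(codebook$characters[[ci]], codebook)
    for (r in seq_len(reps_per_class)) {
      i <- i + 1L
      s_seed <- derive_seed(base_seed, seed_offset, ci, r, 1L)
      g_seed <- derive_seed(base_seed, seed_offset, ci, r, 2L)
      seeding <- bits_to_seeding(bits, layout, noise, seed = s_seed)
      pat <- tryCatch(
        simulate_pattern(seeding, params, geometry, seed = g_seed,
                         influence_weight = influence_weight),
        error = function(e) {
          abort_emorfi(sprintf(
            "simulation failed for class %d (%s), replicate %d: %s",
            ci, codebook$characters[[ci]], r, conditionMessage(e)
          ), "emorfi_simulation_error")
        }
      )
      if (!is.null(crop_radius)) pat <- crop_center(pat, crop_radius)
      images[[i]] <- preprocess_pattern(pat, img_side)
      labels[i] <- ci
      seeds[i, ] <- c(s_seed, g_seed)
    }
  }
  structure(
    list(
      images = images, labels = labels, characters = codebook$characters,
      reps_per_class = as.integer(reps_per_class), img_side = as.integer(img_side),
      codebook_digest = obj_digest(unclass(codebook)),
      config_digest = obj_digest(list(
        params = unclass(params), layout = unclass(layout),
        shape = geometry$shape, area = geometry$area,
        epsilon = geometry$epsilon, noise = unclass(noise),
        crop_radius = crop_radius, influence_weight = influence_weight
      )),
      base_seed = as.integer(base_seed), seed_offset = as.integer(seed_offset),
      seeds = seeds
    ),
    class = "emorfi_dataset"
  )
}

#' Generate a held-out test set
#'
#' Same contract as [generate_dataset()] but on a seed stream that must be
#' disjoint from the training stream: generating train and test with the
#' same `base_seed` and `seed_offset` is refused.
#'
#' @inheritParams generate_dataset
#' @param train An optional `emorfi_dataset` to check disjointness against.
#' @param reps_per_class Test replicates per class (default 100, the
#'   standard evaluation size).
#' @param seed_offset Defaults to 1 (training uses 0).
#' @export
make_test_set <- function(codebook, layout, params = growth_params(),
                          geometry = NULL, reps_per_class = 100L,
                          base_seed = 1L, noise = seeding_noise(),
                          img_side = 80L, crop_radius = NULL,
                          seed_offset = 1L, influence_weight = 0.002,
                          train = NULL) {
  if (!is.null(train) && train$base_seed == base_seed &&
      train$seed_offset == seed_offset) {
    abort_emorfi("test seed stream overlaps the training stream",
                 "emorfi_validation_error")
  }
  generate_dataset(codebook, layout, params, geometry, reps_per_class,
                   base_seed, noise, img_side, crop_radius, seed_offset,
                   influence_weight)
}

#' @export
print.emorfi_dataset <- function(x, ...) {
  cat(sprintf(
    "<emorfi_dataset> %d items: %d classes x %d replicates, %dx%d px\n",
    length(x$images), length(x$characters), x$reps_per_class,
    x$img_side, x$img_side
  ))
  invisible(x)
}

#' Subsample replicates per class
#'
#' Keeps the first `reps` replicates of each class (replicate order is the
#' generation order, so this is deterministic and nested: the 10-replicate
#' subset of a 100-replicate dataset equals the directly generated
#' 10-replicate dataset).
#'
#' @param dataset An `emorfi_dataset`.
#' @param reps Number of replicates per class to keep.
#' @export
subset_replicates <- function(dataset, reps) {
  if (reps > dataset$reps_per_class) {
    abort_emorfi("not enough replicates to subset", "emorfi_validation_error")
  }
  keep <- unlist(lapply(seq_along(dataset$characters), function(ci) {
    which(dataset$labels == ci)[seq_len(reps)]
  }))
  out <- dataset
  out$images <- dataset$images[keep]
  out$labels <- dataset$labels[keep]
  out$seeds <- dataset$seeds[keep, , drop = FALSE]
  out$reps_per_class <- as.integer(reps)
  out
}

#' Summarize a dataset
#'
#' @param x An `emorfi_dataset`.
#' @param ... Unused.
#' @return One row per item: `character`, `label`, `replicate`, the two
#'   item seeds and the mean image intensity.
#' @export
tidy.emorfi_dataset <- function(x, ...) {
  tibble(
    character = x$characters[x$labels],
    label = x$labels,
    replicate = unlist(lapply(table(x$labels), seq_len), use.names = FALSE),
    seeding_seed = x$seeds[, "seeding"],
    growth_seed = x$seeds[, "growth"],
    mean_intensity = vapply(x$images, mean, 0)
  )
}

#' @export
glance.emorfi_dataset <- function(x, ...) {
  tibble(
    n_items = length(x$images),
    n_classes = length(x$characters),
    reps_per_class = x$reps_per_class,
    img_side = x$img_side,
    base_seed = x$base_seed,
    seed_offset = x$seed_offset,
    codebook_digest = x$codebook_digest,
    config_digest = x$config_digest
  )
}

#' Write a dataset to disk as PNG files plus a JSON manifest
#'
#' One directory per class holding `rep%03d.png` files, and `manifest.json`
#' recording characters, seeds, digests and geometry so the dataset can be
#' audited or selectively regenerated.
#'
#' @param dataset An `emorfi_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep_counter <- integer(length(dataset$characters))
  files <- character(length(dataset$images))
  for (i in seq_along(dataset$images)) {
    ci <- dataset$labels[i]
    rep_counter[ci] <- rep_counter[ci] + 1L
    cls_dir <- file.path(dir, sprintf("class%03d", ci))
    dir.create(cls_dir, showWarnings = FALSE)
    files[i] <- file.path(cls_dir, sprintf("rep%03d.png", rep_counter[ci]))
    png::writePNG(dataset$images[[i]], files[i])
  }
  manifest <- list(
    characters = dataset$characters,
    labels = dataset$labels,
    files = files,
    reps_per_class = dataset$reps_per_class,
    img_side = dataset$img_side,
    base_seed = dataset$base_seed,
    seed_offset = dataset$seed_offset,
    codebook_digest = dataset$codebook_digest,
    config_digest = dataset$config_digest,
    seeds = as.data.frame(dataset$seeds)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return An `emorfi_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  images <- lapply(manifest$files, function(f) {
    img <- png::readPNG(if (file.exists(f)) f else file.path(dir, basename(dirname(f)), basename(f)))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
  structure(
    list(
      images = images, labels = as.integer(manifest$labels),
      characters = manifest$characters,
      reps_per_class = as.integer(manifest$reps_per_class),
      img_side = as.integer(manifest$img_side),
      codebook_digest = manifest$codebook_digest,
      config_digest = manifest$config_digest,
      base_seed = as.integer(manifest$base_seed),
      seed_offset = as.integer(manifest$seed_offset),
      seeds = as.matrix(manifest$seeds)
    ),
    class = "emorfi_dataset"
  )
}
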