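#' Seeding layout for braille-like spot arrays
#'
#' A layout places `n_bits` circular inoculation spots on a near-square grid
#' centered on the field. Bit k of a character's binary string (most
#' significant first) controls grid cell k in row-major order: bit 1 seeds the
#' spot, bit 0 leaves it empty.
#'
#' @param n_bits Number of spots (binary digits).
#' @param spacing Center-to-center distance between adjacent spots, pixels.
#' @param spot_radius Spot radius, pixels.
#' @param field_side Side of the square field, pixels.
#' @param grid_rows,grid_cols Spot-grid shape; defaults to the smallest
#'   near-square row-major grid holding `n_bits` cells (1x1, 1x2, 2x2, 2x3,
#'   2x4 for 1, 2, 4, 5-6, 7-8 bits).
#' @param allow_overlap Permit `spacing <= 2 * spot_radius` (overlapping
#'   spots); off by default.
#' @return An `emorfi_layout` object.
#' @examples
#' seeding_layout(4) # the default 2x2, spacing 15, radius 5 array
#' @export
seeding_layout <- function(n_bits, spacing = 15, spot_radius = 5,
                           field_side = 451L, grid_rows = NULL,
                           grid_cols = NULL, allow_overlap = FALSE) {
  n_bits <- as.integer(n_bits)
  if (n_bits < 1L) abort_emorfi("n_bits must be >= 1", "emorfi_validation_error")
  if (is.null(grid_rows) || is.null(grid_cols)) {
    grid_rows <- floor(sqrt(n_bits))
    grid_cols <- ceiling(n_bits / grid_rows)
  }
  if (grid_rows * grid_cols < n_bits) {
    abort_emorfi("grid too small for n_bits spots", "emorfi_geometry_error")
  }
  if (n_bits > 1L && !allow_overlap && spacing <= 2 * spot_radius) {
    abort_emorfi("spots overlap: spacing must exceed 2 * spot_radius",
                 "emorfi_geometry_error")
  }
  layout <- structure(
    list(
      n_bits = n_bits, spacing = spacing, spot_radius = spot_radius,
      field_side = as.integer(field_side),
      grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols)
    ),
    class = "emorfi_layout"
  )
  centers <- spot_centers(layout)
  if (any(centers - spot_radius < 1) ||
      any(centers + spot_radius > field_side)) {
    abort_emorfi("spots exceed field bounds", "emorfi_geometry_error")
  }
  layout
}

#' @export
print.emorfi_layout <- function(x, ...) {
  cat(sprintf(
    "<emorfi_layout> %d spots on %dx%d grid, spacing %g px, radius %g px, field %d px\n",
    x$n_bits, x$grid_rows, x$grid_cols, x$spacing, x$spot_radius, x$field_side
  ))
  invisible(x)
}

#' Spot centers of a seeding layout
#'
#' @param layout An `emorfi_layout`.
#' @return A matrix with one `(row, col)` center per bit, in pixel
#'   coordinates (1-based), bit order = row-major grid order.
#' @export
spot_centers <- function(layout) {
  stopifnot(inherits(layout, "emorfi_layout"))
  mid <- (layout$field_side + 1) / 2
  row_off <- (seq_len(layout$grid_rows) - (layout$grid_rows + 1) / 2) * layout$spacing
  col_off <- (seq_len(layout$grid_cols) - (layout$grid_cols + 1) / 2) * layout$spacing
  centers <- cbind(
    row = mid + rep(row_off, each = layout$grid_cols),
    col = mid + rep(col_off, times = layout$grid_rows)
  )
  centers[seq_len(layout$n_bits), , drop = FALSE]
}

#' Seeding-noise description
#'
#' Uneven cell inoculation is modelled by drawing every in-spot pixel's
#' intensity i.i.d. from a Gaussian truncated to `[0, 1]` (rejection
#' sampling). With `enabled = FALSE` spots are seeded uniformly at `mean`.
#'
#' @param enabled Draw random intensities (default `TRUE`).
#' @param mean Mean of the untruncated Gaussian, default 0.5.
#' @param deviation Standard deviation of the untruncated Gaussian.
#' @return An `emorfi_seeding_noise` object.
#' @export
seeding_noise <- function(enabled = TRUE, mean = 0.5, deviation = 0.15) {
  if (deviation < 0) abort_emorfi("deviation must be >= 0", "emorfi_validation_error")
  structure(list(enabled = isTRUE(enabled), mean = mean, deviation = deviation),
            class = "emorfi_seeding_noise")
}

rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, draw[draw >= 0 & draw <= 1])
  }
  out[seq_len(n)]
}

#' Build a seeding field from a bit string
#'
#' Every pixel within `spot_radius` of the center of a 1-bit's spot receives
#' an intensity draw from the truncated Gaussian; 0-bit spots and background
#' stay zero.
#'
#' @param bits Binary string of length `layout$n_bits`.
#' @param layout An `emorfi_layout`.
#' @param noise An `emorfi_seeding_noise` (default: enabled, mean 0.5,
#'   deviation 0.15).
#' @param seed Optional integer seed making the draw reproducible.
#' @return An `emorfi_field`: a `field_side` x `field_side` numeric matrix in
#'   `[0, 1]` with provenance attributes.
#' @export
bits_to_seeding <- function(bits, layout, noise = seeding_noise(), seed = NULL) {
  stopifnot(inherits(layout, "emorfi_layout"))
  digits <- strsplit(bits, "")[[1]]
  if (length(digits) != layout$n_bits || !all(digits %in% c("0", "1"))) {
    abort_emorfi(sprintf(
      "bit string %s does not match the %d-bit layout", deparse(bits), layout$n_bits
    ), "emorfi_validation_error")
  }
  field <- matrix(0, layout$field_side, layout$field_side)
  centers <- spot_centers(layout)
  draw <- function(n) {
    if (noise$enabled) rtruncnorm01(n, noise$mean, noise$deviation)
    else rep(noise$mean, n)
  }
  fill <- function() {
    for (k in which(digits == "1")) {
      rr <- round(centers[k, "row"]); cc <- round(centers[k, "col"])
      r <- layout$spot_radius
      rows <- max(1, rr - r):min(layout$field_side, rr + r)
      cols <- max(1, cc - r):min(layout$field_side, cc + r)
      dist2 <- outer((rows - centers[k, "row"])^2, (cols - centers[k, "col"])^2, `+`)
      inside <- dist2 <= r^2
      vals <- matrix(0, length(rows), length(cols))
      vals[inside] <- draw(sum(inside))
      field[rows, cols] <<- pmax(field[rows, cols], vals)
    }
  }
  if (is.null(seed)) fill() else with_seed(seed, fill())
  structure(field, class = c("emorfi_field", "matrix"),
            bits = bits, seed = seed)
}

#' Seed a character directly
#'
#' Convenience wrapper: `char -> bits -> seeding field`.
#'
#' @inheritParams bits_to_seeding
#' @param char Character to encode.
#' @param codebook An `emorfi_codebook`.
#' @export
char_to_seeding <- function(char, codebook, layout, noise = seeding_noise(),
                            seed = NULL) {
  if (layout$n_bits != codebook$n_bits) {
    abort_emorfi("layout and codebook disagree on n_bits", "emorfi_validation_error")
  }
  f <- bits_to_seeding(char_to_bits(char, codebook), layout, noise, seed)
  attr(f, "character") <- char
  f
}
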