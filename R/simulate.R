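#' One discrete growth step
#'
#' Computes the local growth activation — the zero-padded convolution of the
#' (possibly noise-perturbed) kernel with the colonization field, plus the
#' weighted plate influence — and colonizes exactly the pixels where it is
#' positive:
#' \deqn{N_{t+1} = \mathbf{1}\big[\mathrm{conv}(K, N_t) + w_I\, I > 0\big].}
#' A pixel keeps or gains colonization when short-range expansion from its
#' occupied neighborhood outweighs the longer-range inhibition (plus any
#' boundary suppression); otherwise it empties. With the default parameters
#' expansion and inhibition are nearly balanced, so a growing front is
#' unstable and splits into branches. Pixels outside the growth domain are
#' forced to zero after every step.
#'
#' The convolution runs through padded FFTs; an explicit nested-sum
#' evaluation of the same update is used as a cross-check in the test suite.
#'
#' @param colony Numeric matrix (colonization in `[0, 1]`; real-valued
#'   seeding intensities weight the very first convolution, after which the
#'   field is an occupancy pattern).
#' @param kernel An `emorfi_kernel`, possibly with per-step noise already
#'   added by [sample_kernel_noise()].
#' @param influence Plate-influence matrix from [boundary_influence_field()],
#'   or `NULL` for none.
#' @param mask Logical domain mask, or `NULL` for the whole field.
#' @param influence_weight Weight applied to the influence term; see
#'   [simulate_pattern()] for the default.
#' @return The next colonization matrix (values 0 or 1).
#' @export
growth_step <- function(colony, kernel, influence = NULL, mask = NULL,
                        influence_weight = 0.002) {
  if (!is.null(influence) && !all(dim(influence) == dim(colony))) {
    abort_emorfi("colony and influence grids differ in shape", "emorfi_validation_error")
  }
  if (!is.null(mask) && !all(dim(mask) == dim(colony))) {
    abort_emorfi("colony and mask grids differ in shape", "emorfi_validation_error")
  }
  act <- conv2_fft(colony, unclass(kernel))
  if (!is.null(influence)) act <- act + influence_weight * influence
  # strict positivity with a 1e-9 guard: an exact expansion/inhibition tie
  # must not colonize on the sign of floating-point rounding noise
  nxt <- matrix(as.numeric(act > 1e-9), nrow(colony), ncol(colony))
  if (!is.null(mask)) nxt[!mask] <- 0
  nxt
}

# Zero-padded linear convolution of field with a centered (odd-sided) kernel,
# via FFT on the padded grid; returns the central n x m block.
conv2_fft <- function(field, kernel) {
  n <- nrow(field); m <- ncol(field)
  kc <- (nrow(kernel) - 1L) / 2L
  pn <- n + 2L * kc; pm <- m + 2L * kc
  pf <- matrix(0, pn, pm)
  pf[(kc + 1):(kc + n), (kc + 1):(kc + m)] <- field
  pk <- matrix(0, pn, pm)
  pk[1:nrow(kernel), 1:ncol(kernel)] <- kernel
  # shift kernel center to (1,1) for circular convolution on the padded grid
  pk <- pk[c((kc + 1):pn, 1:kc), c((kc + 1):pm, 1:kc)]
  conv <- Re(fft(fft(pf) * fft(pk), inverse = TRUE)) / (pn * pm)
  conv[(kc + 1):(kc + n), (kc + 1):(kc + m)]
}

#' Simulate a colony pattern from a seeding field
#'
#' Iterates [growth_step()] — resampling kernel noise every step when
#' `params$snr` is set — until the total colonization changes by less than
#' `stop_tol * domain_area` for `stop_patience` consecutive steps, or
#' `max_steps` is reached. The final field is quantized (round half up) to an
#' 8-bit grayscale pattern image.
#'
#' @param seeding Seeding field matrix (e.g. from [bits_to_seeding()]).
#' @param params An `emorfi_growth_params`.
#' @param geometry An `emorfi_geometry` on the same field side.
#' @param seed Optional integer seed for the kernel-noise stream.
#' @param influence_weight Weight of the plate-influence term. The default
#'   0.002 lets an `epsilon = 1` plate bias growth across the whole domain
#'   (activation deduction about 1 at the center and 2 at the boundary,
#'   against front activations of order 1-10) without extinguishing the
#'   colony, while for `epsilon = 2000` it only trims a thin boundary shell.
#' @return An `emorfi_pattern`: integer matrix in 0..255 with metadata
#'   attributes (`steps`, `converged`, `seed`, `character`, `params_digest`).
#' @export
simulate_pattern <- function(seeding, params = growth_params(),
                             geometry = NULL, seed = NULL,
                             influence_weight = 0.002) {
  side <- nrow(seeding)
  if (is.null(geometry)) {
    geometry <- domain_geometry("circle", field_side = side, area_frac = pi / 4)
  }
  if (geometry$field_side != side) {
    abort_emorfi("seeding and geometry field sizes differ", "emorfi_validation_error")
  }
  kernel <- build_kernel(params)
  influence <- boundary_influence_field(geometry)
  colony <- pmin(pmax(unclass(seeding), 0), 1)
  colony[!geometry$mask] <- 0

  run <- function() {
    quiet <- 0L
    tol <- params$stop_tol * sum(geometry$mask)
    total <- sum(colony)
    steps <- 0L
    converged <- FALSE
    while (steps < params$max_steps) {
      k_t <- sample_kernel_noise(kernel, params$snr)
      colony <<- growth_step(colony, k_t, influence, geometry$mask,
                             influence_weight)
      steps <- steps + 1L
      new_total <- sum(colony)
      quiet <- if (abs(new_total - total) < tol) quiet + 1L else 0L
      total <- new_total
      if (quiet >= params$stop_patience) {
        converged <- TRUE
        break
      }
    }
    list(steps = steps, converged = converged)
  }
  status <- if (is.null(seed)) run() else with_seed(seed, run())

  px <- matrix(as.integer(floor(255 * colony + 0.5)), side, side)
  structure(
    px, class = c("emorfi_pattern", "matrix"),
    steps = status$steps, converged = status$converged, seed = seed,
    character = attr(seeding, "character"),
    params_digest = obj_digest(list(params = unclass(params),
                                    shape = geometry$shape,
                                    area = geometry$area,
                                    epsilon = geometry$epsilon))
  )
}

#' @export
print.emorfi_pattern <- function(x, ...) {
  cat(sprintf(
    "<emorfi_pattern> %dx%d, %d steps%s%s\n",
    nrow(x), ncol(x), attr(x, "steps") %||% NA_integer_,
    if (isTRUE(attr(x, "converged"))) " (converged)" else "",
    if (!is.null(attr(x, "character"))) paste0(", character ", deparse(attr(x, "character"))) else ""
  ))
  invisible(x)
}

#' Classify the morphology of a final pattern
#'
#' Three regimes matter for encoding: `disk` (the colony floods the domain
#' and the input is lost), `trivial` (the final pattern is essentially the
#' seeding, so decoding is perfect but insecure) and `branching` (the usable
#' regime). Classification uses the colonized fraction of the domain and the
#' intersection-over-union between the binarized pattern and seeding.
#'
#' @param pattern An `emorfi_pattern` (or 0..255 matrix).
#' @param seeding The seeding field it grew from.
#' @param mask Optional domain mask; default full field.
#' @param theta_disk Colonized-fraction threshold for `disk` (default 0.8).
#' @param theta_trivial IoU threshold for `trivial` (default 0.6).
#' @param level Binarization level on the `[0, 1]` scale (default 0.1).
#' @return `"disk"`, `"trivial"` or `"branching"`.
#' @export
classify_morphology <- function(pattern, seeding, mask = NULL,
                                theta_disk = 0.8, theta_trivial = 0.6,
                                level = 0.1) {
  p <- unclass(pattern) / 255
  s <- pmin(pmax(unclass(seeding), 0), 1)
  if (!all(dim(p) == dim(s))) {
    abort_emorfi("pattern and seeding grids differ in shape", "emorfi_validation_error")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(p), ncol(p))
  pb <- p > level & mask
  sb <- s > level & mask
  frac <- sum(pb) / sum(mask)
  if (frac > theta_disk) return("disk")
  union <- sum(pb | sb)
  iou <- if (union == 0) 1 else sum(pb & sb) / union
  if (iou > theta_trivial) return("trivial")
  "branching"
}

#' Crop the center of a pattern
#'
#' Zeroes every pixel outside a centered circle, removing the imprint of the
#' domain boundary (used before decoding shape-encrypted patterns). A radius
#' larger than the field leaves the pattern unchanged.
#'
#' @param pattern An `emorfi_pattern` or numeric matrix.
#' @param crop_radius Radius of the retained disk, px (> 0).
#' @return The cropped pattern with a `crop_radius` attribute.
#' @export
crop_center <- function(pattern, crop_radius) {
  if (crop_radius <= 0) {
    abort_emorfi("crop_radius must be > 0", "emorfi_validation_error")
  }
  side_r <- nrow(pattern); side_c <- ncol(pattern)
  mid_r <- (side_r + 1) / 2; mid_c <- (side_c + 1) / 2
  d2 <- outer((seq_len(side_r) - mid_r)^2, (seq_len(side_c) - mid_c)^2, `+`)
  out <- pattern
  out[d2 > crop_radius^2] <- if (is.integer(pattern)) 0L else 0
  attr(out, "crop_radius") <- crop_radius
  out
}
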