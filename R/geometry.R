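#' Growth-domain geometry and plate influence
#'
#' The plate boundary suppresses colonization. With `d(x, y)` the Euclidean
#' distance of a pixel to the domain boundary and `R` the maximum of that
#' distance field (the innermost, "highest contour" point), the influence is
#' \deqn{I(x, y) = -k\, 2^{-\varepsilon d(x, y) / R}.}
#' With the default `epsilon = 2000` the influence is numerically zero except
#' in a vanishingly thin boundary shell; with `epsilon = 1` it reaches the
#' domain center at half its boundary strength, so the final pattern depends
#' on the domain *shape* — the basis of shape-key encryption.
#'
#' Supported shapes: `circle`, `square`, `diamond` (square rotated 45
#' degrees) and upward-pointing equilateral `triangle`, all centered on the
#' field and sized to a common area so that shapes are comparable.
#'
#' @param shape One of `"circle"`, `"square"`, `"diamond"`, `"triangle"`.
#' @param field_side Field side, px.
#' @param area Domain area in px^2. Default: `area_frac * field_side^2`.
#' @param area_frac Domain area as a fraction of the field square; the
#'   default 0.4 is close to the largest equilateral triangle that fits, so
#'   every supported shape of that area fits the field. A full-field circular
#'   plate (diameter = `field_side`) corresponds to `area_frac = pi / 4`.
#' @param k Influence magnitude at the boundary (default 1000).
#' @param epsilon Influence decay shape (1 for encryption, 2000 otherwise).
#' @return An `emorfi_geometry` with the binary domain `mask`, boundary
#'   distance field `dist`, its maximum `R`, and the shape parameters.
#' @export
domain_geometry <- function(shape = c("circle", "square", "diamond", "triangle"),
                            field_side = 451L, area = NULL, area_frac = 0.4,
                            k = 1000, epsilon = 2000) {
  shape <- match.arg(shape)
  field_side <- as.integer(field_side)
  if (is.null(area)) area <- area_frac * field_side^2
  mid <- (field_side + 1) / 2
  x <- matrix(rep(seq_len(field_side), each = field_side), field_side) - mid
  y <- matrix(rep(seq_len(field_side), times = field_side), field_side) - mid
  mask <- switch(shape,
    circle = {
      r <- sqrt(area / pi)
      x^2 + y^2 <= r^2
    },
    square = {
      s <- sqrt(area)
      pmax(abs(x), abs(y)) <= s / 2
    },
    diamond = {
      s <- sqrt(area) # rotated square of side s: |x| + |y| <= s/sqrt(2)
      abs(x) + abs(y) <= s / sqrt(2)
    },
    triangle = {
      s <- sqrt(4 * area / sqrt(3)) # side of the equilateral triangle
      h <- s * sqrt(3) / 2
      # centroid at field center, apex up; row index grows downward so the
      # upward axis is -y. Apex at up = 2h/3, base at up = -h/3.
      up <- -y
      (up >= -h / 3) & (up <= 2 * h / 3 - sqrt(3) * abs(x))
    }
  )
  if (!any(mask)) abort_emorfi("empty domain mask", "emorfi_geometry_error")
  dist <- distance_to_boundary(mask)
  R <- max(dist)
  if (R <= 0) abort_emorfi("degenerate domain: R = 0", "emorfi_geometry_error")
  structure(
    list(shape = shape, field_side = field_side, area = area, k = k,
         epsilon = epsilon, mask = mask, dist = dist, R = R),
    class = "emorfi_geometry"
  )
}

# Euclidean distance of each in-domain pixel to the nearest out-of-domain
# pixel; exact distance transform via EBImage.
distance_to_boundary <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  d <- EBImage::distmap(m, metric = "euclidean")
  d <- as.matrix(EBImage::imageData(d))
  d[!mask] <- 0
  d
}

#' @export
print.emorfi_geometry <- function(x, ...) {
  cat(sprintf(
    "<emorfi_geometry> %s, field %d px, area %.0f px^2, R = %.1f, k = %g, epsilon = %g\n",
    x$shape, x$field_side, x$area, x$R, x$k, x$epsilon
  ))
  invisible(x)
}

#' Equal-area geometries for shape-key comparisons
#'
#' @param shapes Character vector of shapes.
#' @param ... Passed to [domain_geometry()] (same `area`/`area_frac` for all,
#'   enforcing equal areas).
#' @return Named list of `emorfi_geometry` objects.
#' @export
equal_area_geometries <- function(shapes = c("circle", "square", "diamond", "triangle"),
                                  ...) {
  out <- lapply(shapes, function(s) domain_geometry(s, ...))
  names(out) <- shapes
  out
}

#' Plate influence as a function of boundary distance
#'
#' @param d Euclidean distance(s) to the boundary, px.
#' @param R Maximum boundary distance of the domain, px.
#' @param k Influence magnitude (default 1000).
#' @param epsilon Decay shape.
#' @return `-k * 2^(-epsilon * d / R)`.
#' @export
plate_influence <- function(d, R, k = 1000, epsilon = 2000) {
  if (R <= 0) abort_emorfi("R must be > 0", "emorfi_geometry_error")
  -k * 2^(-epsilon * d / R)
}

#' Plate-influence field
#'
#' @param geometry An `emorfi_geometry`.
#' @return Numeric matrix `I(x, y) = -k * 2^(-epsilon * d / R)`, zero outside
#'   the domain.
#' @export
boundary_influence_field <- function(geometry) {
  stopifnot(inherits(geometry, "emorfi_geometry"))
  I <- plate_influence(geometry$dist, geometry$R, geometry$k, geometry$epsilon)
  I[!geometry$mask] <- 0
  I
}
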