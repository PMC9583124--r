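#' Growth-model parameters
#'
#' The colony grows by repeated convolution with a radially symmetric kernel
#' combining short-range expansion (magnitude `b`, half-effect distance `d1`,
#' sharpness `h1`) and longer-range inhibition (half-effect distance `d2`,
#' sharpness `h2`):
#' \deqn{K(d) = b\,2^{-(d/d_1)^{h_1}} - 2^{-(d/d_2)^{h_2}}}
#' With the very large default exponents the two terms are near-step
#' functions: K is about `b - 1` inside `d1`, about `-1` between `d1` and
#' `d2`, and about 0 beyond `d2`. The defaults `b = 6.5`, `d1/d2 = 0.4`,
#' `h1 = 1000`, `h2 = 2000` put expansion and inhibition in close balance and
#' produce branching colonies.
#'
#' Optional white Gaussian noise is added to every kernel element at every
#' time step; its standard deviation is `RMS(K)/snr` where the RMS is taken
#' over the kernel's truncated support and `snr` is a linear (not dB)
#' signal-to-noise ratio. `snr = NULL` disables growth noise (the default
#' regime); `snr = 3.5` is the intermediate noise level used throughout the
#' decoding experiments.
#'
#' @param b Expansion-to-inhibition magnitude (> 0).
#' @param d2 Inhibition half-effect distance, px.
#' @param d1 Expansion half-effect distance, px; default `0.4 * d2`.
#' @param h1,h2 Sharpness exponents (>= 1).
#' @param snr Linear kernel signal-to-noise ratio, or `NULL` for noiseless
#'   growth.
#' @param kernel_cutoff Truncation radius of the kernel, px; default
#'   `ceiling(1.5 * d2)` (K is numerically 0 well before that).
#' @param max_steps Step cap for [simulate_pattern()].
#' @param stop_tol Termination tolerance on the change in total colonization,
#'   as a fraction of the domain area.
#' @param stop_patience Consecutive quiet steps required to stop.
#' @return An `emorfi_growth_params` object.
#' @export
growth_params <- function(b = 6.5, d2 = 10, d1 = 0.4 * d2, h1 = 1000,
                          h2 = 2000, snr = NULL,
                          kernel_cutoff = ceiling(1.5 * d2),
                          max_steps = 500L, stop_tol = 1e-4,
                          stop_patience = 5L) {
  if (b <= 0) abort_emorfi("b must be > 0", "emorfi_validation_error")
  if (!(0 < d1 && d1 < d2)) {
    abort_emorfi("need 0 < d1 < d2", "emorfi_validation_error")
  }
  if (d2 > kernel_cutoff) {
    abort_emorfi("kernel_cutoff must be >= d2", "emorfi_validation_error")
  }
  if (h1 < 1 || h2 < 1) abort_emorfi("h1, h2 must be >= 1", "emorfi_validation_error")
  if (!is.null(snr) && snr <= 0) abort_emorfi("snr must be > 0", "emorfi_validation_error")
  structure(
    list(b = b, d1 = d1, d2 = d2, h1 = h1, h2 = h2, snr = snr,
         kernel_cutoff = kernel_cutoff, max_steps = as.integer(max_steps),
         stop_tol = stop_tol, stop_patience = as.integer(stop_patience)),
    class = "emorfi_growth_params"
  )
}

#' @export
print.emorfi_growth_params <- function(x, ...) {
  cat(sprintf(
    "<emorfi_growth_params> b=%g d1=%g d2=%g h1=%g h2=%g snr=%s cutoff=%g\n",
    x$b, x$d1, x$d2, x$h1, x$h2,
    if (is.null(x$snr)) "none" else format(x$snr), x$kernel_cutoff
  ))
  invisible(x)
}

kernel_value <- function(d, params) {
  # 2^{-(d/d1)^h1}: guard overflow of the inner power; huge powers -> term 0
  pow_term <- function(d, scale, h) {
    r <- d / scale
    out <- numeric(length(r))
    small <- r <= 1
    out[small] <- 2^(-(r[small]^h))
    # r > 1 with h ~ 1000: 2^{-huge} underflows to 0, which is the intent
    out[!small] <- 2^(-pmin(r[!small]^h, 1e6))
    out
  }
  params$b * pow_term(d, params$d1, params$h1) - pow_term(d, params$d2, params$h2)
}

#' Build the (noiseless) growth kernel
#'
#' Evaluates K on the integer offset grid out to `kernel_cutoff`, zero beyond.
#'
#' @param params An `emorfi_growth_params`.
#' @return An `emorfi_kernel`: a square numeric matrix of odd side
#'   `2 * kernel_cutoff + 1` with attributes `cutoff`, `pos_mass`
#'   (\eqn{\sum \max(K, 0)}, the normalizer used by [growth_step()]) and
#'   `rms` (root-mean-square of K over its support, the noise reference).
#' @export
build_kernel <- function(params) {
  stopifnot(inherits(params, "emorfi_growth_params"))
  cut <- params$kernel_cutoff
  off <- -cut:cut
  d <- sqrt(outer(off^2, off^2, `+`))
  k <- matrix(kernel_value(as.vector(d), params), nrow = length(off))
  k[d > cut] <- 0
  support <- d <= cut
  structure(
    k, class = c("emorfi_kernel", "matrix"), cutoff = cut,
    pos_mass = sum(pmax(k, 0)),
    rms = sqrt(mean(k[support]^2)),
    support = support
  )
}

#' Add one time step's white kernel noise
#'
#' Returns `K + sigma * Z` with `Z` i.i.d. standard normal on the kernel
#' support and `sigma = RMS(K)/snr`. Call once per time step; with
#' `snr = NULL` the kernel is returned unchanged.
#'
#' @param kernel An `emorfi_kernel`.
#' @param snr Linear signal-to-noise ratio (or `NULL`).
#' @return A kernel matrix of the same shape.
#' @export
sample_kernel_noise <- function(kernel, snr) {
  if (is.null(snr)) return(kernel)
  if (snr <= 0) abort_emorfi("snr must be > 0", "emorfi_validation_error")
  sigma <- attr(kernel, "rms") / snr
  noisy <- unclass(kernel)
  support <- attr(kernel, "support")
  noisy[support] <- noisy[support] + rnorm(sum(support), 0, sigma)
  attributes(noisy) <- attributes(kernel)
  noisy
}
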