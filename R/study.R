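#' Reduced-scale study configurations
#'
#' The full-scale platform operates on 451 x 451 fields with a 15-character,
#' 4-bit dictionary and hundreds of replicates per class — cluster-scale
#' dataset generation. These helpers bundle the package's reduced-scale twin
#' of those conditions, used throughout the test suite and the worked
#' examples.
#'
#' `reduced_study()` gives the baseline conditions: a 96 x 96 field with the
#' kernel scaled proportionally (`d2 = 5`, `d1 = 2`), a 2-bit / 3-character
#' dictionary with spacing 10 and spot radius 3, the default full-field
#' circular plate, intermediate growth noise `snr = 3.5`, and a compact CNN
#' (6 + 12 filters, 32-wide hidden layer) that monitors training loss for
#' early stopping (tiny validation splits are too noisy to monitor at this
#' scale).
#'
#' `reduced_encryption_study()` is the reduced-scale twin of the shape-key
#' encryption experiment: equal-area domains (40% of the field square) with
#' `epsilon = 1` so the plate influence reaches the colony center, a
#' six-character dictionary assigned only equal-weight (two-spot) 4-bit
#' codes — so classes differ in *which* spots are seeded, never in how many
#' — and a center crop at 75% of the innermost boundary distance to strip
#' the overt domain imprint before decoding.
#'
#' @param n_chars Dictionary size (must fit `n_bits`).
#' @param n_bits Bits per character.
#' @param snr Growth-noise signal-to-noise ratio (`NULL` = noiseless).
#' @param spacing Spot spacing, px.
#' @param field_side Field side, px.
#' @param max_steps Growth-step cap; 30 is past pattern establishment at
#'   this scale.
#' @param epochs,patience CNN training schedule; the long patience rides out
#'   the early loss plateau before feature learning takes off, which would
#'   otherwise trigger a premature stop at chance accuracy.
#' @return A list with elements `codebook`, `layout`, `params`, `spec`, and
#'   `geometry` (baseline) or `geometries` + `crop_radius` +
#'   `influence_weight` (encryption).
#' @export
reduced_study <- function(n_chars = 3, n_bits = 2, snr = 3.5, spacing = 10,
                          field_side = 96L, max_steps = 30L, epochs = 60L,
                          patience = 12L) {
  chars <- c(LETTERS, letters, as.character(0:9))[seq_len(n_chars)]
  list(
    codebook = build_codebook(chars, n_bits),
    layout = seeding_layout(n_bits, spacing = spacing, spot_radius = 3,
                            field_side = field_side, allow_overlap = TRUE),
    params = growth_params(d2 = 5, snr = snr, max_steps = max_steps),
    geometry = domain_geometry("circle", field_side = field_side,
                               area_frac = pi / 4),
    # learning rate 3e-4: Adam's sign-normalized steps at the canonical 1e-3
    # are large relative to the Glorot scale of this small network and can
    # collapse it onto the uniform-output saddle within one epoch
    spec = decoder_spec(conv1_filters = 6L, conv2_filters = 12L,
                        fc_width = 32L, learning_rate = 3e-4,
                        epochs = epochs, patience = patience, val_frac = 0)
  )
}

#' @rdname reduced_study
#' @param shapes Domain shapes compared as secret keys.
#' @export
reduced_encryption_study <- function(shapes = c("circle", "square"),
                                     snr = 3.5, field_side = 96L,
                                     max_steps = 30L, epochs = 60L,
                                     patience = 12L) {
  base <- reduced_study(snr = snr, field_side = field_side,
                        max_steps = max_steps, epochs = epochs,
                        patience = patience)
  geometries <- lapply(shapes, function(sh) {
    domain_geometry(sh, field_side = field_side, area_frac = 0.4, epsilon = 1)
  })
  names(geometries) <- shapes
  list(
    codebook = build_codebook(LETTERS[1:6], 4,
                              indices = c(3L, 5L, 6L, 9L, 10L, 12L)),
    layout = seeding_layout(4, spacing = 10, spot_radius = 3,
                            field_side = field_side, allow_overlap = TRUE),
    params = base$params,
    geometries = geometries,
    crop_radius = 0.75 * min(vapply(geometries, function(g) g$R, 0)),
    influence_weight = 0.002,
    spec = base$spec
  )
}
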