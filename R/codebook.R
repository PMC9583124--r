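#' Build a character codebook
#'
#' Assigns each character of a dictionary a nonzero index, encoded as an
#' `n_bits`-digit binary string. Index 0 (the all-zero string) is never
#' assigned: it would seed no cells and therefore produce no pattern. An
#' `n_bits`-bit codebook can hold at most `2^n_bits - 1` characters; e.g.
#' 2, 4 and 6 bits give capacities of 3, 15 and 63, and a 7-bit codebook holds
#' the 100 printable ASCII characters with room to spare.
#'
#' @param characters Character vector of distinct single symbols, in the order
#'   they should be indexed (first character gets index 1).
#' @param n_bits Number of binary digits (spots) per character.
#' @param indices Optional explicit index assignment (distinct integers in
#'   `1..2^n_bits - 1`, one per character). The default assigns `1..n` in
#'   list order; an explicit assignment lets a dictionary use, e.g., only
#'   equal-weight bit codes.
#' @return An object of class `emorfi_codebook` with fields `characters`,
#'   `n_bits` and `index` (named integer vector character -> index).
#' @examples
#' cb <- build_codebook(c(LETTERS[1:5], 0:9), 4)
#' char_to_bits("A", cb)
#' @export
build_codebook <- function(characters, n_bits, indices = NULL) {
  characters <- as.character(characters)
  n_bits <- as.integer(n_bits)
  if (n_bits < 1L) abort_emorfi("n_bits must be a positive integer", "emorfi_validation_error")
  if (anyDuplicated(characters)) {
    abort_emorfi("characters must be distinct", "emorfi_validation_error")
  }
  capacity <- 2^n_bits - 1
  if (length(characters) < 1L || length(characters) > capacity) {
    abort_emorfi(
      sprintf(
        "dictionary of %d characters exceeds the %d-slot capacity of %d bits",
        length(characters), capacity, n_bits
      ),
      "emorfi_capacity_error"
    )
  }
  idx <- if (is.null(indices)) seq_along(characters) else as.integer(indices)
  if (length(idx) != length(characters) || anyDuplicated(idx) ||
      any(idx < 1L) || any(idx > capacity)) {
    abort_emorfi("indices must be distinct integers in 1..2^n_bits - 1, one per character",
                 "emorfi_validation_error")
  }
  names(idx) <- characters
  structure(
    list(characters = characters, n_bits = n_bits, index = idx),
    class = "emorfi_codebook"
  )
}

#' @export
print.emorfi_codebook <- function(x, ...) {
  cat(sprintf(
    "<emorfi_codebook> %d characters, %d bits (capacity %d)\n",
    length(x$characters), x$n_bits, 2^x$n_bits - 1
  ))
  invisible(x)
}

#' @export
format.emorfi_codebook <- function(x, ...) {
  sprintf("codebook[%d chars, %d bits]", length(x$characters), x$n_bits)
}

int_to_bits <- function(i, n_bits) {
  paste(rev((i %/% 2^(0:(n_bits - 1))) %% 2), collapse = "")
}

#' Convert a character to its binary seeding string
#'
#' @param char A single character present in the codebook.
#' @param codebook An `emorfi_codebook`.
#' @return A string of `n_bits` binary digits, most-significant first.
#' @export
char_to_bits <- function(char, codebook) {
  stopifnot(inherits(codebook, "emorfi_codebook"))
  i <- unname(codebook$index[as.character(char)])
  if (length(i) != 1L || is.na(i)) {
    abort_emorfi(sprintf("character %s is not in the codebook", deparse(char)),
                 "emorfi_lookup_error")
  }
  int_to_bits(i, codebook$n_bits)
}

#' Convert a binary string back to its character
#'
#' @param bits An `n_bits`-digit binary string.
#' @param codebook An `emorfi_codebook`.
#' @return The character assigned to that index.
#' @export
bits_to_char <- function(bits, codebook) {
  stopifnot(inherits(codebook, "emorfi_codebook"))
  i <- strtoi(bits, base = 2L)
  pos <- match(i, codebook$index)
  if (is.na(i) || is.na(pos)) {
    abort_emorfi(sprintf("bit string %s maps to no codebook entry", deparse(bits)),
                 "emorfi_lookup_error")
  }
  codebook$characters[[pos]]
}

#' Tabulate a codebook
#'
#' @param x An `emorfi_codebook`.
#' @param ... Unused.
#' @return A tibble with columns `character`, `index`, `bits`.
#' @export
tidy.emorfi_codebook <- function(x, ...) {
  tibble(
    character = x$characters,
    index = as.integer(x$index),
    bits = vapply(as.integer(x$index), int_to_bits, "", n_bits = x$n_bits)
  )
}

#' Serialize a codebook and layout to JSON
#'
#' Writes the codebook (characters, bits, index assignment) and optionally a
#' seeding layout and noise settings into one JSON document, so an encoding
#' configuration can be shared or versioned.
#'
#' @param codebook An `emorfi_codebook`.
#' @param path Output file.
#' @param layout Optional `emorfi_layout`.
#' @param noise Optional `emorfi_seeding_noise`.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(codebook, path, layout = NULL, noise = NULL) {
  stopifnot(inherits(codebook, "emorfi_codebook"))
  doc <- list(
    characters = codebook$characters,
    n_bits = codebook$n_bits,
    indices = as.integer(codebook$index)
  )
  if (!is.null(layout)) doc$layout <- unclass(layout)
  if (!is.null(noise)) doc$noise <- unclass(noise)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a codebook (and layout) written by [write_codebook()]
#'
#' @param path JSON file.
#' @return A list with `codebook`, and `layout` / `noise` when present.
#' @examples
#' cfg <- read_codebook(system.file("extdata", "codebook15.json",
#'                                  package = "emorfi"))
#' char_to_bits("C", cfg$codebook)
#' @export
read_codebook <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(codebook = build_codebook(doc$characters, doc$n_bits,
                                        indices = doc$indices))
  if (!is.null(doc$layout)) {
    out$layout <- seeding_layout(
      doc$layout$n_bits, spacing = doc$layout$spacing,
      spot_radius = doc$layout$spot_radius,
      field_side = doc$layout$field_side,
      grid_rows = doc$layout$grid_rows, grid_cols = doc$layout$grid_cols,
      allow_overlap = TRUE
    )
  }
  if (!is.null(doc$noise)) {
    out$noise <- seeding_noise(doc$noise$enabled, doc$noise$mean,
                               doc$noise$deviation)
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
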