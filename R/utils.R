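#' @useDynLib emorfi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif fft predict
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_emorfi <- function(msg, class) {
  stop(structure(
    class = c(class, "emorfi_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Short content digest of an R object
#'
#' FNV-1a hash (64-bit, reported as 16 hex characters) of the object's
#' serialized bytes. Used to stamp codebooks, growth configurations and model
#' parameters into provenance metadata so that datasets and checkpoints can be
#' matched up later.
#'
#' @param x Any R object.
#' @return A 16-character hexadecimal string.
#' @export
obj_digest <- function(x) {
  bytes <- serialize(x, NULL, version = 2L)
  # skip the serialization header (R version stamps would break stability)
  bytes <- bytes[-seq_len(14L)]
  fnv1a64(as.integer(bytes))
}

fnv1a64 <- function(ints) {
  # 64-bit FNV-1a carried as two 32-bit halves in doubles
  lo <- 0x84222325
  hi <- 0x0cbf29ce
  prime_lo <- 0x000001b3
  for (b in ints) {
    lo <- bitwXor32(lo, b)
    # multiply (hi,lo) by 0x100000001b3 mod 2^64
    new_lo <- mul32_lo(lo, prime_lo)
    new_hi <- (mul32_hi(lo, prime_lo) + mul32_lo(hi, prime_lo) + lo) %% 4294967296
    lo <- new_lo
    hi <- new_hi
  }
  paste0(format_hex32(hi), format_hex32(lo))
}

format_hex32 <- function(v) {
  paste0(sprintf("%04x", as.integer(v %/% 65536)),
         sprintf("%04x", as.integer(v %% 65536)))
}

bitwXor32 <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  xh <- bitwXor(as.integer(ah), as.integer(bh))
  xl <- bitwXor(as.integer(al), as.integer(bl))
  xh * 65536 + xl
}

mul32_lo <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  ((al * bl) + (((ah * bl + al * bh) %% 65536) * 65536)) %% 4294967296
}

mul32_hi <- function(a, b) {
  # high 32 bits of a*b for a,b < 2^32
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  mid <- ah * bl + al * bh + (al * bl) %/% 65536
  (ah * bh + mid %/% 65536) %% 4294967296
}

#' Derive a child RNG seed from a base seed and integer context
#'
#' Splitmix-style integer mixing keeps replicate streams decorrelated while
#' remaining reproducible and parallel-safe: item (class i, replicate j) can be
#' regenerated in isolation. The result is always in [1, 2^31 - 2].
#'
#' @param base_seed Integer base seed.
#' @param ... Further integers identifying the stream (class index,
#'   replicate index, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(base_seed, ...) {
  parts <- c(as.numeric(base_seed), as.numeric(unlist(list(...))))
  m <- 2147483647
  h <- 0
  for (p in parts) {
    h <- (mulmod(h, 2654435761, m) + (p %% m) + 1013904223) %% m
  }
  h <- mulmod(h, 2654435761, m) # final mix so the last part is scrambled too
  as.integer(h %% 2147483645 + 1)
}

# (a * b) mod m without double-precision overflow (a, b < 2^32, m < 2^31)
mulmod <- function(a, b, m) {
  a <- a %% m
  bh <- b %/% 65536
  bl <- b %% 65536
  (((a * bh) %% m) * 65536 + a * bl) %% m
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
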