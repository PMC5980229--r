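# Internal helpers shared across modules.

# Total length of the intersection of a set of half-open intervals with
# [lo, hi). `ints` is a 2-column matrix (start, end); may have zero rows.
interval_occupancy <- function(ints, lo, hi) {
  if (is.null(ints) || nrow(ints) == 0L) return(0)
  sum(pmax(0, pmin(ints[, 2L], hi) - pmax(ints[, 1L], lo)))
}

as_interval_matrix <- function(x) {
  if (is.null(x)) return(matrix(numeric(0), ncol = 2L))
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2L)
    return(x)
  }
  matrix(as.numeric(x), ncol = 2L, byrow = TRUE)
}

# Overlap of one interval [b1, b2) with each of a vector of intervals given
# as parallel start/end vectors; returns the summed overlap per (b1, b2) pair
# when b1/b2 are vectors and the mask is a single interval.
mask_overlap <- function(b1, b2, m1, m2) {
  if (is.null(m1) || length(m1) == 0L) return(rep(0, length(b1)))
  pmax(0, pmin(b2, m2) - pmax(b1, m1))
}

# Deterministic derivation of child seeds from one top-level seed.
# Linear congruential step modulo the Mersenne prime 2^31 - 1 keeps every
# child a valid 32-bit R seed and distinct streams for distinct indices.
child_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 48271 + 7919 * (as.double(stream) + 1)) %% 2147483647)
}

# 32-bit djb2 polynomial hash of a character vector, as 8 hex digits.
# Exact in double arithmetic (intermediates stay below 2^53). Used to stamp
# run outputs with a configuration fingerprint.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

fmt_time <- function(x, digits = 9L) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- ""
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
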