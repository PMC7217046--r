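# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child-seed derivation so one top-level seed drives several
# independent generators. Kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483629) * 7919 + k * 104729) %% 2147483629)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_whole <- function(x) {
  is_scalar_number(x) && abs(x - round(x)) < .Machine$double.eps^0.5
}

# Logical mask for a filled disk on an h x w raster, pixel-center convention.
disk_mask <- function(h, w, cy, cx, r) {
  yy <- matrix(seq_len(h) - 0.5, nrow = h, ncol = w)
  xx <- matrix(seq_len(w) - 0.5, nrow = h, ncol = w, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}
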