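deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# minimal absolute angular difference in degrees, result in [0, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# signed difference a - b wrapped to (-180, 180]
ang_diff_signed <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# round half away from zero (base round() is banker's)
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# derive a child seed (< 2^31) from a parent seed and a stream index
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483563) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
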