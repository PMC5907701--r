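# Internal numeric helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a label
#'
#' All stochastic components draw from streams derived from one master seed,
#' so that a single `seed` argument controls a whole run. The derivation is a
#' small integer hash kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param ... labels (integers or strings) identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  labels <- unlist(list(...), use.names = FALSE)
  h <- as.double(seed) %% 2147483647
  for (lab in labels) {
    if (is.character(lab)) {
      lab <- sum(utf8ToInt(lab) * seq_along(utf8ToInt(lab)))
    }
    h <- (h * 48271 + as.double(lab) * 9973 + 1) %% 2147483647
  }
  as.integer(h)
}

# Reflect (half-sample symmetric) indices into 1..n: ... 2 1 | 1 2 ... n | n n-1 ...
# Arithmetic in double so arbitrarily remote (degenerate) coordinates fold
# back without integer overflow.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2 * n
  k <- (as.numeric(idx) - 1) %% period
  k <- ifelse(k < 0, k + period, k)
  as.integer(round(ifelse(k < n, k + 1, period - k)))
}

# Pad a matrix by `m` cells on every side with half-sample reflection.
pad_reflect <- function(mat, m) {
  n1 <- nrow(mat); n2 <- ncol(mat)
  mat[reflect_index(seq(1L - m, n1 + m), n1),
      reflect_index(seq(1L - m, n2 + m), n2), drop = FALSE]
}

# Bilinear interpolation of matrix `mat` at fractional (row, col) positions;
# coordinates outside the map are reflected back in.
bilinear <- function(mat, r, c) {
  n1 <- nrow(mat); n2 <- ncol(mat)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  i1 <- reflect_index(r0, n1)
  i2 <- reflect_index(r0 + 1, n1)
  j1 <- reflect_index(c0, n2)
  j2 <- reflect_index(c0 + 1, n2)
  mat[cbind(i1, j1)] * (1 - fr) * (1 - fc) +
    mat[cbind(i2, j1)] * fr * (1 - fc) +
    mat[cbind(i1, j2)] * (1 - fr) * fc +
    mat[cbind(i2, j2)] * fr * fc
}

# Round half away from zero (the convention used for printed percentages).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
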