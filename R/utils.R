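# Internal helpers shared across modules.

#' Wrap an angle to the signed interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180]; exactly 180 maps to +180.
#' @keywords internal
wrap_deg <- function(x) {
  e <- x %% 360
  e[e > 180] <- e[e > 180] - 360
  e
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Numerically stable log(exp(a) + exp(b))
#' @keywords internal
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  # where both are -Inf the result is -Inf, not NaN
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Derive a stream of child seeds from one master seed, each < 2^31.
child_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits.  Used to stamp
# output files with the configuration they came from.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  to_signed <- function(u) if (u >= 2^31) u - 2^32 else u
  to_unsigned <- function(s) if (s < 0) s + 2^32 else s
  for (b in bytes) {
    h <- to_unsigned(bitwXor(as.integer(to_signed(h)), as.integer(b)))
    # modular multiply by the FNV prime in two 16-bit halves to stay within
    # double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  # format in two 16-bit halves: %x needs values inside integer range
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
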