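# Shared numeric helpers. Rounding and reflection conventions are fixed here
# so that rasterization and kernel rotation are bit-stable across platforms.

#' Round half away from zero
#'
#' Deterministic rounding used throughout the package (R's `round()` rounds
#' half to even, which is not what the rasterizer wants at `x.5` boundaries).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Reflect continuous coordinates into the image domain
#'
#' Mirror (half-sample symmetric) boundary rule on 0-based pixel-center
#' coordinates: a coordinate `c` outside `[-0.5, L - 0.5)` is mapped to
#' `-1 - c` (low edge) or `2L - 1 - c` (high edge), repeatedly until inside.
#'
#' @param x numeric vector of 0-based coordinates.
#' @param L image extent in pixels.
#' @return reflected coordinates in `[-0.5, L - 0.5)`.
#' @export
#' @examples
#' mirror_reflect(-3.2, 256) # 2.2
mirror_reflect <- function(x, L) {
  out <- x
  bad <- which(out < -0.5 | out >= L - 0.5)
  it <- 0L
  while (length(bad) > 0L) {
    v <- out[bad]
    v <- ifelse(v < -0.5, -1 - v, v)
    v <- ifelse(v >= L - 0.5, 2 * L - 1 - v, v)
    out[bad] <- v
    bad <- bad[out[bad] < -0.5 | out[bad] >= L - 0.5]
    it <- it + 1L
    if (it > 64L) stop("mirror_reflect failed to converge", call. = FALSE)
  }
  out
}

#' Deterministic substream seed for a named pipeline stage
#'
#' Derives an integer seed from a master seed and a stage label so that one
#' top-level seed fans out into independent, reproducible substreams
#' (generation, tie-breaking, evaluation, ...). Derived seeds stay within
#' 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param label stage name.
#' @param index optional within-stage index.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h * 9973 + index * 101) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
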