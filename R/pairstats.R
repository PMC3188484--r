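# Pairwise coactivation statistics of suprathreshold oriented elements.

#' Create an empty pair-statistics accumulator
#'
#' Pair statistics count coactive pairs of suprathreshold orientation-filter
#' elements, indexed by relative displacement (within a Euclidean cutoff
#' radius `R`), relative orientation (modulo pi, binned to the bank's
#' orientations) and the absolute orientation of the center element. Both
#' orderings of every pair are counted; the exact self-pair is excluded.
#'
#' @param n_orient number of orientation bins.
#' @param R cutoff radius, pixels.
#' @param class_label `"target"` or `"distractor"`.
#' @param weighted if `TRUE`, pairs contribute the product of the two
#'   activities instead of 1.
#' @return object of class `pair_stats` with a `(2R+1) x (2R+1) x n_orient x
#'   n_orient` counts array `[dy, dx, theta_rel, theta_center]`.
#' @export
pair_stats <- function(n_orient, R,
                       class_label = c("target", "distractor"),
                       weighted = FALSE) {
  stopifnot(n_orient >= 2L, R >= 1L)
  D <- 2L * as.integer(R) + 1L
  structure(
    list(counts = array(0, dim = c(D, D, n_orient, n_orient)),
         R = as.integer(R), n_orient = as.integer(n_orient),
         n_images = 0L, class_label = match.arg(class_label),
         weighted = isTRUE(weighted)),
    class = "pair_stats"
  )
}

#' Accumulate pair statistics from one activity field
#'
#' @param stats a [pair_stats()] accumulator.
#' @param field an `orientation_field` (post-transfer; suprathreshold means
#'   value > 0).
#' @return the updated accumulator.
#' @export
accumulate_pair_stats <- function(stats, field) {
  stopifnot(inherits(stats, "pair_stats"))
  d <- dim(field)
  if (length(d) != 3L || d[3] != stats$n_orient) {
    stop("field orientation count does not match pair_stats", call. = FALSE)
  }
  inc <- accumulate_pairs_cpp(as.array(unclass(field)), stats$R,
                              stats$weighted)
  stats$counts <- stats$counts + inc
  stats$n_images <- stats$n_images + 1L
  stats
}

#' @export
print.pair_stats <- function(x, ...) {
  cat("<pair_stats>", x$class_label, "| R =", x$R, "px,",
      x$n_orient, "orientations,", x$n_images, "images, total count",
      format(sum(x$counts)), "\n")
  invisible(x)
}

# Rotate a D x D x n_rel table by `angle` about the center, mapping each cell
# to the nearest integer offset (half away from zero); colliding cells are
# summed, so mass is conserved. The relative-orientation axis is untouched
# (relative orientation is rotation invariant).
rotate_table <- function(tab, angle) {
  D <- dim(tab)[1]
  R <- (D - 1L) %/% 2L
  off <- seq(-R, R)
  dx <- matrix(off, D, D, byrow = TRUE)
  dy <- matrix(off, D, D)
  nx <- round_half_away(cos(angle) * dx - sin(angle) * dy)
  ny <- round_half_away(sin(angle) * dx + cos(angle) * dy)
  nx <- pmax(pmin(nx, R), -R)
  ny <- pmax(pmin(ny, R), -R)
  lin <- as.vector((ny + R) + D * (nx + R) + 1)
  out <- array(0, dim = dim(tab))
  for (j in seq_len(dim(tab)[3])) {
    acc <- rowsum(as.vector(tab[, , j]), group = lin)
    slice <- numeric(D * D)
    slice[as.integer(rownames(acc))] <- acc[, 1]
    out[, , j] <- slice
  }
  out
}

#' Canonicalize pair statistics
#'
#' The image ensemble is translation invariant and isotropic, so the center
#' element can be rotated to a canonical orientation (bank index 0) without
#' loss. Each per-center-orientation table is rotated by minus its center
#' angle step (nearest-integer coordinate mapping, mass conserving) and the
#' tables are averaged.
#'
#' @param stats an accumulated [pair_stats()].
#' @return a `(2R+1) x (2R+1) x n_orient` array over (dy, dx, theta_rel).
#' @export
canonicalize <- function(stats) {
  stopifnot(inherits(stats, "pair_stats"))
  Th <- stats$n_orient
  acc <- array(0, dim = dim(stats$counts)[1:3])
  for (i in seq_len(Th)) {
    acc <- acc + rotate_table(stats$counts[, , , i], -(i - 1) * pi / Th)
  }
  acc / Th
}
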