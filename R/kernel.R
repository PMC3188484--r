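# Object-Distractor Difference (ODD) kernels and the parametric Bowtie
# baseline. A kernel holds a canonical table (center element at the origin,
# canonical orientation = bank index 0) plus one rotated instance per
# absolute center orientation, used by the lateral dynamics.

new_lateral_kernel <- function(canonical, strength, R, n_orient,
                               angle_offset, kind, meta = list()) {
  D <- 2L * R + 1L
  rotated <- array(0, dim = c(D, D, n_orient, n_orient))
  for (i in seq_len(n_orient)) {
    rotated[, , , i] <- rotate_table(canonical, (i - 1) * pi / n_orient)
  }
  structure(
    list(canonical = canonical, rotated = rotated, strength = strength,
         R = as.integer(R), n_orient = as.integer(n_orient),
         angle_offset = angle_offset, kind = kind, quantized = NULL,
         meta = meta),
    class = "lateral_kernel"
  )
}

#' Build an ODD kernel from class statistics
#'
#' The Object-Distractor Difference kernel is the normalized difference of
#' the canonicalized pair statistics of target and distractor images:
#' `K = alpha * H_t - beta * H_d`, with `alpha` and `beta` chosen so each
#' class contribution integrates to the kernel strength `S`
#' (`alpha * sum(H_t) = beta * sum(H_d) = S`). The kernel therefore sums to
#' exactly zero: lateral support for randomly placed edges is neutral.
#'
#' @param target_stats,distractor_stats accumulated [pair_stats()] with
#'   identical geometry.
#' @param strength total ODD strength `S` (dimensionless). The default was
#'   chosen by a pilot strength sweep (see the package vignette) so that,
#'   under the default front end and raw-mode dynamics, classification
#'   accuracy improves monotonically with iterations and is near optimal.
#' @return object of class `lateral_kernel` (kind `"odd"`).
#' @export
odd_kernel <- function(target_stats, distractor_stats, strength = 2000) {
  stopifnot(inherits(target_stats, "pair_stats"),
            inherits(distractor_stats, "pair_stats"),
            target_stats$R == distractor_stats$R,
            target_stats$n_orient == distractor_stats$n_orient,
            strength > 0)
  h_t <- canonicalize(target_stats)
  h_d <- canonicalize(distractor_stats)
  if (sum(h_t) <= 0 || sum(h_d) <= 0) {
    stop("empty pair statistics: cannot normalize an ODD kernel",
         call. = FALSE)
  }
  canonical <- (strength / sum(h_t)) * h_t - (strength / sum(h_d)) * h_d
  new_lateral_kernel(
    canonical, strength, target_stats$R, target_stats$n_orient,
    angle_offset = attr(target_stats, "angle_offset") %||% pi / 32,
    kind = "odd",
    meta = list(n_target_images = target_stats$n_images,
                n_distractor_images = distractor_stats$n_images,
                weighted = target_stats$weighted)
  )
}

#' Rescale a kernel to a new total strength
#'
#' Kernel entries are linear in the strength, so sweeping strength does not
#' require retraining.
#'
#' @param kernel a `lateral_kernel`.
#' @param strength new total strength.
#' @return rescaled kernel.
#' @export
rescale_kernel <- function(kernel, strength) {
  stopifnot(inherits(kernel, "lateral_kernel"), strength > 0)
  f <- strength / kernel$strength
  kernel$canonical <- kernel$canonical * f
  kernel$rotated <- kernel$rotated * f
  kernel$strength <- strength
  kernel$quantized <- NULL
  kernel
}

#' Bowtie parameters
#'
#' A parametric association field of the form used by earlier contour models:
#' excitation fans out along the preferred axis (both ends) within an opening
#' angle and a maximal orientation difference, inhibition surrounds it
#' independently of orientation; both fall off as Gaussians of distance.
#'
#' @param opening_angle total angular width of the excitatory fan, radians.
#' @param max_orient_diff largest relative orientation (modulo pi, folded to
#'   `[0, pi/2]`) still treated as excitatory, radians.
#' @param sigma_exc,sigma_inh Gaussian distance falloffs, pixels.
#' @param strength total strength `S`, normalized as for [odd_kernel()]. The
#'   default is the Bowtie family's own calibrated near-optimum (its mass is
#'   spread over a much larger support than a trained kernel's, so its useful
#'   scale differs).
#' @return object of class `bowtie_params`.
#' @export
bowtie_params <- function(opening_angle = pi / 2,
                          max_orient_diff = pi / 4,
                          sigma_exc = 21,
                          sigma_inh = 21,
                          strength = 150) {
  stopifnot(opening_angle > 0, opening_angle <= pi,
            max_orient_diff > 0, max_orient_diff <= pi / 2,
            sigma_exc > 0, sigma_inh > 0, strength > 0)
  structure(list(opening_angle = opening_angle,
                 max_orient_diff = max_orient_diff,
                 sigma_exc = sigma_exc, sigma_inh = sigma_inh,
                 strength = strength),
            class = "bowtie_params")
}

#' Build a Bowtie kernel
#'
#' An entry at displacement `delta` and relative orientation `theta_rel` is
#' excitatory iff the direction of `delta` lies within half the opening angle
#' of the center element's axis (either end) and the folded orientation
#' difference does not exceed `max_orient_diff`; its value is
#' `exp(-|delta|^2 / (2 sigma_exc^2))`. All other entries are inhibitory,
#' `-exp(-|delta|^2 / (2 sigma_inh^2))`, independent of orientation.
#' Excitatory and inhibitory parts are normalized to `+S` and `-S`.
#'
#' @param params a [bowtie_params()].
#' @param R cutoff radius, pixels.
#' @param n_orient number of orientation bins.
#' @param angle_offset canonical axis angle (the filter bank's
#'   `angle_offset`).
#' @return object of class `lateral_kernel` (kind `"bowtie"`).
#' @export
bowtie_kernel <- function(params = bowtie_params(), R = 63L, n_orient = 8L,
                          angle_offset = pi / 32) {
  stopifnot(inherits(params, "bowtie_params"))
  D <- 2L * R + 1L
  off <- seq(-R, R)
  dx <- matrix(off, D, D, byrow = TRUE)
  dy <- matrix(off, D, D)
  d2 <- dx^2 + dy^2
  inside <- d2 <= R^2 & d2 > 0
  beta <- atan2(dy, dx)
  # angular distance from displacement direction to the axis line (mod pi)
  dir_dist <- abs((beta - angle_offset + pi / 2) %% pi - pi / 2)
  in_fan <- dir_dist <= params$opening_angle / 2

  canonical <- array(0, dim = c(D, D, n_orient))
  for (j in seq_len(n_orient)) {
    dth <- (j - 1) * pi / n_orient
    dth <- min(dth, pi - dth)
    exc_mask <- inside & in_fan & (dth <= params$max_orient_diff)
    slice <- matrix(0, D, D)
    slice[exc_mask] <- exp(-d2[exc_mask] / (2 * params$sigma_exc^2))
    slice[inside & !exc_mask] <-
      -exp(-d2[inside & !exc_mask] / (2 * params$sigma_inh^2))
    canonical[, , j] <- slice
  }
  pos <- sum(canonical[canonical > 0])
  neg <- -sum(canonical[canonical < 0])
  if (pos <= 0 || neg <= 0) {
    stop("degenerate bowtie geometry: one part is empty", call. = FALSE)
  }
  canonical[canonical > 0] <- canonical[canonical > 0] *
    (params$strength / pos)
  canonical[canonical < 0] <- canonical[canonical < 0] *
    (params$strength / neg)
  new_lateral_kernel(canonical, params$strength, R, n_orient, angle_offset,
                     kind = "bowtie", meta = unclass(params))
}

#' Quantize a kernel to unsigned 8-bit codes
#'
#' Symmetric affine map `code = round(128 + 127 * value / max|K|)` clipped to
#' `[0, 255]`; zero maps exactly to code 128, `+max|K|` to 255. The stored
#' scale inverts the map; round-trip error is at most `max|K| / 254` per
#' entry. An all-zero kernel stores all-128 codes with scale 0.
#'
#' @param kernel a `lateral_kernel`.
#' @return the kernel with a `quantized` field (`codes` integer array on the
#'   canonical table, `scale = max|K|`).
#' @export
quantize_kernel <- function(kernel) {
  stopifnot(inherits(kernel, "lateral_kernel"))
  scale <- max(abs(kernel$canonical))
  if (scale == 0) {
    codes <- array(128L, dim = dim(kernel$canonical))
  } else {
    codes <- round_half_away(128 + 127 * kernel$canonical / scale)
    codes <- array(as.integer(pmax(pmin(codes, 255), 0)),
                   dim = dim(kernel$canonical))
  }
  kernel$quantized <- list(codes = codes, scale = scale)
  kernel
}

#' Recover kernel values from 8-bit codes
#'
#' @param kernel a quantized `lateral_kernel`.
#' @return numeric array: the dequantized canonical table.
#' @export
dequantize_kernel <- function(kernel) {
  stopifnot(inherits(kernel, "lateral_kernel"),
            !is.null(kernel$quantized))
  if (kernel$quantized$scale == 0) {
    return(array(0, dim = dim(kernel$quantized$codes)))
  }
  (kernel$quantized$codes - 128) * kernel$quantized$scale / 127
}

#' @export
print.lateral_kernel <- function(x, ...) {
  cat("<lateral_kernel>", x$kind, "| R =", x$R, "px,", x$n_orient,
      "orientations, strength S =", format(x$strength), "\n")
  cat("  canonical sum:", format(sum(x$canonical), digits = 3),
      "| max |K|:", format(max(abs(x$canonical)), digits = 3),
      if (!is.null(x$quantized)) "| 8-bit quantized" else "", "\n")
  invisible(x)
}

#' Serialize / restore a kernel
#'
#' Writes the kernel as an RDS file plus a small JSON sidecar with the
#' human-readable metadata (kind, strength, geometry, provenance counts).
#'
#' @param kernel a `lateral_kernel`.
#' @param path file path (`.rds`); the sidecar gets `.json` appended.
#' @return `path`, invisibly (`write`) or the kernel (`read`).
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "lateral_kernel"))
  saveRDS(kernel, path)
  meta <- list(kind = kernel$kind, strength = kernel$strength, R = kernel$R,
               n_orient = kernel$n_orient,
               angle_offset = kernel$angle_offset, meta = kernel$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  k <- readRDS(path)
  stopifnot(inherits(k, "lateral_kernel"))
  k
}
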