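# Orientation-selective front end: oriented difference-of-elliptical-Gaussian
# filters, piecewise-linear transfer function, DoG preprocessing for natural
# grayscale images.

# Elliptical Gaussian on kernel grid offsets, long axis at `angle`, center
# displaced by `shift` (x, y). Unnormalized.
elliptical_gaussian <- function(extent, angle, sigma_long, sigma_short,
                                shift = c(0, 0)) {
  h <- (extent - 1) / 2
  off <- seq(-h, h)
  dx <- matrix(off, extent, extent, byrow = TRUE) - shift[1]
  dy <- matrix(off, extent, extent) - shift[2]
  u_par <- dx * cos(angle) + dy * sin(angle)
  u_perp <- -dx * sin(angle) + dy * cos(angle)
  exp(-(u_par^2 / (2 * sigma_long^2) + u_perp^2 / (2 * sigma_short^2)))
}

#' Build the oriented filter bank
#'
#' One kernel per orientation `delta + i * pi / n_orient`, `i = 0 ..
#' n_orient - 1`: a central excitatory elliptical Gaussian (sd `sigma_long`
#' along the preferred axis, `sigma_long / aspect` across it) minus two
#' identically shaped inhibitory Gaussians offset by `flank_offset` pixels
#' orthogonally on either side. The excitatory subunit is scaled to integrate
#' to `exc_total` and each inhibitory subunit to `-exc_total / 2`, so every
#' kernel sums to (numerically) zero.
#'
#' @param params a [filter_params()].
#' @return object of class `filter_bank`: `kernels` is an
#'   `extent x extent x n_orient` array; `angles` the preferred orientations
#'   (radians, modulo pi); plus the parameter set.
#' @export
filter_bank <- function(params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  E <- params$extent
  sigma_short <- params$sigma_long / params$aspect
  half_needed <- max(3 * params$sigma_long,
                     params$flank_offset + 3 * sigma_short)
  if ((E - 1) / 2 < half_needed) {
    warning("filter extent truncates subunits before 3 sigma; proceeding",
            call. = FALSE)
  }
  angles <- params$angle_offset +
    (seq_len(params$n_orient) - 1) * pi / params$n_orient
  kernels <- array(0, dim = c(E, E, params$n_orient))
  for (i in seq_along(angles)) {
    a <- angles[i]
    nrm <- c(-sin(a), cos(a))  # unit normal to the preferred axis
    exc <- elliptical_gaussian(E, a, params$sigma_long, sigma_short)
    inh1 <- elliptical_gaussian(E, a, params$sigma_long, sigma_short,
                                shift = params$flank_offset * nrm)
    inh2 <- elliptical_gaussian(E, a, params$sigma_long, sigma_short,
                                shift = -params$flank_offset * nrm)
    kernels[, , i] <- params$exc_total * exc / sum(exc) -
      (params$exc_total / 2) * inh1 / sum(inh1) -
      (params$exc_total / 2) * inh2 / sum(inh2)
  }
  structure(c(list(kernels = kernels, angles = angles), unclass(params)),
            class = "filter_bank")
}

#' Piecewise-linear synaptic transfer function
#'
#' Hard threshold at 0.5 and saturation at 1: `f(x) = 0` for `x < 0.5`,
#' `f(x) = x` for `0.5 <= x <= 1`, `f(x) = 1` for `x > 1`. Applied
#' element-wise; shape and dim attributes are preserved.
#'
#' @param x numeric vector, matrix or array.
#' @return same shape, values in `[0, 1] `.
#' @export
#' @examples
#' transfer(c(0.3, 0.75, 1.2)) # 0, 0.75, 1
transfer <- function(x) {
  out <- x
  out[x < 0.5] <- 0
  out[x > 1] <- 1
  out
}

#' Compute the orientation-selective activity field
#'
#' Cross-correlates the binary image with each oriented kernel (no kernel
#' flip, mirror-padded borders) and passes the result through the transfer
#' function. The output is the model's initial cortical activity field.
#'
#' @param image an `L x L` 0/1 matrix ([rasterize()] output or compatible).
#' @param bank a [filter_bank()].
#' @param raw if `TRUE`, return pre-transfer retinal drive instead.
#' @return object of class `orientation_field`: an `L x L x n_orient` array
#'   with attributes `angles` and `angle_offset`.
#' @export
orientation_field <- function(image, bank, raw = FALSE) {
  stopifnot(inherits(bank, "filter_bank"))
  img <- matrix(as.numeric(image), nrow(image))
  # scatter from nonzero pixels when the drawing is sparse; identical result
  drive <- if (mean(img != 0) < 0.15) {
    conv2_mirror_sparse_cpp(img, bank$kernels)
  } else {
    conv2_mirror_cpp(img, bank$kernels)
  }
  out <- if (raw) drive else transfer(drive)
  attr(out, "angles") <- bank$angles
  attr(out, "angle_offset") <- bank$angle_offset
  class(out) <- c("orientation_field", class(out))
  out
}

#' Difference-of-Gaussians edge preprocessing
#'
#' Converts a grayscale image into a binary edge map: the image is filtered
#' with a center-surround difference of Gaussians (surround sd =
#' `sigma_ratio * sigma_c`) and hard-thresholded at the `q` quantile of the
#' response distribution. This lets natural images enter the same contour
#' pipeline as the synthetic line drawings. A constant image yields an
#' all-zero output.
#'
#' @param gray numeric matrix in `[0, 1]`.
#' @param sigma_c center Gaussian sd, px.
#' @param sigma_ratio surround/center sd ratio.
#' @param q response quantile used as the binarization threshold.
#' @return a `binary_image` matrix of 0/1.
#' @export
dog_preprocess <- function(gray, sigma_c = 1, sigma_ratio = 1.6, q = 0.9) {
  stopifnot(is.matrix(gray), sigma_c > 0, sigma_ratio > 1, q > 0, q < 1)
  sigma_s <- sigma_ratio * sigma_c
  E <- 2L * as.integer(ceiling(3 * sigma_s)) + 1L
  h <- (E - 1) / 2
  off <- seq(-h, h)
  d2 <- outer(off^2, off^2, `+`)
  gc <- exp(-d2 / (2 * sigma_c^2)); gc <- gc / sum(gc)
  gs <- exp(-d2 / (2 * sigma_s^2)); gs <- gs / sum(gs)
  dog <- array(gc - gs, dim = c(E, E, 1L))
  resp <- conv2_mirror_cpp(gray, dog)[, , 1]
  thr <- max(quantile(resp, q), 1e-12)
  img <- matrix(as.integer(resp > thr), nrow(gray))
  class(img) <- c("binary_image", class(img))
  img
}
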