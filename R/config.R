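#' Stimulus generator configuration
#'
#' Parameters of the amoeba/no-amoeba image generator. An *amoeba* is a
#' radial frequency pattern: a deformed circle whose radius is a superposition
#' of `n_freq` sinusoidal components of the polar angle, sampled at `n_polar`
#' discrete angles, fragmented by `n_gaps` periodically placed gaps. Clutter is
#' built from independent amoebas whose fragment groups are rigidly rotated
#' about their centroids, making them locally indistinguishable from target
#' fragments.
#'
#' All concrete values are exposed here; the defaults give visually plausible
#' stimuli at a 256-pixel canvas and are used throughout the package's own
#' experiments.
#'
#' @param image_size square image extent L, pixels.
#' @param n_polar number of discrete polar angles P used to sample the radius.
#' @param n_freq number of radial frequency components (target complexity).
#' @param amp_mean,amp_sd normal distribution of component amplitudes.
#' @param rmax_lo,rmax_hi bounds on the maximum radius, as fractions of L.
#' @param rmin_lo_frac,rmin_hi_frac bounds on the minimum radius, as fractions
#'   of the sampled maximum radius.
#' @param n_gaps number of gaps (hence fragments) per amoeba.
#' @param gap_lo,gap_hi gap widths, in polar-angle steps (integers).
#' @param poisson_mean,poisson_cutoff clutter group sizes are zero-excluded
#'   Poisson(`poisson_mean`) draws clipped to `[1, poisson_cutoff]`.
#' @param n_clutter_target clutter sets added to each target image.
#' @param n_sets_distractor clutter sets composing each distractor image.
#' @param n_sets_mask clutter sets composing each mask image.
#' @return an object of class `amoeba_config`.
#' @export
#' @examples
#' cfg <- amoeba_config(n_freq = 2)
#' cfg$image_size
amoeba_config <- function(image_size = 256L,
                          n_polar = 512L,
                          n_freq = 2L,
                          amp_mean = 0,
                          amp_sd = 1,
                          rmax_lo = 1 / 16,
                          rmax_hi = 1 / 4,
                          rmin_lo_frac = 0.25,
                          rmin_hi_frac = 1,
                          n_gaps = 8L,
                          gap_lo = 2L,
                          gap_hi = 8L,
                          poisson_mean = 2,
                          poisson_cutoff = 4L,
                          n_clutter_target = 3L,
                          n_sets_distractor = 4L,
                          n_sets_mask = 8L) {
  cfg <- list(
    image_size = as.integer(image_size), n_polar = as.integer(n_polar),
    n_freq = as.integer(n_freq), amp_mean = amp_mean, amp_sd = amp_sd,
    rmax_lo = rmax_lo, rmax_hi = rmax_hi,
    rmin_lo_frac = rmin_lo_frac, rmin_hi_frac = rmin_hi_frac,
    n_gaps = as.integer(n_gaps), gap_lo = as.integer(gap_lo),
    gap_hi = as.integer(gap_hi), poisson_mean = poisson_mean,
    poisson_cutoff = as.integer(poisson_cutoff),
    n_clutter_target = as.integer(n_clutter_target),
    n_sets_distractor = as.integer(n_sets_distractor),
    n_sets_mask = as.integer(n_sets_mask)
  )
  class(cfg) <- "amoeba_config"
  validate_amoeba_config(cfg)
  cfg
}

validate_amoeba_config <- function(cfg) {
  stopifnot(
    cfg$image_size >= 16L,
    cfg$n_freq >= 1L,
    cfg$n_polar >= 8L * cfg$n_freq,
    cfg$rmax_lo > 0, cfg$rmax_lo <= cfg$rmax_hi, cfg$rmax_hi < 0.5,
    cfg$rmin_lo_frac > 0, cfg$rmin_lo_frac <= cfg$rmin_hi_frac,
    cfg$rmin_hi_frac <= 1,
    cfg$n_gaps >= 1L, cfg$gap_lo >= 1L, cfg$gap_lo <= cfg$gap_hi,
    cfg$poisson_cutoff >= 1L, cfg$poisson_mean > 0,
    cfg$n_polar %% cfg$n_gaps == 0L
  )
  if (cfg$n_gaps * cfg$gap_hi >= cfg$n_polar) {
    stop("invalid config: n_gaps * gap_hi must be < n_polar ",
         "(fragments would vanish)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.amoeba_config <- function(x, ...) {
  cat("<amoeba_config> L =", x$image_size, "px, P =", x$n_polar,
      "angles, n_freq =", x$n_freq, "\n")
  cat("  r_max in [", x$rmax_lo, ",", x$rmax_hi, "] * L;",
      "r_min in [", x$rmin_lo_frac, ",", x$rmin_hi_frac, "] * r_max\n")
  cat("  ", x$n_gaps, "gaps of", x$gap_lo, "-", x$gap_hi, "steps;",
      "group sizes ~ Poisson(", x$poisson_mean, ") in [1,",
      x$poisson_cutoff, "]\n")
  cat("  composition: target 1 +", x$n_clutter_target,
      ", distractor", x$n_sets_distractor, ", mask", x$n_sets_mask, "\n")
  invisible(x)
}

#' Orientation-selective filter bank parameters
#'
#' The front end converts a binary line drawing into per-orientation activity
#' maps using oriented difference-of-elliptical-Gaussian filters: a central
#' excitatory elongated Gaussian subunit flanked by two identically shaped
#' inhibitory subunits offset orthogonally to the preferred axis. All subunits
#' carry the same integrated strength (to within sign), so each kernel sums to
#' approximately zero.
#'
#' @param n_orient number of orientations spanning half a turn.
#' @param angle_offset global rotation (radians) of all preferred axes, used
#'   to keep filter axes off the pixel lattice and mitigate aliasing.
#' @param extent square kernel support, pixels (odd).
#' @param sigma_long Gaussian standard deviation along the preferred axis, px.
#' @param aspect ratio of long to short subunit standard deviation.
#' @param flank_offset distance of each inhibitory subunit from the center,
#'   orthogonal to the preferred axis, px.
#' @param exc_total integrated strength of the excitatory subunit (the two
#'   inhibitory subunits each integrate to `-exc_total / 2`). The default was
#'   calibrated so binary contours yield clean suprathreshold edge maps.
#' @return object of class `filter_params`.
#' @export
filter_params <- function(n_orient = 8L,
                          angle_offset = pi / 32,
                          extent = 15L,
                          sigma_long = 2,
                          aspect = 3,
                          flank_offset = 2,
                          exc_total = 1.4) {
  stopifnot(n_orient >= 2L, extent %% 2L == 1L, sigma_long > 0,
            aspect >= 1, flank_offset > 0, exc_total > 0)
  p <- list(n_orient = as.integer(n_orient), angle_offset = angle_offset,
            extent = as.integer(extent), sigma_long = sigma_long,
            aspect = aspect, flank_offset = flank_offset,
            exc_total = exc_total)
  class(p) <- "filter_params"
  p
}

#' Relaxation dynamics configuration
#'
#' @param n_iterations number of multiplicative lateral-interaction iterations.
#' @param support_mode `"raw"` multiplies activity by the support `C` itself,
#'   so elements whose neighborhoods provide insufficient support fall below
#'   the transfer threshold and are suppressed, while a zero-sum kernel gives
#'   randomly arranged edges neutral (near-zero) support; `"offset"` uses
#'   `1 + C` (neutral = multiplicative identity), retained for sensitivity
#'   analysis — with trained kernels the support of real contour elements is
#'   almost everywhere positive, so offset mode cannot suppress clutter (see
#'   the package vignette).
#' @return object of class `dynamics_config`.
#' @export
dynamics_config <- function(n_iterations = 8L,
                            support_mode = c("raw", "offset")) {
  stopifnot(n_iterations >= 0L)
  d <- list(n_iterations = as.integer(n_iterations),
            support_mode = match.arg(support_mode))
  class(d) <- "dynamics_config"
  d
}
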