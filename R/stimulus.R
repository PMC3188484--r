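# Amoeba/no-amoeba stimulus synthesis.
#
# Coordinates are 0-based continuous pixel-center coordinates, x rightward,
# y downward; images are integer matrices indexed [y + 1, x + 1].

#' Sample an amoeba radial profile
#'
#' Draws one closed radial frequency pattern: the raw radius at `P` uniform
#' polar angles is `sum_k a_k * sin(k * phi + phi_k)` over `k = 1..n_freq`,
#' with amplitudes `a_k ~ N(amp_mean, amp_sd^2)` and phases uniform on
#' `[0, 2*pi)`. The profile is then linearly rescaled so that its maximum
#' radius equals a draw `r_max ~ U(rmax_lo * L, rmax_hi * L)` and its minimum
#' equals `r_min ~ U(rmin_lo_frac * r_max, rmin_hi_frac * r_max)`. The center
#' is sampled uniformly so that no contour point can cross an image boundary.
#'
#' A degenerate flat profile (raw range below 1e-9, e.g. all amplitudes zero)
#' is resampled up to `max_retry` times before failing.
#'
#' @param cfg an [amoeba_config()].
#' @param max_retry resampling cap for degenerate profiles.
#' @return object of class `amoeba_contour`: fields `center` (x, y), `angles`,
#'   `radii`, `r_max`, `r_min`, and (after [fragment_contour()]) `fragments`.
#' @export
sample_amoeba_profile <- function(cfg, max_retry = 20L) {
  validate_amoeba_config(cfg)
  P <- cfg$n_polar
  L <- cfg$image_size
  phi <- 2 * pi * (seq_len(P) - 1) / P

  r_raw <- NULL
  for (try in seq_len(max_retry)) {
    a <- rnorm(cfg$n_freq, cfg$amp_mean, cfg$amp_sd)
    ph <- runif(cfg$n_freq, 0, 2 * pi)
    r <- rowSums(vapply(seq_len(cfg$n_freq),
                        function(k) a[k] * sin(k * phi + ph[k]),
                        numeric(P)))
    if (max(r) - min(r) >= 1e-9) {
      r_raw <- r
      break
    }
  }
  if (is.null(r_raw)) {
    stop("degenerate amoeba profile: raw radius range below tolerance after ",
         max_retry, " attempts", call. = FALSE)
  }

  r_max <- runif(1, cfg$rmax_lo * L, cfg$rmax_hi * L)
  r_min <- runif(1, cfg$rmin_lo_frac * r_max, cfg$rmin_hi_frac * r_max)
  radii <- r_min + (r_raw - min(r_raw)) *
    (r_max - r_min) / (max(r_raw) - min(r_raw))

  center <- c(runif(1, r_max, (L - 1) - r_max),
              runif(1, r_max, (L - 1) - r_max))

  structure(
    list(center = center, angles = phi, radii = radii,
         r_max = r_max, r_min = r_min, n_freq = cfg$n_freq,
         fragments = NULL),
    class = "amoeba_contour"
  )
}

#' Fragment an amoeba contour with periodic gaps
#'
#' Deletes `n_gaps` gaps from the closed contour. Gap start positions are
#' periodic — `P / n_gaps` polar steps apart, with the first start uniform on
#' `[0, P / n_gaps)` — and each gap width is an integer uniform on
#' `[gap_lo, gap_hi]` polar steps. Deleted samples are removed outright, so
#' the angle subtended by each fragment shrinks with the width of the gap
#' preceding it.
#'
#' @param contour an unfragmented `amoeba_contour`.
#' @param cfg an [amoeba_config()].
#' @return the contour with `fragments`: a list of exactly `n_gaps` integer
#'   index vectors (1-based indices into `angles`/`radii`, circular order).
#' @export
fragment_contour <- function(contour, cfg) {
  validate_amoeba_config(cfg)
  if (!is.null(contour$fragments)) {
    stop("contour is already fragmented", call. = FALSE)
  }
  P <- cfg$n_polar
  G <- cfg$n_gaps
  spacing <- P %/% G

  g0 <- sample.int(spacing, 1L) - 1L
  widths <- cfg$gap_lo +
    sample.int(cfg$gap_hi - cfg$gap_lo + 1L, G, replace = TRUE) - 1L
  starts <- (g0 + (seq_len(G) - 1L) * spacing) %% P

  fragments <- vector("list", G)
  for (i in seq_len(G)) {
    from <- (starts[i] + widths[i]) %% P               # first surviving index
    len <- spacing - widths[i]                         # samples until next gap
    fragments[[i]] <- ((from + seq_len(len) - 1L) %% P) + 1L
  }
  contour$fragments <- fragments
  contour$gap_widths <- widths
  contour
}

# Cartesian points (0-based) of a subset of polar samples, n x 2 (x, y).
contour_points <- function(contour, idx = seq_along(contour$angles)) {
  r <- contour$radii[idx]
  phi <- contour$angles[idx]
  cbind(contour$center[1] + r * cos(phi),
        contour$center[2] + r * sin(phi))
}

#' Fragment set from an intact amoeba
#'
#' Packages the fragments of an amoeba as a single unrotated group — the
#' target object of a trial.
#'
#' @param contour a fragmented `amoeba_contour`.
#' @return object of class `fragment_set` (`groups`: list of groups, each a
#'   list of n x 2 point matrices; `provenance`).
#' @export
amoeba_set <- function(contour) {
  if (is.null(contour$fragments)) {
    stop("contour must be fragmented first", call. = FALSE)
  }
  pts <- lapply(contour$fragments, function(ix) contour_points(contour, ix))
  structure(list(groups = list(pts), provenance = "amoeba"),
            class = "fragment_set")
}

# Zero-excluded Poisson draw clipped to [1, cutoff].
truncated_poisson <- function(n, mean, cutoff) {
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- 0L
    while (s < 1L) s <- rpois(1L, mean)
    out[i] <- min(s, cutoff)
  }
  out
}

#' Turn an amoeba into clutter
#'
#' Groups consecutive fragments greedily, with group sizes drawn from a
#' zero-excluded Poisson clipped to `[1, poisson_cutoff]`, then rigidly
#' rotates each group about the centroid of its points by an independent
#' angle uniform on `[0, 2*pi)`. The rotated fragments are locally identical
#' to amoeba fragments but no longer support a closed contour. Points are
#' kept in continuous coordinates; out-of-bounds points are mirrored back
#' into the image at rasterization.
#'
#' @param contour a fragmented `amoeba_contour`.
#' @param cfg an [amoeba_config()].
#' @param angles optional fixed rotation angles (radians), one per group,
#'   recycled; mainly for tests.
#' @return a `fragment_set` with provenance `"clutter"`.
#' @export
make_clutter <- function(contour, cfg, angles = NULL) {
  if (is.null(contour$fragments)) {
    stop("contour must be fragmented first", call. = FALSE)
  }
  n_frag <- length(contour$fragments)
  sizes <- integer(0)
  while (sum(sizes) < n_frag) {
    sizes <- c(sizes, truncated_poisson(1L, cfg$poisson_mean,
                                        cfg$poisson_cutoff))
  }
  # greedy consecutive partition; last group truncated to what remains
  groups <- list()
  at <- 1L
  for (s in sizes) {
    take <- min(s, n_frag - at + 1L)
    if (take <= 0L) break
    idx <- seq.int(at, at + take - 1L)
    groups[[length(groups) + 1L]] <-
      lapply(contour$fragments[idx], function(ix) contour_points(contour, ix))
    at <- at + take
  }

  rot <- if (is.null(angles)) runif(length(groups), 0, 2 * pi) else
    rep_len(angles, length(groups))
  for (g in seq_along(groups)) {
    pts_all <- do.call(rbind, groups[[g]])
    ctr <- colMeans(pts_all)
    cs <- cos(rot[g]); sn <- sin(rot[g])
    groups[[g]] <- lapply(groups[[g]], function(p) {
      dx <- p[, 1] - ctr[1]; dy <- p[, 2] - ctr[2]
      cbind(ctr[1] + cs * dx - sn * dy,
            ctr[2] + sn * dx + cs * dy)
    })
  }
  structure(list(groups = groups, provenance = "clutter"),
            class = "fragment_set")
}

# 8-connected Bresenham line between integer endpoints, inclusive.
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  n <- max(dx, dy)
  if (n == 0L) return(cbind(x0, y0))
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  err <- dx - dy
  xs <- integer(n + 1L); ys <- integer(n + 1L)
  x <- x0; y <- y0
  for (i in seq_len(n + 1L)) {
    xs[i] <- x; ys[i] <- y
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  cbind(xs, ys)
}

#' Rasterize fragment sets to a binary image
#'
#' Each fragment's continuous points are mirrored into the image domain
#' (see [mirror_reflect()]), rounded to the nearest pixel (half away from
#' zero), and consecutive points are connected with 8-connected Bresenham
#' segments. The image is the union (logical OR) over all sets.
#'
#' @param sets a `fragment_set` or list of them (an empty list yields an
#'   all-zero image).
#' @param L image extent, pixels.
#' @return an `L x L` integer matrix of 0/1, class `binary_image`.
#' @export
rasterize <- function(sets, L) {
  if (inherits(sets, "fragment_set")) sets <- list(sets)
  img <- matrix(0L, L, L)
  for (s in sets) {
    for (grp in s$groups) {
      for (pts in grp) {
        px <- as.integer(round_half_away(mirror_reflect(pts[, 1], L)))
        py <- as.integer(round_half_away(mirror_reflect(pts[, 2], L)))
        n <- length(px)
        img[py[1] + 1L, px[1] + 1L] <- 1L
        if (n > 1L) {
          for (i in seq_len(n - 1L)) {
            if (max(abs(px[i + 1L] - px[i]), abs(py[i + 1L] - py[i])) <= 1L) {
              img[py[i + 1L] + 1L, px[i + 1L] + 1L] <- 1L
            } else {
              seg <- bresenham(px[i], py[i], px[i + 1L], py[i + 1L])
              img[cbind(seg[, 2] + 1L, seg[, 1] + 1L)] <- 1L
            }
          }
        }
      }
    }
  }
  class(img) <- c("binary_image", class(img))
  img
}

#' Generate one amoeba/no-amoeba trial
#'
#' A trial consists of a target image (one fragmented amoeba plus
#' `n_clutter_target` clutter sets, each derived from an independent amoeba),
#' a distractor image (`n_sets_distractor` clutter sets), and a mask image
#' (`n_sets_mask` clutter sets obtained by re-rotating fresh groupings of the
#' very amoebas used for this trial's target and distractor). Because targets
#' and distractors are built from the same number of equally fragmented
#' amoebas, the two classes match in mean ON-pixel count over the ensemble.
#'
#' @param cfg an [amoeba_config()].
#' @param seed optional integer; when given, seeds the trial so the triplet is
#'   reproducible bit for bit.
#' @return list with `target`, `distractor`, `mask` (binary images) and
#'   `manifest` (one-row tibble of composition bookkeeping).
#' @export
generate_trial <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- cfg$image_size
  n_amoebas <- 1L + cfg$n_clutter_target + cfg$n_sets_distractor

  amoebas <- lapply(seq_len(n_amoebas), function(i) {
    fragment_contour(sample_amoeba_profile(cfg), cfg)
  })

  target_sets <- c(
    list(amoeba_set(amoebas[[1]])),
    lapply(amoebas[seq_len(cfg$n_clutter_target) + 1L],
           make_clutter, cfg = cfg)
  )
  distractor_sets <- lapply(
    amoebas[seq_len(cfg$n_sets_distractor) + 1L + cfg$n_clutter_target],
    make_clutter, cfg = cfg
  )
  mask_idx <- rep_len(seq_len(n_amoebas), cfg$n_sets_mask)
  mask_sets <- lapply(amoebas[mask_idx], make_clutter, cfg = cfg)

  manifest <- tibble::tibble(
    n_freq = cfg$n_freq,
    n_sets_target = 1L + cfg$n_clutter_target,
    n_sets_distractor = cfg$n_sets_distractor,
    n_sets_mask = cfg$n_sets_mask,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )

  list(target = rasterize(target_sets, L),
       distractor = rasterize(distractor_sets, L),
       mask = rasterize(mask_sets, L),
       manifest = manifest)
}
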