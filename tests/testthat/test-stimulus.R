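test_that("sampled amoeba profiles hit their radius bounds and stay in frame", {
  set.seed(101)
  cfg <- amoeba_config(n_freq = 2)
  for (i in 1:1000) {
    ct <- sample_amoeba_profile(cfg)
    expect_lt(abs(max(ct$radii) - ct$r_max), 1e-9)
    expect_lt(abs(min(ct$radii) - ct$r_min), 1e-9)
    if (i <= 50) {
      pts <- oddfield:::contour_points(ct)
      expect_true(all(pts >= 0 & pts <= cfg$image_size - 1))
    }
  }
})

test_that("a flat radial profile triggers the degenerate-resample path", {
  cfg <- amoeba_config(n_freq = 1, amp_mean = 0, amp_sd = 0)
  set.seed(1)
  expect_error(sample_amoeba_profile(cfg), "degenerate")
})

test_that("fragmentation deletes periodic gaps of the configured widths", {
  set.seed(7)
  cfg <- amoeba_config(n_polar = 360L, n_gaps = 4L, gap_lo = 5L, gap_hi = 5L,
                       n_freq = 2)
  ct <- fragment_contour(sample_amoeba_profile(cfg), cfg)
  expect_length(ct$fragments, 4L)
  expect_true(all(ct$gap_widths == 5L))
  expect_identical(sum(lengths(ct$fragments)), 360L - 4L * 5L)
  # surviving indices are disjoint
  expect_identical(anyDuplicated(unlist(ct$fragments)), 0L)

  cfg2 <- amoeba_config(n_freq = 2)  # gaps U[2, 8]
  for (i in 1:1000) {
    ct <- fragment_contour(sample_amoeba_profile(cfg2), cfg2)
    w <- ct$gap_widths
    stopifnot(all(w >= cfg2$gap_lo), all(w <= cfg2$gap_hi),
              length(ct$fragments) == cfg2$n_gaps)
  }
  succeed()
})

test_that("refragmenting or invalid gap configs raise errors", {
  cfg <- amoeba_config(n_freq = 2)
  set.seed(2)
  ct <- fragment_contour(sample_amoeba_profile(cfg), cfg)
  expect_error(fragment_contour(ct, cfg), "already fragmented")
  expect_error(amoeba_config(n_polar = 64L, n_gaps = 8L, gap_hi = 8L),
               "invalid config")
})

test_that("clutter groups fragments greedily and rotates about centroids", {
  set.seed(11)
  cfg <- amoeba_config(n_freq = 2)
  ct <- fragment_contour(sample_amoeba_profile(cfg), cfg)

  # cutoff 1 forces singleton groups
  cfg1 <- cfg; cfg1$poisson_cutoff <- 1L
  fs <- make_clutter(ct, cfg1)
  expect_length(fs$groups, cfg$n_gaps)

  # zero rotation leaves coordinates untouched
  fs0 <- make_clutter(ct, cfg, angles = 0)
  orig <- lapply(ct$fragments, function(ix) oddfield:::contour_points(ct, ix))
  expect_equal(do.call(rbind, unlist(fs0$groups, recursive = FALSE)),
               do.call(rbind, orig), tolerance = 1e-12)

  # centroid of every group is invariant under its random rotation
  for (rep in 1:50) {
    ct2 <- fragment_contour(sample_amoeba_profile(cfg), cfg)
    before <- lapply(ct2$fragments,
                     function(ix) oddfield:::contour_points(ct2, ix))
    fs2 <- make_clutter(ct2, cfg)
    at <- 1L
    for (grp in fs2$groups) {
      n_in <- length(grp)
      pts_before <- do.call(rbind, before[at:(at + n_in - 1L)])
      pts_after <- do.call(rbind, grp)
      expect_lt(max(abs(colMeans(pts_before) - colMeans(pts_after))), 1e-9)
      # per-fragment point counts conserved
      expect_identical(vapply(grp, nrow, 1L),
                       vapply(before[at:(at + n_in - 1L)], nrow, 1L))
      at <- at + n_in
    }
  }
})

test_that("rasterization reflects, rounds half away from zero, and connects", {
  expect_equal(sum(rasterize(list(), 64)), 0)

  # stated reflection rule: x = -3.2 with L = 256 lands in pixel column 2
  fs <- structure(list(groups = list(list(cbind(-3.2, 5))),
                       provenance = "clutter"), class = "fragment_set")
  img <- rasterize(fs, 256)
  expect_identical(which(img == 1L, arr.ind = TRUE),
                   matrix(c(6L, 3L), 1, dimnames = list(NULL, c("row", "col"))))

  # n collinear integer points -> exactly n ON pixels
  pts <- cbind(10:19, 10:19)
  fs2 <- structure(list(groups = list(list(pts)), provenance = "amoeba"),
                   class = "fragment_set")
  expect_identical(sum(rasterize(fs2, 64)), 10L)

  # distant points get Bresenham-connected into an 8-connected path
  fs3 <- structure(list(groups = list(list(cbind(c(0, 9), c(0, 3)))),
                        provenance = "amoeba"), class = "fragment_set")
  img3 <- rasterize(fs3, 32)
  expect_identical(sum(img3), 10L)
})

test_that("mirror_reflect implements the stated boundary rule", {
  expect_equal(mirror_reflect(-3.2, 256), 2.2)
  expect_equal(mirror_reflect(256.4, 256), 254.6)
  expect_equal(mirror_reflect(c(-0.5, 255.49), 256), c(-0.5, 255.49))
  expect_equal(oddfield:::round_half_away(c(-2.5, -0.5, 0.5, 2.5)),
               c(-3, -1, 1, 3))
})

test_that("trials are reproducible and carry the stated composition", {
  cfg <- amoeba_config(n_freq = 4)
  tr1 <- generate_trial(cfg, seed = 33)
  tr2 <- generate_trial(cfg, seed = 33)
  expect_identical(tr1$target, tr2$target)
  expect_identical(tr1$distractor, tr2$distractor)
  expect_identical(tr1$mask, tr2$mask)

  expect_identical(tr1$manifest$n_sets_target, 4L)
  expect_identical(tr1$manifest$n_sets_distractor, 4L)
  expect_identical(tr1$manifest$n_sets_mask, 8L)
  expect_identical(tr1$manifest$n_freq, 4L)
  expect_true(all(tr1$target %in% c(0L, 1L)))
})
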