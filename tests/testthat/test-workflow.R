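# Small image sizes keep the pipeline tests fast; geometry scales freely.
small_cfg <- function(n_freq = 2L) {
  amoeba_config(image_size = 96L, n_polar = 256L, n_freq = n_freq,
                n_gaps = 8L, gap_lo = 2L, gap_hi = 6L)
}

test_that("datasets are written deterministically and round-trip", {
  root <- withr::local_tempdir()
  cfg <- small_cfg()
  m1 <- generate_dataset(cfg, file.path(root, "d1"), n_trials = 2L,
                         nf_list = c(2L, 8L), seed = 5L)
  pngs <- list.files(file.path(root, "d1"), pattern = "\\.png$",
                     recursive = TRUE)
  expect_length(pngs, 2L * 2L * 3L)
  expect_error(generate_dataset(cfg, file.path(root, "d1"), n_trials = 2L,
                                nf_list = c(2L, 8L), seed = 5L),
               "already exists")

  m2 <- generate_dataset(cfg, file.path(root, "d2"), n_trials = 2L,
                         nf_list = c(2L, 8L), seed = 5L)
  f1 <- file.path(root, "d1", "2", "trial_001", "target.png")
  f2 <- file.path(root, "d2", "2", "trial_001", "target.png")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  tr <- read_trial(file.path(root, "d1", "2", "trial_001"))
  direct <- generate_trial(`$<-`(cfg, "n_freq", 2L),
                           seed = m1$trials[[1]]$seed)
  expect_identical(unclass(tr$target), unclass(direct$target))
  expect_identical(unclass(tr$mask), unclass(direct$mask))
})

test_that("training is order-independent and cancels on identical classes", {
  set.seed(50)
  bank <- filter_bank(filter_params())
  cfg <- small_cfg()
  imgs <- lapply(1:3, function(i) generate_image(cfg, "target"))
  fields <- lapply(imgs, orientation_field, bank = bank)

  acc <- function(order) {
    st <- pair_stats(bank$n_orient, 12L, "target")
    for (i in order) st <- accumulate_pair_stats(st, fields[[i]])
    st
  }
  expect_identical(acc(1:3)$counts, acc(c(3, 1, 2))$counts)

  # same image set as both classes: exact cancellation
  st <- acc(1:3)
  std <- st; std$class_label <- "distractor"
  k <- odd_kernel(st, std, strength = 5)
  expect_true(all(abs(k$canonical) < 1e-12))
})

test_that("trial evaluation yields the documented table layout", {
  bank <- filter_bank(filter_params())
  kb <- bowtie_kernel(bowtie_params(strength = 20), R = 12L,
                      n_orient = bank$n_orient,
                      angle_offset = bank$angle_offset)
  cfg <- small_cfg()
  res <- evaluate_kernel(kb, cfg, bank, nf_list = c(2L, 4L), n_trials = 4L,
                         n_iterations = 2L, seed = 3L)
  expect_identical(nrow(res), 2L * (2L + 1L))
  expect_true(all(res$iteration[res$n_freq == 2] == 0:2))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_true(all(res$pc_se == binomial_error(res$pc, res$n_trials)))

  # iteration-0 rows are the pre-lateral baseline, identical across kernels
  kb2 <- rescale_kernel(kb, 40)
  res2 <- evaluate_kernel(kb2, cfg, bank, nf_list = c(2L, 4L), n_trials = 4L,
                          n_iterations = 2L, seed = 3L)
  expect_equal(res2$auc[res2$iteration == 0], res$auc[res$iteration == 0])

  sweep <- strength_sweep(kb, c(10, 20), cfg, bank, nf_list = 2L,
                          n_trials = 3L, n_iterations = 1L, seed = 3L)
  expect_identical(nrow(sweep), 2L * 2L)
  expect_identical(unique(sweep$strength), c(10, 20))
})

test_that("trial tables are deterministic under a fixed seed", {
  bank <- filter_bank(filter_params())
  kb <- bowtie_kernel(bowtie_params(strength = 20), R = 12L,
                      n_orient = bank$n_orient,
                      angle_offset = bank$angle_offset)
  cfg <- small_cfg()
  t1 <- run_2afc_trials(kb, cfg, bank, n_trials = 3L, n_iterations = 1L,
                        seed = 7L)
  t2 <- run_2afc_trials(kb, cfg, bank, n_trials = 3L, n_iterations = 1L,
                        seed = 7L)
  expect_identical(t1, t2)
  expect_identical(t1$psi_left[t1$target_side == "left"],
                   t1$psi_target[t1$target_side == "left"])
})

test_that("experiment configurations survive a JSON round trip", {
  cfg <- experiment_config(generator = small_cfg(),
                           dynamics = dynamics_config(3L, "raw"),
                           seed = 17L)
  path <- withr::local_tempfile(fileext = ".json")
  write_experiment_config(cfg, path)
  back <- read_experiment_config(path)
  expect_equal(unclass(back$generator), unclass(cfg$generator))
  expect_identical(back$dynamics$n_iterations, 3L)
  expect_identical(back$seed, 17L)
  expect_equal(back$training$strength, cfg$training$strength)
})

test_that("autoplot methods return ggplot objects", {
  set.seed(60)
  cfg <- small_cfg()
  img <- generate_image(cfg, "target")
  expect_s3_class(autoplot(img), "ggplot")
  bank <- filter_bank(filter_params())
  expect_s3_class(autoplot(orientation_field(img, bank)), "ggplot")
  expect_s3_class(autoplot(toy_kernel()), "ggplot")
  trials <- tibble::tibble(signal = rnorm(40),
                           target_side = rep(c("left", "right"), 20))
  expect_s3_class(autoplot(roc_curve(trials)), "ggplot")
  fit <- fit_psychometric(0:5, psychometric_fun(0:5, 1.2, 0.9),
                          asymptote = 0.9)
  expect_s3_class(autoplot(fit), "ggplot")
  res <- tibble::tibble(n_freq = 2L, iteration = 0:2,
                        auc = c(0.5, 0.7, 0.8), pc = c(0.5, 0.7, 0.8),
                        pc_se = 0.05, n_trials = 10L)
  expect_s3_class(plot_evaluation(res), "ggplot")
})
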