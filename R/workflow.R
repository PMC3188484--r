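# End-to-end pipelines: generate -> train -> relax -> evaluate -> fit.

#' Generate a single image of one class
#'
#' Cheaper than [generate_trial()] when only one class is needed (e.g. while
#' accumulating training statistics).
#'
#' @param cfg an [amoeba_config()].
#' @param type `"target"`, `"distractor"` or `"mask"`.
#' @return a `binary_image`.
#' @export
generate_image <- function(cfg, type = c("target", "distractor", "mask")) {
  type <- match.arg(type)
  n <- switch(type,
              target = 1L + cfg$n_clutter_target,
              distractor = cfg$n_sets_distractor,
              mask = cfg$n_sets_mask)
  amoebas <- lapply(seq_len(n), function(i) {
    fragment_contour(sample_amoeba_profile(cfg), cfg)
  })
  sets <- if (type == "target") {
    c(list(amoeba_set(amoebas[[1]])),
      lapply(amoebas[-1], make_clutter, cfg = cfg))
  } else {
    lapply(amoebas, make_clutter, cfg = cfg)
  }
  rasterize(sets, cfg$image_size)
}

#' Train an ODD kernel from synthetic images
#'
#' Generates target and distractor images on the fly (complexities cycled
#' round-robin through `nf_list`), accumulates suprathreshold pair
#' statistics for each class, and builds the normalized difference kernel.
#' Training is order independent: statistics are sums over images.
#'
#' @param n_target,n_distractor training set sizes per class.
#' @param gen_cfg an [amoeba_config()] (its `n_freq` is overridden by
#'   `nf_list`).
#' @param bank a [filter_bank()].
#' @param nf_list radial-frequency counts cycled over the training images.
#' @param R pair-statistics cutoff radius, pixels (must be below a quarter
#'   of the image size).
#' @param strength total ODD strength `S`.
#' @param weighted activity-weighted accumulation (default: count).
#' @param seed optional integer; seeds image generation.
#' @param keep_stats attach the two accumulated [pair_stats()] to the kernel.
#' @return a `lateral_kernel` of kind `"odd"`.
#' @export
train_odd_kernel <- function(n_target = 200L, n_distractor = 200L,
                             gen_cfg = amoeba_config(),
                             bank = filter_bank(),
                             nf_list = c(2L, 4L, 6L, 8L),
                             R = 63L, strength = 2000, weighted = FALSE,
                             seed = NULL, keep_stats = FALSE) {
  stopifnot(R < gen_cfg$image_size / 4)
  if (!is.null(seed)) set.seed(substream_seed(seed, "train"))
  stats_t <- pair_stats(bank$n_orient, R, "target", weighted)
  stats_d <- pair_stats(bank$n_orient, R, "distractor", weighted)
  for (i in seq_len(n_target)) {
    cfg_i <- gen_cfg
    cfg_i$n_freq <- as.integer(nf_list[(i - 1L) %% length(nf_list) + 1L])
    img <- generate_image(cfg_i, "target")
    stats_t <- accumulate_pair_stats(stats_t, orientation_field(img, bank))
  }
  for (i in seq_len(n_distractor)) {
    cfg_i <- gen_cfg
    cfg_i$n_freq <- as.integer(nf_list[(i - 1L) %% length(nf_list) + 1L])
    img <- generate_image(cfg_i, "distractor")
    stats_d <- accumulate_pair_stats(stats_d, orientation_field(img, bank))
  }
  attr(stats_t, "angle_offset") <- bank$angle_offset
  k <- odd_kernel(stats_t, stats_d, strength = strength)
  k$angle_offset <- bank$angle_offset
  k$meta$nf_list <- nf_list
  if (keep_stats) {
    k$meta$target_stats <- stats_t
    k$meta$distractor_stats <- stats_d
  }
  k
}

#' Run 2AFC trials through the relaxation dynamics
#'
#' Each trial pairs an independent target and distractor image at the given
#' complexity, runs both through the front end and `n_iterations` of the
#' lateral dynamics, and records the total activity of each image at every
#' iteration (iteration 0 = bottom-up responses before any lateral
#' interaction). The target is placed left or right with equal probability.
#'
#' @param kernel a `lateral_kernel`.
#' @param gen_cfg an [amoeba_config()]; `n_freq` is taken from here.
#' @param bank a [filter_bank()].
#' @param n_trials number of trials.
#' @param n_iterations lateral-interaction iterations.
#' @param support_mode see [lateral_support()].
#' @param seed optional integer seed.
#' @return tibble with columns `trial`, `iteration`, `n_freq`,
#'   `psi_target`, `psi_distractor`, `target_side`, `psi_left`, `psi_right`.
#' @export
run_2afc_trials <- function(kernel, gen_cfg = amoeba_config(),
                            bank = filter_bank(), n_trials = 100L,
                            n_iterations = 8L,
                            support_mode = c("raw", "offset"),
                            seed = NULL) {
  support_mode <- match.arg(support_mode)
  if (!is.null(seed)) set.seed(substream_seed(seed, "trials"))
  cfg_dyn <- dynamics_config(n_iterations, support_mode)
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    t_img <- generate_image(gen_cfg, "target")
    d_img <- generate_image(gen_cfg, "distractor")
    side <- if (runif(1) < 0.5) "left" else "right"
    run_t <- lateral_iterate(orientation_field(t_img, bank), kernel,
                             cfg_dyn, keep_fields = FALSE)
    run_d <- lateral_iterate(orientation_field(d_img, bank), kernel,
                             cfg_dyn, keep_fields = FALSE)
    rows[[i]] <- tibble::tibble(
      trial = i,
      iteration = 0:n_iterations,
      n_freq = gen_cfg$n_freq,
      psi_target = unname(run_t$psi),
      psi_distractor = unname(run_d$psi),
      target_side = side
    )
  }
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out,
    psi_left = ifelse(.data$target_side == "left",
                      .data$psi_target, .data$psi_distractor),
    psi_right = ifelse(.data$target_side == "left",
                       .data$psi_distractor, .data$psi_target))
}

#' Evaluate a kernel on the 2AFC task
#'
#' Runs [run_2afc_trials()] for each complexity in `nf_list` and summarizes
#' performance per iteration: ROC AUC (100 equally spaced thresholds by
#' default), percent correct, and its binomial standard error.
#'
#' @inheritParams run_2afc_trials
#' @param nf_list complexities to evaluate.
#' @param n_thresholds ROC threshold count.
#' @return tibble with columns `n_freq`, `iteration`, `auc`, `pc`, `pc_se`,
#'   `n_trials`.
#' @export
evaluate_kernel <- function(kernel, gen_cfg = amoeba_config(),
                            bank = filter_bank(),
                            nf_list = c(2L, 4L, 6L, 8L),
                            n_trials = 100L, n_iterations = 8L,
                            n_thresholds = 100L,
                            support_mode = c("raw", "offset"),
                            seed = NULL) {
  support_mode <- match.arg(support_mode)
  out <- vector("list", length(nf_list))
  for (j in seq_along(nf_list)) {
    cfg_j <- gen_cfg
    cfg_j$n_freq <- as.integer(nf_list[j])
    trials <- run_2afc_trials(
      kernel, cfg_j, bank, n_trials, n_iterations, support_mode,
      seed = if (is.null(seed)) NULL else substream_seed(seed, "eval", j)
    )
    out[[j]] <- summarize_trials(trials, n_thresholds,
                                 seed = if (is.null(seed)) NULL else
                                   substream_seed(seed, "ties", j))
  }
  dplyr::bind_rows(out)
}

#' Summarize per-iteration 2AFC performance
#'
#' @param trials output of [run_2afc_trials()].
#' @param n_thresholds ROC threshold count.
#' @param seed tie-breaking seed for percent correct.
#' @return tibble (`n_freq`, `iteration`, `auc`, `pc`, `pc_se`, `n_trials`).
#' @export
summarize_trials <- function(trials, n_thresholds = 100L, seed = NULL) {
  trials |>
    dplyr::group_by(.data$n_freq, .data$iteration) |>
    dplyr::group_modify(function(df, key) {
      scored <- classify_2afc(df, seed = seed)
      roc <- roc_curve(scored, n_thresholds = n_thresholds)
      pc <- mean(scored$correct)
      tibble::tibble(auc = attr(roc, "auc"), pc = pc,
                     pc_se = binomial_error(pc, nrow(df)),
                     n_trials = nrow(df))
    }) |>
    dplyr::ungroup()
}

#' Sweep kernel strength
#'
#' Re-evaluates a kernel at several total strengths (entries are linear in
#' strength, so no retraining is needed) — the robustness experiment.
#'
#' @inheritParams evaluate_kernel
#' @param strengths numeric vector of total strengths.
#' @return tibble like [evaluate_kernel()] with a `strength` column.
#' @export
strength_sweep <- function(kernel, strengths, gen_cfg = amoeba_config(),
                           bank = filter_bank(), nf_list = 2L,
                           n_trials = 50L, n_iterations = 4L,
                           n_thresholds = 100L, seed = NULL) {
  purrr::map_dfr(strengths, function(s) {
    res <- evaluate_kernel(rescale_kernel(kernel, s), gen_cfg, bank,
                           nf_list, n_trials, n_iterations, n_thresholds,
                           seed = seed)
    dplyr::mutate(res, strength = s, .before = 1)
  })
}
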