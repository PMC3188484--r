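# On-disk datasets: PNG stimuli + JSON manifest, and experiment configs.

#' Write an amoeba/no-amoeba dataset to disk
#'
#' Layout: `<root>/<n_freq>/trial_<i>/{target,distractor,mask}.png`
#' (8-bit grayscale, ON = 255), plus `<root>/manifest.json` echoing the
#' configuration, seeds and per-trial composition. Deterministic under
#' (config, seed).
#'
#' @param cfg an [amoeba_config()] (`n_freq` overridden per set).
#' @param root output directory (created if missing).
#' @param n_trials trials per complexity.
#' @param nf_list complexities to generate.
#' @param seed integer master seed.
#' @param force overwrite an existing manifest.
#' @return the manifest, invisibly.
#' @export
generate_dataset <- function(cfg = amoeba_config(), root, n_trials = 10L,
                             nf_list = c(2L, 4L, 6L, 8L), seed = 1L,
                             force = FALSE) {
  manifest_path <- file.path(root, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    stop("dataset already exists at ", root, " (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  trials <- list()
  for (nf in nf_list) {
    cfg_nf <- cfg
    cfg_nf$n_freq <- as.integer(nf)
    for (i in seq_len(n_trials)) {
      trial_seed <- substream_seed(seed, paste0("gen", nf), i)
      tr <- generate_trial(cfg_nf, seed = trial_seed)
      dir_i <- file.path(root, nf, sprintf("trial_%03d", i))
      dir.create(dir_i, recursive = TRUE, showWarnings = FALSE)
      for (nm in c("target", "distractor", "mask")) {
        png::writePNG(matrix(as.numeric(tr[[nm]]), nrow(tr[[nm]])),
                      file.path(dir_i, paste0(nm, ".png")))
      }
      trials[[length(trials) + 1L]] <-
        c(list(dir = file.path(nf, sprintf("trial_%03d", i)),
               trial = i, seed = trial_seed),
          as.list(tr$manifest[, c("n_freq", "n_sets_target",
                                  "n_sets_distractor", "n_sets_mask")]))
    }
  }
  manifest <- list(config = unclass(cfg), seed = seed, nf_list = nf_list,
                   n_trials = n_trials, trials = trials)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read one trial from a dataset directory
#'
#' @param dir a `trial_*` directory written by [generate_dataset()].
#' @return list of `target`, `distractor`, `mask` binary images.
#' @export
read_trial <- function(dir) {
  read1 <- function(nm) {
    m <- png::readPNG(file.path(dir, paste0(nm, ".png")))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    img <- matrix(as.integer(m > 0.5), nrow(m))
    class(img) <- c("binary_image", class(img))
    img
  }
  list(target = read1("target"), distractor = read1("distractor"),
       mask = read1("mask"))
}

#' Serialize / restore an orientation field
#'
#' @param field an `orientation_field`.
#' @param path file path (`.rds`).
#' @return `path` invisibly (`write`) or the field (`read`).
#' @export
write_field <- function(field, path) {
  saveRDS(field, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  readRDS(path)
}

#' Assemble a full experiment configuration
#'
#' Bundles every tunable of the pipeline into one JSON-serializable object,
#' so published parameter values can be dropped in without code changes.
#'
#' @param generator an [amoeba_config()].
#' @param filters a [filter_params()].
#' @param training list: `n_target`, `n_distractor`, `R`, `strength`,
#'   `weighted`.
#' @param dynamics a [dynamics_config()].
#' @param evaluation list: `n_trials`, `n_thresholds`, `nf_list`.
#' @param seed master seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(generator = amoeba_config(),
                              filters = filter_params(),
                              training = list(n_target = 200L,
                                              n_distractor = 200L,
                                              R = 63L, strength = 2000,
                                              weighted = FALSE),
                              dynamics = dynamics_config(),
                              evaluation = list(n_trials = 100L,
                                                n_thresholds = 100L,
                                                nf_list = c(2L, 4L, 6L, 8L)),
                              seed = 1L) {
  stopifnot(inherits(generator, "amoeba_config"),
            inherits(filters, "filter_params"),
            inherits(dynamics, "dynamics_config"),
            is.numeric(seed))
  structure(list(generator = generator, filters = filters,
                 training = training, dynamics = dynamics,
                 evaluation = evaluation, seed = as.integer(seed)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path JSON file path.
#' @export
write_experiment_config <- function(x, path) {
  stopifnot(inherits(x, "experiment_config"))
  jsonlite::write_json(lapply(x, unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_config(
    generator = do.call(amoeba_config, raw$generator),
    filters = do.call(filter_params, raw$filters),
    training = raw$training,
    dynamics = dynamics_config(raw$dynamics$n_iterations,
                               raw$dynamics$support_mode),
    evaluation = raw$evaluation,
    seed = raw$seed
  )
}

#' Run the full pipeline
#'
#' Train an ODD kernel, evaluate it across complexities and iterations, fit
#' the psychometric function per complexity (asymptote pinned to the final
#' measured AUC, onset at iteration 0), and optionally write results
#' (kernel RDS, metrics CSV, fits JSON) under `output_root`.
#'
#' @param config an [experiment_config()].
#' @param output_root optional output directory.
#' @param kernel_kind `"odd"` or `"bowtie"`.
#' @return list: `kernel`, `results` (tibble), `fits` (named list of
#'   [fit_psychometric()] objects).
#' @export
run_experiment <- function(config = experiment_config(), output_root = NULL,
                           kernel_kind = c("odd", "bowtie")) {
  kernel_kind <- match.arg(kernel_kind)
  bank <- filter_bank(config$filters)
  kernel <- if (kernel_kind == "odd") {
    train_odd_kernel(
      n_target = config$training$n_target,
      n_distractor = config$training$n_distractor,
      gen_cfg = config$generator, bank = bank,
      nf_list = config$evaluation$nf_list,
      R = config$training$R, strength = config$training$strength,
      weighted = isTRUE(config$training$weighted),
      seed = config$seed
    )
  } else {
    bowtie_kernel(bowtie_params(strength = config$training$strength),
                  R = config$training$R, n_orient = bank$n_orient,
                  angle_offset = bank$angle_offset)
  }
  results <- evaluate_kernel(
    kernel, config$generator, bank,
    nf_list = config$evaluation$nf_list,
    n_trials = config$evaluation$n_trials,
    n_iterations = config$dynamics$n_iterations,
    n_thresholds = config$evaluation$n_thresholds,
    support_mode = config$dynamics$support_mode,
    seed = config$seed
  )
  fits <- lapply(split(results, results$n_freq), function(df) {
    df <- df[order(df$iteration), ]
    fit_psychometric(df$iteration, df$auc,
                     asymptote = df$auc[nrow(df)], onset = 0)
  })
  if (!is.null(output_root)) {
    dir.create(output_root, recursive = TRUE, showWarnings = FALSE)
    write_kernel(kernel, file.path(output_root, "kernel.rds"))
    utils::write.csv(results, file.path(output_root, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(fits, glance),
                         file.path(output_root, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(kernel = kernel, results = results, fits = fits)
}
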