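# 2AFC scoring, ROC/AUC analysis and chance-anchored psychometric fits.
# This layer is tabular: trials in, tibbles out.

#' Classify 2AFC trials from total activity
#'
#' The side with the larger total activity is reported as the target; the
#' absolute activity difference serves as confidence. Exact ties are broken
#' by a fair coin (seeded for reproducibility).
#'
#' @param trials a data frame with numeric `psi_left`, `psi_right` and
#'   `target_side` (`"left"`/`"right"`).
#' @param seed optional integer seed for tie-breaking.
#' @return the input as a tibble with `signal` (`psi_left - psi_right`),
#'   `choice`, `confidence` and `correct` columns added.
#' @export
classify_2afc <- function(trials, seed = NULL) {
  stopifnot(all(c("psi_left", "psi_right", "target_side") %in% names(trials)))
  if (!is.null(seed)) set.seed(seed)
  trials <- tibble::as_tibble(trials)
  signal <- trials$psi_left - trials$psi_right
  coin <- ifelse(rbinom(nrow(trials), 1L, 0.5) == 1L, "left", "right")
  choice <- dplyr::case_when(signal > 0 ~ "left",
                             signal < 0 ~ "right",
                             TRUE ~ coin)
  dplyr::mutate(trials,
                signal = signal,
                choice = choice,
                confidence = abs(signal),
                correct = choice == .data$target_side)
}

#' ROC curve from 2AFC trial signals
#'
#' Sweeps a confidence threshold over the signed signal
#' (`psi_left - psi_right`): the true positive rate at threshold `c` is the
#' proportion of target-left trials with `signal > c`, the false positive
#' rate the proportion of target-right trials with `signal > c` (ties at the
#' threshold count as "not above"). Thresholds are either `n_thresholds`
#' equally spaced values spanning the signal range, or placed at the data
#' values themselves (`thresholds = "data"`), which reproduces the
#' Mann-Whitney pair probability exactly. The AUC is the trapezoid area with
#' endpoints (0,0) and (1,1) appended, and estimates the probability that a
#' random target image outscores a random distractor image.
#'
#' @param trials data frame with `signal` and `target_side` columns
#'   (e.g. from [classify_2afc()]).
#' @param n_thresholds number of equally spaced thresholds.
#' @param thresholds `"equal"` or `"data"`.
#' @return object of class `roc_curve`: a tibble of (threshold, fpr, tpr)
#'   with attributes `auc` and `n_trials`.
#' @export
roc_curve <- function(trials, n_thresholds = 100L,
                      thresholds = c("equal", "data")) {
  thresholds <- match.arg(thresholds)
  stopifnot(all(c("signal", "target_side") %in% names(trials)))
  s_left <- trials$signal[trials$target_side == "left"]
  s_right <- trials$signal[trials$target_side == "right"]
  if (length(s_left) == 0L || length(s_right) == 0L) {
    stop("undefined ROC: trials must include both target sides",
         call. = FALSE)
  }
  thr <- if (thresholds == "equal") {
    rng <- range(trials$signal)
    if (rng[1] == rng[2]) rng[1] else
      seq(rng[1], rng[2], length.out = n_thresholds)
  } else {
    sort(unique(trials$signal))
  }
  tpr <- vapply(thr, function(c) mean(s_left > c), numeric(1))
  fpr <- vapply(thr, function(c) mean(s_right > c), numeric(1))

  pts <- tibble::tibble(threshold = c(Inf, thr, -Inf),
                        fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(tibble::new_tibble(pts, nrow = nrow(pts),
                               class = "roc_curve"),
            auc = auc, n_trials = nrow(trials))
}

#' @export
tidy.roc_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_trials = attr(x, "n_trials"),
                 n_points = nrow(x))
}

#' Area under a ROC curve
#'
#' @param x a `roc_curve`.
#' @return the AUC, a number in `[0, 1]`.
#' @export
auc <- function(x) {
  stopifnot(inherits(x, "roc_curve"))
  attr(x, "auc")
}

#' Binomial standard error of a proportion
#'
#' `sqrt(p * (1 - p) / n)`, on the proportion scale — the error bar used for
#' percent-correct performance estimates.
#'
#' @param p proportion in `[0, 1]`.
#' @param n number of trials.
#' @return standard error(s).
#' @export
#' @examples
#' binomial_error(0.5, 100) # 0.05
binomial_error <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1), all(n >= 1))
  sqrt(p * (1 - p) / n)
}

#' Chance-anchored saturating psychometric function
#'
#' `F(t) = 0.5 + (A - 0.5) * (1 - exp(-(t - t0) / tau))` for `t >= t0`, and
#' `F(t) = 0.5` below the onset: performance starts at chance at `t0` and
#' saturates exponentially toward the asymptote `A` with time constant
#' `tau`. The functional form is isolated here so it can be swapped in one
#' place.
#'
#' @param t time axis (SOA in ms, or lateral-interaction iterations).
#' @param tau time constant (same units as `t`).
#' @param asymptote saturation accuracy `A` in `(0.5, 1]`.
#' @param onset chance-performance onset `t0`.
#' @return accuracy values.
#' @export
psychometric_fun <- function(t, tau, asymptote, onset = 0) {
  ifelse(t >= onset,
         0.5 + (asymptote - 0.5) * (1 - exp(-(t - onset) / tau)),
         0.5)
}

#' Fit the psychometric function to accuracy data
#'
#' Least-squares fit of [psychometric_fun()] over the time constant `tau`,
#' with the asymptote either pinned (e.g. to the final measured AUC, the
#' convention used for model fits) or free. The onset is always fixed.
#' Non-monotone data are still fit; when the asymptote is indistinguishable
#' from chance or `tau` runs into the search boundary, the fit is flagged as
#' non-converged and `tau` may be infinite.
#'
#' @param x time axis values (at least 3).
#' @param auc measured accuracies (AUC) in `[0, 1]`.
#' @param asymptote a number to pin `A`, or `NULL` to fit it.
#' @param onset fixed onset `t0`.
#' @return object of class `psychometric_fit` with `tidy()`, `glance()`,
#'   `predict()` and `autoplot()` methods.
#' @export
fit_psychometric <- function(x, auc, asymptote = NULL, onset = 0) {
  stopifnot(length(x) == length(auc), length(x) >= 3L,
            all(auc >= 0 & auc <= 1))
  span <- max(max(x) - onset, 1e-6)
  lo <- log(span) - log(1e4)
  hi <- log(span) + log(1e4)
  free_a <- is.null(asymptote)

  sse <- function(tau, a) {
    sum((psychometric_fun(x, tau, a, onset) - auc)^2)
  }

  if (free_a) {
    fit <- optim(c(log(span / 2), max(mean(auc), 0.51)),
                 function(p) sse(exp(p[1]), p[2]),
                 method = "L-BFGS-B",
                 lower = c(lo, 0.5 + 1e-9), upper = c(hi, 1))
    u <- fit$par[1]; a_hat <- fit$par[2]
  } else {
    a_hat <- asymptote
    if (abs(a_hat - 0.5) < 1e-9) {
      u <- hi  # chance-level data: tau unidentifiable
    } else {
      opt <- optimize(function(u) sse(exp(u), a_hat), interval = c(lo, hi),
                      tol = 1e-11)
      u <- opt$minimum
    }
  }
  at_boundary <- (u >= hi - 1e-3) || (u <= lo + 1e-3)
  tau <- if (u >= hi - 1e-3 && abs(a_hat - 0.5) < 1e-9) Inf else exp(u)
  fitted <- psychometric_fun(x, tau, a_hat, onset)

  structure(
    list(tau = tau, asymptote = a_hat, onset = onset, chance = 0.5,
         free_asymptote = free_a,
         converged = !at_boundary && abs(a_hat - 0.5) > 1e-9,
         data = tibble::tibble(x = x, auc = auc),
         fitted = fitted, residuals = auc - fitted),
    class = "psychometric_fit"
  )
}

#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$x else newdata
  psychometric_fun(t, object$tau, object$asymptote, object$onset)
}

#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("tau", "asymptote", "onset"),
    estimate = c(x$tau, x$asymptote, x$onset),
    fixed = c(FALSE, !x$free_asymptote, TRUE)
  )
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, asymptote = x$asymptote, onset = x$onset,
                 sigma = sqrt(mean(x$residuals^2)),
                 n = nrow(x$data), converged = x$converged)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit> tau =", format(x$tau, digits = 4),
      "| asymptote =", format(x$asymptote, digits = 4),
      if (x$free_asymptote) "(free)" else "(pinned)",
      "| onset =", x$onset, "\n")
  if (!x$converged) cat("  warning: fit did not converge cleanly\n")
  invisible(x)
}
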