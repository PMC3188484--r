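# Iterative multiplicative modulation of the activity field by lateral
# support from the association-field kernel.

#' Lateral support for an activity field
#'
#' The raw support term is the linear cross-correlation of the kernel's
#' rotated instances with the surrounding activity:
#' `C(x, theta) = sum_{delta, theta'} K_theta(delta, theta' - theta) *
#' A(x + delta, theta')`, with mirror-padded borders. `"raw"` mode (the
#' default used by the relaxation dynamics) returns `C` itself: a zero-sum
#' kernel then gives randomly arranged edges near-zero — neutral — support,
#' and multiplying by it suppresses them. `"offset"` mode returns `1 + C`
#' (neutral = multiplicative identity), kept for sensitivity analysis.
#'
#' @param field an `orientation_field` (`L x L x n_orient`).
#' @param kernel a `lateral_kernel` with matching orientation count.
#' @param mode `"raw"` or `"offset"`.
#' @return `L x L x n_orient` numeric array.
#' @export
lateral_support <- function(field, kernel, mode = c("raw", "offset")) {
  mode <- match.arg(mode)
  stopifnot(inherits(kernel, "lateral_kernel"))
  d <- dim(field)
  if (length(d) != 3L || d[3] != kernel$n_orient) {
    stop("field geometry does not match kernel (orientation count)",
         call. = FALSE)
  }
  C <- lateral_support_cpp(as.array(unclass(field)), kernel$rotated)
  if (mode == "offset") C + 1 else C
}

#' Run the multiplicative relaxation dynamics
#'
#' Each iteration multiplies the previous activity by the current lateral
#' support and passes the product through the transfer function:
#' `A_{n+1} = transfer(A_n * support_n)`. The same kernel is used at every
#' iteration. Because modulation is multiplicative, no element can become
#' active that was not active in the original field (no illusory activity),
#' and activities stay in `[0, 1]`.
#'
#' @param field an initial `orientation_field` (values in `[0, 1]`).
#' @param kernel a `lateral_kernel`.
#' @param cfg a [dynamics_config()] (or an integer iteration count).
#' @param keep_fields if `FALSE`, only total activities are retained —
#'   useful when scoring many trials.
#' @return object of class `relaxation_run`: `fields` (list of arrays for
#'   iterations `0..n`, or `NULL`), `psi` (total activity per iteration,
#'   names `"0"..."n"`), `support_mode`, `n_iterations`.
#' @export
lateral_iterate <- function(field, kernel, cfg = dynamics_config(),
                            keep_fields = TRUE) {
  if (is.numeric(cfg)) cfg <- dynamics_config(n_iterations = cfg)
  stopifnot(inherits(cfg, "dynamics_config"))
  a <- as.array(unclass(field))
  psi <- numeric(cfg$n_iterations + 1L)
  psi[1] <- sum(a)
  fields <- if (keep_fields) vector("list", cfg$n_iterations + 1L)
  if (keep_fields) fields[[1]] <- a
  for (n in seq_len(cfg$n_iterations)) {
    s <- lateral_support(a, kernel, mode = cfg$support_mode)
    a <- transfer(a * s)
    psi[n + 1L] <- sum(a)
    if (keep_fields) fields[[n + 1L]] <- a
  }
  names(psi) <- as.character(0:cfg$n_iterations)
  structure(
    list(fields = fields, psi = psi,
         n_iterations = cfg$n_iterations, support_mode = cfg$support_mode),
    class = "relaxation_run"
  )
}

#' Total activity of a field
#'
#' Sum of activity over all positions and orientations — the scalar decision
#' signal of the 2AFC classifier.
#'
#' @param field an `orientation_field` or plain array.
#' @return a number.
#' @export
total_activity <- function(field) {
  sum(field)
}

#' @export
print.relaxation_run <- function(x, ...) {
  cat("<relaxation_run>", x$n_iterations, "iterations (",
      x$support_mode, "support )\n")
  cat("  total activity:", paste(format(x$psi, digits = 4), collapse = " -> "),
      "\n")
  invisible(x)
}
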