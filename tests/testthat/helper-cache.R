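# Shared fixtures. The trained kernel and its evaluations are expensive, so
# they are built once and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_bank <- function() cached("bank", filter_bank())

# ODD kernel trained under the package's study conditions: 200 + 200 images,
# complexities 2/4/6/8 cycled, default front end and geometry.
trained_kernel <- function() {
  cached("kernel",
         train_odd_kernel(n_target = 200L, n_distractor = 200L,
                          bank = default_bank(), seed = 1L))
}

eval_nf <- function(nf) {
  cached(paste0("eval_nf", nf),
         evaluate_kernel(trained_kernel(), bank = default_bank(),
                         nf_list = nf, n_trials = 100L, n_iterations = 4L,
                         seed = 1L))
}

# Small random kernel for oracle tests of the dynamics machinery.
toy_kernel <- function(R = 6L, n_orient = 4L, seed = 42L) {
  set.seed(seed)
  D <- 2L * R + 1L
  canonical <- array(rnorm(D * D * n_orient), dim = c(D, D, n_orient))
  off <- seq(-R, R)
  outside <- outer(off^2, off^2, `+`) > R^2
  for (j in seq_len(n_orient)) {
    s <- canonical[, , j]
    s[outside] <- 0
    canonical[, , j] <- s
  }
  oddfield:::new_lateral_kernel(canonical, strength = 1, R = R,
                                n_orient = n_orient, angle_offset = 0,
                                kind = "toy")
}

# Brute-force raw lateral support (mirror padding), the independent oracle.
bf_support <- function(field, kernel) {
  d <- dim(field)
  L <- d[1]; M <- d[2]; Th <- d[3]
  R <- kernel$R
  refl <- function(i, n) {
    while (i < 0 || i >= n) i <- if (i < 0) -1 - i else 2 * n - 1 - i
    i
  }
  out <- array(0, dim = d)
  for (tc in seq_len(Th)) {
    for (x in 0:(M - 1)) {
      for (y in 0:(L - 1)) {
        acc <- 0
        for (dx in -R:R) {
          for (dy in -R:R) {
            xe <- refl(x + dx, M); ye <- refl(y + dy, L)
            for (trel in 0:(Th - 1)) {
              te <- ((tc - 1 + trel) %% Th) + 1
              acc <- acc + kernel$rotated[dy + R + 1, dx + R + 1,
                                          trel + 1, tc] *
                field[ye + 1, xe + 1, te]
            }
          }
        }
        out[y + 1, x + 1, tc] <- acc
      }
    }
  }
  out
}

# Brute-force pair statistics over suprathreshold elements.
bf_pairs <- function(field, R, weighted = FALSE) {
  d <- dim(field)
  Th <- d[3]
  D <- 2L * R + 1L
  counts <- array(0, dim = c(D, D, Th, Th))
  act <- which(field > 0, arr.ind = TRUE)  # (y, x, theta)
  n <- nrow(act)
  if (n >= 2L) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        dx <- act[j, 2] - act[i, 2]
        dy <- act[j, 1] - act[i, 1]
        if (dx^2 + dy^2 > R^2) next
        trel <- ((act[j, 3] - act[i, 3]) %% Th) + 1
        w <- if (weighted) {
          field[act[i, 1], act[i, 2], act[i, 3]] *
            field[act[j, 1], act[j, 2], act[j, 3]]
        } else 1
        counts[dy + R + 1, dx + R + 1, trel, act[i, 3]] <-
          counts[dy + R + 1, dx + R + 1, trel, act[i, 3]] + w
      }
    }
  }
  counts
}

# Mann-Whitney AUC oracle: P(left > right) + 0.5 P(tie).
mw_auc <- function(s_left, s_right) {
  gt <- outer(s_left, s_right, `>`)
  eq <- outer(s_left, s_right, `==`)
  mean(gt + 0.5 * eq)
}
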