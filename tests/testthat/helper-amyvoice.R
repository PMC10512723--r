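# Shared fixture builders. Everything is generated in code; no files.

# Two Gaussian clusters separated by `delta` SD units on every informative
# column; the remaining columns are pure noise.
toy_separable <- function(n = 40L, p = 8L, informative = 1:2, delta = 3,
                          seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[y == 1L, informative] <- x[y == 1L, informative] + delta
  colnames(x) <- sprintf("v%02d", seq_len(p))
  list(x = x, y = y)
}

# A tiny cohort pair (features + cohort) for pipeline-level tests.
small_cohort <- function(seed = 1L, n = 52L, npos = 30L, effect = 0.8) {
  generate_cohort(synth_config(n_subjects = n, n_positive = npos,
                               effect_size = effect, seed = seed))
}

# Brute-force Shapley via permutation averaging: for every ordering of the
# features, accumulate each feature's marginal contribution to the
# coalition value, then average. Independent of the enumeration path.
shap_permutation_oracle <- function(score_fn, background, x) {
  M <- ncol(background)
  coalition_value <- function(idx) {
    mat <- background
    for (j in idx) mat[, j] <- x[j]
    mean(score_fn(mat))
  }
  # cache v(S) over bitmasks so the permutation loop is cheap
  v <- vapply(0:(2^M - 1), function(s) {
    coalition_value(which(bitwAnd(s, 2^(0:(M - 1))) != 0))
  }, numeric(1))
  perms <- gtools_permutations(M)
  phi <- numeric(M)
  for (r in seq_len(nrow(perms))) {
    mask <- 0L
    for (j in perms[r, ]) {
      new_mask <- bitwOr(mask, bitwShiftL(1L, j - 1L))
      phi[j] <- phi[j] + v[new_mask + 1L] - v[mask + 1L]
      mask <- new_mask
    }
  }
  phi / nrow(perms)
}

# All permutations of 1:n (small n only), no external dependency.
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

# Hand-rolled stratified k-fold KNN balanced-accuracy error, used as the
# independent oracle for subset_fitness. Mirrors the documented contract
# (training-fold z-scoring, pooled predictions) with plain loops.
fitness_oracle <- function(x, y, subset, k, folds, seed) {
  if (length(subset) == 0) return(1.0)
  xs <- x[, subset, drop = FALSE]
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  pred <- integer(length(y))
  for (f in seq_len(folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    mu <- colMeans(xs[tr, , drop = FALSE])
    sdv <- apply(xs[tr, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    ztr <- scale(xs[tr, , drop = FALSE], mu, sdv)
    zte <- scale(xs[te, , drop = FALSE], mu, sdv)
    for (i in seq_along(te)) {
      d <- sqrt(rowSums((ztr - matrix(zte[i, ], nrow(ztr), ncol(ztr),
                                      byrow = TRUE))^2))
      nb <- order(d)[seq_len(min(k, length(d)))]
      pred[te[i]] <- as.integer(mean(y[tr][nb] == 1L) >= 0.5)
    }
  }
  sens <- mean(pred[y == 1L] == 1L)
  spec <- mean(pred[y == 0L] == 0L)
  1 - (sens + spec) / 2
}

# Fresh temp file path (cleaned with the session tempdir).
withr_local_tempfile <- function() tempfile(fileext = ".csv")
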