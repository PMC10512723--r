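# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All exported stochastic entry points go
# through this so that library users' RNG streams are never clobbered.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed derived from a master seed; kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647)
}

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    abort_field(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    abort_field(field, sprintf(
      "must be a single number in %s%s, %s%s",
      if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]"
    ))
  }
  as.double(x)
}

# Pairwise Euclidean distances between the rows of two matrices,
# computed without loops (cross-product expansion).
euclidean_cross <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Vectorized column standard deviations (denominator n - 1).
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  v <- (colSums(x * x) - n * mu^2) / (n - 1)
  v[v < 0] <- 0  # guard tiny negative round-off
  sqrt(v)
}

# Column-wise z-scoring with training statistics; zero-variance columns get
# unit scale so they standardize to a constant instead of NaN.
zscore_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- col_sds(x)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(center = mu, scale = sdv)
}

zscore_apply <- function(x, stats) {
  x <- sweep(x, 2, stats$center, "-")
  sweep(x, 2, stats$scale, "/")
}

# Stratified fold assignment: shuffles within each class, then deals folds
# round-robin so class balance is preserved as closely as possible.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
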