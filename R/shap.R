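#' Exact Shapley attribution of one prediction
#'
#' Computes, by full coalition enumeration, the Shapley decomposition of a
#' model score for one subject against a background set. The value of a
#' coalition `S` is the interventional marginal expectation: the mean
#' score over the background rows with the features in `S` replaced by the
#' subject's values. The attribution of feature `j` is the Shapley-weighted
#' average of its marginal contributions
#' `sum over S excluding j of |S|! (M - |S| - 1)! / M! * (v(S + j) - v(S))`,
#' and `v(empty) ` is the base value. Enumeration is guarded at 20
#' features (2^20 coalitions).
#'
#' @param score_fn Function taking a numeric matrix (rows = subjects with
#'   the background's columns) and returning a numeric score per row.
#' @param background Numeric matrix of background rows (nonempty).
#' @param x Numeric vector (or 1-row matrix) of the subject's features.
#' @return An object of class `amy_shap`: a list with `base_value`,
#'   `attributions` (named per feature), `score`, and `subject` (`NA`
#'   unless set by the caller).
#' @export
exact_shap <- function(score_fn, background, x) {
  background <- as.matrix(background)
  x <- as.numeric(x)
  M <- ncol(background)
  if (length(x) != M) stop("`x` must match the background's columns",
                           call. = FALSE)
  if (nrow(background) == 0L) stop("background must be nonempty", call. = FALSE)
  if (M > 20L) {
    stop("more than 20 features: reduce the feature set before exact ",
         "Shapley enumeration", call. = FALSE)
  }
  nb <- nrow(background)
  n_coal <- bitwShiftL(1L, M)

  # v(S) for every coalition, encoded as a bitmask over features
  v <- numeric(n_coal)
  for (s in 0:(n_coal - 1L)) {
    mat <- background
    for (j in seq_len(M)) {
      if (bitwAnd(s, bitwShiftL(1L, j - 1L)) != 0L) mat[, j] <- x[j]
    }
    v[s + 1L] <- mean(score_fn(mat))
  }

  sizes <- vapply(0:(n_coal - 1L), function(s) sum(bitwAnd(
    s, bitwShiftL(1L, 0:(M - 1L))) != 0L), numeric(1))
  # weight is only used for coalitions excluding some feature (|S| < M)
  wt <- ifelse(sizes < M,
               factorial(sizes) * factorial(pmax(M - sizes - 1, 0)) /
                 factorial(M),
               0)

  phi <- numeric(M)
  for (j in seq_len(M)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(n_coal - 1L), bit) == 0L)  # 1-based
    s <- without - 1L
    phi[j] <- sum(wt[without] * (v[bitwOr(s, bit) + 1L] - v[without]))
  }
  names(phi) <- colnames(background)

  structure(
    list(base_value = v[1L], attributions = phi,
         score = v[n_coal], subject = NA_character_),
    class = "amy_shap"
  )
}

#' @export
print.amy_shap <- function(x, ...) {
  cat(sprintf("<amy_shap> base %.4f -> score %.4f\n", x$base_value, x$score))
  print(round(sort(x$attributions, decreasing = TRUE), 4))
  invisible(x)
}

#' Explain all held-out predictions of a cohort
#'
#' For every subject, fits the model on the remaining `n - 1` subjects
#' (leave-one-out), uses that training fold as the Shapley background, and
#' decomposes the held-out positive-class score with [exact_shap()].
#' Global importance is the mean absolute attribution per feature in
#' descending order; the direction summary is the Pearson correlation
#' between each feature's values and its attributions (positive:
#' high feature values push toward amyloid positivity).
#'
#' @param spec A [model_spec()].
#' @param x Numeric matrix restricted to the selected features (at most
#'   20 columns).
#' @param y Binary labels.
#' @param selected Feature names (defaults to `colnames(x)`).
#' @param seed Master seed for per-fold model fitting.
#' @return An object of class `amy_explanation`: list with
#'   `explanations` (one `amy_shap` per subject), `attributions`
#'   (subjects x features matrix), `importance` (named, descending mean
#'   absolute attribution), `direction` (named correlations), `seed`.
#' @export
explain_cohort <- function(spec, x, y, selected = colnames(x), seed = 1L) {
  x <- as.matrix(x)
  if (!is.null(selected)) {
    if (!is.null(colnames(x)) && all(selected %in% colnames(x))) {
      x <- x[, selected, drop = FALSE]
    }
  }
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  y <- as.integer(y)
  n <- nrow(x)
  M <- ncol(x)
  if (M > 20L) stop("at most 20 selected features", call. = FALSE)
  attr_mat <- matrix(NA_real_, n, M, dimnames = list(rownames(x),
                                                     colnames(x)))
  explanations <- vector("list", n)
  for (i in seq_len(n)) {
    spec_i <- spec
    spec_i$seed <- derive_seed(seed, i)
    m <- fit_model(spec_i, x[-i, , drop = FALSE], y[-i])
    fn <- function(mat) {
      colnames(mat) <- colnames(x)
      predict_model(m, mat)$score
    }
    ex <- exact_shap(fn, x[-i, , drop = FALSE], x[i, ])
    ex$subject <- if (!is.null(rownames(x))) rownames(x)[i] else
      as.character(i)
    explanations[[i]] <- ex
    attr_mat[i, ] <- ex$attributions
  }
  importance <- sort(colMeans(abs(attr_mat)), decreasing = TRUE)
  direction <- vapply(seq_len(M), function(j) {
    if (stats::sd(x[, j]) == 0 || stats::sd(attr_mat[, j]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[, j], attr_mat[, j])
  }, numeric(1))
  names(direction) <- colnames(x)
  structure(
    list(explanations = explanations, attributions = attr_mat,
         importance = importance, direction = direction, seed = seed),
    class = "amy_explanation"
  )
}

#' @export
print.amy_explanation <- function(x, ...) {
  cat(sprintf("<amy_explanation> %d subjects, %d features\n",
              nrow(x$attributions), ncol(x$attributions)))
  cat("importance (mean |attribution|):\n")
  print(round(x$importance, 4))
  invisible(x)
}
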