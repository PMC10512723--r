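#' Classification metrics from pooled held-out predictions
#'
#' Accuracy, precision, recall, F1 (harmonic mean, positive class), and
#' AUC computed as the Mann-Whitney statistic on the positive-class scores
#' with midrank handling of ties. When no positives are predicted,
#' precision is reported as 0 with a warning (and F1 follows as 0).
#'
#' @param truth Binary true labels (1 = positive); both classes required.
#' @param label Predicted binary labels.
#' @param score Positive-class scores in `[0,1]`.
#' @return Named numeric vector: `accuracy`, `precision`, `recall`, `f1`,
#'   `auc`.
#' @export
compute_metrics <- function(truth, label, score) {
  truth <- as.integer(truth)
  label <- as.integer(label)
  if (length(unique(truth)) < 2L) {
    stop("both classes must be present among the true labels", call. = FALSE)
  }
  tp <- sum(truth == 1L & label == 1L)
  tn <- sum(truth == 0L & label == 0L)
  fp <- sum(truth == 0L & label == 1L)
  fn <- sum(truth == 1L & label == 0L)
  accuracy <- (tp + tn) / length(truth)
  if (tp + fp == 0L) {
    warning("no predicted positives; precision reported as 0")
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  # Mann-Whitney AUC with midranks
  r <- rank(score)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  auc <- (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  c(accuracy = accuracy, precision = precision, recall = recall,
    f1 = f1, auc = auc)
}

#' Leave-one-out cross-validation
#'
#' For each subject, fits the model on the remaining `n - 1` subjects and
#' predicts the held-out one. Per-fold model seeds are derived
#' deterministically from `seed`.
#'
#' @param spec A [model_spec()].
#' @param x Numeric matrix (subjects x features).
#' @param y Binary labels; both classes present, `n >= 3`.
#' @param seed Master seed.
#' @return A data.frame (class `amy_predictions`) with columns
#'   `subject`, `truth`, `label`, `score`.
#' @export
loocv <- function(spec, x, y, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  out <- data.frame(subject = if (!is.null(rownames(x))) rownames(x) else
    as.character(seq_len(n)),
    truth = y, label = NA_integer_, score = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      stop("training fold contains a single class", call. = FALSE)
    }
    spec_i <- spec
    spec_i$seed <- derive_seed(seed, i)
    m <- fit_model(spec_i, x[-i, , drop = FALSE], ytr)
    p <- predict_model(m, x[i, , drop = FALSE])
    out$label[i] <- p$label
    out$score[i] <- p$score
  }
  class(out) <- c("amy_predictions", "data.frame")
  out
}

#' Bootstrap-nested leave-one-out cross-validation
#'
#' The full goodness-of-fit scheme: in each of `B` iterations, every
#' subject is predicted by a model fitted on a with-replacement resample
#' (of size `n - 1`, redrawn until both classes are present) of the other
#' `n - 1` subjects; the `n` pooled predictions of the iteration yield one
#' vector of metrics, and the `B` vectors form the metric distributions
#' summarized by their mean and 2.5/97.5 percentiles. Iteration seeds are
#' derived deterministically from the master seed.
#'
#' @param spec A [model_spec()].
#' @param x Numeric matrix (subjects x features).
#' @param y Binary labels.
#' @param B Bootstrap iterations. Default 5000.
#' @param seed Master seed.
#' @param resample_fn Test hook: a function `(candidates, size)` returning
#'   the training indices. The default draws with replacement; passing
#'   `function(cand, size) cand` makes the scheme collapse to plain
#'   [loocv()].
#' @return An object of class `amy_metric_dist`: a list with `samples`
#'   (B x 5 matrix), `mean`, `lo`, `hi`, `B`, `seed`, `n_redraws`.
#' @export
bootstrap_loocv <- function(spec, x, y, B = 5000L, seed = 1L,
                            resample_fn = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  B <- check_count(B, "B", 1L)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  default_resample <- is.null(resample_fn)
  if (default_resample) {
    resample_fn <- function(cand, size) sample(cand, size, replace = TRUE)
  }
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  samples <- matrix(NA_real_, B, 5L, dimnames = list(NULL, metric_names))
  n_redraws <- 0L
  for (b in seq_len(B)) {
    iter_seed <- derive_seed(seed, b)
    res <- with_local_seed(iter_seed, {
      label <- integer(n)
      score <- numeric(n)
      for (i in seq_len(n)) {
        cand <- setdiff(seq_len(n), i)
        repeat {
          tr <- resample_fn(cand, n - 1L)
          if (length(unique(y[tr])) == 2L) break
          n_redraws <- n_redraws + 1L
        }
        spec_i <- spec
        spec_i$seed <- derive_seed(iter_seed, i)
        m <- fit_model(spec_i, x[tr, , drop = FALSE], y[tr])
        p <- predict_model(m, x[i, , drop = FALSE])
        label[i] <- p$label
        score[i] <- p$score
      }
      suppressWarnings(compute_metrics(y, label, score))
    })
    samples[b, ] <- res
  }
  structure(
    list(samples = samples,
         mean = colMeans(samples),
         lo = apply(samples, 2, stats::quantile, 0.025, names = FALSE),
         hi = apply(samples, 2, stats::quantile, 0.975, names = FALSE),
         B = B, seed = seed, n_redraws = n_redraws),
    class = "amy_metric_dist"
  )
}

#' @export
print.amy_metric_dist <- function(x, ...) {
  cat(sprintf("<amy_metric_dist> B = %d\n", x$B))
  for (m in colnames(x$samples)) {
    cat(sprintf("  %-9s %s\n", m, format_metric(x, m)))
  }
  invisible(x)
}

#' Format one metric as "mean [lo-hi]"
#' @param dist An [bootstrap_loocv()] result.
#' @param metric Metric name.
#' @return Character scalar like `"0.75 [0.67-0.83]"`.
#' @export
format_metric <- function(dist, metric) {
  sprintf("%.2f [%.2f-%.2f]", dist$mean[[metric]], dist$lo[[metric]],
          dist$hi[[metric]])
}

#' Run a configured study end-to-end
#'
#' Assembles the configured feature set from a feature table and cohort
#' table, optionally runs the swarm wrapper selector on the full dataset
#' (the default, matching the single reported subset; set
#' `config$swarm_nested` via [run_study()]'s `nested_selection` for a
#' fully nested variant, which is slower and avoids the selection's
#' optimistic bias), evaluates the model by the configured scheme, and
#' returns a structured report with a formatted five-metric row.
#'
#' @param config A [run_config()].
#' @param feature_table Acoustic feature table (data.frame).
#' @param cohort_table Cohort data.frame with `amyloid_status`.
#' @param nested_selection When `TRUE`, rerun feature selection inside
#'   every training resample instead of once up front. Off by default;
#'   the up-front mode reports the selection the explanation stage also
#'   uses, at the cost of an optimistic bias in the evaluation.
#' @return List with `selection` (or `NULL`), `metrics`
#'   (`amy_metric_dist` or plain LOOCV metric vector), `predictions`
#'   (LOOCV only), `row` (named character vector `"x.xx [x.xx-x.xx]"`),
#'   `explanation` (when requested), `config`.
#' @export
run_study <- function(config, feature_table, cohort_table,
                      nested_selection = FALSE) {
  stopifnot(inherits(config, "amy_run_config"))
  design <- assemble_design(feature_table, cohort_table, config$feature_set)
  x <- design$x
  y <- design$y
  selection <- NULL
  if (config$select && !nested_selection) {
    selection <- vlpso_run(x, y, config$swarm)
    x <- x[, selection$selected_idx, drop = FALSE]
  }
  if (config$select && nested_selection) {
    warning("nested selection re-runs the swarm inside every resample; ",
            "this is slow and its selected sets vary across folds")
  }
  spec <- config$model

  if (config$evaluation == "loocv") {
    if (nested_selection && config$select) {
      pred <- nested_loocv_select(config, x, y)
    } else {
      pred <- loocv(spec, x, y, seed = config$seed)
    }
    met <- suppressWarnings(compute_metrics(pred$truth, pred$label,
                                            pred$score))
    row <- vapply(names(met), function(m) sprintf("%.2f", met[[m]]),
                  character(1))
    metrics <- met
  } else {
    if (nested_selection && config$select) {
      stop("nested selection is only supported with evaluation = 'loocv'",
           call. = FALSE)
    }
    metrics <- bootstrap_loocv(spec, x, y, B = config$n_bootstrap,
                               seed = config$seed)
    row <- vapply(colnames(metrics$samples), function(m)
      format_metric(metrics, m), character(1))
    pred <- NULL
  }

  explanation <- NULL
  if (isTRUE(config$explain)) {
    if (ncol(x) > 20L) {
      warning("explanation skipped: more than 20 active features")
    } else {
      explanation <- explain_cohort(spec, x, y,
                                    selected = colnames(x),
                                    seed = config$seed)
    }
  }
  list(selection = selection, metrics = metrics, predictions = pred,
       row = row, explanation = explanation, config = config)
}

# Fully nested LOOCV: the swarm selector is rerun on each training fold.
nested_loocv_select <- function(config, x, y) {
  n <- nrow(x)
  out <- data.frame(subject = if (!is.null(rownames(x))) rownames(x) else
    as.character(seq_len(n)),
    truth = y, label = NA_integer_, score = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sw <- config$swarm
    sw$seed <- derive_seed(config$seed, i)
    sel <- vlpso_run(x[-i, , drop = FALSE], y[-i], sw)
    spec_i <- config$model
    spec_i$seed <- derive_seed(config$seed, i)
    m <- fit_model(spec_i, x[-i, sel$selected_idx, drop = FALSE], y[-i])
    p <- predict_model(m, x[i, sel$selected_idx, drop = FALSE])
    out$label[i] <- p$label
    out$score[i] <- p$score
  }
  class(out) <- c("amy_predictions", "data.frame")
  out
}
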