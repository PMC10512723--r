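#' Classifier specification
#'
#' One fit/predict contract over the classifier families used for amyloid
#' prediction: elastic net and random forest on the raw (standardized)
#' features, PCA-preceded elastic net / logistic regression / SVM / KNN,
#' and plain KNN (the classifier paired with the swarm wrapper selector).
#'
#' @param family One of `"elastic_net"`, `"random_forest"`,
#'   `"pca_elastic_net"`, `"pca_logistic"`, `"pca_svm"`, `"pca_knn"`,
#'   `"knn"`.
#' @param pca_components Retained principal components for `pca_*`
#'   families. Default 9.
#' @param hyperparameters Family-specific list. Elastic net: `alpha`
#'   (mixing, default 0.5), `lambda` (fixed penalty; when absent a
#'   20-point logarithmic grid is searched by seeded 5-fold CV),
#'   `nlambda` (default 20), `cv_folds` (default 5). Random forest:
#'   `ntree` (default 500), `mtry` (default `floor(sqrt(p))`),
#'   `max_depth` (default 25). SVM: `gamma` (RBF width, default
#'   `1/n_features` on the standardized scale), `lambda` (regularization,
#'   default `1/n`), `epochs` (default 50). KNN: `k` (default 5).
#' @param seed Integer seed for all fitting randomness.
#' @return An object of class `amy_model_spec`.
#' @export
model_spec <- function(family = c("knn", "elastic_net", "random_forest",
                                  "pca_elastic_net", "pca_logistic",
                                  "pca_svm", "pca_knn"),
                       pca_components = 9L,
                       hyperparameters = list(),
                       seed = 1L) {
  family <- match.arg(family)
  pca_components <- check_count(pca_components, "pca_components", 1L)
  seed <- check_count(seed, "seed", 0L)
  stopifnot(is.list(hyperparameters))
  structure(
    list(family = family, pca_components = pca_components,
         hyperparameters = hyperparameters, seed = seed),
    class = "amy_model_spec"
  )
}

hp <- function(spec, name, default) {
  v <- spec$hyperparameters[[name]]
  if (is.null(v)) default else v
}

uses_pca <- function(family) startsWith(family, "pca_")

#' Fit a classifier
#'
#' Standardizes columns with training statistics (zero-variance columns
#' are dropped with a warning and recorded), optionally projects onto the
#' leading principal components of the standardized training data, and
#' fits the family's classifier. All preprocessing parameters are frozen
#' from the training rows only.
#'
#' @param spec A [model_spec()].
#' @param x Numeric training matrix (subjects x features).
#' @param y Binary labels (1 = positive); both classes must be present.
#' @return An object of class `amy_model`.
#' @export
fit_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "amy_model_spec"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present in y", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  # missing values: mean imputation from the training rows only
  impute <- colMeans(x, na.rm = TRUE)
  if (anyNA(x)) {
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- impute[na_idx[, 2L]]
  }
  sdv <- col_sds(x)
  keep <- which(is.finite(sdv) & sdv > 0)
  if (length(keep) < ncol(x)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[-keep], collapse = ", "))
  }
  if (length(keep) == 0L) stop("no non-degenerate columns", call. = FALSE)
  xk <- x[, keep, drop = FALSE]
  zs <- zscore_fit(xk)
  z <- zscore_apply(xk, zs)

  pca <- NULL
  if (uses_pca(spec$family)) {
    kmax <- min(nrow(z) - 1L, ncol(z))
    if (spec$pca_components > kmax) {
      stop(sprintf("pca_components = %d exceeds min(n - 1, p) = %d",
                   spec$pca_components, kmax), call. = FALSE)
    }
    pr <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    pca <- list(rotation = pr$rotation[, seq_len(spec$pca_components),
                                       drop = FALSE],
                sdev = pr$sdev[seq_len(spec$pca_components)])
    z <- z %*% pca$rotation
  }

  fitted <- with_local_seed(spec$seed, switch(
    spec$family,
    elastic_net = ,
    pca_elastic_net = fit_elastic_net(spec, z, y),
    random_forest = fit_random_forest(spec, z, y),
    pca_logistic = fit_logistic(z, y),
    pca_svm = fit_rbf_svm(spec, z, y),
    knn = ,
    pca_knn = list(train_x = z, train_y = y, k = hp(spec, "k", 5L))
  ))

  structure(
    list(spec = spec, feature_names = colnames(x), keep = keep,
         impute = impute, zstats = zs, pca = pca, fitted = fitted,
         prevalence = mean(y == 1L)),
    class = "amy_model"
  )
}

fit_elastic_net <- function(spec, z, y) {
  alpha <- hp(spec, "alpha", 0.5)
  lambda <- hp(spec, "lambda", NULL)
  if (is.null(lambda)) {
    folds <- hp(spec, "cv_folds", 5L)
    folds <- min(folds, min(tabulate(y + 1L, 2L)))
    foldid <- stratified_folds(y, folds)
    cv <- glmnet::cv.glmnet(z, y, family = "binomial", alpha = alpha,
                            nlambda = hp(spec, "nlambda", 20L),
                            foldid = foldid, standardize = FALSE)
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(z, y, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = FALSE)
  list(glmnet = fit, lambda = lambda)
}

fit_logistic <- function(z, y) {
  X <- cbind(1, z)
  f <- irls_logistic(X, y)
  if (f$separated) {
    warning("logistic fit is separating; scores saturate at 0/1")
  }
  list(beta = f$coefficients)
}

# ---- random forest: bagged CART with per-node feature subsampling ----

gini_best_split <- function(v, y) {
  ord <- order(v)
  vs <- v[ord]
  ys <- y[ord]
  n <- length(v)
  cum1 <- cumsum(ys)
  tot <- cum1[n]
  cuts <- which(vs[-n] < vs[-1])  # splits only between distinct values
  if (!length(cuts)) return(NULL)
  n1 <- cuts
  n2 <- n - n1
  p1 <- cum1[cuts] / n1
  p2 <- (tot - cum1[cuts]) / n2
  imp <- n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)
  b <- which.min(imp)
  list(threshold = (vs[cuts[b]] + vs[cuts[b] + 1]) / 2, impurity = imp[b])
}

grow_tree <- function(x, y, mtry, max_depth, depth = 0L) {
  n <- length(y)
  pbar <- mean(y)
  if (n < 2L || pbar == 0 || pbar == 1 || depth >= max_depth) {
    return(list(leaf = TRUE, prob = pbar))
  }
  feats <- sample.int(ncol(x), min(mtry, ncol(x)))
  best <- NULL
  for (j in feats) {
    s <- gini_best_split(x[, j], y)
    if (!is.null(s) && (is.null(best) || s$impurity < best$impurity)) {
      best <- s
      best$feature <- j
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, prob = pbar))
  go_left <- x[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(x[go_left, , drop = FALSE], y[go_left],
                        mtry, max_depth, depth + 1L),
       right = grow_tree(x[!go_left, , drop = FALSE], y[!go_left],
                         mtry, max_depth, depth + 1L))
}

predict_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) {
      out[idx] <<- node$prob
      return()
    }
    left <- x[idx, node$feature] <= node$threshold
    rec(node$left, idx[left])
    rec(node$right, idx[!left])
  }
  rec(tree, seq_len(nrow(x)))
  out
}

fit_random_forest <- function(spec, z, y) {
  ntree <- hp(spec, "ntree", 500L)
  mtry <- hp(spec, "mtry", max(1L, floor(sqrt(ncol(z)))))
  max_depth <- hp(spec, "max_depth", 25L)
  trees <- vector("list", ntree)
  n <- nrow(z)
  for (b in seq_len(ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(z[idx, , drop = FALSE], y[idx], mtry, max_depth)
  }
  list(trees = trees)
}

# ---- RBF SVM: kernelized Pegasos with logistic score calibration ----

rbf_kernel <- function(a, b, gamma) {
  exp(-gamma * euclidean_cross(a, b)^2)
}

fit_rbf_svm <- function(spec, z, y) {
  n <- nrow(z)
  gamma <- hp(spec, "gamma", 1 / ncol(z))
  lambda <- hp(spec, "lambda", 1 / n)
  epochs <- hp(spec, "epochs", 50L)
  ypm <- ifelse(y == 1L, 1, -1)
  K <- rbf_kernel(z, z, gamma)
  alpha <- numeric(n)
  t <- 0L
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1L
      f <- sum(alpha * ypm * K[, i]) / (lambda * t)
      if (ypm[i] * f < 1) alpha[i] <- alpha[i] + 1
    }
  }
  dec <- as.numeric((K %*% (alpha * ypm)) / (lambda * t))
  # 1-d logistic calibration of decision values -> probabilities
  cal <- irls_logistic(cbind(1, dec), y)
  list(alpha = alpha, ypm = ypm, support = z, gamma = gamma,
       lambda = lambda, t_final = t, calibration = cal$coefficients)
}

#' Predict with a fitted classifier
#'
#' Applies the frozen preprocessing (standardization, PCA projection) and
#' the family's scoring rule. Scores are positive-class probabilities
#' (KNN: neighbour vote fraction; random forest: mean tree leaf
#' probability; elastic net / logistic: inverse-logit; SVM: calibrated
#' decision values); labels apply the fixed 0.5 threshold.
#'
#' @param model An [fit_model()] result.
#' @param x Numeric matrix with the training columns.
#' @return List with `score` (in `[0,1]`) and `label` (0/1).
#' @export
predict_model <- function(model, x) {
  stopifnot(inherits(model, "amy_model"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(colnames(x))) {
    missing <- setdiff(model$feature_names, colnames(x))
    if (length(missing)) {
      stop("test data lacks training column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- x[, model$feature_names, drop = FALSE]
  } else if (ncol(x) != length(model$feature_names)) {
    stop(sprintf("expected %d columns, got %d",
                 length(model$feature_names), ncol(x)), call. = FALSE)
  }
  if (anyNA(x)) {
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- model$impute[na_idx[, 2L]]
  }
  z <- zscore_apply(x[, model$keep, drop = FALSE], model$zstats)
  if (!is.null(model$pca)) z <- z %*% model$pca$rotation
  ft <- model$fitted
  score <- switch(
    model$spec$family,
    elastic_net = ,
    pca_elastic_net = as.numeric(
      stats::predict(ft$glmnet, newx = z, type = "response")),
    random_forest = {
      probs <- vapply(ft$trees, predict_tree, numeric(nrow(z)), x = z)
      if (nrow(z) == 1L) mean(probs) else rowMeans(matrix(probs, nrow(z)))
    },
    pca_logistic = as.numeric(stats::plogis(cbind(1, z) %*% ft$beta)),
    pca_svm = {
      dec <- as.numeric(
        (rbf_kernel(z, ft$support, ft$gamma) %*% (ft$alpha * ft$ypm)) /
          (ft$lambda * ft$t_final))
      as.numeric(stats::plogis(ft$calibration[1] + ft$calibration[2] * dec))
    },
    knn = ,
    pca_knn = knn_score(ft$train_x, ft$train_y, z, k = ft$k)
  )
  score <- pmin(pmax(score, 0), 1)
  list(score = score, label = knn_label(score))
}
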