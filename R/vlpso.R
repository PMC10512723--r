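#' Swarm configuration for wrapper feature selection
#'
#' Hyperparameters of the variable-length particle swarm selector. The
#' defaults follow the comprehensive-learning PSO literature the
#' variable-length variant builds on: 30 particles spread over 8 length
#' divisions, position-threshold decoding at 0.6, inertia decayed linearly
#' from 0.9 to 0.4, acceleration 1.49445, exemplar refresh after 7
#' non-improving evaluations, and length renewal after 3 stagnant
#' iterations of the global best. The fitness is 1 minus the balanced
#' accuracy of a k-nearest-neighbour classifier under stratified
#' cross-validation.
#'
#' @param population_size Number of particles. Default 30.
#' @param n_divisions Number of length divisions. Default 8.
#' @param threshold Position decoding threshold in (0,1); a ranked feature
#'   is selected when its position strictly exceeds it. Default 0.6.
#' @param inertia_max,inertia_min Linear inertia schedule. Defaults 0.9, 0.4.
#' @param acceleration Exemplar acceleration constant. Default 1.49445.
#' @param max_velocity Velocity clamp. Default 0.6.
#' @param refresh_gap Non-improving pbest evaluations before a particle's
#'   exemplars are reassigned. Default 7.
#' @param renewal_gap Stagnant gbest iterations before the maximum particle
#'   length is renewed. Default 3.
#' @param max_iterations Swarm iterations. Default 100.
#' @param knn_k Neighbours of the fitness classifier. Default 5.
#' @param fitness_folds Stratified CV folds of the fitness. Default 10.
#' @param seed Integer seed for swarm and fitness randomness.
#' @return An object of class `amy_swarm_config`.
#' @export
swarm_config <- function(population_size = 30L, n_divisions = 8L,
                         threshold = 0.6, inertia_max = 0.9,
                         inertia_min = 0.4, acceleration = 1.49445,
                         max_velocity = 0.6, refresh_gap = 7L,
                         renewal_gap = 3L, max_iterations = 100L,
                         knn_k = 5L, fitness_folds = 10L, seed = 1L) {
  population_size <- check_count(population_size, "population_size", 2L)
  n_divisions <- check_count(n_divisions, "n_divisions", 1L)
  if (n_divisions > population_size) {
    abort_field("n_divisions", "must not exceed population_size")
  }
  threshold <- check_number(threshold, "threshold", 0, 1,
                            open_lower = TRUE, open_upper = TRUE)
  inertia_max <- check_number(inertia_max, "inertia_max", 0)
  inertia_min <- check_number(inertia_min, "inertia_min", 0, inertia_max)
  acceleration <- check_number(acceleration, "acceleration", 0,
                               open_lower = TRUE)
  max_velocity <- check_number(max_velocity, "max_velocity", 0,
                               open_lower = TRUE)
  refresh_gap <- check_count(refresh_gap, "refresh_gap", 1L)
  renewal_gap <- check_count(renewal_gap, "renewal_gap", 1L)
  max_iterations <- check_count(max_iterations, "max_iterations", 1L)
  knn_k <- check_count(knn_k, "knn_k", 1L)
  fitness_folds <- check_count(fitness_folds, "fitness_folds", 2L)
  seed <- check_count(seed, "seed", 0L)
  structure(
    list(population_size = population_size, n_divisions = n_divisions,
         threshold = threshold, inertia_max = inertia_max,
         inertia_min = inertia_min, acceleration = acceleration,
         max_velocity = max_velocity, refresh_gap = refresh_gap,
         renewal_gap = renewal_gap, max_iterations = max_iterations,
         knn_k = knn_k, fitness_folds = fitness_folds, seed = seed),
    class = "amy_swarm_config"
  )
}

#' Rank features by symmetric uncertainty with the class label
#'
#' Symmetric uncertainty `SU(X;Y) = 2 I(X;Y) / (H(X) + H(Y))` between each
#' feature and the label, with continuous features discretized into 10
#' equal-frequency bins on the provided data (features with at most 10
#' distinct values are treated as already discrete). Features are ordered
#' by descending SU; ties break toward the lower original column index,
#' and constant features (SU defined as 0) rank last.
#'
#' @param x Numeric matrix (subjects x features).
#' @param y Binary label vector.
#' @return List with `order` (feature indices, most relevant first) and
#'   `su` (the SU value per original column).
#' @export
rank_relevance <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (min(table(y)) < 2L) stop("need >= 2 subjects per class", call. = FALSE)
  su <- vapply(seq_len(ncol(x)), function(j) {
    symmetric_uncertainty(x[, j], y)
  }, numeric(1))
  list(order = order(-su, seq_along(su)), su = su)
}

discretize_ef <- function(v, bins = 10L) {
  u <- unique(v)
  if (length(u) <= bins) return(match(v, sort(u)))
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(rep.int(1L, length(v)))
  as.integer(cut(v, breaks = br, include.lowest = TRUE))
}

entropy_nat <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

symmetric_uncertainty <- function(v, y) {
  xd <- discretize_ef(v)
  hx <- entropy_nat(table(xd))
  hy <- entropy_nat(table(y))
  if (hx == 0 || hy == 0) return(0)
  hxy <- entropy_nat(table(xd, y))
  mi <- hx + hy - hxy
  max(0, 2 * mi / (hx + hy))
}

#' Decode a particle position into a feature subset
#'
#' A ranked feature `j` (within the particle's length) is selected iff its
#' position strictly exceeds the threshold.
#'
#' @param position Numeric vector of positions in `[0,1]`.
#' @param threshold Decoding threshold.
#' @return Integer indices (into the ranked feature list) of the selected
#'   features; possibly empty.
#' @export
decode_particle <- function(position, threshold = 0.6) {
  which(position > threshold)
}

#' Wrapper fitness of a feature subset
#'
#' `1 - balanced accuracy` of a k-nearest-neighbour classifier restricted
#' to the subset's columns, under seeded stratified k-fold
#' cross-validation. Columns are z-scored with each training fold's
#' statistics; predictions are pooled over folds before the balanced
#' accuracy (mean of sensitivity and specificity) is computed. The empty
#' subset scores 1 by convention. When the fold count exceeds the minority
#' class size it is reduced to that size with a warning.
#'
#' @param x Numeric matrix (subjects x features).
#' @param y Binary labels (1 = positive).
#' @param subset Integer column indices; may be empty.
#' @param knn_k Neighbours. Default 5.
#' @param folds CV folds. Default 10.
#' @param seed Seed for the fold assignment.
#' @return Fitness in `[0, 1]` (lower is better).
#' @export
subset_fitness <- function(x, y, subset, knn_k = 5L, folds = 10L, seed = 1L) {
  if (length(subset) == 0L) return(1.0)
  x <- as.matrix(x)[, subset, drop = FALSE]
  y <- as.integer(y)
  minority <- min(tabulate(y + 1L, 2L))
  if (folds > minority) {
    warning(sprintf("reducing folds from %d to minority class size %d",
                    folds, minority))
    folds <- minority
  }
  fold <- with_local_seed(seed, stratified_folds(y, folds))
  pred <- integer(length(y))
  for (f in seq_len(folds)) {
    te <- fold == f
    st <- zscore_fit(x[!te, , drop = FALSE])
    tr <- zscore_apply(x[!te, , drop = FALSE], st)
    ts <- zscore_apply(x[te, , drop = FALSE], st)
    pred[te] <- knn_label(knn_score(tr, y[!te], ts, k = knn_k))
  }
  sens <- mean(pred[y == 1L] == 1L)
  spec <- mean(pred[y == 0L] == 0L)
  1 - (sens + spec) / 2
}

# Assign comprehensive-learning exemplars for particle i: per dimension,
# with probability pc learn from the better of two randomly drawn peers
# whose pbest covers that dimension; otherwise from the own pbest. At
# least one dimension is forced to a peer when possible.
assign_exemplars <- function(i, lengths, pbest_fit, pc) {
  len <- lengths[i]
  ex <- rep.int(i, len)
  learned <- FALSE
  for (j in seq_len(len)) {
    if (stats::runif(1) < pc) {
      cand <- which(lengths >= j)
      cand <- cand[cand != i]
      if (length(cand)) {
        pick <- if (length(cand) == 1L) c(cand, cand) else
          sample(cand, 2L, replace = TRUE)
        ex[j] <- pick[which.min(pbest_fit[pick])]
        learned <- TRUE
      }
    }
  }
  if (!learned && len > 0L) {
    j <- sample.int(len, 1L)
    cand <- which(lengths >= j)
    cand <- cand[cand != i]
    if (length(cand)) ex[j] <- cand[sample.int(length(cand), 1L)]
  }
  ex
}

#' Variable-length particle swarm feature selection
#'
#' Wrapper feature selection for a binary outcome. Features are first
#' ranked by symmetric uncertainty with the label; each particle spans a
#' prefix of this ranking, with prefix lengths evenly spaced over
#' `n_divisions` divisions (`ceil(d * n_features / n_divisions)`).
#' Positions in `[0,1]` decode to subsets by thresholding; fitness is the
#' cross-validated KNN error ([subset_fitness()]). Particles follow
#' per-dimension comprehensive-learning exemplars, reassigned after
#' `refresh_gap` non-improving evaluations; when the global best stagnates
#' for `renewal_gap` iterations the maximum length is renewed to the
#' best-performing division's length and longer particles truncate (their
#' personal bests are re-evaluated). Fitness ties break toward fewer
#' selected features, then earlier discovery.
#'
#' @param x Numeric matrix (subjects x features), at least 2 features.
#' @param y Binary labels (1 = positive); both classes present.
#' @param config A [swarm_config()].
#' @return An object of class `amy_selection` with elements
#'   `selected` (original column names), `selected_idx`, `best_fitness`,
#'   `trace` (gbest fitness per iteration, non-increasing),
#'   `n_evaluations`, `ranking`, `su`, `seed`, `config`.
#' @export
vlpso_run <- function(x, y, config = swarm_config()) {
  if (!inherits(config, "amy_swarm_config")) {
    stop("`config` must be a swarm_config()", call. = FALSE)
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  if (ncol(x) < 2L) stop("need at least 2 features", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))

  rk <- rank_relevance(x, y)
  xr <- x[, rk$order, drop = FALSE]
  nf <- ncol(x)
  pop <- config$population_size
  ndiv <- config$n_divisions
  theta <- config$threshold
  fitness_seed <- derive_seed(config$seed, 777L)
  n_eval <- 0L
  n_reeval <- 0L
  evaluate <- function(position) {
    sel <- decode_particle(position, theta)
    n_eval <<- n_eval + 1L
    list(fit = subset_fitness(xr, y, sel, knn_k = config$knn_k,
                              folds = config$fitness_folds,
                              seed = fitness_seed),
         size = length(sel), sel = sel)
  }

  with_local_seed(config$seed, {
    div_len <- ceiling(seq_len(ndiv) * nf / ndiv)
    division <- rep_len(seq_len(ndiv), pop)
    lengths <- div_len[division]
    pc <- 0.05 + 0.45 * (exp(10 * (seq_len(pop) - 1) / (pop - 1)) - 1) /
      (exp(10) - 1)

    pos <- lapply(lengths, function(L) stats::runif(L))
    vel <- lapply(lengths, function(L) numeric(L))
    pbest_pos <- pos
    pbest_fit <- numeric(pop)
    pbest_size <- integer(pop)
    stag <- integer(pop)
    gbest <- list(fit = Inf, size = Inf, sel = integer(0))
    update_gbest <- function(ev) {
      if (ev$fit < gbest$fit ||
          (ev$fit == gbest$fit && ev$size < gbest$size)) {
        gbest <<- ev
        TRUE
      } else FALSE
    }
    for (i in seq_len(pop)) {
      ev <- evaluate(pos[[i]])
      pbest_fit[i] <- ev$fit
      pbest_size[i] <- ev$size
      update_gbest(ev)
    }
    exemplar <- lapply(seq_len(pop), function(i)
      assign_exemplars(i, lengths, pbest_fit, pc[i]))
    trace <- gbest$fit
    gbest_stag <- 0L

    for (t in seq_len(config$max_iterations)) {
      w <- config$inertia_max -
        (config$inertia_max - config$inertia_min) *
        (t - 1) / max(1, config$max_iterations - 1)
      improved_gbest <- FALSE
      for (i in seq_len(pop)) {
        L <- lengths[i]
        ex <- exemplar[[i]]
        target <- vapply(seq_len(L), function(j) pbest_pos[[ex[j]]][j],
                         numeric(1))
        v <- w * vel[[i]] +
          config$acceleration * stats::runif(L) * (target - pos[[i]])
        v <- pmin(pmax(v, -config$max_velocity), config$max_velocity)
        p <- pmin(pmax(pos[[i]] + v, 0), 1)
        vel[[i]] <- v
        pos[[i]] <- p
        ev <- evaluate(p)
        if (ev$fit < pbest_fit[i] ||
            (ev$fit == pbest_fit[i] && ev$size < pbest_size[i])) {
          pbest_fit[i] <- ev$fit
          pbest_size[i] <- ev$size
          pbest_pos[[i]] <- p
          stag[i] <- 0L
        } else {
          stag[i] <- stag[i] + 1L
          if (stag[i] >= config$refresh_gap) {
            exemplar[[i]] <- assign_exemplars(i, lengths, pbest_fit, pc[i])
            stag[i] <- 0L
          }
        }
        if (update_gbest(ev)) improved_gbest <- TRUE
      }
      gbest_stag <- if (improved_gbest) 0L else gbest_stag + 1L

      if (gbest_stag >= config$renewal_gap && max(lengths) > min(div_len)) {
        # renew the maximum length to the best division's current length
        div_avg <- vapply(seq_len(ndiv), function(d) {
          mean(pbest_fit[division == d])
        }, numeric(1))
        lmax <- lengths[division == which.min(div_avg)][1]
        div_len <- ceiling(seq_len(ndiv) * lmax / ndiv)
        new_lengths <- pmin(lengths, div_len[division])
        for (i in which(new_lengths < lengths)) {
          L <- new_lengths[i]
          pos[[i]] <- pos[[i]][seq_len(L)]
          vel[[i]] <- vel[[i]][seq_len(L)]
          pbest_pos[[i]] <- pbest_pos[[i]][seq_len(L)]
          n_reeval <- n_reeval + 1L
          ev <- evaluate(pbest_pos[[i]])
          pbest_fit[i] <- ev$fit
          pbest_size[i] <- ev$size
          update_gbest(ev)
        }
        lengths <- new_lengths
        exemplar <- lapply(seq_len(pop), function(i)
          assign_exemplars(i, lengths, pbest_fit, pc[i]))
        stag[] <- 0L
        gbest_stag <- 0L
      }
      trace <- c(trace, gbest$fit)
    }

    sel_ranked <- gbest$sel
    if (length(sel_ranked) == 0L) sel_ranked <- 1L  # degenerate fallback
    selected_idx <- sort(rk$order[sel_ranked])
    structure(
      list(selected = colnames(x)[selected_idx],
           selected_idx = selected_idx,
           best_fitness = gbest$fit,
           trace = trace,
           n_evaluations = n_eval,
           n_reevaluations = n_reeval,
           ranking = rk$order, su = rk$su,
           seed = config$seed, config = config),
      class = "amy_selection"
    )
  })
}

#' @export
print.amy_selection <- function(x, ...) {
  cat(sprintf("<amy_selection> %d feature(s), fitness %.4f, %d evaluations\n",
              length(x$selected), x$best_fitness, x$n_evaluations))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
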