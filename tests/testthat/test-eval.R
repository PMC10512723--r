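test_that("metrics match closed-form arithmetic on a fixed confusion", {
  # TP = 25, FN = 5, FP = 8, TN = 14
  truth <- c(rep(1L, 30), rep(0L, 22))
  label <- c(rep(1L, 25), rep(0L, 5), rep(1L, 8), rep(0L, 14))
  score <- ifelse(label == 1L, 0.9, 0.1)
  m <- compute_metrics(truth, label, score)
  expect_equal(unname(m["accuracy"]), 0.75)
  expect_equal(unname(m["recall"]), 25 / 30, tolerance = 1e-12)
  expect_equal(unname(m["precision"]), 25 / 33, tolerance = 1e-12)
  expect_equal(unname(m["f1"]),
               2 * (25 / 33) * (25 / 30) / (25 / 33 + 25 / 30),
               tolerance = 1e-12)
})

test_that("AUC follows the Mann-Whitney midrank convention", {
  truth <- c(0, 0, 1, 1)
  expect_equal(unname(compute_metrics(truth, truth,
                                      c(0.1, 0.2, 0.8, 0.9))["auc"]), 1)
  expect_equal(unname(compute_metrics(truth, truth,
                                      rep(0.5, 4))["auc"]), 0.5)
  # brute-force all-pairs oracle on random small prediction sets
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    truth_r <- c(0L, 1L, rbinom(n - 2, 1, 0.5))
    score_r <- round(runif(n), 1)  # induces ties
    label_r <- as.integer(score_r >= 0.5)
    pairs <- expand.grid(p = which(truth_r == 1L), n = which(truth_r == 0L))
    brute <- mean(ifelse(score_r[pairs$p] > score_r[pairs$n], 1,
                         ifelse(score_r[pairs$p] == score_r[pairs$n],
                                0.5, 0)))
    m <- suppressWarnings(compute_metrics(truth_r, label_r, score_r))
    expect_equal(unname(m["auc"]), brute, tolerance = 1e-12)
  }
})

test_that("degenerate prediction sets are handled as documented", {
  truth <- c(0, 0, 1, 1)
  expect_warning(m <- compute_metrics(truth, rep(0L, 4), rep(0.2, 4)),
                 "no predicted positives")
  expect_equal(unname(m["precision"]), 0)
  expect_equal(unname(m["f1"]), 0)
  expect_error(compute_metrics(rep(1L, 4), rep(1L, 4), rep(0.5, 4)),
               "both classes")
})

test_that("LOOCV is exact on twin constructions and deterministic", {
  # each subject has an identical twin: k = 1 LOOCV must be perfect
  base <- matrix(rnorm(10 * 3), 10, 3)
  x <- rbind(base, base)
  y <- rep(rep(c(0L, 1L), each = 5), 2)
  colnames(x) <- c("a", "b", "c")
  spec <- model_spec("knn", hyperparameters = list(k = 1), seed = 1)
  pr <- loocv(spec, x, y, seed = 1)
  expect_equal(mean(pr$label == pr$truth), 1.0)
  pr2 <- loocv(spec, x, y, seed = 1)
  expect_identical(pr, pr2)
  expect_error(loocv(spec, x[1:2, ], y[1:2], seed = 1), "at least 3")
})

test_that("bootstrap scheme: B = 1, invariants, and the identity hook", {
  toy <- toy_separable(n = 20, p = 4, delta = 2, seed = 31)
  spec <- model_spec("knn", seed = 1)
  b1 <- bootstrap_loocv(spec, toy$x, toy$y, B = 1, seed = 3)
  expect_equal(nrow(b1$samples), 1L)
  expect_equal(unname(b1$mean), unname(b1$samples[1, ]))

  bd <- bootstrap_loocv(spec, toy$x, toy$y, B = 40, seed = 3)
  for (mname in colnames(bd$samples)) {
    v <- bd$samples[, mname]
    expect_lte(min(v), bd$lo[[mname]])
    expect_lte(bd$lo[[mname]], bd$mean[[mname]])
    expect_lte(bd$mean[[mname]], bd$hi[[mname]])
    expect_lte(bd$hi[[mname]], max(v))
    expect_true(all(v >= 0 & v <= 1))
  }

  # identity resample hook reproduces plain LOOCV exactly
  hook <- function(cand, size) cand
  bid <- bootstrap_loocv(spec, toy$x, toy$y, B = 3, seed = 9,
                         resample_fn = hook)
  pr <- loocv(spec, toy$x, toy$y, seed = 9)
  ref <- suppressWarnings(compute_metrics(pr$truth, pr$label, pr$score))
  for (b in 1:3) expect_identical(unname(bid$samples[b, ]), unname(ref))
})

test_that("well-separated classes give near-perfect bootstrap AUC", {
  toy <- toy_separable(n = 30, p = 5, informative = 1:2, delta = 4,
                       seed = 41)
  spec <- model_spec("knn", seed = 1)
  bd <- bootstrap_loocv(spec, toy$x, toy$y, B = 100, seed = 2)
  expect_gt(bd$mean[["auc"]], 0.95)
})

test_that("percentile intervals cover the null AUC", {
  # reduced-scale coverage check: null data, the 95% AUC interval should
  # cover 0.5 in nearly all replicate runs
  cover <- logical(10)
  for (r in 1:10) {
    set.seed(5000 + r)
    x <- matrix(rnorm(16 * 3), 16, 3)
    colnames(x) <- c("a", "b", "c")
    y <- rep(c(0L, 1L), 8)
    bd <- bootstrap_loocv(model_spec("knn", seed = 1), x, y, B = 150,
                          seed = 6000 + r)
    cover[r] <- bd$lo[["auc"]] <= 0.5 && 0.5 <= bd$hi[["auc"]]
  }
  expect_gte(sum(cover), 8L)
})

test_that("run_study emits the documented report shape", {
  sim <- small_cohort(seed = 51, n = 30, npos = 17, effect = 1.2)
  cfg <- run_config(feature_set = "acoustic", model = "knn",
                    evaluation = "bootstrap_loocv", n_bootstrap = 20,
                    swarm = swarm_config(max_iterations = 6,
                                         population_size = 8,
                                         n_divisions = 4,
                                         fitness_folds = 5, seed = 2),
                    seed = 2)
  rep1 <- run_study(cfg, sim$features, sim$cohort)
  expect_true(all(grepl("^\\d\\.\\d{2} \\[\\d\\.\\d{2}-\\d\\.\\d{2}\\]$",
                        rep1$row)))
  expect_named(rep1$row, c("accuracy", "precision", "recall", "f1", "auc"))
  expect_s3_class(rep1$selection, "amy_selection")
  rep2 <- run_study(cfg, sim$features, sim$cohort)
  expect_identical(rep1$row, rep2$row)

  # plain LOOCV route with no selection
  cfg_l <- run_config(feature_set = "neuropsych_demographic",
                      model = "pca_knn", evaluation = "loocv", seed = 3)
  rep3 <- run_study(cfg_l, sim$features, sim$cohort)
  expect_null(rep3$selection)
  expect_true(all(grepl("^\\d\\.\\d{2}$", rep3$row)))
})

test_that("permuted labels drive LOOCV AUC to chance", {
  # mini null calibration; the 200-replicate version is an acceptance
  # criterion
  sim <- small_cohort(seed = 61, n = 24, npos = 12, effect = 1)
  d <- assemble_design(sim$features, sim$cohort, "acoustic")
  x <- d$x[, 1:6]
  spec <- model_spec("knn", seed = 1)
  aucs <- numeric(40)
  set.seed(99)
  for (r in 1:40) {
    yp <- sample(d$y)
    pr <- loocv(spec, x, yp, seed = r)
    aucs[r] <- suppressWarnings(
      compute_metrics(pr$truth, pr$label, pr$score))[["auc"]]
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})
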