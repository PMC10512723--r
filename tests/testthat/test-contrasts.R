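# Printed-table reproduction values: pooled t from the WAIS-III
# similarities row (means 7.8/10.8, SDs 2.8/3.0, n 30/22 -> 3.70), and
# continuity-corrected chi-square from cell counts reconstructed from the
# printed percentages (APOE: 17/30 vs 4/22 -> 6.29; sex: 19/30 vs 15/22
# -> 0.00).

test_that("pooled t reproduces the similarities row", {
  r <- pooled_t(7.8, 2.8, 30, 10.8, 3.0, 22)
  expect_equal(round(r$t, 2), 3.70)
  expect_equal(r$df, 50)
  expect_lt(r$p, 0.001)
})

test_that("corrected chi-square reproduces the APOE and sex rows", {
  apoe <- chi2_corrected(17, 13, 4, 18)
  expect_equal(round(apoe$chi2, 2), 6.29)
  expect_equal(round(apoe$p, 3), 0.012)
  sex <- chi2_corrected(19, 11, 15, 7)
  expect_equal(round(sex$chi2, 2), 0.00)
  # the table prints 0.945; the exact upper tail of the corrected
  # statistic is 0.9457
  expect_lt(abs(sex$p - 0.945), 0.002)
})

test_that("pooled t degenerate and symmetry behavior", {
  r0 <- pooled_t(5, 1, 10, 5, 1, 10)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_warning(ri <- pooled_t(1, 0, 5, 2, 0, 5), "infinite")
  expect_true(ri$infinite)
  expect_equal(ri$p, 0)
  # antisymmetric in group order before the absolute value: |t| invariant
  a <- pooled_t(7.8, 2.8, 30, 10.8, 3.0, 22)
  b <- pooled_t(10.8, 3.0, 22, 7.8, 2.8, 30)
  expect_equal(a$t, b$t)
  expect_equal(a$p, b$p)
})

test_that("summary-based and raw-vector paths agree to 1e-12", {
  set.seed(42)
  for (rep in 1:25) {
    x1 <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    x2 <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    raw <- pooled_t(x1 = x1, x2 = x2)
    summ <- pooled_t(mean(x1), sd(x1), length(x1),
                     mean(x2), sd(x2), length(x2))
    expect_equal(raw$t, summ$t, tolerance = 1e-12)
    expect_equal(raw$p, summ$p, tolerance = 1e-12)
  }
})

test_that("corrected chi-square is invariant under row and column swaps", {
  set.seed(7)
  for (rep in 1:20) {
    cells <- rpois(4, 10) + 1
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    base <- chi2_corrected(a, b, c_, d)$chi2
    expect_equal(chi2_corrected(c_, d, a, b)$chi2, base)     # row swap
    expect_equal(chi2_corrected(b, a, d, c_)$chi2, base)     # column swap
    expect_equal(chi2_corrected(d, c_, b, a)$chi2, base)     # both
  }
  expect_equal(chi2_corrected(10, 10, 5, 5)$chi2, 0)
  expect_error(chi2_corrected(0, 0, 3, 4), "margin")
  expect_error(chi2_corrected(-1, 2, 3, 4), "nonnegative")
})

test_that("adjusted logistic recovers a known coefficient", {
  set.seed(314)
  n <- 2000
  pred <- rnorm(n)
  age <- rnorm(n, 73, 8)
  sex <- rbinom(n, 1, 0.65)
  edu <- rnorm(n, 9, 4)
  eta <- -0.2 + 0.8 * pred + 0.02 * (age - 73) - 0.1 * sex
  y <- rbinom(n, 1, plogis(eta))
  fit <- adjusted_logistic(y, pred, cbind(age = age, sex = sex,
                                          education = edu))
  expect_false(fit$separated)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficient - 0.8), 0.15)
  expect_equal(fit$odds_ratio, exp(fit$coefficient))
})

test_that("adjusted logistic Wald test has calibrated type-I error", {
  set.seed(2718)
  n_sim <- 1000
  rej <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    n <- 120
    y <- rbinom(n, 1, 0.55)
    pred <- rnorm(n)
    cov <- cbind(age = rnorm(n, 73, 8), sex = rbinom(n, 1, 0.6),
                 education = rnorm(n, 9, 4))
    rej[s] <- adjusted_logistic(y, pred, cov)$p < 0.05
  }
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("logistic fit matches the closed-form 2x2 log odds ratio", {
  # binary predictor, no covariates: beta = log(ad / bc) of the 2x2 table
  set.seed(11)
  pred <- rbinom(300, 1, 0.5)
  y <- rbinom(300, 1, plogis(-0.3 + 0.9 * pred))
  fit <- adjusted_logistic(y, pred, covariates = NULL)
  a <- sum(y == 1 & pred == 1); b <- sum(y == 0 & pred == 1)
  c_ <- sum(y == 1 & pred == 0); d <- sum(y == 0 & pred == 0)
  expect_equal(fit$coefficient, log((a * d) / (b * c_)), tolerance = 1e-6)
})

test_that("degenerate predictors are rejected, separation is flagged", {
  y <- rep(c(0, 1), 20)
  expect_error(adjusted_logistic(y, rep(1, 40)), "rank")
  # perfectly separating predictor
  expect_warning(fit <- adjusted_logistic(y, ifelse(y == 1, 10, -10)),
                 "separation")
  expect_true(fit$separated)
  expect_true(is.na(fit$p))
})

test_that("contrast_table mirrors the element operations", {
  sim <- small_cohort(seed = 10)
  ct <- contrast_table(sim$features, sim$cohort)
  expect_equal(nrow(ct), (ncol(sim$cohort) - 3L) + 88L)
  # one categorical row (sex), chi2 kind
  expect_equal(ct$kind[ct$variable == "sex"], "chi2_corrected")
  # spot-check one acoustic row against the direct call
  pos <- sim$cohort$amyloid_status == "positive"
  v <- sim$features[["mfcc1_sma3_amean"]]
  direct <- pooled_t(x1 = v[pos], x2 = v[!pos])
  row <- ct[ct$variable == "mfcc1_sma3_amean", ]
  expect_equal(row$statistic, direct$t)
  expect_equal(row$p, direct$p)
  # single-variable cohort -> single row
  mini <- data.frame(subject_id = sim$cohort$subject_id,
                     age = sim$cohort$age,
                     amyloid_status = sim$cohort$amyloid_status)
  expect_equal(nrow(contrast_table(NULL, mini)), 1L)
})

test_that("null cohorts yield ~5% significant acoustic contrasts", {
  n_rep <- 60L
  rate <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- generate_cohort(synth_config(effect_size = 0,
                                        seed = 400000L + r))
    ct <- contrast_table(sim$features,
                         sim$cohort[, c("subject_id", "amyloid_status")])
    rate[r] <- mean(ct$p < 0.05)
  }
  expect_gt(mean(rate), 0.05 - 0.02)
  expect_lt(mean(rate), 0.05 + 0.02)
})
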