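#' Pooled-variance two-sample t test from group summaries or raw vectors
#'
#' The classical equal-variance two-sample t statistic, reported as an
#' absolute value with `df = n1 + n2 - 2` and a two-sided p-value. Either
#' supply the six group summaries, or pass two raw vectors via `x1`/`x2`
#' and the summaries are computed first. A Welch (unpooled) variant is
#' available behind `welch = TRUE`.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @param x1,x2 Optional raw vectors; when given, they override the
#'   summaries.
#' @param welch Use the Welch statistic and Satterthwaite df instead of the
#'   pooled form. Default `FALSE`.
#' @return List with `t` (absolute value), `df`, `p`, and `infinite`
#'   (`TRUE` when the pooled variance is zero with unequal means; then
#'   `p = 0` and a warning is issued).
#' @export
#' @examples
#' pooled_t(7.8, 2.8, 30, 10.8, 3.0, 22)$t  # 3.70 to 2 d.p.
pooled_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                     x1 = NULL, x2 = NULL, welch = FALSE) {
  if (!is.null(x1) || !is.null(x2)) {
    stopifnot(is.numeric(x1), is.numeric(x2))
    mean1 <- mean(x1); sd1 <- stats::sd(x1); n1 <- length(x1)
    mean2 <- mean(x2); sd2 <- stats::sd(x2); n2 <- length(x2)
  }
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("sd must be nonnegative", call. = FALSE)
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    se <- sqrt(se2)
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  if (se == 0) {
    if (mean1 == mean2) {
      return(list(t = 0, df = df, p = 1, infinite = FALSE))
    }
    warning("zero pooled variance with unequal means: infinite statistic")
    return(list(t = Inf, df = df, p = 0, infinite = TRUE))
  }
  tval <- abs(mean1 - mean2) / se
  list(t = tval, df = df, p = 2 * stats::pt(tval, df, lower.tail = FALSE),
       infinite = FALSE)
}

#' Continuity-corrected chi-square for a 2x2 table
#'
#' Yates-corrected statistic
#' `n (|ad - bc| - n/2)^2 / (r1 r2 c1 c2)`, floored at zero when
#' `|ad - bc| <= n/2`, with a p-value from the chi-square distribution on
#' one degree of freedom.
#'
#' @param a,b,c,d Nonnegative integer cell counts of the table
#'   `rbind(c(a, b), c(c, d))`.
#' @return List with `chi2` and `p`.
#' @export
#' @examples
#' chi2_corrected(17, 13, 4, 18)$chi2  # 6.29 to 2 d.p.
chi2_corrected <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin in 2x2 table", call. = FALSE)
  delta <- abs(a * d - b * c) - n / 2
  chi2 <- if (delta <= 0) 0 else n * delta^2 / prod(margins)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Plain IRLS logistic regression. Returns coefficients, their covariance,
# convergence info, and a separation flag (any standardized coefficient
# diverging past `sep_limit`).
irls_logistic <- function(X, y, tol = 1e-8, max_iter = 100L, sep_limit = 15) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient (constant or collinear predictor)",
         call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1  # intercept column
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  separated <- any(abs(beta * sds) > sep_limit)
  list(coefficients = beta, cov = cov, converged = converged,
       iterations = it, separated = separated)
}

#' Covariate-adjusted logistic association
#'
#' Fits a maximum-likelihood logistic regression of the binary amyloid
#' label on a predictor adjusted for age, sex and years of education
#' (iteratively reweighted least squares, convergence when the largest
#' coefficient change falls below 1e-8, at most 100 iterations) and
#' returns the predictor's coefficient, odds ratio and two-sided Wald
#' p-value. Perfect separation (a coefficient diverging beyond 15 on the
#' standardized scale) is flagged rather than reported as a number.
#'
#' @param labels Binary vector (0/1, logical, or a factor whose second
#'   level is the positive class); both classes must be present.
#' @param predictor Numeric vector.
#' @param covariates Numeric matrix or data.frame of adjustment covariates
#'   (e.g. age, sex 0/1, education); may be `NULL` for an unadjusted fit.
#' @return List with `coefficient`, `odds_ratio`, `se`, `p`, `separated`,
#'   `converged`. When `separated` is `TRUE` the numeric fields are `NA`.
#' @export
adjusted_logistic <- function(labels, predictor, covariates = NULL) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L) {
    stop("`labels` must be binary with both classes present", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, predictor = as.numeric(predictor))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    storage.mode(cv) <- "double"
    X <- cbind(X, cv)
  }
  fit <- irls_logistic(X, y)
  if (fit$separated) {
    warning("perfect separation detected; estimates not reported")
    return(list(coefficient = NA_real_, odds_ratio = NA_real_,
                se = NA_real_, p = NA_real_,
                separated = TRUE, converged = fit$converged))
  }
  beta <- fit$coefficients[2L]
  se <- sqrt(fit$cov[2L, 2L])
  zst <- beta / se
  list(coefficient = unname(beta), odds_ratio = unname(exp(beta)),
       se = unname(se),
       p = unname(2 * stats::pnorm(abs(zst), lower.tail = FALSE)),
       separated = FALSE, converged = fit$converged)
}

#' Bivariate group contrasts for a whole cohort
#'
#' Contrasts every numeric variable (pooled-variance t) and every
#' categorical variable (continuity-corrected chi-square) between
#' amyloid-positive and amyloid-negative subjects. No multiple-testing
#' correction is applied; the table is descriptive.
#'
#' @param feature_table Optional acoustic feature table (data.frame with
#'   `subject_id`); its columns are contrasted alongside the cohort
#'   variables. May be `NULL`.
#' @param cohort_table Cohort data.frame with `amyloid_status` and
#'   `subject_id`.
#' @param welch Use Welch instead of pooled t. Default `FALSE`.
#' @return A data.frame with one row per variable: `variable`, `kind`
#'   (`pooled_t` or `chi2_corrected`), group summaries (`summary_pos`,
#'   `summary_neg`: "mean (sd)" or "%"), `statistic`, `df`, `p`.
#' @export
contrast_table <- function(feature_table = NULL, cohort_table, welch = FALSE) {
  status <- cohort_table$amyloid_status
  if (is.null(status)) stop("cohort table lacks `amyloid_status`", call. = FALSE)
  pos <- status == "positive"
  vars <- setdiff(names(cohort_table),
                  c("subject_id", "amyloid_status", "abeta42"))
  rows <- list()
  add_numeric <- function(v, x) {
    r <- pooled_t(x1 = x[pos], x2 = x[!pos], welch = welch)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = v, kind = "pooled_t",
      summary_pos = sprintf("%.1f (%.1f)", mean(x[pos]), stats::sd(x[pos])),
      summary_neg = sprintf("%.1f (%.1f)", mean(x[!pos]), stats::sd(x[!pos])),
      statistic = r$t, df = r$df, p = r$p, stringsAsFactors = FALSE)
  }
  add_categorical <- function(v, x) {
    lev <- levels(factor(x))[1]
    a <- sum(x[pos] == lev); b <- sum(x[pos] != lev)
    c_ <- sum(x[!pos] == lev); d <- sum(x[!pos] != lev)
    r <- chi2_corrected(a, c_, b, d)  # rows = level yes/no, cols = group
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = v, kind = "chi2_corrected",
      summary_pos = sprintf("%.1f%%", 100 * a / sum(pos)),
      summary_neg = sprintf("%.1f%%", 100 * c_ / sum(!pos)),
      statistic = r$chi2, df = 1, p = r$p, stringsAsFactors = FALSE)
  }
  for (v in vars) {
    x <- cohort_table[[v]]
    if (is.numeric(x)) add_numeric(v, x) else add_categorical(v, x)
  }
  if (!is.null(feature_table)) {
    ids <- feature_table$subject_id
    stopifnot(identical(ids, cohort_table$subject_id))
    for (v in setdiff(names(feature_table), "subject_id")) {
      add_numeric(v, feature_table[[v]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
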