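#' Configuration for the synthetic cohort generator
#'
#' Describes the statistical world the generator draws from: a two-group
#' (amyloid-positive / amyloid-negative) MCI cohort with demographics,
#' a 13-test neuropsychological battery, CSF A-beta-42 levels, and an
#' equicorrelated 88-column acoustic block in which a small set of
#' informative features carries a standardized group mean difference.
#'
#' @param n_subjects Total cohort size. Default 52.
#' @param n_positive Number of amyloid-positive subjects. Default 30
#'   (prevalence 57.7%).
#' @param n_acoustic Number of acoustic columns; when 88 the canonical
#'   [acoustic_schema()] names are used, otherwise generic `ac_001, ...`.
#' @param informative_features Names of acoustic columns that receive a
#'   group mean shift. Default [key_acoustic_features()].
#' @param effect_size Standardized mean difference (positive minus negative,
#'   in pooled-SD units) planted on each informative feature. Default 0.8.
#' @param correlation Equicorrelation coefficient in `[0, 1)` shared by all
#'   pairs of acoustic features. Default 0.3.
#' @param group_params Per-group means/SDs and truncation bounds for
#'   demographics and neuropsychology; see [default_group_params()].
#' @param abeta_params A-beta-42 (pg/mL) group distributions: a list with
#'   `mean_pos`, `sd_pos`, `mean_neg`, `sd_neg`. Group draws are truncated
#'   at the 796 pg/mL clinical cutoff so the biomarker always agrees with
#'   the group label.
#' @param seed Integer seed driving all sampling.
#'
#' @return An object of class `amy_synth_config`.
#' @export
synth_config <- function(n_subjects = 52L,
                         n_positive = 30L,
                         n_acoustic = 88L,
                         informative_features = key_acoustic_features(),
                         effect_size = 0.8,
                         correlation = 0.3,
                         group_params = default_group_params(),
                         abeta_params = list(mean_pos = 600, sd_pos = 100,
                                             mean_neg = 1100, sd_neg = 250),
                         seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2L)
  n_positive <- check_count(n_positive, "n_positive", min = 1L)
  if (n_positive > n_subjects) {
    abort_field("n_positive", "must not exceed n_subjects")
  }
  n_acoustic <- check_count(n_acoustic, "n_acoustic", min = 1L)
  effect_size <- check_number(effect_size, "effect_size", lower = 0)
  correlation <- check_number(correlation, "correlation",
                              lower = 0, upper = 1, open_upper = TRUE)
  schema <- if (n_acoustic == 88L) acoustic_schema() else
    sprintf("ac_%03d", seq_len(n_acoustic))
  informative_features <- as.character(informative_features)
  if (anyDuplicated(informative_features)) {
    abort_field("informative_features", "must not contain duplicates")
  }
  missing <- setdiff(informative_features, schema)
  if (length(missing)) {
    abort_field("informative_features",
                paste("not in the acoustic schema:",
                      paste(missing, collapse = ", ")))
  }
  req <- c("mean_pos", "sd_pos", "mean_neg", "sd_neg")
  if (!is.list(abeta_params) || !all(req %in% names(abeta_params))) {
    abort_field("abeta_params",
                "must be a list with mean_pos, sd_pos, mean_neg, sd_neg")
  }
  if (!is.data.frame(group_params) ||
      !all(c("variable", "mean_pos", "sd_pos", "mean_neg", "sd_neg",
             "lower", "upper") %in% names(group_params))) {
    abort_field("group_params", "must have the default_group_params() layout")
  }
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(n_subjects = n_subjects, n_positive = n_positive,
         n_acoustic = n_acoustic, acoustic_names = schema,
         informative_features = informative_features,
         effect_size = effect_size, correlation = correlation,
         group_params = group_params, abeta_params = abeta_params,
         seed = seed),
    class = "amy_synth_config"
  )
}

#' @export
print.amy_synth_config <- function(x, ...) {
  cat(sprintf(
    "<amy_synth_config> %d subjects (%d positive), %d acoustic features\n",
    x$n_subjects, x$n_positive, x$n_acoustic))
  cat(sprintf("  planted: %d informative features, effect size %.2f, rho %.2f, seed %d\n",
              length(x$informative_features), x$effect_size,
              x$correlation, x$seed))
  invisible(x)
}

#' Dichotomize CSF A-beta-42 into amyloid status
#'
#' Applies the clinical cutoff: a subject is amyloid *positive* when the
#' CSF A-beta-42 concentration is strictly below 796 pg/mL, and negative
#' otherwise (796 itself is negative).
#'
#' @param abeta42 Numeric vector of A-beta-42 concentrations in pg/mL;
#'   all values must be positive and non-missing.
#' @param cutoff Cutoff in pg/mL. Default 796.
#' @return Factor with levels `c("negative", "positive")`.
#' @export
#' @examples
#' dichotomize_amyloid(c(795, 796))
dichotomize_amyloid <- function(abeta42, cutoff = 796) {
  if (!is.numeric(abeta42) || length(abeta42) == 0L) {
    stop("`abeta42` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(abeta42) || any(abeta42 <= 0)) {
    stop("`abeta42` must be positive and non-missing (pg/mL)", call. = FALSE)
  }
  factor(ifelse(abeta42 < cutoff, "positive", "negative"),
         levels = c("negative", "positive"))
}

# One-sided truncated normal draws via inverse-CDF, vectorized.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  # guard against u hitting exactly 0/1 in degenerate configurations
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic amyloid cohort
#'
#' Draws a cohort under the world described by a [synth_config()]:
#' exactly `n_positive` amyloid-positive subjects; demographics and
#' neuropsychological scores as independent truncated Gaussians with the
#' configured per-group means/SDs; A-beta-42 as per-group truncated
#' Gaussians respecting the 796 pg/mL cutoff; and an acoustic block drawn
#' from a multivariate Gaussian with equicorrelation `correlation`, unit
#' variances, and a mean shift of `effect_size` (in SD units) on the
#' informative columns of the positive group (split symmetrically around
#' zero so the pooled scale is unchanged).
#'
#' @param config An [synth_config()] object.
#' @return A list with elements `features` (a data.frame: `subject_id`
#'   plus the acoustic columns) and `cohort` (a data.frame: `subject_id`,
#'   `age`, `sex`, `education`, `mmse`, the 13 battery scores, `abeta42`,
#'   `amyloid_status`).
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(seed = 42))
#' table(cohort$cohort$amyloid_status)
generate_cohort <- function(config = synth_config()) {
  if (!inherits(config, "amy_synth_config")) {
    config <- do.call(synth_config, config)
  }
  n <- config$n_subjects
  npos <- config$n_positive
  p <- config$n_acoustic
  with_local_seed(config$seed, {
    subject_id <- sprintf("S%03d", seq_len(n))
    status <- factor(rep(c("positive", "negative"), c(npos, n - npos)),
                     levels = c("negative", "positive"))
    pos <- status == "positive"

    # --- acoustic block: equicorrelated Gaussian via one shared factor ---
    # X_ij = sqrt(rho) * z_i + sqrt(1 - rho) * e_ij has unit variance and
    # pairwise correlation rho for every pair of columns.
    rho <- config$correlation
    z <- stats::rnorm(n)
    e <- matrix(stats::rnorm(n * p), n, p)
    ac <- sqrt(rho) * z + sqrt(1 - rho) * e
    colnames(ac) <- config$acoustic_names
    info <- match(config$informative_features, config$acoustic_names)
    if (length(info)) {
      shift <- config$effect_size / 2
      ac[pos, info] <- ac[pos, info] + shift
      ac[!pos, info] <- ac[!pos, info] - shift
    }

    # --- demographics & neuropsychology: truncated Gaussians per group ---
    gp <- config$group_params
    clin <- list()
    for (r in seq_len(nrow(gp))) {
      v <- gp$variable[r]
      if (v == "sex_female") next
      x <- numeric(n)
      x[pos] <- rtruncnorm(sum(pos), gp$mean_pos[r], gp$sd_pos[r],
                           gp$lower[r], gp$upper[r])
      x[!pos] <- rtruncnorm(sum(!pos), gp$mean_neg[r], gp$sd_neg[r],
                            gp$lower[r], gp$upper[r])
      clin[[v]] <- x
    }
    sexrow <- which(gp$variable == "sex_female")
    pfem_pos <- gp$mean_pos[sexrow]
    pfem_neg <- gp$mean_neg[sexrow]
    sex <- character(n)
    sex[pos] <- ifelse(stats::runif(sum(pos)) < pfem_pos, "female", "male")
    sex[!pos] <- ifelse(stats::runif(sum(!pos)) < pfem_neg, "female", "male")

    # --- biomarker: truncated at the cutoff so label and level agree ---
    ab <- config$abeta_params
    abeta <- numeric(n)
    abeta[pos] <- rtruncnorm(sum(pos), ab$mean_pos, ab$sd_pos,
                             lower = 1e-6, upper = 796 - 1e-9)
    abeta[!pos] <- rtruncnorm(sum(!pos), ab$mean_neg, ab$sd_neg,
                              lower = 796)

    cohort <- data.frame(
      subject_id = subject_id,
      age = clin$age,
      sex = factor(sex, levels = c("female", "male")),
      education = clin$education,
      mmse = clin$mmse,
      stringsAsFactors = FALSE
    )
    for (v in neuropsych_schema()) cohort[[v]] <- clin[[v]]
    cohort$abeta42 <- abeta
    cohort$amyloid_status <- dichotomize_amyloid(abeta)
    stopifnot(identical(cohort$amyloid_status, status))

    features <- data.frame(subject_id = subject_id, ac,
                           check.names = FALSE, stringsAsFactors = FALSE)
    list(features = features, cohort = cohort)
  })
}
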