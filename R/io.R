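#' Read an acoustic feature table from CSV
#'
#' Accepts two dialects: a plain comma-separated table whose first column is
#' the subject identifier, and the semicolon-separated functional-summary
#' dialect written by the openSMILE command-line tool (leading `name`
#' column). The delimiter is sniffed from the header line (`,` or `;`).
#' When all 88 canonical eGeMAPS names are present the columns are
#' reordered to [acoustic_schema()].
#'
#' @param path Path to the CSV file.
#' @param strict_schema When `TRUE`, require exactly the 88 canonical
#'   acoustic columns; a missing or unknown column is an error naming it.
#' @return A data.frame with `subject_id` followed by numeric feature
#'   columns (class `amy_feature_table`).
#' @export
read_feature_csv <- function(path, strict_schema = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr(";", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L) stop("feature CSV needs an id column and at least one feature",
                          call. = FALSE)
  names(df)[1] <- "subject_id"
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    dup <- unique(df$subject_id[duplicated(df$subject_id)])
    stop("duplicate subject id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  feat <- names(df)[-1]
  for (j in feat) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      w <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(w) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric value at row %d, column '%s'", bad[1], j),
             call. = FALSE)
      }
      df[[j]] <- w
    }
  }
  schema <- acoustic_schema()
  if (strict_schema) {
    missing <- setdiff(schema, feat)
    if (length(missing)) {
      stop("missing acoustic column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    unknown <- setdiff(feat, schema)
    if (length(unknown)) {
      stop("unknown column(s) under strict schema: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (all(schema %in% feat)) {
    df <- df[, c("subject_id", schema, setdiff(feat, schema)), drop = FALSE]
  }
  class(df) <- c("amy_feature_table", "data.frame")
  df
}

#' Write an acoustic feature table to CSV
#'
#' UTF-8, header row, `subject_id` first, `.` decimal separator.
#'
#' @param x Feature table data.frame (first column `subject_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(x, path) {
  stopifnot(is.data.frame(x), names(x)[1] == "subject_id")
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Expects a `subject_id` column plus demographics, neuropsychology, and
#' either an `abeta42` column (pg/mL, from which `amyloid_status` is
#' derived via [dichotomize_amyloid()]) or an `amyloid_status` column with
#' values `positive`/`negative`.
#'
#' @param path Path to the CSV file.
#' @return Cohort data.frame with a factor `amyloid_status`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "subject_id"
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject id(s) in cohort table", call. = FALSE)
  }
  if ("sex" %in% names(df)) {
    df$sex <- factor(df$sex, levels = c("female", "male"))
  }
  if ("abeta42" %in% names(df)) {
    df$amyloid_status <- dichotomize_amyloid(df$abeta42)
  } else if ("amyloid_status" %in% names(df)) {
    df$amyloid_status <- factor(df$amyloid_status,
                                levels = c("negative", "positive"))
    if (anyNA(df$amyloid_status)) {
      stop("amyloid_status must be 'positive' or 'negative'", call. = FALSE)
    }
  } else {
    stop("cohort table needs an `abeta42` or `amyloid_status` column",
         call. = FALSE)
  }
  df
}

#' Write a cohort table to CSV
#' @param x Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(is.data.frame(x), names(x)[1] == "subject_id")
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble a modeling design matrix
#'
#' Joins the acoustic feature table and the cohort table on `subject_id`
#' and returns one of the three input configurations used for modeling:
#' `"neuropsych_demographic"` (13 battery scores + age, sex, education = 16
#' columns), `"acoustic"` (88 columns), or `"acoustic_demographic"` (92
#' columns). Sex is coded 0/1 with female = 1; the response is coded 1 for
#' amyloid positive.
#'
#' In the combined acoustic set, sex enters as the two one-hot indicator
#' columns `sex_female`/`sex_male` (92 columns total); in the
#' neuropsychological set it is the single 0/1 `sex` column (16 columns).
#'
#' @param feature_table Feature table (data.frame, `subject_id` first).
#' @param cohort_table Cohort data.frame with `amyloid_status`.
#' @param feature_set One of `"neuropsych_demographic"`, `"acoustic"`,
#'   `"acoustic_demographic"`.
#' @return List with `x` (numeric matrix, subjects x columns, rownames =
#'   subject ids), `y` (integer 0/1), `feature_names`.
#' @export
assemble_design <- function(feature_table, cohort_table,
                            feature_set = c("acoustic",
                                            "acoustic_demographic",
                                            "neuropsych_demographic")) {
  feature_set <- match.arg(feature_set)
  ids_f <- feature_table$subject_id
  ids_c <- cohort_table$subject_id
  only_f <- setdiff(ids_f, ids_c)
  only_c <- setdiff(ids_c, ids_f)
  if (length(only_f) || length(only_c)) {
    stop("subject ids do not match one-to-one; unmatched: ",
         paste(c(only_f, only_c), collapse = ", "), call. = FALSE)
  }
  cohort_table <- cohort_table[match(ids_f, ids_c), , drop = FALSE]
  demo <- cbind(
    age = cohort_table$age,
    sex = as.integer(cohort_table$sex == "female"),
    education = cohort_table$education
  )
  acoustic_cols <- setdiff(names(feature_table), "subject_id")
  x <- switch(
    feature_set,
    neuropsych_demographic = {
      np <- as.matrix(cohort_table[, neuropsych_schema(), drop = FALSE])
      cbind(np, demo)
    },
    acoustic = as.matrix(feature_table[, acoustic_cols, drop = FALSE]),
    acoustic_demographic = cbind(
      as.matrix(feature_table[, acoustic_cols, drop = FALSE]),
      age = cohort_table$age,
      sex_female = as.integer(cohort_table$sex == "female"),
      sex_male = as.integer(cohort_table$sex == "male"),
      education = cohort_table$education)
  )
  storage.mode(x) <- "double"
  rownames(x) <- ids_f
  y <- as.integer(cohort_table$amyloid_status == "positive")
  list(x = x, y = y, feature_names = colnames(x))
}

#' Pipeline run configuration
#'
#' Bundles everything a full run needs: the feature set, the model, the
#' evaluation scheme and its bootstrap count, seeds, and (optionally) the
#' swarm configuration for wrapper feature selection. The wrapper selector
#' is only offered for feature sets containing acoustic variables; the
#' 16-column neuropsychological/demographic set is modeled without it.
#'
#' @param feature_set One of `"neuropsych_demographic"`, `"acoustic"`,
#'   `"acoustic_demographic"`.
#' @param model A [model_spec()] or a family name accepted by it.
#' @param evaluation `"bootstrap_loocv"` (default) or `"loocv"`.
#' @param n_bootstrap Bootstrap iterations for `bootstrap_loocv`.
#'   Default 5000.
#' @param select When `TRUE`, run the swarm wrapper selector before
#'   modeling. Default `TRUE` for acoustic feature sets with a KNN model.
#' @param swarm Optional [swarm_config()].
#' @param explain When `TRUE`, compute exact Shapley attributions of the
#'   held-out predictions after evaluation (only when the active feature
#'   count is at most 20).
#' @param seed Master seed.
#' @return An object of class `amy_run_config`.
#' @export
run_config <- function(feature_set = "acoustic",
                       model = "knn",
                       evaluation = c("bootstrap_loocv", "loocv"),
                       n_bootstrap = 5000L,
                       select = NULL,
                       swarm = NULL,
                       explain = FALSE,
                       seed = 1L) {
  feature_set <- match.arg(feature_set,
                           c("acoustic", "acoustic_demographic",
                             "neuropsych_demographic"))
  evaluation <- match.arg(evaluation)
  n_bootstrap <- check_count(n_bootstrap, "n_bootstrap", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  if (is.character(model)) model <- model_spec(model, seed = seed)
  if (is.null(select)) {
    select <- feature_set != "neuropsych_demographic" &&
      model$family == "knn"
  }
  if (select && feature_set == "neuropsych_demographic") {
    abort_field("select",
                "wrapper selection is not offered for the neuropsych_demographic set")
  }
  if (is.null(swarm)) swarm <- swarm_config(seed = seed)
  structure(
    list(feature_set = feature_set, model = model, evaluation = evaluation,
         n_bootstrap = n_bootstrap, select = select, swarm = swarm,
         explain = explain, seed = seed),
    class = "amy_run_config"
  )
}
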