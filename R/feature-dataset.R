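#' Feature datasets: subjects x conditions x measures with group labels
#'
#' A `feature_dataset` holds a complete, balanced repeated-measures design:
#' every subject is observed once under each of `k` conditions, and each
#' observation is a vector of `n` numeric measures (e.g. spectral band
#' powers, correlation-dimension estimates).  Subjects carry a group label
#' (patients vs. controls, say); the group factor is what the F-ratio
#' machinery tests.
#'
#' Internally the values live in a 3-d array `[subject, condition, measure]`
#' with a named group vector; [as.data.frame.feature_dataset()] converts to
#' the long format used on disk (one row per subject x condition, one column
#' per measure).
#'
#' @param data a data.frame in long format with columns `subject`, `group`,
#'   `condition` and one numeric column per measure.
#' @param subject_col,group_col,condition_col names of the id columns.
#' @return an object of class `feature_dataset` with elements
#'   `values` (3-d array), `group` (named character vector, one entry per
#'   subject), `subjects`, `conditions`, `measures`.
#' @examples
#' df <- expand.grid(subject = paste0("s", 1:4), condition = c("a", "b"),
#'                   stringsAsFactors = FALSE)
#' df$group <- ifelse(df$subject %in% c("s1", "s2"), "g1", "g2")
#' df$x <- rnorm(nrow(df))
#' fd <- feature_dataset(df)
#' fd
#' @export
feature_dataset <- function(data, subject_col = "subject",
                            group_col = "group",
                            condition_col = "condition") {
  stopifnot(is.data.frame(data))
  id_cols <- c(subject_col, group_col, condition_col)
  missing_cols <- setdiff(id_cols, names(data))
  if (length(missing_cols) > 0L) {
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  measures <- setdiff(names(data), id_cols)
  if (length(measures) < 1L) {
    stop("format error: no measure columns found (need at least one)",
         call. = FALSE)
  }
  for (mcol in measures) {
    v <- data[[mcol]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L) {
        stop("parse error: non-numeric value in measure '", mcol,
             "' at row ", bad[1L], call. = FALSE)
      }
      data[[mcol]] <- vn
    }
  }

  subjects <- unique(as.character(data[[subject_col]]))
  conditions <- unique(as.character(data[[condition_col]]))
  grp_tab <- unique(data.frame(
    subject = as.character(data[[subject_col]]),
    group = as.character(data[[group_col]]),
    stringsAsFactors = FALSE
  ))
  if (anyDuplicated(grp_tab$subject)) {
    dup <- grp_tab$subject[duplicated(grp_tab$subject)][1L]
    stop("validation error: subject '", dup,
         "' is assigned to more than one group", call. = FALSE)
  }
  group <- stats::setNames(grp_tab$group, grp_tab$subject)[subjects]

  # completeness: exactly one row per subject x condition
  key <- paste(data[[subject_col]], data[[condition_col]], sep = "\r")
  expected <- as.vector(outer(subjects, conditions, paste, sep = "\r"))
  missing_cells <- setdiff(expected, key)
  if (anyDuplicated(key) || length(missing_cells) > 0L) {
    miss_lab <- vapply(strsplit(missing_cells, "\r", fixed = TRUE),
                       function(p) paste0("(", p[1L], ", ", p[2L], ")"),
                       character(1L))
    stop("validation error: design is not complete and balanced; ",
         if (length(miss_lab)) paste0("missing cells: ",
                                      paste(utils::head(miss_lab, 5L),
                                            collapse = ", "))
         else "duplicated subject x condition rows",
         call. = FALSE)
  }

  values <- array(NA_real_,
                  dim = c(length(subjects), length(conditions),
                          length(measures)),
                  dimnames = list(subjects, conditions, measures))
  si <- match(as.character(data[[subject_col]]), subjects)
  ci <- match(as.character(data[[condition_col]]), conditions)
  for (j in seq_along(measures)) {
    values[cbind(si, ci, j)] <- data[[measures[j]]]
  }
  if (!all(is.finite(values))) {
    stop("validation error: non-finite measure values present", call. = FALSE)
  }

  new_feature_dataset(values, group)
}

new_feature_dataset <- function(values, group) {
  fd <- structure(
    list(values = values,
         group = group,
         subjects = dimnames(values)[[1L]],
         conditions = dimnames(values)[[2L]],
         measures = dimnames(values)[[3L]]),
    class = "feature_dataset")
  validate_feature_dataset(fd)
}

validate_feature_dataset <- function(fd) {
  stopifnot(inherits(fd, "feature_dataset"))
  if (length(fd$measures) < 1L) {
    stop("validation error: dataset must contain at least one measure",
         call. = FALSE)
  }
  if (length(fd$conditions) < 1L) {
    stop("validation error: dataset must contain at least one condition",
         call. = FALSE)
  }
  tab <- table(fd$group)
  if (any(tab < 2L)) {
    stop("validation error: every group needs at least 2 subjects",
         call. = FALSE)
  }
  if (!all(is.finite(fd$values))) {
    stop("validation error: non-finite measure values present", call. = FALSE)
  }
  fd
}

#' Read a feature table from a CSV file
#'
#' The expected dialect is comma-separated UTF-8 text with a header row,
#' columns `subject`, `group`, `condition`, plus one numeric column per
#' measure, and one row per subject x condition.  Row order is irrelevant.
#'
#' @param path path to a CSV file.
#' @inheritParams feature_dataset
#' @return a [feature_dataset()].
#' @export
read_feature_table <- function(path, subject_col = "subject",
                               group_col = "group",
                               condition_col = "condition") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  feature_dataset(df, subject_col = subject_col, group_col = group_col,
                  condition_col = condition_col)
}

#' Write a feature table to CSV
#'
#' Emits the long format of [read_feature_table()]: rows ordered by subject
#' then condition, measure columns in sorted name order (deterministic
#' output for identical datasets).
#'
#' @param fd a [feature_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fd, path) {
  validate_feature_dataset(fd)
  df <- as.data.frame(fd)
  df <- df[order(match(df$subject, fd$subjects),
                 match(df$condition, fd$conditions)), ]
  meas <- sort(fd$measures)
  df <- df[, c("subject", "group", "condition", meas)]
  # full double precision so read o write is the identity
  for (m in meas) df[[m]] <- sprintf("%.17g", df[[m]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.feature_dataset <- function(x, ...) {
  S <- length(x$subjects); k <- length(x$conditions)
  df <- data.frame(
    subject = rep(x$subjects, times = k),
    group = rep(unname(x$group), times = k),
    condition = rep(x$conditions, each = S),
    stringsAsFactors = FALSE)
  for (j in seq_along(x$measures)) {
    df[[x$measures[j]]] <- as.vector(x$values[, , j])
  }
  df
}

#' Restrict a dataset to a subset of measures and/or conditions
#'
#' Returns a new, still complete and balanced `feature_dataset` containing
#' only the requested measures and conditions.  Restriction is idempotent
#' and selections on the two axes commute.
#'
#' @param fd a [feature_dataset()].
#' @param measures character vector of measure names to keep (default: all).
#' @param conditions character vector of condition labels to keep
#'   (default: all).
#' @param subjects character vector of subject ids to keep (default: all);
#'   mainly used internally by the resampling engine.
#' @return a [feature_dataset()].
#' @export
restrict <- function(fd, measures = NULL, conditions = NULL,
                     subjects = NULL) {
  validate_feature_dataset(fd)
  measures <- if (is.null(measures)) fd$measures else as.character(measures)
  conditions <- if (is.null(conditions)) fd$conditions
                else as.character(conditions)
  subjects <- if (is.null(subjects)) fd$subjects else as.character(subjects)
  unknown <- c(setdiff(measures, fd$measures),
               setdiff(conditions, fd$conditions),
               setdiff(subjects, fd$subjects))
  if (length(unknown) > 0L) {
    stop("unknown name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(measures) || anyDuplicated(conditions) ||
      anyDuplicated(subjects)) {
    stop("duplicated names in selection", call. = FALSE)
  }
  values <- fd$values[subjects, conditions, measures, drop = FALSE]
  new_feature_dataset(values, fd$group[subjects])
}

#' Number of subjects, conditions, measures and groups
#' @param fd a [feature_dataset()].
#' @return a named integer vector with elements `subjects`, `conditions`,
#'   `measures`, `groups`.
#' @export
dataset_dims <- function(fd) {
  c(subjects = length(fd$subjects),
    conditions = length(fd$conditions),
    measures = length(fd$measures),
    groups = length(unique(fd$group)))
}

#' @export
print.feature_dataset <- function(x, ...) {
  d <- dataset_dims(x)
  cat("Feature dataset: ", d["subjects"], " subjects in ", d["groups"],
      " groups x ", d["conditions"], " conditions x ", d["measures"],
      " measures\n", sep = "")
  cat("  groups:    ", paste(sprintf("%s (n=%d)",
                                     names(table(x$group)),
                                     as.integer(table(x$group))),
                             collapse = ", "), "\n", sep = "")
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  measures:  ", paste(x$measures, collapse = ", "), "\n")
  invisible(x)
}
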