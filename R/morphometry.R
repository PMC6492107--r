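covariate_cols <- c("subject_id", "age", "sex", "group", "dataset")

#' Construct a validated morphometry table
#'
#' A morphometry table holds one row per subject: the covariates
#' `subject_id`, `age` (integer years), `sex` (`"M"`/`"F"`), `group`
#' (e.g. `"HC"`, `"SCZ"`), `dataset` (cohort label), followed by the regional
#' features in schema order (thickness in mm, volume in mm^3).
#'
#' Rows whose age falls outside `age_range` are dropped with a message; this
#' mirrors the cohort inclusion rule of the normative reference (ages 22-37).
#'
#' @param df Data frame with the covariate columns and all schema features.
#' @param schema A `feature_schema`; features are reordered to schema order.
#' @param age_range Inclusive integer age range; rows outside it are dropped.
#'   Use `NULL` to disable filtering.
#' @return A `morphometry_table` (data frame with `schema` attribute).
#' @export
as_morphometry_table <- function(df, schema = default_schema(),
                                 age_range = c(22L, 37L)) {
  missing <- setdiff(covariate_cols, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  missing_feat <- setdiff(schema$name, names(df))
  if (length(missing_feat) > 0) {
    stop("missing feature column(s): ",
         paste(utils::head(missing_feat, 5), collapse = ", "),
         if (length(missing_feat) > 5) sprintf(" (+%d more)", length(missing_feat) - 5))
  }
  df <- df[c(covariate_cols, schema$name)]
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  }
  if (!all(df$sex %in% c("M", "F"))) {
    stop("sex must be coded 'M' or 'F'")
  }
  if (any(!is.finite(df$age)) || any(df$age != round(df$age))) {
    stop("age must be integer years")
  }
  df$age <- as.integer(df$age)
  for (nm in schema$name) {
    v <- df[[nm]]
    if (!is.numeric(v)) {
      bad <- suppressWarnings(is.na(as.numeric(as.character(v))))
      stop(sprintf("non-numeric values in feature '%s' (e.g. row %s)",
                   nm, df$subject_id[which(bad)[1]]))
    }
    if (anyNA(v)) {
      stop(sprintf("missing values in feature '%s' (e.g. subject %s)",
                   nm, df$subject_id[which(is.na(v))[1]]))
    }
    df[[nm]] <- as.numeric(v)
  }
  if (!is.null(age_range)) {
    keep <- df$age >= age_range[1] & df$age <= age_range[2]
    if (any(!keep)) {
      message(sprintf("dropped %d subject(s) outside age range [%d, %d]",
                      sum(!keep), age_range[1], age_range[2]))
      df <- df[keep, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  attr(df, "schema") <- schema
  class(df) <- c("morphometry_table", "data.frame")
  df
}

#' Read a morphometry table
#'
#' Two dialects are supported. `"tidy_csv"` is the canonical format: one CSV
#' with columns `subject_id,age,sex,group,dataset,<feature names>`.
#' `"freesurfer_tsv"` joins the tab-separated tables written by FreeSurfer's
#' `aparcstats2table` (one per hemisphere) and `asegstats2table` with a
#' covariates CSV, on subject id.
#'
#' @param path For `"tidy_csv"`, the CSV path. For `"freesurfer_tsv"`, a named
#'   list with elements `lh`, `rh` (aparc thickness tables), `aseg`
#'   (volume table) and `covariates` (CSV with `subject_id,age,sex,group,dataset`).
#' @param schema A `feature_schema`.
#' @param dialect `"tidy_csv"` or `"freesurfer_tsv"`.
#' @param age_range Inclusive age filter (see [as_morphometry_table()]).
#' @return A `morphometry_table`.
#' @export
read_morphometry <- function(path, schema = default_schema(),
                             dialect = c("tidy_csv", "freesurfer_tsv"),
                             age_range = c(22L, 37L)) {
  dialect <- match.arg(dialect)
  if (dialect == "tidy_csv") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    need <- c("lh", "rh", "aseg", "covariates")
    if (!is.list(path) || !all(need %in% names(path))) {
      stop("freesurfer_tsv dialect needs a list with elements: ",
           paste(need, collapse = ", "))
    }
    for (p in unlist(path)) if (!file.exists(p)) stop("file not found: ", p)
    read_fs <- function(p) {
      tb <- utils::read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
      names(tb)[1] <- "subject_id"  # first column header varies by exporter
      tb$subject_id <- as.character(tb$subject_id)
      tb
    }
    lh <- read_fs(path$lh)
    rh <- read_fs(path$rh)
    aseg <- read_fs(path$aseg)
    cov <- utils::read.csv(path$covariates, stringsAsFactors = FALSE,
                           check.names = FALSE)
    cov$subject_id <- as.character(cov$subject_id)
    df <- Reduce(function(a, b) merge(a, b, by = "subject_id"),
                 list(cov, lh, rh, aseg))
  }
  as_morphometry_table(df, schema = schema, age_range = age_range)
}

#' Write a morphometry table as tidy CSV
#' @param table A `morphometry_table`.
#' @param path Output CSV path.
#' @export
write_morphometry <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the subjects x features matrix from a morphometry table
#' @param table A `morphometry_table`.
#' @return Numeric matrix (subjects x features) in schema order, with
#'   subject ids as row names.
#' @export
feature_matrix <- function(table) {
  schema <- table_schema(table)
  m <- as.matrix(as.data.frame(table)[schema$name])
  rownames(m) <- table$subject_id
  m
}

table_schema <- function(table) {
  schema <- attr(table, "schema")
  if (is.null(schema)) stop("not a morphometry_table: schema attribute missing")
  schema
}

#' @export
print.morphometry_table <- function(x, ...) {
  sch <- attr(x, "schema")
  cat(sprintf("<morphometry_table> %d subjects, %d features\n", nrow(x), nrow(sch)))
  grp <- table(x$group, x$dataset)
  print(grp)
  invisible(x)
}

# subset methods keep the schema attribute attached
#' @export
`[.morphometry_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c(covariate_cols) %in% names(out))) {
    attr(out, "schema") <- attr(x, "schema")
    class(out) <- c("morphometry_table", "data.frame")
  }
  out
}
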