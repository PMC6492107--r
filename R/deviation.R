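#' Total deviation metric of one subject
#'
#' The mean squared reconstruction error over all regions:
#' `mean((x - xhat)^2)`, computed on normalized features. This is the
#' subject's total neuroanatomical deviation from the normative reference.
#'
#' @param x Normalized feature vector.
#' @param xhat Reconstructed feature vector of the same length.
#' @return Non-negative scalar.
#' @export
deviation_metric <- function(x, xhat) {
  if (length(x) != length(xhat)) stop("x and xhat must have equal length")
  mean((x - xhat)^2)
}

#' Per-subject deviation metrics and regional deviation maps
#'
#' Runs a cohort through the trained model and returns, per subject, the
#' total deviation metric and the per-region squared reconstruction errors
#' (the subject's regional deviation map). The total metric is exactly the
#' mean of the regional errors.
#'
#' @param model A `normative_model`.
#' @param table A `morphometry_table`.
#' @param normalization Optional override of the model's frozen normalization
#'   (see [reconstruct()]).
#' @return A `deviation_result`: data frame with `subject_id`, `group`,
#'   `dataset`, `deviation_metric`, and a `regional_errors` attribute
#'   (subjects x regions matrix of squared errors).
#' @export
compute_deviations <- function(model, table, normalization = NULL) {
  rec <- reconstruct(model, table, normalization)
  sq <- (rec$x - rec$xhat)^2
  rownames(sq) <- table$subject_id
  out <- data.frame(subject_id = table$subject_id, group = table$group,
                    dataset = table$dataset,
                    deviation_metric = rowMeans(sq),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "regional_errors") <- sq
  class(out) <- c("deviation_result", "data.frame")
  out
}

#' Regional squared errors of a deviation result
#' @param dev A `deviation_result`.
#' @return Subjects x regions matrix of squared reconstruction errors.
#' @export
regional_errors <- function(dev) {
  m <- attr(dev, "regional_errors")
  if (is.null(m)) stop("not a deviation_result: regional_errors missing")
  if (nrow(m) != nrow(dev)) {
    stop("regional_errors out of sync with the subject rows")
  }
  m
}

# row subsets carry the matching rows of the regional-error matrix along
#' @export
`[.deviation_result` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "subject_id" %in% names(out)) {
    re <- attr(x, "regional_errors")
    attr(out, "regional_errors") <-
      re[match(out$subject_id, rownames(re)), , drop = FALSE]
    class(out) <- c("deviation_result", "data.frame")
  }
  out
}

#' Write a deviation result as CSV
#'
#' One row per subject: covariate columns, the total deviation metric, then
#' the per-region squared errors.
#'
#' @param dev A `deviation_result`.
#' @param path Output CSV path.
#' @export
write_deviations <- function(dev, path) {
  out <- cbind(as.data.frame(dev), as.data.frame(regional_errors(dev),
                                                 optional = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a deviation result written by [write_deviations()]
#' @param path CSV path.
#' @return A `deviation_result`.
#' @export
read_deviations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("subject_id", "group", "dataset", "deviation_metric")
  sq <- as.matrix(df[setdiff(names(df), meta)])
  rownames(sq) <- df$subject_id
  out <- df[meta]
  attr(out, "regional_errors") <- sq
  class(out) <- c("deviation_result", "data.frame")
  out
}

#' @export
print.deviation_result <- function(x, ...) {
  cat(sprintf("<deviation_result> %d subjects, %d regions\n",
              nrow(x), ncol(regional_errors(x))))
  print(stats::aggregate(deviation_metric ~ group + dataset,
                         as.data.frame(x), stats::median))
  invisible(x)
}
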