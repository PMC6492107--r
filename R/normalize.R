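#' Fit zero-mean unit-variance normalization on a reference table
#'
#' Computes the per-feature mean and population standard deviation (divide by
#' n) of the reference cohort. These parameters are frozen with the trained
#' model and re-used, unchanged, to normalize every test cohort, so that
#' deviations are always measured on the reference scale.
#'
#' Features with (near-)zero variance get their SD floored at `sd_floor` with
#' a warning, so that degenerate synthetic inputs cannot produce divisions by
#' zero.
#'
#' @param table A `morphometry_table` with at least 2 subjects.
#' @param sd_floor Minimum admissible SD.
#' @return A `normalization_params` list: `mean`, `sd` (named vectors in
#'   schema order) and `source` (the reference dataset label).
#' @export
fit_normalization <- function(table, sd_floor = 1e-8) {
  x <- feature_matrix(table)
  if (nrow(x) < 2) stop("need at least 2 subjects to fit normalization")
  mu <- colMeans(x)
  n <- nrow(x)
  sdv <- sqrt(colMeans(x^2) - mu^2)
  sdv[!is.finite(sdv)] <- 0
  degenerate <- sdv < sd_floor
  if (any(degenerate)) {
    warning(sprintf("%d feature(s) with (near-)zero variance; SD floored at %g (e.g. '%s')",
                    sum(degenerate), sd_floor, names(which(degenerate))[1]))
    sdv[degenerate] <- sd_floor
  }
  structure(list(mean = mu, sd = sdv,
                 source = paste(unique(table$dataset), collapse = "+")),
            class = "normalization_params")
}

#' Apply reference normalization to a table
#'
#' Computes `z = (x - mean) / sd` using the *reference* parameters; test data
#' are never re-standardized on their own statistics.
#'
#' @param table A `morphometry_table` (or a numeric feature matrix in schema
#'   order).
#' @param params `normalization_params` from [fit_normalization()].
#' @return Numeric matrix of normalized features (subjects x features).
#' @export
apply_normalization <- function(table, params) {
  x <- if (is.matrix(table)) table else feature_matrix(table)
  if (ncol(x) != length(params$mean)) {
    stop("feature count mismatch between table and normalization params")
  }
  if (!is.null(colnames(x)) && !identical(colnames(x), names(params$mean))) {
    stop("feature order mismatch between table and normalization params")
  }
  sweep(sweep(x, 2, params$mean, "-"), 2, params$sd, "/")
}

#' Invert reference normalization
#' @param z Normalized matrix (subjects x features).
#' @param params `normalization_params`.
#' @return Matrix on the original measurement scale.
#' @export
invert_normalization <- function(z, params) {
  sweep(sweep(z, 2, params$sd, "*"), 2, params$mean, "+")
}

#' Serialize normalization parameters to JSON
#'
#' Written as a feature-name -> \{mean, sd\} map plus the reference source id.
#'
#' @param params `normalization_params`.
#' @param path Output JSON path.
#' @export
write_normalization <- function(params, path) {
  per_feature <- mapply(function(m, s) list(mean = m, sd = s),
                        params$mean, params$sd, SIMPLIFY = FALSE)
  jsonlite::write_json(list(source = params$source, features = per_feature),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read normalization parameters from JSON
#' @param path JSON path written by [write_normalization()].
#' @return `normalization_params`.
#' @export
read_normalization <- function(path) {
  obj <- jsonlite::read_json(path)
  mu <- vapply(obj$features, function(f) f$mean, numeric(1))
  sdv <- vapply(obj$features, function(f) f$sd, numeric(1))
  structure(list(mean = mu, sd = sdv, source = obj$source),
            class = "normalization_params")
}

#' @export
print.normalization_params <- function(x, ...) {
  cat(sprintf("<normalization_params> %d features, source: %s\n",
              length(x$mean), x$source))
  invisible(x)
}
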