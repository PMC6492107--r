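#' Two-sample Mann-Whitney U test
#'
#' The U statistic counts pairs where a value from `a` exceeds a value from
#' `b`, with half credit for ties. The two-sided p-value uses the exact null
#' distribution of U when `length(a) * length(b) <= 400` and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' corrections is used. The branch taken is reported in `method`.
#'
#' @param a,b Non-empty numeric samples.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) branch;
#'   `NULL` (default) applies the size/ties rule above. The exact branch is
#'   unavailable with ties.
#' @return List with `u`, `p` (two-sided), `method` (`"exact"` or
#'   `"normal_approx"`), and the sample sizes.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be nonempty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (is.null(exact)) exact <- (na * nb <= 400) && !has_ties
  if (exact && has_ties) {
    stop("exact p-value unavailable with ties; use exact = FALSE")
  }
  if (exact) {
    # exact null distribution of U (all rank arrangements equally likely)
    p <- if (u > na * nb / 2) {
      2 * stats::pwilcox(u - 1, na, nb, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, na, nb)
    }
    method <- "exact"
  } else {
    mu <- na * nb / 2
    n <- na + nb
    sigma2 <- (na * nb / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    d <- u - mu
    d <- d - sign(d) * 0.5  # continuity correction toward the mean
    # a fully tied pooled sample carries no evidence at all
    p <- if (sigma2 <= 0) 1 else 2 * stats::pnorm(-abs(d / sqrt(sigma2)))
    method <- "normal_approx"
  }
  list(u = u, p = min(p, 1), method = method, n_a = na, n_b = nb)
}

#' Cliff's delta effect size
#'
#' The probability difference that a value from `a` exceeds one from `b`:
#' `delta = (#\{a_i > b_j\} - #\{a_i < b_j\}) / (n_a n_b)`, in \[-1, 1\].
#' Computed through the tie-corrected U statistic, which gives the identical
#' value without the O(n^2) pair enumeration.
#'
#' @param a,b Non-empty numeric samples.
#' @return Signed scalar in \[-1, 1\].
#' @export
cliffs_delta <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be nonempty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  2 * u / (na * nb) - 1
}

check_same_dataset <- function(dev_a, dev_b) {
  ds <- unique(c(dev_a$dataset, dev_b$dataset))
  if (length(ds) != 1) {
    stop("groups come from different datasets (", paste(ds, collapse = ", "),
         "); comparisons are restricted to groups from the same dataset ",
         "to avoid site and scanner effects")
  }
  invisible(ds)
}

#' Group comparison of total deviation metrics
#'
#' Compares the total deviation metric of two groups from the same dataset
#' with the two-tailed Mann-Whitney U test, and reports Cliff's delta
#' (signed, `a` vs `b`) with its absolute value, plus per-group mean, SD and
#' median. The deviation metric is typically right-skewed, hence the
#' rank-based test on medians.
#'
#' @param dev_a,dev_b `deviation_result`s of the two groups (e.g. patients
#'   and healthy controls) from the same dataset.
#' @param exact Passed to [mann_whitney_u()].
#' @return A `group_comparison` list.
#' @export
compare_groups <- function(dev_a, dev_b, exact = NULL) {
  check_same_dataset(dev_a, dev_b)
  a <- dev_a$deviation_metric
  b <- dev_b$deviation_metric
  mw <- mann_whitney_u(a, b, exact = exact)
  delta <- cliffs_delta(a, b)
  summarize <- function(x, label) {
    list(group = label, n = length(x), mean = mean(x), sd = stats::sd(x),
         median = stats::median(x))
  }
  structure(list(
    group_a = summarize(a, paste(unique(dev_a$group), collapse = "+")),
    group_b = summarize(b, paste(unique(dev_b$group), collapse = "+")),
    u = mw$u, p = mw$p, method = mw$method,
    cliffs_delta = delta, abs_cliffs_delta = abs(delta)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(g) sprintf("%s (n=%d): mean %.3f +/- %.3f, median %.3f",
                             g$group, g$n, g$mean, g$sd, g$median)
  cat("<group_comparison>\n  ", fmt(x$group_a), "\n  ", fmt(x$group_b), "\n",
      sprintf("  U = %.1f, two-sided p = %.4g (%s), Cliff's delta = %.4f\n",
              x$u, x$p, x$method, x$cliffs_delta))
  invisible(x)
}

regional_table <- function(mat_a, mat_b, region_names, threshold, exact) {
  stats_list <- lapply(seq_along(region_names), function(i) {
    mw <- mann_whitney_u(mat_a[, i], mat_b[, i], exact = exact)
    c(u = mw$u, p = mw$p, delta = cliffs_delta(mat_a[, i], mat_b[, i]))
  })
  st <- do.call(rbind, stats_list)
  out <- data.frame(region = region_names, u = st[, "u"], p = st[, "p"],
                    abs_cliffs_delta = abs(st[, "delta"]),
                    significant = st[, "p"] < threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_cliffs_delta), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("regional_comparison", "data.frame")
  out
}

#' Region-wise comparison of deviation maps
#'
#' Compares each region's squared reconstruction error between two groups
#' from the same dataset with the Mann-Whitney U test, reporting |Cliff's
#' delta| as the magnitude of regional deviation. Regions are flagged
#' significant at a conservative uncorrected threshold (default p < .01,
#' an expected false-positive rate of 1%; no Bonferroni-style correction,
#' since neighbouring and homotopic regions are correlated). Output sorted
#' by |Cliff's delta|, largest first.
#'
#' @param dev_a,dev_b `deviation_result`s of the two groups.
#' @param threshold Significance threshold on the per-region p-value.
#' @param exact Passed to [mann_whitney_u()].
#' @return A `regional_comparison` data frame: `region`, `u`, `p`,
#'   `abs_cliffs_delta`, `significant`.
#' @export
regional_comparison <- function(dev_a, dev_b, threshold = 0.01, exact = NULL) {
  check_same_dataset(dev_a, dev_b)
  ea <- regional_errors(dev_a)
  eb <- regional_errors(dev_b)
  regional_table(ea, eb, colnames(ea), threshold, exact)
}

#' Mass-univariate comparison on the original features
#'
#' Applies the identical region-wise statistics (Mann-Whitney U, |Cliff's
#' delta|, uncorrected threshold) directly to the raw feature values, without
#' the normative model. This is the classical univariate analysis the
#' deviation mapping is contrasted against: it is blind to alterations that
#' only change a region's correlation with other regions.
#'
#' @param table_a,table_b `morphometry_table`s of the two groups (same
#'   schema).
#' @param threshold Significance threshold.
#' @param exact Passed to [mann_whitney_u()].
#' @return A `regional_comparison` data frame.
#' @export
mass_univariate <- function(table_a, table_b, threshold = 0.01, exact = NULL) {
  sa <- table_schema(table_a)
  sb <- table_schema(table_b)
  if (!identical(sa$name, sb$name)) stop("tables have different schemas")
  regional_table(feature_matrix(table_a), feature_matrix(table_b),
                 sa$name, threshold, exact)
}

#' @export
print.regional_comparison <- function(x, ...) {
  cat(sprintf("<regional_comparison> %d regions, %d significant at p < %g\n",
              nrow(x), sum(x$significant), attr(x, "threshold")))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more regions\n")
  invisible(x)
}
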