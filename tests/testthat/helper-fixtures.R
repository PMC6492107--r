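# Shared fixtures: small cohorts and reduced model configs keep unit tests
# fast; sizes are scaled up only where a statistical check needs them.

small_cohort <- function(seed = 1, n_ref = 150, n_hc = 40, n_pat = 40, ...) {
  generate_cohort(cohort_spec(n_reference = n_ref, n_controls = n_hc,
                              n_patients = n_pat, seed = seed, ...))
}

tiny_config <- function(epochs = 30, seed = 1, ...) {
  model_config(h1_units = 30, z_units = 15, h2_units = 30, epochs = epochs,
               batch_size = 32, seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fresh file path in a throwaway directory under the session tempdir
withr_local_file <- function(name) {
  d <- tempfile("fixture")
  dir.create(d)
  file.path(d, name)
}

# a hand-made deviation_result, for statistics tests that need controlled
# regional error patterns
forge_deviations <- function(errors, group, dataset = "clinical") {
  stopifnot(is.matrix(errors))
  if (is.null(colnames(errors))) {
    colnames(errors) <- sprintf("region%03d", seq_len(ncol(errors)))
  }
  ids <- sprintf("s%04d", seq_len(nrow(errors)))
  rownames(errors) <- ids
  out <- data.frame(subject_id = ids, group = group, dataset = dataset,
                    deviation_metric = rowMeans(errors),
                    stringsAsFactors = FALSE)
  attr(out, "regional_errors") <- errors
  class(out) <- c("deviation_result", "data.frame")
  out
}

# independent brute-force oracles -------------------------------------------

# exact two-sided Mann-Whitney p by enumerating all C(n, na) group assignments
mw_enumerate <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_stat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(seq_len(na))
  us <- apply(utils::combn(na + nb, na), 2, u_stat)
  mu <- na * nb / 2
  # two-sided: arrangements at least as extreme (as far from the mean)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

cliff_brute <- function(a, b) {
  (sum(outer(a, b, ">")) - sum(outer(a, b, "<"))) / (length(a) * length(b))
}

auc_brute <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

xcov_brute <- function(z, y) {
  n <- nrow(z)
  acc <- 0
  for (i in seq_len(ncol(z))) {
    for (j in seq_len(ncol(y))) {
      cij <- sum((z[, i] - mean(z[, i])) * (y[, j] - mean(y[, j]))) / n
      acc <- acc + cij^2
    }
  }
  0.5 * acc
}
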