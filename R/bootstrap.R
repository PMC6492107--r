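#' Area under the ROC curve from scores
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with half credit for ties (rank formulation of the
#' AUC-ROC).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default soft-margin grid for the linear SVM
#'
#' Powers of two with odd exponents from -15 to 15 (16 values).
#' @return Numeric vector of C values.
#' @export
default_c_grid <- function() 2^seq(-15, 15, by = 2)

#' Bootstrap evaluation specification
#'
#' @param n_reps Bootstrap repetitions.
#' @param train_fraction Fraction of subjects defining the bootstrap training
#'   set size (drawn with replacement; out-of-bag subjects form the test set).
#' @param c_grid Candidate soft-margin values for the SVM grid search.
#' @param cv_folds Stratified CV folds for the grid search.
#' @param ci_level Percentile confidence level.
#' @param seed Master seed; every repetition derives its own sub-seed.
#' @return A `bootstrap_spec` list.
#' @export
bootstrap_spec <- function(n_reps = 1000, train_fraction = 0.7,
                           c_grid = default_c_grid(), cv_folds = 10,
                           ci_level = 0.95, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (length(c_grid) == 0) stop("c_grid must be nonempty")
  structure(list(n_reps = as.integer(n_reps), train_fraction = train_fraction,
                 c_grid = sort(as.numeric(c_grid)),
                 cv_folds = as.integer(cv_folds),
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "bootstrap_spec")
}

performance_distribution <- function(auc_samples, method, ci_level) {
  alpha <- (1 - ci_level) / 2
  ci <- unname(stats::quantile(auc_samples, c(alpha, 1 - alpha)))
  structure(list(auc_samples = auc_samples,
                 median = stats::median(auc_samples),
                 ci_low = ci[1], ci_high = ci[2],
                 ci_level = ci_level, method = method),
            class = "performance_distribution")
}

#' @export
print.performance_distribution <- function(x, ...) {
  cat(sprintf("<performance_distribution> %s: median AUC %.3f (%d%% CI [%.3f, %.3f], %d reps)\n",
              x$method, x$median, round(100 * x$ci_level), x$ci_low,
              x$ci_high, length(x$auc_samples)))
  invisible(x)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

balanced_accuracy <- function(truth, pred) {
  mean(vapply(unique(truth), function(cls) {
    mean(pred[truth == cls] == cls)
  }, numeric(1)))
}

# Choose C by stratified k-fold CV on the (bootstrap) training set,
# maximizing mean balanced accuracy; ties go to the smallest C.
select_svm_cost <- function(X, y, c_grid, k, class_weights) {
  k_eff <- min(k, min(table(y)))
  fold <- stratified_folds(y, k_eff)
  cw <- if (class_weights) {
    tab <- table(y)
    stats::setNames(as.numeric(sum(tab) / (length(tab) * tab)), names(tab))
  } else NULL
  scores <- vapply(c_grid, function(cost) {
    accs <- vapply(seq_len(k_eff), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || sum(!tr) == 0) return(NA_real_)
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = cost, scale = FALSE, class.weights = cw)
      balanced_accuracy(y[!tr], stats::predict(fit, X[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  c_grid[which.max(scores)]  # which.max takes the first (smallest C) on ties
}

#' Bootstrap AUC distribution of a linear SVM classifier
#'
#' The classical case-control baseline: per repetition, a bootstrap training
#' set of `floor(train_fraction * n)` subjects is drawn with replacement from
#' the clinical cohort, the out-of-bag subjects form the test set, the
#' soft-margin C is selected by stratified k-fold cross-validation on the
#' training set (maximizing mean balanced accuracy over `c_grid`), the linear
#' SVM is refit on the full bootstrap training set, and the test subjects are
#' scored for the patient class. Features are normalized with the *reference*
#' cohort parameters for consistency with the normative model.
#'
#' Repetitions whose out-of-bag set lacks a class are redrawn (and counted in
#' `n_redrawn`). The test score defaults to the decision margin, whose AUC
#' equals that of calibrated probabilities up to monotonicity;
#' `score = "probability"` uses Platt-calibrated probabilities instead.
#'
#' @param clinical A `morphometry_table` with control and patient groups.
#' @param reference_norm `normalization_params` fit on the healthy reference.
#' @param spec A `bootstrap_spec`.
#' @param control_label Group label of the controls (default `"HC"`); every
#'   other group is treated as the patient class.
#' @param score `"margin"` or `"probability"`.
#' @param class_weights Inverse-frequency class weighting (default off).
#' @param permute_labels Permute the group labels freshly within every
#'   repetition. This is the chance reference: the resulting AUC distribution
#'   is centred on 0.5 by construction, whereas a single fixed shuffle would
#'   only recentre the distribution on that shuffle's realized chance AUC.
#' @return A `performance_distribution` (method `"svm"`).
#' @export
bootstrap_svm_auc <- function(clinical, reference_norm, spec = bootstrap_spec(),
                              control_label = "HC",
                              score = c("margin", "probability"),
                              class_weights = FALSE, permute_labels = FALSE) {
  score <- match.arg(score)
  X <- apply_normalization(clinical, reference_norm)
  y_obs <- factor(ifelse(clinical$group == control_label, "HC", "PAT"),
                  levels = c("HC", "PAT"))
  if (length(unique(y_obs)) < 2) stop("clinical table needs both classes")
  n <- nrow(X)
  n_train <- floor(spec$train_fraction * n)
  seeds <- derive_seeds(spec$seed, spec$n_reps)
  n_redrawn <- 0L
  aucs <- vapply(seq_len(spec$n_reps), function(rep_i) {
    with_seed(seeds[rep_i], {
      y <- if (permute_labels) sample(y_obs) else y_obs
      repeat {
        tr <- sample.int(n, n_train, replace = TRUE)
        te <- setdiff(seq_len(n), unique(tr))
        if (length(unique(y[tr])) == 2 && length(unique(y[te])) == 2) break
        n_redrawn <<- n_redrawn + 1L
      }
      cost <- select_svm_cost(X[tr, , drop = FALSE], y[tr], spec$c_grid,
                              spec$cv_folds, class_weights)
      cw <- if (class_weights) {
        tab <- table(y[tr])
        stats::setNames(as.numeric(sum(tab) / (length(tab) * tab)), names(tab))
      } else NULL
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = cost, scale = FALSE, class.weights = cw,
                        probability = (score == "probability"))
      if (score == "probability") {
        pr <- stats::predict(fit, X[te, , drop = FALSE], probability = TRUE)
        s <- attr(pr, "probabilities")[, "PAT"]
      } else {
        dv <- attr(stats::predict(fit, X[te, , drop = FALSE],
                                  decision.values = TRUE), "decision.values")
        # orient the margin so that larger = more patient-like
        s <- dv[, 1] * if (colnames(dv)[1] == "HC/PAT") -1 else 1
      }
      auc_from_scores(s, y[te] == "PAT")
    })
  }, numeric(1))
  if (n_redrawn > 0) {
    message(sprintf("redrew %d bootstrap sample(s) with a single-class split",
                    n_redrawn))
  }
  performance_distribution(aucs, "svm", spec$ci_level)
}

#' Bootstrap AUC distribution of the normative deviation score
#'
#' Per repetition, the healthy reference cohort is resampled with replacement
#' (same size), the normative autoencoder is retrained on the resample, the
#' clinical cohort is normalized with the *original* reference parameters
#' (not the resample's), every clinical subject is scored by the total
#' deviation metric, and the AUC against the true group labels is recorded.
#'
#' @param reference Healthy reference `morphometry_table`.
#' @param clinical Clinical `morphometry_table` (controls + patients).
#' @param config A `model_config` (use reduced `epochs` for tractable
#'   runs; the per-repetition seed is derived from `spec$seed`).
#' @param spec A `bootstrap_spec`.
#' @param control_label Group label of the controls.
#' @param coding A `label_coding`.
#' @param permute_labels Permute the group labels freshly within every
#'   repetition (chance reference; see [bootstrap_svm_auc()]).
#' @return A `performance_distribution` (method `"normative"`).
#' @export
bootstrap_normative_auc <- function(reference, clinical,
                                    config = model_config(),
                                    spec = bootstrap_spec(),
                                    control_label = "HC",
                                    coding = label_coding(),
                                    permute_labels = FALSE) {
  original_norm <- fit_normalization(reference)
  is_patient <- clinical$group != control_label
  if (all(is_patient) || !any(is_patient)) {
    stop("clinical table needs both classes")
  }
  n <- nrow(reference)
  seeds <- derive_seeds(spec$seed, spec$n_reps)
  cfg <- config
  aucs <- vapply(seq_len(spec$n_reps), function(rep_i) {
    drawn <- with_seed(seeds[rep_i], list(
      idx = sample.int(n, n, replace = TRUE),
      labels = if (permute_labels) sample(is_patient) else is_patient))
    boot_ref <- reference[drawn$idx, ]
    boot_ref$subject_id <- sprintf("boot%05d", seq_along(drawn$idx))
    cfg$seed <- seeds[rep_i] %% .Machine$integer.max
    fit <- train_normative(boot_ref, cfg, coding)
    dev <- compute_deviations(fit, clinical, normalization = original_norm)
    auc_from_scores(dev$deviation_metric, drawn$labels)
  }, numeric(1))
  performance_distribution(aucs, "normative", spec$ci_level)
}
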