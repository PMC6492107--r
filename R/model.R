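#' Autoencoder model configuration
#'
#' Hyperparameters of the semi-supervised denoising autoencoder. Defaults
#' reproduce the reference configuration: a 104-100-75-100-104 network with
#' SELU hidden layers, L2 coefficient 1e-3 on weight matrices, additive
#' Gaussian input corruption with SD 0.1 (on normalized features), 2000
#' epochs of Adam in mini-batches of 64, with a per-epoch exponential
#' learning-rate decay from 0.05 down to 0.0005 at the final epoch.
#'
#' @param input_dim Number of input features.
#' @param h1_units,z_units,h2_units Hidden layer widths; `z_units` (the
#'   latent bottleneck) must be smaller than `h1_units`.
#' @param l2_coefficient L2 penalty on weight matrices (biases excluded).
#' @param corruption_sd SD of the additive Gaussian corruption noise applied
#'   to normalized inputs during training; 0 disables denoising.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size (remainder batch kept).
#' @param lr_initial,lr_final Adam learning rate at the first/last epoch;
#'   decay is multiplicative per epoch.
#' @param loss_weights Length-4 weights for the reconstruction, age
#'   cross-entropy, sex cross-entropy, and XCov terms.
#' @param seed Integer seed controlling initialization, shuffling and
#'   corruption noise.
#' @return A `model_config` list.
#' @export
model_config <- function(input_dim = 104L, h1_units = 100L, z_units = 75L,
                         h2_units = 100L, l2_coefficient = 1e-3,
                         corruption_sd = 0.1, epochs = 2000L,
                         batch_size = 64L, lr_initial = 0.05,
                         lr_final = 0.0005,
                         loss_weights = c(recon = 1, age = 1, sex = 1, xcov = 1),
                         seed = 1L) {
  counts <- c(input_dim, h1_units, z_units, h2_units, epochs, batch_size)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("dimensions, epochs and batch_size must be positive integers")
  }
  if (z_units >= h1_units) {
    stop("z_units must be smaller than h1_units (constrained latent code)")
  }
  if (lr_final >= lr_initial) stop("lr_final must be smaller than lr_initial")
  if (corruption_sd < 0 || l2_coefficient < 0) {
    stop("corruption_sd and l2_coefficient must be non-negative")
  }
  if (length(loss_weights) != 4 || any(loss_weights < 0)) {
    stop("loss_weights must be 4 non-negative values")
  }
  structure(list(
    input_dim = as.integer(input_dim), h1_units = as.integer(h1_units),
    z_units = as.integer(z_units), h2_units = as.integer(h2_units),
    l2_coefficient = l2_coefficient, corruption_sd = corruption_sd,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr_initial = lr_initial, lr_final = lr_final,
    loss_weights = stats::setNames(as.numeric(loss_weights),
                                   c("recon", "age", "sex", "xcov")),
    seed = as.integer(seed)
  ), class = "model_config")
}

#' Build an untrained model
#'
#' Initializes the network weights for a configuration: SELU layers with the
#' LeCun-normal initializer, softmax heads and the linear output layer with
#' Glorot-uniform. Deterministic given `config$seed`.
#'
#' @param config A `model_config`.
#' @param coding A `label_coding` fixing the head widths.
#' @return List with `params` (weight matrices/biases), `config`, `coding`.
#' @export
build_model <- function(config, coding = label_coding()) {
  params <- with_seed(config$seed,
                      init_params(config, length(coding$age_classes),
                                  length(coding$sex_classes)))
  list(params = params, config = config, coding = coding)
}

#' Cross-covariance (XCov) disentanglement cost
#'
#' `0.5 * sum_ij C_ij^2`, where `C` is the batch cross-covariance matrix
#' between the latent units and the covariate-head outputs. Penalizing it
#' during training pushes age/sex information out of the latent code and into
#' the supervised heads.
#'
#' @param z_batch Batch x latent-units matrix.
#' @param yhat_batch Batch x head-outputs matrix (concatenated age and sex
#'   probabilities).
#' @return Non-negative scalar.
#' @export
xcov_cost <- function(z_batch, yhat_batch) {
  z_batch <- as.matrix(z_batch); yhat_batch <- as.matrix(yhat_batch)
  if (nrow(z_batch) != nrow(yhat_batch)) stop("batch sizes differ")
  if (nrow(z_batch) < 2) stop("XCov needs a batch of at least 2")
  xcov_value(z_batch, yhat_batch)
}

lr_schedule <- function(config) {
  e <- config$epochs
  if (e == 1) return(config$lr_initial)
  gamma <- (config$lr_final / config$lr_initial)^(1 / (e - 1))
  config$lr_initial * gamma^(seq_len(e) - 1)
}

#' Train the normative autoencoder on a healthy reference cohort
#'
#' Fits the zero-mean unit-variance normalization on the reference table,
#' then trains the denoising autoencoder: each mini-batch is corrupted with
#' fresh additive Gaussian noise, and the loss is the sum of the
#' reconstruction MSE against the *clean* input, the age and sex
#' cross-entropies, and the XCov penalty, plus the L2 weight penalty.
#' Optimization is Adam with a per-epoch exponential learning-rate decay.
#' Fully deterministic given `config$seed`.
#'
#' @param reference_table A `morphometry_table` of healthy subjects (the
#'   normative reference); needs at least `batch_size` rows.
#' @param config A `model_config`.
#' @param coding A `label_coding`; all ages must be encodable.
#' @param holdout Optional `morphometry_table`; its (uncorrupted)
#'   reconstruction MSE is recorded per epoch.
#' @param normalization Optional pre-fit `normalization_params`; by default
#'   fit on `reference_table`.
#' @return A `normative_model`: `config`, `params` (trained weights),
#'   `normalization` (frozen), `coding`, and `history` (one row per epoch
#'   with the loss terms, the L2 penalty, and the learning rate).
#' @export
train_normative <- function(reference_table, config = model_config(),
                            coding = label_coding(), holdout = NULL,
                            normalization = NULL) {
  if (nrow(reference_table) < config$batch_size) {
    stop("reference table smaller than one mini-batch")
  }
  schema <- table_schema(reference_table)
  if (nrow(schema) != config$input_dim) {
    stop("config input_dim does not match the table's feature count")
  }
  if (is.null(normalization)) normalization <- fit_normalization(reference_table)
  X <- apply_normalization(reference_table, normalization)
  labs <- encode_labels(reference_table, coding)
  # unname everything so gradient products don't attach dimnames to weights
  dimnames(X) <- NULL
  labs <- lapply(labs, function(m) { dimnames(m) <- NULL; m })
  Xhold <- if (!is.null(holdout)) apply_normalization(holdout, normalization)
  n <- nrow(X)
  w <- config$loss_weights
  lrs <- lr_schedule(config)
  hist <- matrix(NA_real_, config$epochs, 8,
                 dimnames = list(NULL, c("epoch", "lr", "total", "recon_mse",
                                         "age_ce", "sex_ce", "xcov",
                                         "l2_penalty")))
  holdout_mse <- rep(NA_real_, config$epochs)

  fitted <- with_seed(config$seed, {
    params <- init_params(config, ncol(labs$age), ncol(labs$sex))
    state <- adam_init(params)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      acc <- numeric(5)  # total, recon, age, sex, xcov (subject-weighted)
      l2_acc <- 0
      for (s in starts) {
        b <- idx[s:min(s + config$batch_size - 1, n)]
        Xb <- X[b, , drop = FALSE]
        Xc <- if (config$corruption_sd > 0) {
          Xb + matrix(stats::rnorm(length(Xb), sd = config$corruption_sd),
                      nrow(Xb), ncol(Xb))
        } else Xb
        out <- nn_loss_grads(params, Xc, Xb, labs$age[b, , drop = FALSE],
                             labs$sex[b, , drop = FALSE], w,
                             config$l2_coefficient)
        if (!is.finite(out$total)) {
          stop(sprintf(paste0("non-finite loss at epoch %d ",
                              "(recon %.4g, age %.4g, sex %.4g, xcov %.4g)"),
                       epoch, out$recon, out$age_ce, out$sex_ce, out$xcov))
        }
        upd <- adam_step(params, out$grads, state, lrs[epoch])
        params <- upd$params
        state <- upd$state
        nb <- length(b)
        acc <- acc + nb * c(out$total, out$recon, out$age_ce, out$sex_ce,
                            out$xcov)
        l2_acc <- l2_acc + nb * out$l2_penalty
      }
      hist[epoch, ] <- c(epoch, lrs[epoch], acc / n, l2_acc / n)
      if (!is.null(Xhold)) {
        fwh <- nn_forward(params, Xhold)
        holdout_mse[epoch] <- mean((fwh$Xhat - Xhold)^2)
      }
    }
    params
  })

  history <- as.data.frame(hist)
  if (!is.null(Xhold)) history$holdout_recon_mse <- holdout_mse
  structure(list(config = config, params = fitted,
                 normalization = normalization, coding = coding,
                 schema = schema, history = history),
            class = "normative_model")
}

#' Reconstruct a cohort through a trained normative model
#'
#' Normalizes the input with the model's frozen reference parameters (no
#' refitting on test data), runs an uncorrupted forward pass, and returns the
#' reconstruction plus the covariate-head outputs and the latent code.
#'
#' @param model A `normative_model`.
#' @param table A `morphometry_table` conforming to the model's schema.
#' @param normalization Optional `normalization_params` overriding the
#'   model's frozen parameters (used by the bootstrap protocol, which scores
#'   clinical data with the original reference normalization).
#' @return List with `x` (normalized input), `xhat` (reconstruction),
#'   `yhat_age`, `yhat_sex` (head probabilities) and `z` (latent code), all
#'   row-aligned with the table.
#' @export
reconstruct <- function(model, table, normalization = NULL) {
  schema <- table_schema(table)
  if (!identical(schema$name, model$schema$name)) {
    stop("table schema does not match the model's schema")
  }
  if (is.null(normalization)) normalization <- model$normalization
  X <- apply_normalization(table, normalization)
  fw <- nn_forward(model$params, X)
  list(x = X, xhat = fw$Xhat, yhat_age = fw$A, yhat_sex = fw$S, z = fw$Z)
}

#' Age and sex prediction performance of the covariate heads
#'
#' Predicted age is the integer age of the maximal age-head output; reported
#' as mean absolute error in years. Predicted sex is the maximal sex-head
#' class; reported as balanced accuracy (mean per-sex recall).
#'
#' @param model A `normative_model`.
#' @param table A `morphometry_table` with true age and sex.
#' @return List with `age_mae` (years) and `sex_balanced_accuracy`
#'   (proportion in \[0, 1\]).
#' @export
covariate_performance <- function(model, table) {
  rec <- reconstruct(model, table)
  pred_age <- model$coding$age_classes[max.col(rec$yhat_age, "first")]
  pred_sex <- model$coding$sex_classes[max.col(rec$yhat_sex, "first")]
  recalls <- vapply(unique(table$sex), function(s) {
    mean(pred_sex[table$sex == s] == s)
  }, numeric(1))
  list(age_mae = mean(abs(pred_age - table$age)),
       sex_balanced_accuracy = mean(recalls))
}

#' Grid search over symmetric layer widths by k-fold cross-validation
#'
#' Evaluates every configuration with `h1 = h2` drawn from `unit_grid` and a
#' strictly smaller latent width `z` from the same grid, by k-fold
#' cross-validation on the reference cohort. Each fold fits its own
#' normalization and model on the training folds and is scored by the
#' validation reconstruction MSE; the configuration with the lowest mean
#' validation error wins (ties broken toward fewer units).
#'
#' @param reference_table Healthy reference `morphometry_table`.
#' @param unit_grid Candidate layer widths (default 10, 25, 50, 75, 100).
#' @param k_folds Number of CV folds.
#' @param base_config A `model_config` supplying all non-width
#'   hyperparameters (use a reduced `epochs` for tractable searches).
#' @param coding A `label_coding`.
#' @return List with `config` (the winning `model_config`) and `cv_table`
#'   (per-candidate mean/SD validation reconstruction error).
#' @export
select_architecture <- function(reference_table,
                                unit_grid = c(10, 25, 50, 75, 100),
                                k_folds = 10, base_config = model_config(),
                                coding = label_coding()) {
  if (length(unit_grid) == 0) stop("unit_grid must be nonempty")
  if (k_folds < 2) stop("k_folds must be at least 2")
  grid <- sort(unique(as.integer(unit_grid)))
  candidates <- do.call(rbind, lapply(grid, function(h1) {
    z <- grid[grid < h1]
    if (length(z) == 0) return(NULL)
    data.frame(h1 = h1, z = z, h2 = h1)
  }))
  if (is.null(candidates)) {
    stop("no candidate satisfies z < h1 on this grid")
  }
  n <- nrow(reference_table)
  fold_id <- with_seed(base_config$seed,
                       sample(rep(seq_len(k_folds), length.out = n)))
  val_err <- matrix(NA_real_, nrow(candidates), k_folds)
  for (i in seq_len(nrow(candidates))) {
    cfg <- model_config(
      input_dim = base_config$input_dim, h1_units = candidates$h1[i],
      z_units = candidates$z[i], h2_units = candidates$h2[i],
      l2_coefficient = base_config$l2_coefficient,
      corruption_sd = base_config$corruption_sd, epochs = base_config$epochs,
      batch_size = base_config$batch_size,
      lr_initial = base_config$lr_initial, lr_final = base_config$lr_final,
      loss_weights = base_config$loss_weights, seed = base_config$seed)
    for (k in seq_len(k_folds)) {
      train_tab <- reference_table[fold_id != k, ]
      val_tab <- reference_table[fold_id == k, ]
      fit <- train_normative(train_tab, cfg, coding)
      rec <- reconstruct(fit, val_tab)
      val_err[i, k] <- mean((rec$xhat - rec$x)^2)
    }
  }
  cv_table <- cbind(candidates,
                    mean_val_recon_mse = rowMeans(val_err),
                    sd_val_recon_mse = apply(val_err, 1, stats::sd))
  best <- which.min(cv_table$mean_val_recon_mse)
  best_cfg <- model_config(
    input_dim = base_config$input_dim, h1_units = candidates$h1[best],
    z_units = candidates$z[best], h2_units = candidates$h2[best],
    l2_coefficient = base_config$l2_coefficient,
    corruption_sd = base_config$corruption_sd, epochs = base_config$epochs,
    batch_size = base_config$batch_size,
    lr_initial = base_config$lr_initial, lr_final = base_config$lr_final,
    loss_weights = base_config$loss_weights, seed = base_config$seed)
  list(config = best_cfg, cv_table = cv_table)
}

#' @export
print.normative_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<normative_model> %d-%d-%d-%d-%d, %d epochs",
                     ", final recon MSE %.4f\n"),
              cfg$input_dim, cfg$h1_units, cfg$z_units, cfg$h2_units,
              cfg$input_dim, cfg$epochs,
              utils::tail(x$history$recon_mse, 1)))
  invisible(x)
}

#' Save a trained model to a directory
#'
#' Writes `config.json`, `normalization.json`, `weights.json` (full-precision
#' tensors), `history.csv` and `schema.csv`.
#'
#' @param model A `normative_model`.
#' @param dir Output directory (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(model$config)
  jsonlite::write_json(c(cfg, list(age_classes = model$coding$age_classes,
                                   sex_classes = model$coding$sex_classes)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_normalization(model$normalization, file.path(dir, "normalization.json"))
  jsonlite::write_json(model$params, file.path(dir, "weights.json"),
                       digits = NA, matrix = "rowmajor")
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  write_schema(model$schema, file.path(dir, "schema.csv"))
  invisible(dir)
}

#' Load a trained model saved with [save_model()]
#' @param dir Model directory.
#' @return A `normative_model`.
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  coding <- label_coding(range(cfg$age_classes), cfg$sex_classes)
  config <- model_config(
    input_dim = cfg$input_dim, h1_units = cfg$h1_units, z_units = cfg$z_units,
    h2_units = cfg$h2_units, l2_coefficient = cfg$l2_coefficient,
    corruption_sd = cfg$corruption_sd, epochs = cfg$epochs,
    batch_size = cfg$batch_size, lr_initial = cfg$lr_initial,
    lr_final = cfg$lr_final, loss_weights = cfg$loss_weights, seed = cfg$seed)
  params <- jsonlite::read_json(file.path(dir, "weights.json"),
                                simplifyVector = TRUE)
  params <- lapply(params, function(p) if (is.list(p)) do.call(rbind, p) else p)
  normalization <- read_normalization(file.path(dir, "normalization.json"))
  history <- utils::read.csv(file.path(dir, "history.csv"))
  schema <- read_schema(file.path(dir, "schema.csv"))
  structure(list(config = config, params = params,
                 normalization = normalization, coding = coding,
                 schema = schema, history = history),
            class = "normative_model")
}
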