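test_that("model configuration enforces its invariants", {
  expect_error(model_config(h1_units = 50, z_units = 50), "smaller")
  expect_error(model_config(lr_initial = 0.001, lr_final = 0.01), "smaller")
  expect_error(model_config(epochs = 0), "positive")
  cfg <- model_config()
  expect_equal(c(cfg$h1_units, cfg$z_units, cfg$h2_units), c(100, 75, 100))
  expect_equal(cfg$epochs, 2000L)
  expect_equal(cfg$batch_size, 64L)
  expect_equal(cfg$corruption_sd, 0.1)
  expect_equal(cfg$l2_coefficient, 1e-3)
})

test_that("built model has the decided wiring and is seed-reproducible", {
  cfg <- model_config(seed = 11)
  m <- build_model(cfg)
  # decoder consumes latent + age head + sex head: 75 + 16 + 2 = 93
  expect_equal(dim(m$params$W2), c(93, 100))
  expect_equal(dim(m$params$W1), c(104, 100))
  expect_equal(dim(m$params$Wz), c(100, 75))
  expect_equal(dim(m$params$Wa), c(100, 16))
  expect_equal(dim(m$params$Ws), c(100, 2))
  expect_equal(dim(m$params$Wo), c(100, 104))
  m2 <- build_model(cfg)
  expect_identical(m$params, m2$params)
  # different seed, different weights
  m3 <- build_model(model_config(seed = 12))
  expect_false(identical(m$params, m3$params))
})

test_that("xcov_cost matches its definition and symmetries", {
  # constant latent has zero covariance with anything
  z_const <- matrix(1.7, 10, 3)
  y <- matrix(rnorm(10 * 4), 10, 4)
  expect_equal(xcov_cost(z_const, y), 0)
  # one latent column equal to one head column with batch variance v -> v^2/2
  set.seed(5)
  v_col <- rnorm(12)
  pv <- mean((v_col - mean(v_col))^2)
  expect_equal(xcov_cost(matrix(v_col), matrix(v_col)), 0.5 * pv^2,
               tolerance = 1e-12)
  # invariant under joint row permutation
  set.seed(6)
  z <- matrix(rnorm(20 * 5), 20, 5)
  yy <- matrix(rnorm(20 * 3), 20, 3)
  perm <- sample(20)
  expect_equal(xcov_cost(z, yy), xcov_cost(z[perm, ], yy[perm, ]),
               tolerance = 1e-12)
  expect_error(xcov_cost(z[1, , drop = FALSE], yy[1, , drop = FALSE]),
               "at least 2")
})

test_that("analytic gradients match central finite differences", {
  set.seed(2)
  n <- 6; p <- 7
  cfg <- model_config(input_dim = p, h1_units = 5, z_units = 3, h2_units = 5,
                      seed = 1)
  params <- normdae:::with_seed(1, normdae:::init_params(cfg, 4, 2))
  Xc <- matrix(rnorm(n * p), n, p)
  Xclean <- matrix(rnorm(n * p), n, p)
  Ya <- diag(4)[sample(1:4, n, TRUE), ]
  Ys <- diag(2)[sample(1:2, n, TRUE), ]
  w <- c(1, 0.7, 1.3, 2)   # unequal weights exercise every loss path
  l2 <- 1e-3
  out <- normdae:::nn_loss_grads(params, Xc, Xclean, Ya, Ys, w, l2)
  lossfun <- function(pp) {
    o <- normdae:::nn_loss_grads(pp, Xc, Xclean, Ya, Ys, w, l2)
    o$total + o$l2_penalty
  }
  eps <- 1e-6
  for (nm in names(params)) {
    g <- out$grads[[nm]]
    idx <- sample(length(g), min(6, length(g)))
    num <- vapply(idx, function(i) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- lossfun(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      (up - lossfun(pp)) / (2 * eps)
    }, numeric(1))
    rel <- max(abs(num - g[idx]) / pmax(abs(num) + abs(g[idx]), 1e-8))
    expect_lt(rel, 1e-5)
  }
})

test_that("learning rate decays exponentially to exactly lr_final", {
  cfg <- model_config(epochs = 137)
  lrs <- normdae:::lr_schedule(cfg)
  expect_equal(length(lrs), 137)
  expect_equal(lrs[1], cfg$lr_initial)
  expect_equal(lrs[137], cfg$lr_final, tolerance = 1e-9)
  expect_true(all(diff(lrs) < 0))
  # constant ratio = exponential decay
  expect_lt(max(abs(diff(log(lrs)) - diff(log(lrs))[1])), 1e-12)
})

test_that("training is deterministic and the loss decomposition holds", {
  co <- small_cohort(seed = 2)
  cfg <- tiny_config(epochs = 15, seed = 9)
  f1 <- train_normative(co$reference, cfg)
  f2 <- train_normative(co$reference, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  # recorded total equals the weighted sum of the four recorded terms
  h <- f1$history
  w <- cfg$loss_weights
  recomposed <- w["recon"] * h$recon_mse + w["age"] * h$age_ce +
    w["sex"] * h$sex_ce + w["xcov"] * h$xcov
  expect_lt(max(abs(h$total - recomposed)), 1e-6)
  expect_identical(h$lr, normdae:::lr_schedule(cfg))
})

test_that("a constant dataset is learned to negligible error", {
  co <- small_cohort(seed = 3, n_ref = 64, n_hc = 0, n_pat = 0)
  df <- as.data.frame(co$reference)
  sch <- default_schema()
  for (nm in sch$name) df[[nm]] <- df[[nm]][1]
  tab <- as_morphometry_table(df)
  cfg <- tiny_config(epochs = 200, corruption_sd = 0, seed = 4)
  suppressWarnings(fit <- train_normative(tab, cfg))
  expect_lt(utils::tail(fit$history$recon_mse, 1), 1e-3)
})

test_that("reconstruction is deterministic, shaped, and uses frozen params", {
  co <- small_cohort(seed = 5)
  cfg <- tiny_config(epochs = 20, seed = 5)
  fit <- train_normative(co$reference, cfg)
  r1 <- reconstruct(fit, co$clinical)
  r2 <- reconstruct(fit, co$clinical)
  expect_identical(r1, r2)
  expect_equal(dim(r1$xhat), c(nrow(co$clinical), 104))
  expect_equal(dim(r1$yhat_age), c(nrow(co$clinical), 16))
  expect_equal(dim(r1$z), c(nrow(co$clinical), cfg$z_units))
  expect_true(all(abs(rowSums(r1$yhat_age) - 1) < 1e-12))
  # frozen normalization: test features are scaled by reference parameters
  expect_equal(r1$x, apply_normalization(co$clinical, fit$normalization))
})

test_that("training error does not exceed holdout error on average", {
  errs <- vapply(1:3, function(s) {
    co <- small_cohort(seed = s, n_ref = 180, n_hc = 0, n_pat = 0)
    train_tab <- co$reference[1:140, ]
    hold_tab <- co$reference[141:180, ]
    fit <- train_normative(train_tab, tiny_config(epochs = 60, seed = s),
                           holdout = hold_tab)
    rec_tr <- reconstruct(fit, train_tab)
    rec_ho <- reconstruct(fit, hold_tab)
    c(mean((rec_tr$xhat - rec_tr$x)^2), mean((rec_ho$xhat - rec_ho$x)^2))
  }, numeric(2))
  expect_lt(mean(errs[1, ]), mean(errs[2, ]))
})

test_that("covariate heads learn age and sex from synthetic structure", {
  co <- small_cohort(seed = 6, n_ref = 400, n_hc = 60, n_pat = 0)
  fit <- train_normative(co$reference, tiny_config(epochs = 120, seed = 6))
  perf <- covariate_performance(fit, co$clinical)
  # defaults encode a strong sex effect in volumes and a weak age trend
  expect_gt(perf$sex_balanced_accuracy, 0.8)
  expect_lt(perf$age_mae, 4.5)  # uniform-guess baseline is ~5.3 years
  hist_hold <- train_normative(co$reference, tiny_config(epochs = 5, seed = 6),
                               holdout = co$clinical)$history
  expect_true(all(is.finite(hist_hold$holdout_recon_mse)))
})

test_that("architecture search enumerates z < h1 candidates and picks the argmin", {
  co <- small_cohort(seed = 7, n_ref = 90, n_hc = 0, n_pat = 0)
  base <- model_config(h1_units = 100, z_units = 75, epochs = 3,
                       batch_size = 32, seed = 3)
  expect_error(select_architecture(co$reference, unit_grid = c(10),
                                   k_folds = 2, base_config = base),
               "no candidate")
  res <- select_architecture(co$reference, unit_grid = c(10, 25), k_folds = 2,
                             base_config = base)
  expect_equal(nrow(res$cv_table), 1)
  expect_equal(res$cv_table[1, c("h1", "z", "h2")],
               data.frame(h1 = 25L, z = 10L, h2 = 25L), ignore_attr = TRUE)

  res2 <- select_architecture(co$reference, unit_grid = c(10, 25, 50),
                              k_folds = 2, base_config = base)
  expect_equal(nrow(res2$cv_table), 3)  # (25,10), (50,10), (50,25)
  best <- which.min(res2$cv_table$mean_val_recon_mse)
  expect_equal(res2$config$h1_units, res2$cv_table$h1[best])
  expect_equal(res2$config$z_units, res2$cv_table$z[best])
  # the canonical grid yields 10 candidates
  grid <- c(10, 25, 50, 75, 100)
  n_cand <- sum(outer(grid, grid, function(h, z) z < h))
  expect_equal(n_cand, 10)
})

test_that("model bundles round-trip through disk", {
  co <- small_cohort(seed = 8, n_ref = 100, n_hc = 20, n_pat = 0)
  fit <- train_normative(co$reference, tiny_config(epochs = 10, seed = 8))
  dir <- withr_local_file("model")
  save_model(fit, dir)
  back <- load_model(dir)
  expect_equal(back$params, fit$params, tolerance = 1e-12)
  expect_equal(back$normalization$mean, fit$normalization$mean)
  expect_equal(back$config, fit$config)
  expect_equal(back$history, fit$history, tolerance = 1e-12)
  d1 <- compute_deviations(fit, co$clinical)
  d2 <- compute_deviations(back, co$clinical)
  expect_equal(d1$deviation_metric, d2$deviation_metric, tolerance = 1e-12)
})

test_that("the XCov penalty reduces covariate information in the latent code", {
  cors <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_spec(
      n_reference = 256, n_controls = 0, n_patients = 0,
      age_slopes = NULL, seed = s))
    # strong age effect: amplify the default slopes tenfold
    spec <- cohort_spec(n_reference = 256, n_controls = 0, n_patients = 0,
                        age_slopes = ifelse(default_schema()$kind == "thickness",
                                            -0.03, -100), seed = s)
    co <- generate_cohort(spec)
    mean_abs_cor <- function(w_xcov) {
      cfg <- model_config(h1_units = 30, z_units = 10, h2_units = 30,
                          epochs = 80, batch_size = 64,
                          loss_weights = c(1, 1, 1, w_xcov), seed = s)
      fit <- train_normative(co$reference, cfg)
      z <- reconstruct(fit, co$reference)$z
      keep <- apply(z, 2, stats::sd) > 1e-9
      mean(abs(stats::cor(z[, keep, drop = FALSE], co$reference$age)))
    }
    c(with_xcov = mean_abs_cor(1), without = mean_abs_cor(0))
  }, numeric(2))
  expect_lt(mean(cors["with_xcov", ]), mean(cors["without", ]))
})
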