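# Low-level network machinery for the semi-supervised denoising autoencoder.
#
# Layout (row = subject):
#   encoder   H1 = selu(X W1 + b1)
#   latent    Z  = selu(H1 Wz + bz)
#   heads     A  = softmax(H1 Wa + ba)   (age classes)
#             S  = softmax(H1 Ws + bs)   (sex classes)
#   decoder   D  = [Z, A, S]
#             H2 = selu(D W2 + b2)
#             Xhat = H2 Wo + bo          (linear output)
#
# The heads branch from H1, and the decoder consumes the *predicted* softmax
# probabilities, so inference needs no true labels. All gradients are
# analytic; the test suite checks them against central finite differences.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(x) {
  neg <- x <= 0
  x[neg] <- SELU_ALPHA * (exp(x[neg]) - 1)
  SELU_LAMBDA * x
}

# derivative expressed through the activation value a = selu(x):
# x > 0  ->  lambda;  x <= 0  ->  lambda*alpha*exp(x) = a + lambda*alpha
selu_grad_from_act <- function(a) {
  pos <- a > 0
  a <- a + SELU_LAMBDA * SELU_ALPHA
  a[pos] <- SELU_LAMBDA
  a
}

softmax_rows <- function(logits) {
  z <- exp(logits - as.vector(Reduce(pmax, asplit(logits, 2))))
  z / rowSums(z)
}

# backprop a gradient w.r.t. softmax outputs P to the logits
softmax_backprop <- function(dP, P) {
  tmp <- dP * P
  tmp - P * rowSums(tmp)
}

lecun_normal <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(1 / fan_in)), fan_in, fan_out)
}

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Parameter initialization. SELU layers use the LeCun-normal initializer
# appropriate for self-normalizing networks; softmax heads and the linear
# output layer use Glorot-uniform. Draw order is fixed for determinism.
init_params <- function(config, n_age, n_sex) {
  p <- config$input_dim
  h1 <- config$h1_units; z <- config$z_units; h2 <- config$h2_units
  d <- z + n_age + n_sex
  list(
    W1 = lecun_normal(p, h1),  b1 = numeric(h1),
    Wz = lecun_normal(h1, z),  bz = numeric(z),
    Wa = glorot_uniform(h1, n_age), ba = numeric(n_age),
    Ws = glorot_uniform(h1, n_sex), bs = numeric(n_sex),
    W2 = lecun_normal(d, h2),  b2 = numeric(h2),
    Wo = glorot_uniform(h2, p), bo = numeric(p)
  )
}

nn_forward <- function(params, X) {
  H1 <- selu(X %*% params$W1 + rep(params$b1, each = nrow(X)))
  Z <- selu(H1 %*% params$Wz + rep(params$bz, each = nrow(X)))
  A <- softmax_rows(H1 %*% params$Wa + rep(params$ba, each = nrow(X)))
  S <- softmax_rows(H1 %*% params$Ws + rep(params$bs, each = nrow(X)))
  D <- cbind(Z, A, S)
  H2 <- selu(D %*% params$W2 + rep(params$b2, each = nrow(X)))
  Xhat <- H2 %*% params$Wo + rep(params$bo, each = nrow(X))
  list(H1 = H1, Z = Z, A = A, S = S, D = D, H2 = H2, Xhat = Xhat)
}

# Batch cross-covariance penalty between latent columns and head outputs:
# 0.5 * sum_ij C_ij^2 with C = cov between centred Z and centred Y.
xcov_value <- function(Z, Y) {
  n <- nrow(Z)
  Zc <- sweep(Z, 2, colMeans(Z))
  Yc <- sweep(Y, 2, colMeans(Y))
  C <- crossprod(Zc, Yc) / n
  0.5 * sum(C^2)
}

# Loss and analytic gradients for one mini-batch.
#   Xc: corrupted normalized input (forward pass), Xclean: clean target,
#   Yage/Ysex: one-hot labels, w: 4 loss weights (recon, age, sex, xcov),
#   l2: L2 coefficient on weight matrices (biases excluded).
nn_loss_grads <- function(params, Xc, Xclean, Yage, Ysex, w, l2) {
  n <- nrow(Xc); p <- ncol(Xc)
  fw <- nn_forward(params, Xc)
  H1 <- fw$H1; Z <- fw$Z; A <- fw$A; S <- fw$S; H2 <- fw$H2; Xhat <- fw$Xhat
  ka <- ncol(A); ks <- ncol(S); kz <- ncol(Z)

  resid <- Xhat - Xclean
  recon <- sum(resid^2) / (n * p)
  age_ce <- -sum(Yage * log(pmax(A, 1e-300))) / n
  sex_ce <- -sum(Ysex * log(pmax(S, 1e-300))) / n
  Zc <- sweep(Z, 2, colMeans(Z))
  Y <- cbind(A, S)
  Yc <- sweep(Y, 2, colMeans(Y))
  C <- crossprod(Zc, Yc) / n
  xcov <- 0.5 * sum(C^2)

  weight_mats <- c("W1", "Wz", "Wa", "Ws", "W2", "Wo")
  l2_penalty <- l2 * sum(vapply(weight_mats,
                                function(nm) sum(params[[nm]]^2), numeric(1)))
  total <- w[1] * recon + w[2] * age_ce + w[3] * sex_ce + w[4] * xcov

  # ---- backward ----
  dXhat <- w[1] * 2 * resid / (n * p)
  gWo <- crossprod(H2, dXhat); gbo <- colSums(dXhat)
  dH2 <- tcrossprod(dXhat, params$Wo) * selu_grad_from_act(H2)
  gW2 <- crossprod(fw$D, dH2); gb2 <- colSums(dH2)
  dD <- tcrossprod(dH2, params$W2)

  dZ <- dD[, seq_len(kz), drop = FALSE] + w[4] * (Yc %*% t(C)) / n
  dY_x <- w[4] * (Zc %*% C) / n
  dA <- dD[, kz + seq_len(ka), drop = FALSE] + dY_x[, seq_len(ka), drop = FALSE]
  dS <- dD[, kz + ka + seq_len(ks), drop = FALSE] +
    dY_x[, ka + seq_len(ks), drop = FALSE]

  dAlog <- w[2] * (A - Yage) / n + softmax_backprop(dA, A)
  dSlog <- w[3] * (S - Ysex) / n + softmax_backprop(dS, S)
  dZpre <- dZ * selu_grad_from_act(Z)

  gWa <- crossprod(H1, dAlog); gba <- colSums(dAlog)
  gWs <- crossprod(H1, dSlog); gbs <- colSums(dSlog)
  gWz <- crossprod(H1, dZpre); gbz <- colSums(dZpre)

  dH1 <- (tcrossprod(dZpre, params$Wz) + tcrossprod(dAlog, params$Wa) +
            tcrossprod(dSlog, params$Ws)) * selu_grad_from_act(H1)
  gW1 <- crossprod(Xc, dH1); gb1 <- colSums(dH1)

  grads <- list(W1 = gW1, b1 = gb1, Wz = gWz, bz = gbz, Wa = gWa, ba = gba,
                Ws = gWs, bs = gbs, W2 = gW2, b2 = gb2, Wo = gWo, bo = gbo)
  for (nm in weight_mats) grads[[nm]] <- grads[[nm]] + 2 * l2 * params[[nm]]

  list(total = total, recon = recon, age_ce = age_ce, sex_ce = sex_ce,
       xcov = xcov, l2_penalty = l2_penalty, grads = grads, forward = fw)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
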