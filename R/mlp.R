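# Minimal feed-forward classifier: ReLU hidden layers, softmax output,
# log-loss, Adam updates with minibatches. Deterministic given a seed.
# Kept deliberately small: dense matrices and base-R linear algebra are
# ample at the dataset sizes the package trains on.

mlp_init <- function(d_in, hidden, k_out, seed) {
  set.seed(seed)
  dims <- c(d_in, hidden, k_out)
  layers <- list()
  for (l in seq_len(length(dims) - 1L)) {
    fan_in <- dims[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * dims[l + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, dims[l + 1L]),
      b = rep(0, dims[l + 1L]))
  }
  layers
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  nl <- length(layers)
  for (l in seq_len(nl)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    acts[[l + 1L]] <- if (l < nl) pmax(Z, 0) else Z
  }
  acts
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train a feed-forward softmax classifier
#'
#' ReLU hidden layers, log-loss, Adam optimizer (learning rate 0.001 by
#' default). Features are standardized internally; the scaler is stored with
#' the model. Training is deterministic given `seed`.
#'
#' @param X numeric feature matrix.
#' @param y factor (or coercible) class labels.
#' @param hidden integer vector of hidden-layer sizes.
#' @param lr Adam learning rate.
#' @param epochs passes over the data.
#' @param batch minibatch size.
#' @param seed RNG seed for initialization and shuffling.
#' @return object of class `mlp_classifier`.
#' @export
mlp_fit <- function(X, y, hidden = c(256L, 128L), lr = 0.001,
                    epochs = 150L, batch = 32L, seed = 1L) {
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) < 2L) stop("degenerate labels")
  X <- as.matrix(X)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, `/`)
  n <- nrow(Xs); k <- length(classes)
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  layers <- mlp_init(ncol(Xs), hidden, k, seed)
  nl <- length(layers)
  adam <- lapply(layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0L

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      acts <- mlp_forward(layers, Xs[idx, , drop = FALSE])
      P <- softmax(acts[[nl + 1L]])
      delta <- (P - Y[idx, , drop = FALSE]) / length(idx)
      t <- t + 1L
      for (l in rev(seq_len(nl))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
        }
        a <- adam[[l]]
        a$mW <- beta1 * a$mW + (1 - beta1) * gW
        a$vW <- beta2 * a$vW + (1 - beta2) * gW^2
        a$mb <- beta1 * a$mb + (1 - beta1) * gb
        a$vb <- beta2 * a$vb + (1 - beta2) * gb^2
        adam[[l]] <- a
        corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
        layers[[l]]$W <- layers[[l]]$W -
          lr * (a$mW / corr1) / (sqrt(a$vW / corr2) + eps)
        layers[[l]]$b <- layers[[l]]$b -
          lr * (a$mb / corr1) / (sqrt(a$vb / corr2) + eps)
      }
    }
  }
  structure(list(layers = layers, classes = classes, center = center,
                 scale = scale_, hidden = hidden, lr = lr,
                 epochs = epochs, batch = batch, seed = seed),
            class = "mlp_classifier")
}

#' Predict classes or class probabilities from a fitted MLP
#'
#' @param object an `mlp_classifier`.
#' @param newdata numeric feature matrix.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @export
predict.mlp_classifier <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  acts <- mlp_forward(object$layers, Xs)
  P <- softmax(acts[[length(object$layers) + 1L]])
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}
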