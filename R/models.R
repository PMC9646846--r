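#' Temperature softmax
#'
#' `softmax(z, T)_k = exp(z_k / T) / sum_j exp(z_j / T)`, computed with the
#' usual max-shift for numerical stability. Rows of a matrix are treated as
#' independent logit vectors.
#'
#' @param logits numeric vector, or matrix with one logit vector per row.
#' @param temperature positive scalar T; larger values flatten the output.
#' @return Probabilities of the same shape, each (row) vector summing to 1.
#' @examples
#' softmax(c(log(2), 0))            # 2/3, 1/3
#' softmax(c(10, 0), temperature = 500)
#' @export
softmax <- function(logits, temperature = 1) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0) {
    stopf("temperature must be a positive number")
  }
  if (is.matrix(logits)) {
    z <- logits / temperature
    zmax <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
    e <- exp(z - zmax)
    e / rowSums(e)
  } else {
    z <- logits / temperature
    z <- z - max(z)
    e <- exp(z)
    e / sum(e)
  }
}

#' Classifier specification
#'
#' @param kind `"de_mlp"` (one hidden layer, ReLU, dropout), `"linear_svm"`
#'   (libSVM linear kernel, C = 1), or `"linear_student"` (linear softmax
#'   classifier trained by gradient descent; supports soft targets).
#' @param n_classes number of classes (logit dimension).
#' @param hidden_size hidden width for `de_mlp` (default 248).
#' @param dropout_rate dropout probability for `de_mlp`, in `[0, 1)`;
#'   active during training only.
#' @param epochs,learning_rate,batch_size,l2 optimiser settings for the
#'   gradient-trained kinds (Adam).
#' @param seed integer controlling initialisation and shuffling.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("de_mlp", "linear_svm", "linear_student"),
                            n_classes, hidden_size = 248L,
                            dropout_rate = 0.5, epochs = 80L,
                            learning_rate = 1e-3, batch_size = 32L,
                            l2 = 1e-4, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_classes >= 2, hidden_size >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(kind = kind, n_classes = as.integer(n_classes),
                 hidden_size = as.integer(hidden_size),
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), l2 = l2,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a classifier
#'
#' Labels are integer classes in `[0, n_classes)`. All trained models expose
#' [logits()] and [predict()][predict.eeg_classifier] (argmax over logits,
#' ties broken to the lowest class index). Training is deterministic given
#' the spec's seed.
#'
#' @param spec a [classifier_spec()].
#' @param x instances x features matrix.
#' @param y integer labels in `[0, n_classes)`.
#' @param soft_targets optional instances x n_classes matrix of soft target
#'   distributions mixed into the loss (gradient-trained kinds only); see
#'   [distill_student()].
#' @param imitation mixing weight lambda of the soft targets.
#' @return An `eeg_classifier` model object.
#' @export
train_classifier <- function(spec, x, y, soft_targets = NULL, imitation = 0) {
  stopifnot(inherits(spec, "classifier_spec"), is.matrix(x))
  y <- as.integer(y)
  if (length(y) != nrow(x)) stopf("x has %d rows but y has %d labels",
                                  nrow(x), length(y))
  if (any(y < 0L | y >= spec$n_classes)) {
    stopf("labels must lie in [0, %d)", spec$n_classes)
  }
  if (length(unique(y)) < 2L) stopf("training set contains a single class")
  model <- switch(
    spec$kind,
    de_mlp = ,
    linear_student = train_softmax_net(spec, x, y, soft_targets, imitation),
    linear_svm = {
      if (!is.null(soft_targets) && imitation > 0) {
        stopf("soft targets are only supported by gradient-trained kinds")
      }
      fit <- with_seed(spec$seed,
                       e1071::svm(x, factor(y, levels = 0:(spec$n_classes - 1)),
                                  kernel = "linear", cost = 1, scale = FALSE))
      list(kind = "linear_svm", spec = spec, fit = fit)
    })
  model$n_features <- ncol(x)
  class(model) <- "eeg_classifier"
  model
}

## bias add without sweep()'s dispatch overhead; numerically identical
add_bias <- function(M, b) M + rep(b, each = nrow(M))

## One-hidden-layer (or linear, hidden_size used only for de_mlp) softmax
## network trained with Adam on cross-entropy. Because cross-entropy is
## linear in the target distribution, the generalized-distillation objective
## (1-lambda) * CE(onehot, p) + lambda * CE(soft, p) is trained exactly by
## using the mixed target t = (1-lambda) * onehot + lambda * soft.
train_softmax_net <- function(spec, x, y, soft_targets = NULL,
                              imitation = 0) {
  K <- spec$n_classes
  n <- nrow(x); p <- ncol(x)
  targets <- matrix(0, n, K)
  targets[cbind(seq_len(n), y + 1L)] <- 1
  if (!is.null(soft_targets) && imitation > 0) {
    stopifnot(is.matrix(soft_targets), nrow(soft_targets) == n,
              ncol(soft_targets) == K)
    if (imitation < 0 || imitation > 1) stopf("imitation must be in [0, 1]")
    targets <- (1 - imitation) * targets + imitation * soft_targets
  }
  hidden <- if (spec$kind == "de_mlp") spec$hidden_size else 0L
  with_seed(spec$seed, {
    if (hidden > 0) {
      W1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
      b1 <- rep(0, hidden)
      W2 <- matrix(stats::rnorm(hidden * K, sd = sqrt(2 / hidden)), hidden, K)
      b2 <- rep(0, K)
      params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    } else {
      params <- list(W2 = matrix(0, p, K), b2 = rep(0, K))
    }
    m <- lapply(params, function(q) q * 0)
    v <- lapply(params, function(q) q * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        tb <- targets[idx, , drop = FALSE]
        nb <- length(idx)
        if (hidden > 0) {
          h_pre <- add_bias(xb %*% params$W1, params$b1)
          h <- pmax(h_pre, 0)
          if (spec$dropout_rate > 0) {
            mask <- matrix(stats::runif(nb * hidden) >= spec$dropout_rate,
                           nb, hidden) / (1 - spec$dropout_rate)
            h <- h * mask
          }
          z <- add_bias(h %*% params$W2, params$b2)
          pz <- softmax(z)
          dz <- (pz - tb) / nb
          grads <- list(
            W1 = NULL, b1 = NULL,
            W2 = t(h) %*% dz + spec$l2 * params$W2,
            b2 = colSums(dz))
          dh <- dz %*% t(params$W2)
          if (spec$dropout_rate > 0) dh <- dh * mask
          dh <- dh * (h_pre > 0)
          grads$W1 <- t(xb) %*% dh + spec$l2 * params$W1
          grads$b1 <- colSums(dh)
        } else {
          z <- add_bias(xb %*% params$W2, params$b2)
          pz <- softmax(z)
          dz <- (pz - tb) / nb
          grads <- list(W2 = t(xb) %*% dz + spec$l2 * params$W2,
                        b2 = colSums(dz))
        }
        step <- step + 1
        for (nm in names(grads)) {
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- m[[nm]] / (1 - beta1^step)
          vhat <- v[[nm]] / (1 - beta2^step)
          params[[nm]] <- params[[nm]] -
            spec$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    list(kind = spec$kind, spec = spec, params = params, hidden = hidden)
  })
}

#' Class-score logits of a trained model
#'
#' Inference is deterministic (dropout disabled). For the linear SVM, libSVM
#' pairwise decision values are aggregated into per-class scores (sum of
#' signed pairwise margins), which preserves the argmax-vote decision in the
#' common case while honouring the logits interface.
#'
#' @param model an `eeg_classifier`.
#' @param x instances x features matrix.
#' @return instances x n_classes matrix of unnormalised scores.
#' @export
logits <- function(model, x) {
  stopifnot(inherits(model, "eeg_classifier"), is.matrix(x))
  if (ncol(x) != model$n_features) {
    stopf("model expects %d features, got %d", model$n_features, ncol(x))
  }
  if (model$kind == "linear_svm") {
    K <- model$spec$n_classes
    pr <- predict(model$fit, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    scores <- matrix(0, nrow(x), K)
    pairs <- strsplit(colnames(dv), "/")
    for (j in seq_along(pairs)) {
      a <- as.integer(pairs[[j]][1]) + 1L
      b <- as.integer(pairs[[j]][2]) + 1L
      scores[, a] <- scores[, a] + dv[, j]
      scores[, b] <- scores[, b] - dv[, j]
    }
    scores
  } else {
    params <- model$params
    if (model$hidden > 0) {
      h <- pmax(add_bias(x %*% params$W1, params$b1), 0)
      add_bias(h %*% params$W2, params$b2)
    } else {
      add_bias(x %*% params$W2, params$b2)
    }
  }
}

#' Predict class labels
#'
#' @param object an `eeg_classifier`.
#' @param x instances x features matrix.
#' @param ... unused.
#' @return Integer labels in `[0, n_classes)` (argmax over logits, lowest
#'   index on ties).
#' @export
predict.eeg_classifier <- function(object, x, ...) {
  z <- logits(object, x)
  apply(z, 1, argmax1) - 1L
}

#' Standardisation fitted on training data
#'
#' Per-feature zero-centering and unit scaling, with statistics estimated on
#' the training set only and re-applied to any other split.
#'
#' @param x training instances x features matrix.
#' @return A `feature_scaler` (list with `center`, `scale`).
#' @export
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  structure(list(center = mu, scale = sd), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `feature_scaler`.
#' @param newx matrix to transform.
#' @export
apply_scaler <- function(scaler, newx) {
  stopifnot(inherits(scaler, "feature_scaler"))
  sweep(sweep(newx, 2, scaler$center), 2, scaler$scale, "/")
}
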