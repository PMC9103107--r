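#' Encoder configuration
#'
#' A one-layer convolutional DNA encoder in the DeepBind/DeepSEA style:
#' a valid (no padding) 1-D convolution with stride 1 over the 4 one-hot
#' channels, rectification, then per-channel global max pooling, yielding
#' one embedding dimension per kernel.
#'
#' @param kernel_size Convolution window length; default 24.
#' @param num_kernels Number of kernels = embedding dimension; default 64
#'   (128 for the wide variant).
#' @param seed Integer seed for weight initialization.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(kernel_size = 24L, num_kernels = 64L, seed = 1L) {
  stopifnot(kernel_size >= 1, num_kernels >= 1)
  structure(list(kernel_size = as.integer(kernel_size),
                 num_kernels = as.integer(num_kernels),
                 stride = 1L, seed = as.integer(seed)),
            class = "encoder_config")
}

#' Classifier configuration
#'
#' Two fully connected layers with a dropout layer between them:
#' `num_kernels -> hidden_units -> 2`, softmax output. The second softmax
#' digit is the predicted binding probability.
#'
#' @param hidden_units Hidden-layer width; default 32.
#' @param dropout_rate Dropout probability in `[0, 1)`; default 0.25
#'   (grid-searchable over `{0.1, 0.25, 0.5}`).
#' @param seed Integer seed for weight initialization.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(hidden_units = 32L, dropout_rate = 0.25,
                              seed = 1L) {
  stopifnot(hidden_units >= 1, dropout_rate >= 0, dropout_rate < 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "classifier_config")
}

# Glorot-uniform initialization, seed-deterministic.
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Build a freshly initialized encoder
#'
#' @param config An [encoder_config()].
#' @return A list of class `clr_encoder` holding the kernel weight matrix
#'   (`(4 * kernel_size) x num_kernels`), biases, and the config.
#' @export
new_encoder <- function(config = encoder_config()) {
  withr_seed(config$seed, {
    structure(list(
      W = glorot(4L * config$kernel_size, config$num_kernels),
      b = rep(0, config$num_kernels),
      config = config
    ), class = "clr_encoder")
  })
}

#' Build a freshly initialized classifier
#'
#' @param config A [classifier_config()].
#' @param input_dim Embedding dimension fed to the classifier (the
#'   encoder's `num_kernels`).
#' @return A list of class `clr_classifier`.
#' @export
new_classifier <- function(config = classifier_config(), input_dim = 64L) {
  withr_seed(config$seed + 1L, {
    structure(list(
      W1 = glorot(input_dim, config$hidden_units),
      b1 = rep(0, config$hidden_units),
      W2 = glorot(config$hidden_units, 2L),
      b2 = rep(0, 2L),
      config = config, input_dim = as.integer(input_dim)
    ), class = "clr_classifier")
  })
}

# im2col: batch one-hot matrix X (B x 4L, position-major channels) to the
# stacked window matrix (B*T x 4k), T windows blocked row-wise, rows
# ordered batch-fastest within each window block.
im2col <- function(X, kernel_size) {
  B <- nrow(X)
  L <- ncol(X) / 4L
  k <- kernel_size
  T_ <- L - k + 1L
  if (T_ < 1L) abort("Sequence length is shorter than the kernel size.")
  Xc <- matrix(0, B * T_, 4L * k)
  for (t in seq_len(T_)) {
    cols <- ((t - 1L) * 4L + 1L):((t - 1L) * 4L + 4L * k)
    Xc[((t - 1L) * B + 1L):(t * B), ] <- X[, cols]
  }
  Xc
}

# Encoder forward pass. Returns the embedding matrix plus the cache needed
# for backprop (argmax positions and pre-activations at the maxima).
encoder_forward <- function(encoder, X, want_cache = FALSE) {
  B <- nrow(X)
  k <- encoder$config$kernel_size
  K <- encoder$config$num_kernels
  T_ <- ncol(X) / 4L - k + 1L
  Xc <- im2col(X, k)
  Fp <- Xc %*% encoder$W
  Fp <- sweep(Fp, 2L, encoder$b, `+`)
  A <- pmax(Fp, 0)
  Z <- matrix(0, B, K)
  am <- matrix(0L, B, K)
  for (j in seq_len(K)) {
    Aj <- matrix(A[, j], nrow = B)  # B x T
    amj <- max.col(Aj, ties.method = "first")
    am[, j] <- amj
    Z[, j] <- Aj[cbind(seq_len(B), amj)]
  }
  if (!want_cache) return(list(Z = Z))
  list(Z = Z, Xc = Xc, Fp = Fp, am = am, B = B, T_ = T_)
}

# Gradient of the loss w.r.t. encoder weights given dL/dZ. The max-pool
# routes each channel's gradient to its argmax window; ReLU zeroes it when
# the winning pre-activation is <= 0.
encoder_backward <- function(encoder, cache, dZ) {
  K <- encoder$config$num_kernels
  B <- cache$B
  dW <- matrix(0, nrow(encoder$W), K)
  db <- numeric(K)
  for (j in seq_len(K)) {
    rows <- (cache$am[, j] - 1L) * B + seq_len(B)
    g <- dZ[, j] * (cache$Fp[cbind(rows, j)] > 0)
    nz <- which(g != 0)
    if (length(nz) > 0L) {
      dW[, j] <- crossprod(cache$Xc[rows[nz], , drop = FALSE], g[nz])
      db[j] <- sum(g[nz])
    }
  }
  list(W = dW, b = db)
}

#' Encode a batch of sequences
#'
#' Runs the convolution + ReLU + global-max-pooling encoder over
#' one-hot-encoded sequences.
#'
#' @param encoder A `clr_encoder`.
#' @param sequences Character vector of equal-length DNA sequences (or a
#'   dataset tibble, in which case its `sequence` column is used).
#' @return A `B x num_kernels` embedding matrix.
#' @export
encode <- function(encoder, sequences) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  sequences <- validate_sequences(sequences)
  L <- nchar(sequences[1])
  if (L < encoder$config$kernel_size) {
    abort("Sequence length must be >= the kernel size.")
  }
  encoder_forward(encoder, encode_batch(sequences))$Z
}

# Classifier forward. In training mode, inverted dropout with the current
# RNG stream; evaluation mode is deterministic.
classifier_forward <- function(classifier, Z, training = FALSE,
                               want_cache = FALSE) {
  H_pre <- sweep(Z %*% classifier$W1, 2L, classifier$b1, `+`)
  H <- pmax(H_pre, 0)
  p <- classifier$config$dropout_rate
  D <- NULL
  Hd <- H
  if (training && p > 0) {
    D <- matrix(rbinom(length(H), 1L, 1 - p), nrow(H), ncol(H)) / (1 - p)
    Hd <- H * D
  }
  logits <- sweep(Hd %*% classifier$W2, 2L, classifier$b2, `+`)
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  if (!want_cache) return(list(probs = probs))
  list(probs = probs, Z = Z, H_pre = H_pre, Hd = Hd, D = D)
}

# Cross-entropy backward through the classifier; returns weight grads and
# dL/dZ for the encoder.
classifier_backward <- function(classifier, cache, labels) {
  B <- nrow(cache$probs)
  Y <- unname(cbind(1 - labels, labels))
  dlogits <- (cache$probs - Y) / B
  dW2 <- crossprod(cache$Hd, dlogits)
  db2 <- colSums(dlogits)
  dHd <- dlogits %*% t(classifier$W2)
  dH <- if (is.null(cache$D)) dHd else dHd * cache$D
  dH_pre <- dH * (cache$H_pre > 0)
  dW1 <- crossprod(cache$Z, dH_pre)
  db1 <- colSums(dH_pre)
  dZ <- dH_pre %*% t(classifier$W1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, dZ = dZ)
}

#' Classify embeddings
#'
#' Applies the two-layer softmax classifier in evaluation mode (dropout
#' disabled, deterministic). The second column is the predicted binding
#' probability `y_pred`.
#'
#' @param classifier A `clr_classifier`.
#' @param z An embedding vector or `B x num_kernels` matrix from
#'   [encode()].
#' @return A `B x 2` matrix of class probabilities (rows sum to 1).
#' @export
classify <- function(classifier, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != classifier$input_dim) {
    abort("Embedding dimension does not match the classifier input.")
  }
  classifier_forward(classifier, z)$probs
}

# Stable architecture fingerprint (shapes + structural hyper-parameters),
# shared by contrastive and baseline models by construction.
architecture_hash <- function(encoder, classifier) {
  paste(encoder$config$kernel_size, encoder$config$num_kernels,
        classifier$config$hidden_units, sep = "-")
}
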