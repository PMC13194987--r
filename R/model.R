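MODEL_ARCHS <- c("lstm", "1dcnn", "bilstm", "1dcnn-bilstm")

#' Model configuration
#'
#' Describes one of the four sequence classifiers and its training
#' hyper-parameters. The stacked `1dcnn-bilstm` is the full architecture:
#' input (25 rows x C channels) -> 1-D convolution (128 filters, 11-row
#' receptive field, ReLU, l2 regularisation) -> batch normalisation ->
#' sliding (3 x 1) max-pool -> BiLSTM -> three fully connected layers ->
#' sigmoid probability. `lstm`, `bilstm` and `1dcnn` are the ablation
#' baselines sharing the same three-layer dense head.
#'
#' @param arch one of `"lstm"`, `"1dcnn"`, `"bilstm"`, `"1dcnn-bilstm"`.
#' @param n_channels number of input channels C (3 per inertial sensor, 1
#'   for light or time-of-day, 9 for the combined inertial input).
#' @param n_timesteps rows per window (25 = 5 minutes at 5 rows/minute).
#' @param n_filters convolution filters (conv architectures).
#' @param kernel_span convolution receptive field in rows.
#' @param pool_window,pool_stride sliding max-pool geometry.
#' @param hidden_size LSTM units per direction.
#' @param dense_sizes widths of the three dense head layers; the last must
#'   be 1 (binary output).
#' @param batch_norm whether the conv feature map is batch normalised.
#' @param l2_coeff l2 penalty on the convolution kernel weights.
#' @param learning_rate,batch_size,epochs Adam optimiser settings.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param validation_frac fraction of the training data held out for early
#'   stopping.
#' @param seed integer seed for parameter initialisation and batching.
#' @return An object of class `model_config`.
#' @export
model_config <- function(arch = "1dcnn-bilstm",
                         n_channels = 9L,
                         n_timesteps = 25L,
                         n_filters = 128L,
                         kernel_span = 11L,
                         pool_window = 3L,
                         pool_stride = 1L,
                         hidden_size = 64L,
                         dense_sizes = c(64L, 32L, 1L),
                         batch_norm = TRUE,
                         l2_coeff = 1e-4,
                         learning_rate = 1e-3,
                         batch_size = 32L,
                         epochs = 100L,
                         patience = 10L,
                         validation_frac = 0.1,
                         seed = 1L) {
  arch <- match.arg(tolower(arch), MODEL_ARCHS)
  if (length(dense_sizes) != 3)
    stopf("the dense head has exactly three layers")
  if (dense_sizes[3] != 1) stopf("the final dense layer is the binary output")
  if (kernel_span > n_timesteps) stopf("kernel_span cannot exceed n_timesteps")
  structure(list(arch = arch,
                 n_channels = as.integer(n_channels),
                 n_timesteps = as.integer(n_timesteps),
                 n_filters = as.integer(n_filters),
                 kernel_span = as.integer(kernel_span),
                 pool_window = as.integer(pool_window),
                 pool_stride = as.integer(pool_stride),
                 hidden_size = as.integer(hidden_size),
                 dense_sizes = as.integer(dense_sizes),
                 batch_norm = isTRUE(batch_norm),
                 l2_coeff = l2_coeff,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 validation_frac = validation_frac,
                 seed = as.integer(seed)),
            class = "model_config")
}

uses_conv <- function(cfg) cfg$arch %in% c("1dcnn", "1dcnn-bilstm")
uses_recurrent <- function(cfg) cfg$arch %in% c("lstm", "bilstm", "1dcnn-bilstm")

conv_out_len <- function(cfg) cfg$n_timesteps - cfg$kernel_span + 1L

pool_out_len <- function(cfg) {
  L <- conv_out_len(cfg)
  as.integer(floor((L - cfg$pool_window) / cfg$pool_stride) + 1L)
}

# width of the input to the dense head
head_input_width <- function(cfg) {
  switch(cfg$arch,
         "lstm" = cfg$hidden_size,
         "bilstm" = 2L * cfg$hidden_size,
         "1dcnn" = pool_out_len(cfg) * cfg$n_filters,
         "1dcnn-bilstm" = 2L * cfg$hidden_size)
}

# dimension of each step fed to the recurrent stage
recurrent_input_size <- function(cfg) {
  if (uses_conv(cfg)) cfg$n_filters else cfg$n_channels
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Combined-gate LSTM weight init, column blocks [forget | input | cand | out],
# forget-gate bias started at 1 so early training does not flush the cell.
init_lstm <- function(D, H) {
  W <- glorot(H + D, 4L * H)
  b <- numeric(4L * H)
  b[seq_len(H)] <- 1
  list(W = W, b = b)
}

#' Build an untrained model
#'
#' Allocates and seed-initialises all parameters for the configured
#' architecture (Glorot-uniform weights, zero biases except the LSTM
#' forget-gate bias at 1, batch-norm gain 1 / shift 0).
#'
#' @param config a [model_config()].
#' @return An object of class `smokesense_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  params <- with_seed(child_seed(config$seed, "init", config$arch), {
    p <- list()
    if (uses_conv(config)) {
      K <- config$kernel_span; C <- config$n_channels; F_ <- config$n_filters
      p$Wc <- glorot(K * C, F_)
      p$bc <- numeric(F_)
      if (config$batch_norm) {
        p$gamma <- rep(1, F_)
        p$beta <- numeric(F_)
      }
    }
    if (uses_recurrent(config)) {
      D <- recurrent_input_size(config); H <- config$hidden_size
      fw <- init_lstm(D, H)
      p$Wlf <- fw$W; p$blf <- fw$b
      if (config$arch %in% c("bilstm", "1dcnn-bilstm")) {
        bw <- init_lstm(D, H)
        p$Wlb <- bw$W; p$blb <- bw$b
      }
    }
    U <- head_input_width(config); d <- config$dense_sizes
    p$W1 <- glorot(U, d[1]); p$b1 <- numeric(d[1])
    p$W2 <- glorot(d[1], d[2]); p$b2 <- numeric(d[2])
    p$W3 <- glorot(d[2], d[3]); p$b3 <- numeric(d[3])
    p
  })
  bn <- if (uses_conv(config) && config$batch_norm) {
    list(mean = numeric(config$n_filters), var = rep(1, config$n_filters))
  } else NULL
  structure(list(config = config, params = params, bn = bn,
                 norm = NULL, channels = NULL, trained = FALSE,
                 history = NULL),
            class = "smokesense_model")
}

#' @export
print.smokesense_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf("%s model: %d channels x %d rows, %d parameters (%s)\n",
              toupper(x$config$arch), x$config$n_channels,
              x$config$n_timesteps, n_par,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- batched forward pass -------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

conv_stack_forward <- function(params, X, cfg, bn, training) {
  n <- dim(X)[1]; K <- cfg$kernel_span; F_ <- cfg$n_filters
  L <- conv_out_len(cfg)
  M <- im2col(X, K)                                       # (nL) x (KC)
  Z <- M %*% params$Wc
  Z <- Z + matrix(params$bc, nrow(Z), F_, byrow = TRUE)
  A <- pmax(Z, 0)
  if (cfg$batch_norm) {
    if (training) {
      mu <- colMeans(A)
      va <- colMeans(A * A) - mu * mu
      bn$mean <- BN_MOMENTUM * bn$mean + (1 - BN_MOMENTUM) * mu
      bn$var <- BN_MOMENTUM * bn$var + (1 - BN_MOMENTUM) * va
    } else {
      mu <- bn$mean
      va <- bn$var
    }
    sdv <- sqrt(va + BN_EPS)
    Ahat <- (A - matrix(mu, nrow(A), F_, byrow = TRUE)) /
      matrix(sdv, nrow(A), F_, byrow = TRUE)
    Y <- Ahat * matrix(params$gamma, nrow(A), F_, byrow = TRUE) +
      matrix(params$beta, nrow(A), F_, byrow = TRUE)
  } else {
    Ahat <- NULL; sdv <- NULL
    Y <- A
  }
  Yarr <- array(Y, c(n, L, F_))
  idx <- seq(1L, L - cfg$pool_window + 1L, by = cfg$pool_stride)
  P <- array(-Inf, c(n, length(idx), F_))
  for (d in seq_len(cfg$pool_window) - 1L) {
    P <- pmax(P, Yarr[, idx + d, , drop = FALSE])
  }
  list(P = P, cache = list(M = M, Z = Z, Ahat = Ahat, sdv = sdv,
                           Yarr = Yarr, P = P, idx = idx, n = n, L = L),
       bn = bn)
}

# X_steps: list over time of n x D matrices, in processing order.
lstm_batch_forward <- function(W, b, X_steps, H) {
  n <- nrow(X_steps[[1]])
  T_ <- length(X_steps)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  caches <- vector("list", T_)
  bmat <- matrix(b, n, 4L * H, byrow = TRUE)
  for (t in seq_len(T_)) {
    hx <- cbind(h, X_steps[[t]])
    G <- hx %*% W + bmat
    f <- sigmoid(G[, seq_len(H), drop = FALSE])
    i <- sigmoid(G[, H + seq_len(H), drop = FALSE])
    g <- tanh(G[, 2L * H + seq_len(H), drop = FALSE])
    o <- sigmoid(G[, 3L * H + seq_len(H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    caches[[t]] <- list(hx = hx, f = f, i = i, g = g, o = o,
                        c = cc, tc = tc, c_prev = c_prev)
  }
  list(h_last = h, caches = caches)
}

dense_head_forward <- function(params, U) {
  Z1 <- U %*% params$W1 + matrix(params$b1, nrow(U), ncol(params$W1),
                                 byrow = TRUE)
  H1 <- pmax(Z1, 0)
  Z2 <- H1 %*% params$W2 + matrix(params$b2, nrow(U), ncol(params$W2),
                                  byrow = TRUE)
  H2 <- pmax(Z2, 0)
  logit <- H2 %*% params$W3 + matrix(params$b3, nrow(U), 1, byrow = TRUE)
  list(U = U, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, logit = logit,
       prob = sigmoid(logit))
}

# X: standardized n x T x C array.
forward_batch <- function(params, X, cfg, bn, training = FALSE) {
  n <- dim(X)[1]
  cache <- list()
  if (uses_conv(cfg)) {
    cs <- conv_stack_forward(params, X, cfg, bn, training)
    bn <- cs$bn
    cache$conv <- cs$cache
    S <- cs$P                                   # n x Lp x F
  } else {
    S <- X
  }
  Tp <- dim(S)[2]
  if (uses_recurrent(cfg)) {
    H <- cfg$hidden_size
    steps <- lapply(seq_len(Tp), function(t) matrix(S[, t, ], nrow = n))
    fwd <- lstm_batch_forward(params$Wlf, params$blf, steps, H)
    cache$lstm_f <- fwd
    cache$steps <- steps
    if (cfg$arch %in% c("bilstm", "1dcnn-bilstm")) {
      bwd <- lstm_batch_forward(params$Wlb, params$blb, rev(steps), H)
      cache$lstm_b <- bwd
      U <- cbind(fwd$h_last, bwd$h_last)
    } else {
      U <- fwd$h_last
    }
  } else {
    U <- matrix(S, n, Tp * dim(S)[3])
  }
  head <- dense_head_forward(params, U)
  cache$head <- head
  list(prob = drop(head$prob), logit = drop(head$logit),
       cache = cache, bn = bn)
}

standardize_batch <- function(X, norm) {
  C <- dim(X)[3]
  for (c in seq_len(C)) {
    X[, , c] <- (X[, , c] - norm$center[c]) / norm$scale[c]
  }
  X
}

#' Predict window scores and labels
#'
#' Applies the trained model to new windows: per-window probability of a
#' smoking/lapse/craving event in the 5-minute slot, and the thresholded
#' hard label.
#'
#' @param object a trained `smokesense_model`.
#' @param newdata a `labeled_dataset` with the channel spec the model was
#'   trained on, or a bare `n x 25 x C` array.
#' @param threshold decision threshold on the probability (default 0.5).
#' @param ... unused.
#' @return data.frame with columns `score` (in `[0, 1]`) and `label` (0/1).
#' @export
predict.smokesense_model <- function(object, newdata, threshold = 0.5, ...) {
  if (!object$trained) stopf("model has not been trained")
  if (inherits(newdata, "labeled_dataset")) {
    if (!identical(newdata$channels, object$channels))
      stopf("channel spec of newdata (%s) does not match training (%s)",
            paste(newdata$channels, collapse = ","),
            paste(object$channels, collapse = ","))
    X <- newdata$x
  } else {
    X <- newdata
  }
  if (length(dim(X)) != 3 || dim(X)[2] != object$config$n_timesteps ||
      dim(X)[3] != object$config$n_channels)
    stopf("newdata must be n x %d x %d", object$config$n_timesteps,
          object$config$n_channels)
  X <- standardize_batch(X, object$norm)
  out <- forward_batch(object$params, X, object$config, object$bn,
                       training = FALSE)
  data.frame(score = out$prob,
             label = as.integer(out$prob >= threshold))
}
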