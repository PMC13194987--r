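sigmoid <- function(x) 1 / (1 + exp(-x))

#' Parameters of the convolutional block
#'
#' The first stage of the convolutional architectures: a valid (no-padding)
#' 1-D convolution along the 25-row time axis across all input channels,
#' 128 filters by default, an 11-row receptive field (the kernel covers a
#' row together with the 10 rows before it), bias, ReLU activation with
#' l2 weight regularisation, and a sliding max-pool window of size (3 x 1).
#'
#' @param n_filters number of convolution filters.
#' @param kernel_span receptive field length in rows.
#' @param n_channels number of input channels C.
#' @param weights optional kernel array of dim `kernel_span x C x n_filters`;
#'   initialised to zero if omitted (training supplies real values).
#' @param bias optional per-filter bias vector.
#' @param l2_coeff l2 penalty coefficient on the kernel weights.
#' @param pool_window sliding max window length (rows).
#' @param pool_stride stride of the sliding max window.
#' @return An object of class `conv_block_params`.
#' @export
conv_block_params <- function(n_filters = 128L, kernel_span = 11L,
                              n_channels = 9L, weights = NULL, bias = NULL,
                              l2_coeff = 1e-4, pool_window = 3L,
                              pool_stride = 1L) {
  if (!is_count(n_filters) || !is_count(kernel_span) || !is_count(n_channels))
    stopf("n_filters, kernel_span and n_channels must be positive integers")
  if (is.null(weights))
    weights <- array(0, c(kernel_span, n_channels, n_filters))
  if (!identical(dim(weights), c(as.integer(kernel_span),
                                 as.integer(n_channels),
                                 as.integer(n_filters))))
    stopf("weights must have dim kernel_span x n_channels x n_filters")
  if (is.null(bias)) bias <- numeric(n_filters)
  if (length(bias) != n_filters) stopf("bias must have one entry per filter")
  structure(list(n_filters = as.integer(n_filters),
                 kernel_span = as.integer(kernel_span),
                 n_channels = as.integer(n_channels),
                 weights = weights, bias = bias, l2_coeff = l2_coeff,
                 pool_window = as.integer(pool_window),
                 pool_stride = as.integer(pool_stride)),
            class = "conv_block_params")
}

#' 1-D convolution forward pass
#'
#' Valid multi-channel 1-D convolution along the time axis: output position
#' i of filter k is the inner product of the kernel with rows
#' `i .. i + kernel_span - 1` of all channels, plus the filter bias,
#' followed by ReLU. Output length is `nrow(x) - kernel_span + 1`.
#'
#' @param x numeric matrix, time rows x channels.
#' @param params a [conv_block_params()] whose `n_channels` matches `x`.
#' @param activation `"relu"` (default) or `"linear"` (pre-activation map).
#' @return Feature-map matrix, `(nrow(x) - kernel_span + 1) x n_filters`.
#' @export
conv1d_forward <- function(x, params, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  x <- as.matrix(x)
  K <- params$kernel_span
  if (nrow(x) < K) stopf("input has fewer rows than the kernel span")
  if (ncol(x) != params$n_channels)
    stopf("input has %d channels but params expect %d", ncol(x),
          params$n_channels)
  L <- nrow(x) - K + 1L
  M <- im2col(array(x, c(1L, nrow(x), ncol(x))), K)   # L x (K*C)
  W <- matrix(params$weights, K * params$n_channels, params$n_filters)
  Z <- M %*% W + matrix(params$bias, L, params$n_filters, byrow = TRUE)
  if (activation == "relu") pmax(Z, 0) else Z
}

# Unfold a batch array (n x T x C) into the (n*L) x (K*C) matrix whose rows
# are flattened receptive fields; row order is sample-fastest, column order
# matches as.vector() of a K x C kernel slice.
im2col <- function(X, K) {
  n <- dim(X)[1]; T_ <- dim(X)[2]; C <- dim(X)[3]
  L <- T_ - K + 1L
  M <- matrix(0, n * L, K * C)
  for (c in seq_len(C)) {
    for (k in seq_len(K)) {
      M[, (c - 1L) * K + k] <- as.vector(X[, k:(k + L - 1L), c])
    }
  }
  M
}

#' Sliding max-pool forward pass
#'
#' Sliding maximum of window `window` and stride `stride` applied along the
#' time axis of a feature map, per filter; reduces the variance of the
#' convolved features.
#'
#' @param feature_map matrix, time positions x filters.
#' @param window pooling window length.
#' @param stride pooling stride.
#' @return Pooled matrix with `floor((L - window)/stride) + 1` rows.
#' @export
maxpool_forward <- function(feature_map, window = 3L, stride = 1L) {
  m <- as.matrix(feature_map)
  L <- nrow(m)
  if (window > L) stopf("pool window (%d) longer than feature map (%d)",
                        window, L)
  idx <- seq(1L, L - window + 1L, by = stride)
  out <- matrix(-Inf, length(idx), ncol(m))
  for (d in seq_len(window) - 1L) {
    out <- pmax(out, m[idx + d, , drop = FALSE])
  }
  if (!is.null(colnames(m))) colnames(out) <- colnames(m)
  out
}

#' LSTM cell parameters
#'
#' One direction of an LSTM: forget, input and output gates (sigmoid,
#' values in (0,1)) and a tanh candidate state, each computed from the
#' concatenation of the previous hidden state and the current input. The
#' cell state carries long-term information through the sequence; the
#' hidden state is the per-step output.
#'
#' @param input_size input dimension per step.
#' @param hidden_size number of LSTM units.
#' @param w_f,w_i,w_c,w_o gate weight matrices, each
#'   `(hidden_size + input_size) x hidden_size`, acting on `[h, x]`.
#' @param b_f,b_i,b_c,b_o gate bias vectors of length `hidden_size`.
#' @return An object of class `lstm_cell_params`.
#' @export
lstm_cell_params <- function(input_size, hidden_size,
                             w_f = NULL, w_i = NULL, w_c = NULL, w_o = NULL,
                             b_f = NULL, b_i = NULL, b_c = NULL, b_o = NULL) {
  D <- as.integer(input_size); H <- as.integer(hidden_size)
  mk <- function(w) if (is.null(w)) matrix(0, H + D, H) else {
    w <- as.matrix(w)
    if (!identical(dim(w), c(H + D, H)))
      stopf("gate weights must be (hidden_size + input_size) x hidden_size")
    w
  }
  mkb <- function(b) if (is.null(b)) numeric(H) else {
    if (length(b) != H) stopf("gate bias must have hidden_size entries")
    as.numeric(b)
  }
  structure(list(input_size = D, hidden_size = H,
                 w_f = mk(w_f), w_i = mk(w_i), w_c = mk(w_c), w_o = mk(w_o),
                 b_f = mkb(b_f), b_i = mkb(b_i), b_c = mkb(b_c),
                 b_o = mkb(b_o)),
            class = "lstm_cell_params")
}

#' Single-direction LSTM forward pass
#'
#' Runs the gated recurrence over the rows of `x` with zero initial states:
#' forget gate `f_t = sigmoid(w_f [h_prev, x_t] + b_f)`, input gate `i_t`,
#' candidate `c~_t = tanh(w_c [h_prev, x_t] + b_c)`, cell state
#' `c_t = f_t * c_prev + i_t * c~_t`, output gate `o_t`, hidden state
#' `h_t = o_t * tanh(c_t)`.
#'
#' @param x matrix, time steps x input_size.
#' @param params an [lstm_cell_params()].
#' @param reverse if `TRUE`, process the sequence right-to-left (the
#'   backward direction of a BiLSTM); the returned rows stay in original
#'   time order.
#' @return List with `h` (T x hidden_size hidden states) and `c`
#'   (T x hidden_size cell states), rows in original time order.
#' @export
lstm_forward <- function(x, params, reverse = FALSE) {
  x <- as.matrix(x)
  H <- params$hidden_size
  if (ncol(x) != params$input_size)
    stopf("input dimension %d does not match params (%d)", ncol(x),
          params$input_size)
  T_ <- nrow(x)
  order_ <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  h <- matrix(0, T_, H); cc <- matrix(0, T_, H)
  h_prev <- numeric(H); c_prev <- numeric(H)
  for (t in order_) {
    hx <- c(h_prev, x[t, ])
    f <- sigmoid(drop(hx %*% params$w_f) + params$b_f)
    i <- sigmoid(drop(hx %*% params$w_i) + params$b_i)
    g <- tanh(drop(hx %*% params$w_c) + params$b_c)
    o <- sigmoid(drop(hx %*% params$w_o) + params$b_o)
    c_t <- f * c_prev + i * g
    h_t <- o * tanh(c_t)
    h[t, ] <- h_t; cc[t, ] <- c_t
    h_prev <- h_t; c_prev <- c_t
  }
  list(h = h, c = cc)
}

#' Bidirectional LSTM forward pass
#'
#' Runs a forward pass left-to-right and a backward pass right-to-left and
#' concatenates the two hidden-state streams per step,
#' `h_t = [h_t(forward), h_t(backward)]`, so the output width is twice the
#' hidden size.
#'
#' @param x matrix, time steps x input_size.
#' @param fwd,bwd [lstm_cell_params()] for the two directions.
#' @return Matrix `T x (2 * hidden_size)`; columns 1..H are the forward
#'   stream, H+1..2H the backward stream.
#' @export
bilstm_forward <- function(x, fwd, bwd) {
  hf <- lstm_forward(x, fwd, reverse = FALSE)$h
  hb <- lstm_forward(x, bwd, reverse = TRUE)$h
  cbind(hf, hb)
}
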