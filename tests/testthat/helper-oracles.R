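# Independent reference implementations used to validate the package's
# vectorised operators. These are deliberately written as plain elementwise
# loops, sharing no code with the implementation under test.

# Brute-force valid 1-D convolution + bias + ReLU (triple loop).
ref_conv1d <- function(x, w, b) {
  K <- dim(w)[1]; C <- dim(w)[2]; F_ <- dim(w)[3]
  L <- nrow(x) - K + 1L
  out <- matrix(0, L, F_)
  for (f in seq_len(F_)) {
    for (i in seq_len(L)) {
      s <- b[f]
      for (k in seq_len(K)) {
        for (c in seq_len(C)) {
          s <- s + w[k, c, f] * x[i + k - 1L, c]
        }
      }
      out[i, f] <- max(s, 0)
    }
  }
  out
}

# Sliding maximum, elementwise.
ref_maxpool <- function(m, window = 3L, stride = 1L) {
  starts <- seq(1L, nrow(m) - window + 1L, by = stride)
  out <- matrix(0, length(starts), ncol(m))
  for (j in seq_len(ncol(m))) {
    for (ii in seq_along(starts)) {
      out[ii, j] <- max(m[starts[ii]:(starts[ii] + window - 1L), j])
    }
  }
  out
}

# Scalar gate-by-gate LSTM: forget/input/output sigmoid gates, tanh
# candidate, c_t = f*c_prev + i*cand, h_t = o*tanh(c_t); unit-by-unit loops.
ref_lstm <- function(x, w_f, w_i, w_c, w_o, b_f, b_i, b_c, b_o,
                     reverse = FALSE) {
  sig <- function(z) 1 / (1 + exp(-z))
  T_ <- nrow(x); H <- ncol(w_f)
  h_out <- matrix(0, T_, H)
  h_prev <- numeric(H); c_prev <- numeric(H)
  steps <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  for (t in steps) {
    hx <- c(h_prev, x[t, ])
    h_t <- numeric(H); c_t <- numeric(H)
    for (j in seq_len(H)) {
      f <- sig(sum(hx * w_f[, j]) + b_f[j])
      i <- sig(sum(hx * w_i[, j]) + b_i[j])
      cand <- tanh(sum(hx * w_c[, j]) + b_c[j])
      o <- sig(sum(hx * w_o[, j]) + b_o[j])
      c_t[j] <- f * c_prev[j] + i * cand
      h_t[j] <- o * tanh(c_t[j])
    }
    h_out[t, ] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }
  h_out
}

ref_bilstm <- function(x, fwd, bwd) {
  cbind(ref_lstm(x, fwd$w_f, fwd$w_i, fwd$w_c, fwd$w_o,
                 fwd$b_f, fwd$b_i, fwd$b_c, fwd$b_o, reverse = FALSE),
        ref_lstm(x, bwd$w_f, bwd$w_i, bwd$w_c, bwd$w_o,
                 bwd$b_f, bwd$b_i, bwd$b_c, bwd$b_o, reverse = TRUE))
}

random_lstm_params <- function(D, H, sd = 0.5) {
  lstm_cell_params(D, H,
                   w_f = matrix(rnorm((H + D) * H, 0, sd), H + D, H),
                   w_i = matrix(rnorm((H + D) * H, 0, sd), H + D, H),
                   w_c = matrix(rnorm((H + D) * H, 0, sd), H + D, H),
                   w_o = matrix(rnorm((H + D) * H, 0, sd), H + D, H),
                   b_f = rnorm(H, 0, sd), b_i = rnorm(H, 0, sd),
                   b_c = rnorm(H, 0, sd), b_o = rnorm(H, 0, sd))
}

# AUC as the pairwise concordance probability (ties count one half).
ref_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  d <- outer(sp, sn, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / (length(sp) * length(sn))
}
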