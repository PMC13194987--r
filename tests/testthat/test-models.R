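test_that("convolution matches hand computation and the ReLU floor", {
  p <- conv_block_params(n_filters = 1L, kernel_span = 3L, n_channels = 1L,
                         weights = array(1, c(3, 1, 1)), bias = 0)
  x <- matrix(1:5, ncol = 1)
  expect_equal(as.vector(conv1d_forward(x, p)), c(6, 9, 12))
  # large negative bias floors everything at zero
  p_neg <- conv_block_params(n_filters = 1L, kernel_span = 3L,
                             n_channels = 1L, weights = array(1, c(3, 1, 1)),
                             bias = -1e6)
  expect_true(all(conv1d_forward(x, p_neg) == 0))
  expect_error(conv1d_forward(matrix(1:2, ncol = 1), p), "fewer rows")
  expect_error(conv1d_forward(matrix(1:10, ncol = 2), p), "channels")
})

test_that("convolution agrees with a brute-force triple loop", {
  set.seed(101)
  for (rep in 1:100) {
    K <- sample(2:5, 1); C <- sample(1:4, 1); F_ <- sample(1:4, 1)
    T_ <- K + sample(1:10, 1)
    w <- array(rnorm(K * C * F_), c(K, C, F_))
    b <- rnorm(F_)
    x <- matrix(rnorm(T_ * C), T_, C)
    p <- conv_block_params(n_filters = F_, kernel_span = K, n_channels = C,
                           weights = w, bias = b)
    expect_equal(conv1d_forward(x, p), ref_conv1d(x, w, b),
                 tolerance = 1e-8)
  }
})

test_that("max-pooling matches hand and brute-force references", {
  m <- matrix(c(1, 5, 2, 0, 3), ncol = 1)
  expect_equal(as.vector(maxpool_forward(m, 3, 1)), c(5, 5, 3))
  const <- matrix(2, 6, 2)
  expect_true(all(maxpool_forward(const) == 2))
  expect_error(maxpool_forward(matrix(1:2, ncol = 1), window = 3), "longer")
  set.seed(102)
  for (rep in 1:100) {
    L <- sample(3:20, 1); F_ <- sample(1:5, 1)
    w <- sample(2:min(4, L), 1); s <- sample(1:2, 1)
    m <- matrix(rnorm(L * F_), L, F_)
    got <- maxpool_forward(m, w, s)
    expect_equal(got, ref_maxpool(m, w, s), tolerance = 1e-8)
    # max property: pooled value >= the input at each aligned position
    starts <- seq(1, L - w + 1, by = s)
    expect_true(all(got >= m[starts, , drop = FALSE]))
  }
})

test_that("all-zero LSTM parameters give identically zero hidden states", {
  p <- lstm_cell_params(2, 3)
  x <- matrix(rnorm(10), 5, 2)
  out <- lstm_forward(x, p)
  expect_true(all(out$h == 0))
  expect_true(all(out$c == 0))
})

test_that("a scalar hand-built instance reproduces the gate equations", {
  # 1 unit, 2 steps, hand-picked weights; independent scalar reference
  w <- function(v) matrix(v, 2, 1)
  p <- lstm_cell_params(1, 1, w_f = w(c(0.5, -0.3)), w_i = w(c(0.2, 0.8)),
                        w_c = w(c(-0.4, 0.6)), w_o = w(c(0.7, 0.1)),
                        b_f = 0.1, b_i = -0.2, b_c = 0.3, b_o = 0)
  x <- matrix(c(1, -2), 2, 1)
  got <- lstm_forward(x, p)$h
  ref <- ref_lstm(x, p$w_f, p$w_i, p$w_c, p$w_o, p$b_f, p$b_i, p$b_c, p$b_o)
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("bilstm agrees with the scalar reference on random instances", {
  set.seed(103)
  for (rep in 1:100) {
    D <- sample(1:3, 1); H <- sample(1:3, 1); T_ <- sample(2:6, 1)
    fwd <- random_lstm_params(D, H)
    bwd <- random_lstm_params(D, H)
    x <- matrix(rnorm(T_ * D), T_, D)
    got <- bilstm_forward(x, fwd, bwd)
    expect_equal(dim(got), c(T_, 2L * H))
    expect_equal(got, ref_bilstm(x, fwd, bwd), tolerance = 1e-8)
  }
})

test_that("reversing the input swaps the forward and backward streams", {
  set.seed(104)
  for (rep in 1:20) {
    D <- 2; H <- 2; T_ <- 5
    fwd <- random_lstm_params(D, H)
    bwd <- random_lstm_params(D, H)
    x <- matrix(rnorm(T_ * D), T_, D)
    a <- bilstm_forward(x, fwd, bwd)
    b <- bilstm_forward(x[T_:1, , drop = FALSE], bwd, fwd)
    # running the reversed sequence with swapped direction parameters
    # reproduces the original streams, time-reversed and swapped
    expect_equal(a[, 1:H], b[T_:1, H + 1:H], tolerance = 1e-10)
    expect_equal(a[, H + 1:H], b[T_:1, 1:H], tolerance = 1e-10)
  }
})

test_that("gate activations stay inside their ranges on random passes", {
  set.seed(105)
  p <- random_lstm_params(3, 4, sd = 0.5)
  x <- matrix(rnorm(60), 20, 3)
  sig <- function(z) 1 / (1 + exp(-z))
  h_prev <- numeric(4); c_prev <- numeric(4)
  for (t in 1:20) {
    hx <- c(h_prev, x[t, ])
    f <- sig(drop(hx %*% p$w_f) + p$b_f)
    i <- sig(drop(hx %*% p$w_i) + p$b_i)
    g <- tanh(drop(hx %*% p$w_c) + p$b_c)
    o <- sig(drop(hx %*% p$w_o) + p$b_o)
    expect_true(all(f > 0 & f < 1))
    expect_true(all(i > 0 & i < 1))
    expect_true(all(o > 0 & o < 1))
    expect_true(all(g > -1 & g < 1))
    c_prev <- f * c_prev + i * g
    h_prev <- o * tanh(c_prev)
  }
})

test_that("model building is seed-deterministic and shape-consistent", {
  cfg <- model_config(arch = "1dcnn-bilstm", n_channels = 9, n_filters = 8,
                      hidden_size = 4, dense_sizes = c(8L, 4L, 1L), seed = 3)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(model_config(arch = "1dcnn-bilstm", n_channels = 9,
                                 n_filters = 8, hidden_size = 4,
                                 dense_sizes = c(8L, 4L, 1L), seed = 4))
  expect_false(identical(m1$params, m3$params))
  # dense head is exactly three layers and a binary output
  expect_error(model_config(dense_sizes = c(64L, 32L)), "three layers")
  expect_error(model_config(dense_sizes = c(64L, 32L, 2L)), "binary")
  # all four architecture configs build
  for (arch in c("lstm", "1dcnn", "bilstm", "1dcnn-bilstm")) {
    expect_s3_class(build_model(model_config(arch = arch, n_channels = 9)),
                    "smokesense_model")
  }
})

test_that("the batched forward pass equals the single-sample operators", {
  cfg <- model_config(arch = "1dcnn-bilstm", n_channels = 3, n_filters = 4,
                      kernel_span = 5, hidden_size = 3,
                      dense_sizes = c(6L, 4L, 1L), batch_norm = FALSE,
                      seed = 12)
  m <- build_model(cfg)
  set.seed(106)
  m$params <- lapply(m$params, function(p) p + rnorm(length(p), 0, 0.3))
  n <- 4
  X <- array(rnorm(n * 25 * 3), c(n, 25, 3))
  got <- smokesense:::forward_batch(m$params, X, cfg, m$bn, training = FALSE)
  H <- cfg$hidden_size
  gate <- function(W, b, block) {
    idx <- (block - 1) * H + seq_len(H)
    list(w = W[, idx, drop = FALSE], b = b[idx])
  }
  for (i in seq_len(n)) {
    x <- matrix(X[i, , ], 25, 3)
    cp <- conv_block_params(n_filters = 4L, kernel_span = 5L, n_channels = 3L,
                            weights = array(m$params$Wc, c(5, 3, 4)),
                            bias = m$params$bc)
    A <- conv1d_forward(x, cp)
    P <- maxpool_forward(A, cfg$pool_window, cfg$pool_stride)
    fwd <- lstm_cell_params(4, H,
                            w_f = gate(m$params$Wlf, m$params$blf, 1)$w,
                            w_i = gate(m$params$Wlf, m$params$blf, 2)$w,
                            w_c = gate(m$params$Wlf, m$params$blf, 3)$w,
                            w_o = gate(m$params$Wlf, m$params$blf, 4)$w,
                            b_f = gate(m$params$Wlf, m$params$blf, 1)$b,
                            b_i = gate(m$params$Wlf, m$params$blf, 2)$b,
                            b_c = gate(m$params$Wlf, m$params$blf, 3)$b,
                            b_o = gate(m$params$Wlf, m$params$blf, 4)$b)
    bwd <- lstm_cell_params(4, H,
                            w_f = gate(m$params$Wlb, m$params$blb, 1)$w,
                            w_i = gate(m$params$Wlb, m$params$blb, 2)$w,
                            w_c = gate(m$params$Wlb, m$params$blb, 3)$w,
                            w_o = gate(m$params$Wlb, m$params$blb, 4)$w,
                            b_f = gate(m$params$Wlb, m$params$blb, 1)$b,
                            b_i = gate(m$params$Wlb, m$params$blb, 2)$b,
                            b_c = gate(m$params$Wlb, m$params$blb, 3)$b,
                            b_o = gate(m$params$Wlb, m$params$blb, 4)$b)
    hseq <- bilstm_forward(P, fwd, bwd)
    u <- c(hseq[nrow(hseq), 1:H], hseq[1, H + 1:H])
    relu <- function(z) pmax(z, 0)
    h1 <- relu(u %*% m$params$W1 + m$params$b1)
    h2 <- relu(h1 %*% m$params$W2 + m$params$b2)
    logit <- h2 %*% m$params$W3 + m$params$b3
    expect_equal(got$prob[i], 1 / (1 + exp(-drop(logit))), tolerance = 1e-10)
  }
})

test_that("analytic gradients match finite differences for all archs", {
  set.seed(107)
  ns <- asNamespace("smokesense")
  for (arch in c("lstm", "1dcnn", "bilstm", "1dcnn-bilstm")) {
    cfg <- model_config(arch = arch, n_channels = 3, n_timesteps = 12,
                        n_filters = 4, kernel_span = 5, hidden_size = 3,
                        dense_sizes = c(5L, 4L, 1L), l2_coeff = 1e-3,
                        seed = 9)
    m <- build_model(cfg)
    # perturb away from zero so no ReLU kink sits exactly at a kink point
    m$params <- lapply(m$params, function(p) p + rnorm(length(p), 0, 0.1))
    n <- 5
    X <- array(rnorm(n * 12 * 3), c(n, 12, 3))
    y <- rbinom(n, 1, 0.5)
    lg <- ns$loss_and_grads(m$params, X, y, cfg, m$bn, training = TRUE)
    for (nm in names(lg$grads)) {
      p <- m$params[[nm]]
      for (j in sample(length(p), min(4, length(p)))) {
        eps <- 1e-5
        pp <- m$params; pp[[nm]][j] <- pp[[nm]][j] + eps
        pm <- m$params; pm[[nm]][j] <- pm[[nm]][j] - eps
        num <- (ns$loss_and_grads(pp, X, y, cfg, m$bn, TRUE)$loss -
                  ns$loss_and_grads(pm, X, y, cfg, m$bn, TRUE)$loss) / (2 * eps)
        ana <- lg$grads[[nm]][j]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})

test_that("training separates strong-signal data and is deterministic", {
  p <- cached_fixture("train_participant",
                      small_participant(seed = 111L, phase1_days = 3L))
  ds <- prepare_windows(p$phase1, p$events1, "ACC-GYR-MAG")
  bal <- balance_downsample(ds, seed = 2L)
  sp <- shuffle_split(bal, 0.9, seed = 2L)
  cfg <- do.call(model_config,
                 c(list(arch = "1dcnn-bilstm", n_channels = 9, seed = 7L),
                   quick_model(epochs = 50L)))
  m <- train_model(build_model(cfg), sp$train)
  tr_pred <- predict(m, sp$train)
  expect_gte(mean(tr_pred$label == sp$train$meta$label), 0.95)
  # loss history improves in the best-so-far sense
  expect_lte(min(m$history$train_loss), m$history$train_loss[1])
  # identical seeds give identical fits
  m2 <- train_model(build_model(cfg), sp$train)
  expect_identical(m$params, m2$params)
  # single-class training set is rejected
  pos_only <- smokesense:::subset_dataset(sp$train,
                                          which(sp$train$meta$label == 1L))
  expect_error(train_model(build_model(cfg), pos_only), "both classes")
  cached_fixture("trained_model", list(model = m, split = sp))
})

test_that("prediction returns calibrated scores and consistent labels", {
  fx <- cached_fixture("trained_model", stop("fixture missing"))
  m <- fx$model; sp <- fx$split
  pred <- predict(m, sp$test)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_identical(pred$label, as.integer(pred$score >= 0.5))
  # threshold 0 labels everything positive
  pred0 <- predict(m, sp$test, threshold = 0)
  expect_true(all(pred0$label == 1L))
  # thresholded labels consistent across a sweep
  for (th in c(0.25, 0.5, 0.75)) {
    expect_identical(predict(m, sp$test, threshold = th)$label,
                     as.integer(pred$score >= th))
  }
  # channel-spec mismatch is caught
  ds_acc <- select_channels(sp$test, "ACC")
  expect_error(predict(m, ds_acc), "channel spec")
})
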