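# ---- backward pass --------------------------------------------------------

# BPTT through one direction. caches/X in processing order; gradient is
# injected at the final processed step (the direction's summary state).
lstm_batch_backward <- function(W, caches, dh_last, H) {
  T_ <- length(caches)
  n <- nrow(dh_last)
  D <- ncol(caches[[1]]$hx) - H
  dW <- matrix(0, H + D, 4L * H)
  db <- numeric(4L * H)
  dX <- vector("list", T_)
  dh <- dh_last
  dc <- matrix(0, n, H)
  for (t in rev(seq_len(T_))) {
    cc <- caches[[t]]
    do_ <- dh * cc$tc
    dct <- dc + dh * cc$o * (1 - cc$tc^2)
    df <- dct * cc$c_prev
    di <- dct * cc$g
    dg <- dct * cc$i
    dG <- cbind(df * cc$f * (1 - cc$f),
                di * cc$i * (1 - cc$i),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$hx, dG)
    db <- db + colSums(dG)
    dHX <- dG %*% t(W)
    dh <- dHX[, seq_len(H), drop = FALSE]
    dX[[t]] <- dHX[, H + seq_len(D), drop = FALSE]
    dc <- dct * cc$f
  }
  list(dW = dW, db = db, dX = dX)
}

conv_stack_backward <- function(params, cfg, cache, dP) {
  n <- cache$n; L <- cache$L; F_ <- cfg$n_filters
  idx <- cache$idx
  dY <- array(0, c(n, L, F_))
  taken <- array(FALSE, dim(cache$P))
  for (d in seq_len(cfg$pool_window) - 1L) {
    slice <- cache$Yarr[, idx + d, , drop = FALSE]
    m <- (slice == cache$P) & !taken      # ties go to the earliest position
    taken <- taken | m
    dY[, idx + d, ] <- dY[, idx + d, , drop = FALSE] + dP * m
  }
  dYmat <- matrix(dY, n * L, F_)
  if (cfg$batch_norm) {
    N <- nrow(dYmat)
    gam <- matrix(params$gamma, N, F_, byrow = TRUE)
    dgamma <- colSums(dYmat * cache$Ahat)
    dbeta <- colSums(dYmat)
    s1 <- matrix(dbeta, N, F_, byrow = TRUE)
    s2 <- matrix(dgamma, N, F_, byrow = TRUE)
    dA <- gam / (N * matrix(cache$sdv, N, F_, byrow = TRUE)) *
      (N * dYmat - s1 - cache$Ahat * s2)
  } else {
    dgamma <- NULL; dbeta <- NULL
    dA <- dYmat
  }
  dZ <- dA * (cache$Z > 0)
  dWc <- crossprod(cache$M, dZ) + 2 * cfg$l2_coeff * params$Wc
  dbc <- colSums(dZ)
  out <- list(Wc = dWc, bc = dbc)
  if (cfg$batch_norm) {
    out$gamma <- dgamma
    out$beta <- dbeta
  }
  out
}

# Binary cross-entropy loss (mean over batch) with l2 penalty on the conv
# kernels, plus gradients for every parameter. X must be standardized.
loss_and_grads <- function(params, X, y, cfg, bn, training = TRUE) {
  n <- dim(X)[1]
  fw <- forward_batch(params, X, cfg, bn, training = training)
  p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  if (uses_conv(cfg)) loss <- loss + cfg$l2_coeff * sum(params$Wc^2)

  head <- fw$cache$head
  grads <- list()
  dlogit <- matrix((fw$prob - y) / n, n, 1)
  grads$W3 <- crossprod(head$H2, dlogit)
  grads$b3 <- colSums(dlogit)
  dH2 <- dlogit %*% t(params$W3)
  dZ2 <- dH2 * (head$Z2 > 0)
  grads$W2 <- crossprod(head$H1, dZ2)
  grads$b2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(params$W2)
  dZ1 <- dH1 * (head$Z1 > 0)
  grads$W1 <- crossprod(head$U, dZ1)
  grads$b1 <- colSums(dZ1)
  dU <- dZ1 %*% t(params$W1)

  H <- cfg$hidden_size
  need_dS <- uses_conv(cfg)
  dS_steps <- NULL
  if (uses_recurrent(cfg)) {
    Tp <- length(fw$cache$steps)
    if (cfg$arch %in% c("bilstm", "1dcnn-bilstm")) {
      bf <- lstm_batch_backward(params$Wlf, fw$cache$lstm_f$caches,
                                dU[, seq_len(H), drop = FALSE], H)
      bb <- lstm_batch_backward(params$Wlb, fw$cache$lstm_b$caches,
                                dU[, H + seq_len(H), drop = FALSE], H)
      grads$Wlf <- bf$dW; grads$blf <- bf$db
      grads$Wlb <- bb$dW; grads$blb <- bb$db
      if (need_dS) {
        dS_steps <- bf$dX
        rev_dx <- rev(bb$dX)
        for (t in seq_len(Tp)) dS_steps[[t]] <- dS_steps[[t]] + rev_dx[[t]]
      }
    } else {
      bf <- lstm_batch_backward(params$Wlf, fw$cache$lstm_f$caches, dU, H)
      grads$Wlf <- bf$dW; grads$blf <- bf$db
      if (need_dS) dS_steps <- bf$dX
    }
  }

  if (uses_conv(cfg)) {
    Lp <- pool_out_len(cfg); F_ <- cfg$n_filters
    dP <- if (uses_recurrent(cfg)) {
      arr <- array(0, c(n, Lp, F_))
      for (t in seq_len(Lp)) arr[, t, ] <- dS_steps[[t]]
      arr
    } else {
      array(dU, c(n, Lp, F_))
    }
    cg <- conv_stack_backward(params, cfg, fw$cache$conv, dP)
    grads$Wc <- cg$Wc; grads$bc <- cg$bc
    if (cfg$batch_norm) { grads$gamma <- cg$gamma; grads$beta <- cg$beta }
  }

  list(loss = loss, grads = grads, prob = fw$prob, bn = fw$bn)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

eval_loss_acc <- function(params, X, y, cfg, bn) {
  fw <- forward_batch(params, X, cfg, bn, training = FALSE)
  p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  list(loss = -mean(y * log(p) + (1 - y) * log(1 - p)),
       acc = mean(as.integer(fw$prob >= 0.5) == y))
}

#' Train a model on a labeled dataset
#'
#' Minimises mean binary cross-entropy (plus the conv-kernel l2 penalty)
#' with mini-batch Adam. A stratified validation fraction is carved from
#' the training data for early stopping: training halts after `patience`
#' epochs without validation-loss improvement and the best-epoch weights
#' are restored. Fully deterministic for a fixed config seed.
#'
#' @param model an untrained model from [build_model()].
#' @param dataset a `labeled_dataset` whose channel count matches the model
#'   config; both classes must be present.
#' @param verbose print per-epoch progress.
#' @return The trained model, with `history` (per-epoch losses) attached.
#' @export
train_model <- function(model, dataset, verbose = FALSE) {
  stopifnot(inherits(model, "smokesense_model"),
            inherits(dataset, "labeled_dataset"))
  cfg <- model$config
  y <- dataset$meta$label
  if (length(unique(y)) < 2)
    stopf("training set must contain both classes")
  if (dim(dataset$x)[3] != cfg$n_channels)
    stopf("dataset has %d channels, model expects %d", dim(dataset$x)[3],
          cfg$n_channels)
  X <- dataset$x
  n <- dim(X)[1]

  # per-channel z-scoring with training statistics only
  center <- apply(X, 3, mean)
  scale_ <- apply(X, 3, sd)
  scale_[scale_ < 1e-12] <- 1
  model$norm <- list(center = center, scale = scale_)
  model$channels <- dataset$channels
  X <- standardize_batch(X, model$norm)

  # stratified validation split for early stopping
  val_idx <- integer()
  if (cfg$validation_frac > 0) {
    val_idx <- with_seed(child_seed(cfg$seed, "val"), {
      unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        k <- floor(cfg$validation_frac * length(idx))
        if (k >= 1 && length(idx) - k >= 1) sample(idx, k) else integer()
      }))
    })
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  has_val <- length(val_idx) > 0
  Xv <- X[val_idx, , , drop = FALSE]; yv <- y[val_idx]
  Xt <- X[tr_idx, , , drop = FALSE]; yt <- y[tr_idx]
  nt <- length(tr_idx)

  params <- model$params
  bn <- model$bn
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, bn = bn, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  wait <- 0L

  with_seed(child_seed(cfg$seed, "batches"), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(nt)
      batch_losses <- numeric()
      for (b0 in seq(1, nt, by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, nt)]
        if (length(bi) < 2) next  # batch statistics need >= 2 rows
        lg <- loss_and_grads(params, Xt[bi, , , drop = FALSE], yt[bi],
                             cfg, bn, training = TRUE)
        bn <- lg$bn
        upd <- adam_step(params, lg$grads, opt, cfg$learning_rate)
        params <- upd$params; opt <- upd$state
        batch_losses <- c(batch_losses, lg$loss)
      }
      monitor <- if (has_val) {
        ev <- eval_loss_acc(params, Xv, yv, cfg, bn)
        hist <- rbind(hist, data.frame(epoch = epoch,
                                       train_loss = mean(batch_losses),
                                       val_loss = ev$loss, val_acc = ev$acc))
        ev$loss
      } else {
        hist <- rbind(hist, data.frame(epoch = epoch,
                                       train_loss = mean(batch_losses),
                                       val_loss = NA_real_,
                                       val_acc = NA_real_))
        mean(batch_losses)
      }
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  monitor %.4f", epoch,
                        mean(batch_losses), monitor))
      if (monitor < best$loss - 1e-6) {
        best <- list(loss = monitor, params = params, bn = bn, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })

  model$params <- best$params
  model$bn <- best$bn
  model$trained <- TRUE
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}
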