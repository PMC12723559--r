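# Minimal multilayer perceptron with ReLU hidden layers, softmax output,
# categorical cross-entropy and Nadam (Adam with Nesterov momentum).
# Deterministic under a fixed seed; used by the spike-count decoder and the
# aging-mechanism classifier.

mlp_init <- function(sizes, init_sd = 0.05) {
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, init_sd),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  nl <- length(par$W)
  acts <- vector("list", nl + 1)
  acts[[1]] <- X
  for (l in seq_len(nl)) {
    Z <- acts[[l]] %*% par$W[[l]] +
      matrix(par$b[[l]], nrow(X), length(par$b[[l]]), byrow = TRUE)
    acts[[l + 1]] <- if (l < nl) pmax(Z, 0) else Z
  }
  # softmax with max-shift for stability
  Z <- acts[[nl + 1]]
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z)
  P <- P / rowSums(P)
  list(acts = acts, probs = P)
}

mlp_loss <- function(par, X, Y) {
  P <- mlp_forward(par, X)$probs
  -mean(log(pmax(rowSums(Y * P), 1e-12)))
}

mlp_grad <- function(par, X, Y) {
  nl <- length(par$W)
  fw <- mlp_forward(par, X)
  n <- nrow(X)
  delta <- (fw$probs - Y) / n
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in nl:1) {
    gW[[l]] <- t(fw$acts[[l]]) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * (fw$acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

# train on (X, y); y is an integer class index 1..K; returns fitted
# parameters plus the per-epoch validation loss
mlp_fit <- function(X, y, n_classes, hidden = c(20, 20), lr = 0.001,
                    epochs = 100, batch_size = 32, patience = 10,
                    X_val = NULL, y_val = NULL, init_sd = 0.05,
                    seed = 1) {
  with_seed(seed, {
    sizes <- c(ncol(X), hidden, n_classes)
    par <- mlp_init(sizes, init_sd)
    onehot <- function(yy) {
      Y <- matrix(0, length(yy), n_classes)
      Y[cbind(seq_along(yy), yy)] <- 1
      Y
    }
    Y <- onehot(y)
    Y_val <- if (!is.null(y_val)) onehot(y_val) else NULL

    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    m <- list(W = lapply(par$W, function(w) w * 0),
              b = lapply(par$b, function(v) v * 0))
    v <- m
    t_step <- 0
    best <- list(loss = Inf, par = par, epoch = 0)
    n <- nrow(X)
    val_hist <- numeric(0)

    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        g <- mlp_grad(par, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
        t_step <- t_step + 1
        bc1 <- 1 - beta1^t_step; bc2 <- 1 - beta2^t_step
        for (l in seq_along(par$W)) {
          for (fld in c("W", "b")) {
            gg <- g[[fld]][[l]]
            m[[fld]][[l]] <- beta1 * m[[fld]][[l]] + (1 - beta1) * gg
            v[[fld]][[l]] <- beta2 * v[[fld]][[l]] + (1 - beta2) * gg^2
            mhat <- m[[fld]][[l]] / bc1
            vhat <- v[[fld]][[l]] / bc2
            # Nesterov momentum lookahead
            upd <- (beta1 * mhat + (1 - beta1) * gg / bc1) /
              (sqrt(vhat) + eps)
            par[[fld]][[l]] <- par[[fld]][[l]] - lr * upd
          }
        }
      }
      if (!is.null(Y_val)) {
        vl <- mlp_loss(par, X_val, Y_val)
        val_hist <- c(val_hist, vl)
        if (vl < best$loss - 1e-9) {
          best <- list(loss = vl, par = par, epoch = ep)
        } else if (ep - best$epoch >= patience) {
          par <- best$par
          break
        }
      }
    }
    if (!is.null(Y_val) && best$loss < Inf) par <- best$par
    list(par = par, n_classes = n_classes, val_loss = val_hist,
         epochs_run = if (!is.null(Y_val)) length(val_hist) else epochs)
  })
}

mlp_probs <- function(fit, X) mlp_forward(fit$par, X)$probs

mlp_predict_class <- function(fit, X) max.col(mlp_probs(fit, X))
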