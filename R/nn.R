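# Neural-network primitives: dense layers, LayerNorm/BatchNorm, dropout,
# softmax cross-entropy, and Adam with decoupled weight decay. Written in
# base R matrix algebra with explicit forward caches and hand-derived
# backward passes; correctness is pinned by finite-difference gradient
# checks in the test suite.

nn_linear_init <- function(fan_in, fan_out) {
  list(W = matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
                  fan_in, fan_out),
       b = numeric(fan_out))
}

nn_linear_fwd <- function(p, x) {
  list(out = sweep(x %*% p$W, 2, p$b, "+"), x = x)
}

nn_linear_bwd <- function(p, cache, dout) {
  list(dx = dout %*% t(p$W),
       dW = t(cache$x) %*% dout,
       db = colSums(dout))
}

nn_norm_init <- function(dim) {
  list(gamma = rep(1, dim), beta = numeric(dim),
       run_mean = numeric(dim), run_var = rep(1, dim))
}

.bn_eps <- 1e-5
.bn_momentum <- 0.9

# BatchNorm over rows (the flattened atom axis for per-atom layers, the
# sample axis in the head). Training mode returns updated running stats.
nn_batchnorm_fwd <- function(p, x, train) {
  if (train && nrow(x) > 1) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    inv_sd <- 1 / sqrt(v + .bn_eps)
    xhat <- sweep(xc, 2, inv_sd, "*")
    p$run_mean <- .bn_momentum * p$run_mean + (1 - .bn_momentum) * mu
    p$run_var <- .bn_momentum * p$run_var + (1 - .bn_momentum) * v
    out <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
    list(out = out, cache = list(xhat = xhat, xc = xc, inv_sd = inv_sd,
                                 train = TRUE), p = p)
  } else {
    inv_sd <- 1 / sqrt(p$run_var + .bn_eps)
    xhat <- sweep(sweep(x, 2, p$run_mean), 2, inv_sd, "*")
    out <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
    list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, train = FALSE),
         p = p)
  }
}

nn_batchnorm_bwd <- function(p, cache, dout) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, p$gamma, "*")
  if (isTRUE(cache$train)) {
    n <- nrow(dxhat)
    dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dxhat), byrow = TRUE) -
                  cache$xhat * matrix(colMeans(dxhat * cache$xhat), n,
                                      ncol(dxhat), byrow = TRUE),
                2, cache$inv_sd, "*")
  } else {
    dx <- sweep(dxhat, 2, cache$inv_sd, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# LayerNorm per row (per atom vector / per pooled sample vector).
nn_layernorm_fwd <- function(p, x, train) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + .bn_eps)
  xhat <- xc * inv_sd
  out <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd), p = p)
}

nn_layernorm_bwd <- function(p, cache, dout) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, p$gamma, "*")
  dx <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) *
    cache$inv_sd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

nn_relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
nn_relu_bwd <- function(cache, dout) dout * cache$mask

nn_dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  mask <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}

nn_dropout_bwd <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# Softmax cross-entropy; labels are 0-based class indices.
nn_softmax_ce <- function(logits, labels) {
  n <- nrow(logits)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-300)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = probs, dlogits = dlogits / n)
}

# Adam with decoupled weight decay over a nested list of parameter arrays.
adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      decay_exempt = c("gamma", "beta", "b")) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v, path) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], nm)
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      upd <- mhat / (sqrt(vhat) + eps)
      if (!(path %in% decay_exempt) && weight_decay > 0) {
        upd <- upd + weight_decay * p
      }
      list(p = p - lr * upd, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v, "")
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
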