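# Permutation-invariant set classifier over Gabor atoms: a per-atom encoder,
# a shared MLP, a symmetric pooling mechanism, and an MLP output head. Each
# sample is the (unordered, variable-cardinality) set of atom feature rows of
# one segment; all per-atom layers are applied identically to every atom, so
# the output is invariant to atom order by construction.

#' Configuration for the set classifier
#'
#' @param input_dim feature column count per atom (9, or 10 with the encoded
#'   patient ID appended).
#' @param latent_dim atom-encoder output width, in `[4, 512]`.
#' @param hidden_dim hidden width of the encoder/shared-MLP/head, `[4, 512]`.
#' @param pooling one of `"mean"`, `"max"`, `"attention"`, `"sum"`.
#' @param dropout_rate dropout fraction in `[0, 0.5]`, applied after
#'   activations in the encoder and head.
#' @param regularization one of `"None"`, `"LayerNorm"`, `"BatchNorm"`,
#'   applied after each hidden linear layer, before the activation
#'   (BatchNorm normalizes over the flattened atom axis within a batch;
#'   LayerNorm per atom vector).
#' @param n_classes number of classes (2: pre = 0, post = 1).
#' @param seed RNG seed for weight initialization.
#' @return object of class `deepset_config`.
#' @export
model_config <- function(input_dim, latent_dim = 32L, hidden_dim = 64L,
                         pooling = c("mean", "max", "attention", "sum"),
                         dropout_rate = 0, regularization = "None",
                         n_classes = 2L, seed = 1L) {
  pooling <- match.arg(pooling)
  stopifnot(latent_dim >= 4, latent_dim <= 512,
            hidden_dim >= 4, hidden_dim <= 512,
            dropout_rate >= 0, dropout_rate <= 0.5,
            regularization %in% c("None", "LayerNorm", "BatchNorm"),
            n_classes == 2)
  structure(list(input_dim = as.integer(input_dim),
                 latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim),
                 pooling = pooling, dropout_rate = dropout_rate,
                 regularization = regularization,
                 n_classes = as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "deepset_config")
}

#' Initialize a set-classifier model
#' @param config a [model_config()].
#' @return object of class `deepset_model` holding parameters and config.
#' @export
deepset_init <- function(config) {
  stopifnot(inherits(config, "deepset_config"))
  h <- config$hidden_dim
  L <- config$latent_dim
  h2 <- max(2L, h %/% 2L)
  with_seed(config$seed, {
    params <- list(
      enc1 = nn_linear_init(config$input_dim, h),
      enc2 = nn_linear_init(h, L),
      shared = nn_linear_init(L, h),
      head1 = nn_linear_init(h, h2),
      head2 = nn_linear_init(h2, config$n_classes))
    if (config$regularization != "None") {
      params$norm1 <- nn_norm_init(h)
      params$norm2 <- nn_norm_init(L)
      params$norm3 <- nn_norm_init(h)
      params$norm4 <- nn_norm_init(h2)
    }
    if (config$pooling == "attention") {
      params$attn <- list(W = matrix(stats::rnorm(h, sd = 1 / sqrt(h)), h, 1),
                          b = 0)
    }
    structure(list(params = params, config = config, h2 = h2),
              class = "deepset_model")
  })
}

#' @exportS3Method base::print
print.deepset_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "deepset_model: %d -> %d -> %d (latent) -> %d, pooling=%s, dropout=%.2f, reg=%s\n",
    cfg$input_dim, cfg$hidden_dim, cfg$latent_dim, cfg$hidden_dim,
    cfg$pooling, cfg$dropout_rate, cfg$regularization))
  invisible(x)
}

norm_fwd <- function(model, name, x, train) {
  reg <- model$config$regularization
  if (reg == "None") return(list(out = x, cache = NULL, model = model))
  f <- if (reg == "BatchNorm") nn_batchnorm_fwd else nn_layernorm_fwd
  r <- f(model$params[[name]], x, train)
  model$params[[name]] <- r$p
  list(out = r$out, cache = r$cache, model = model)
}

norm_bwd <- function(model, name, cache, dout) {
  reg <- model$config$regularization
  if (reg == "None") return(list(dx = dout, grads = NULL))
  f <- if (reg == "BatchNorm") nn_batchnorm_bwd else nn_layernorm_bwd
  r <- f(model$params[[name]], cache, dout)
  list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

# Group index helper: list of row indices per sample in a stacked atom matrix.
group_indices <- function(sid, n_samples) {
  split(seq_along(sid), factor(sid, levels = seq_len(n_samples)))
}

#' Attention pooling of per-atom vectors
#'
#' Scores `s_i = w . v_i + b`, weights `alpha = softmax(s)` within each
#' sample, output `sum_i alpha_i v_i` (so `sum alpha_i = 1`): single-head
#' additive gating, the simplest permutation-invariant attention.
#'
#' @param H `n_atoms x dim` matrix of per-atom vectors.
#' @param w,b score weight vector (length dim) and bias.
#' @param sid sample index per row (defaults to a single sample).
#' @return list with `pooled` (`n_samples x dim`) and `alpha`.
#' @export
attention_pool <- function(H, w, b = 0, sid = rep(1L, nrow(H))) {
  n_samples <- max(sid)
  scores <- as.numeric(H %*% matrix(w, ncol = 1)) + b
  gmax <- as.numeric(tapply(scores, sid, max)[as.character(sid)])
  e <- exp(scores - gmax)
  denom <- as.numeric(rowsum(e, sid)[sid, 1])
  alpha <- e / denom
  pooled <- rowsum(H * alpha, sid)
  list(pooled = pooled, alpha = alpha)
}

pool_fwd <- function(model, H, sid, n_samples, groups) {
  pooling <- model$config$pooling
  if (pooling == "sum") {
    list(out = rowsum(H, sid), cache = list())
  } else if (pooling == "mean") {
    counts <- as.numeric(lengths(groups))
    list(out = rowsum(H, sid) / counts, cache = list(counts = counts))
  } else if (pooling == "max") {
    d <- ncol(H)
    out <- matrix(0, n_samples, d)
    argmax <- matrix(0L, n_samples, d)
    for (g in seq_len(n_samples)) {
      rows <- groups[[g]]
      sub <- H[rows, , drop = FALSE]
      am <- max.col(t(sub), ties.method = "first")
      argmax[g, ] <- rows[am]
      out[g, ] <- sub[cbind(am, seq_len(d))]
    }
    list(out = out, cache = list(argmax = argmax))
  } else {  # attention
    ap <- attention_pool(H, model$params$attn$W[, 1], model$params$attn$b, sid)
    list(out = ap$pooled, cache = list(alpha = ap$alpha, H = H))
  }
}

pool_bwd <- function(model, cache, dpool, H, sid, n_samples, groups) {
  pooling <- model$config$pooling
  if (pooling == "sum") {
    list(dH = dpool[sid, , drop = FALSE], grads = NULL)
  } else if (pooling == "mean") {
    list(dH = dpool[sid, , drop = FALSE] / cache$counts[sid], grads = NULL)
  } else if (pooling == "max") {
    dH <- matrix(0, nrow(H), ncol(H))
    d <- ncol(H)
    for (g in seq_len(n_samples)) {
      idx <- cbind(cache$argmax[g, ], seq_len(d))
      dH[idx] <- dH[idx] + dpool[g, ]
    }
    list(dH = dH, grads = NULL)
  } else {  # attention
    alpha <- cache$alpha
    w <- model$params$attn$W[, 1]
    dH <- dpool[sid, , drop = FALSE] * alpha
    dalpha <- rowSums(dpool[sid, , drop = FALSE] * H)
    s_dot <- rowsum(alpha * dalpha, sid)[sid, 1]
    dscores <- alpha * (dalpha - s_dot)
    dH <- dH + outer(dscores, w)
    dW <- matrix(colSums(H * dscores), ncol = 1)
    db <- sum(dscores)
    list(dH = dH, grads = list(attn = list(W = dW, b = db)))
  }
}

#' Forward pass of the set classifier on a stacked atom batch
#'
#' @param model a `deepset_model`.
#' @param X stacked atom feature matrix (`total_atoms x input_dim`).
#' @param sid integer sample index (1..n_samples) per atom row.
#' @param n_samples number of samples in the batch.
#' @param train `FALSE` (eval mode: dropout off, norm statistics frozen) or
#'   `TRUE` (dropout active, BatchNorm uses and updates batch statistics).
#' @return list with `logits` (`n_samples x 2`), `latent` (`total_atoms x
#'   latent_dim`, the atom-encoder output), `model` (with updated running
#'   statistics when training), and `cache` for [deepset_backward()].
#' @export
deepset_forward <- function(model, X, sid, n_samples = max(sid),
                            train = FALSE) {
  stopifnot(inherits(model, "deepset_model"))
  if (!all(is.finite(X))) stop("NaN or non-finite values in features")
  cfg <- model$config
  groups <- group_indices(sid, n_samples)
  drop <- cfg$dropout_rate

  l1 <- nn_linear_fwd(model$params$enc1, X)
  n1 <- norm_fwd(model, "norm1", l1$out, train); model <- n1$model
  r1 <- nn_relu_fwd(n1$out)
  d1 <- nn_dropout_fwd(r1$out, drop, train)

  l2 <- nn_linear_fwd(model$params$enc2, d1$out)
  n2 <- norm_fwd(model, "norm2", l2$out, train); model <- n2$model
  r2 <- nn_relu_fwd(n2$out)
  latent <- r2$out                    # atom-encoder output = the atom latent
  d2 <- nn_dropout_fwd(latent, drop, train)

  l3 <- nn_linear_fwd(model$params$shared, d2$out)
  n3 <- norm_fwd(model, "norm3", l3$out, train); model <- n3$model
  r3 <- nn_relu_fwd(n3$out)
  H <- r3$out

  pf <- pool_fwd(model, H, sid, n_samples, groups)

  l4 <- nn_linear_fwd(model$params$head1, pf$out)
  n4 <- norm_fwd(model, "norm4", l4$out, train); model <- n4$model
  r4 <- nn_relu_fwd(n4$out)
  d4 <- nn_dropout_fwd(r4$out, drop, train)

  l5 <- nn_linear_fwd(model$params$head2, d4$out)

  cache <- list(l1 = l1, n1 = n1$cache, r1 = r1, d1 = d1,
                l2 = l2, n2 = n2$cache, r2 = r2, d2 = d2,
                l3 = l3, n3 = n3$cache, r3 = r3,
                pool = pf$cache, H = H,
                l4 = l4, n4 = n4$cache, r4 = r4, d4 = d4, l5 = l5,
                sid = sid, n_samples = n_samples, groups = groups)
  list(logits = l5$out, latent = latent, model = model, cache = cache)
}

#' Backward pass (gradients of all parameters)
#' @param model a `deepset_model`.
#' @param cache from [deepset_forward()] with `train = TRUE`.
#' @param dlogits upstream gradient on the logits.
#' @return nested gradient list matching `model$params`.
#' @export
deepset_backward <- function(model, cache, dlogits) {
  grads <- list()
  b5 <- nn_linear_bwd(model$params$head2, cache$l5, dlogits)
  grads$head2 <- list(W = b5$dW, b = b5$db)
  dd4 <- nn_dropout_bwd(cache$d4, b5$dx)
  dr4 <- nn_relu_bwd(cache$r4, dd4)
  nb4 <- norm_bwd(model, "norm4", cache$n4, dr4)
  if (!is.null(nb4$grads)) grads$norm4 <- nb4$grads
  b4 <- nn_linear_bwd(model$params$head1, cache$l4, nb4$dx)
  grads$head1 <- list(W = b4$dW, b = b4$db)

  pb <- pool_bwd(model, cache$pool, b4$dx, cache$H, cache$sid,
                 cache$n_samples, cache$groups)
  if (!is.null(pb$grads)) grads <- c(grads, pb$grads)

  dr3 <- nn_relu_bwd(cache$r3, pb$dH)
  nb3 <- norm_bwd(model, "norm3", cache$n3, dr3)
  if (!is.null(nb3$grads)) grads$norm3 <- nb3$grads
  b3 <- nn_linear_bwd(model$params$shared, cache$l3, nb3$dx)
  grads$shared <- list(W = b3$dW, b = b3$db)

  dd2 <- nn_dropout_bwd(cache$d2, b3$dx)
  dr2 <- nn_relu_bwd(cache$r2, dd2)
  nb2 <- norm_bwd(model, "norm2", cache$n2, dr2)
  if (!is.null(nb2$grads)) grads$norm2 <- nb2$grads
  b2 <- nn_linear_bwd(model$params$enc2, cache$l2, nb2$dx)
  grads$enc2 <- list(W = b2$dW, b = b2$db)

  dd1 <- nn_dropout_bwd(cache$d1, b2$dx)
  dr1 <- nn_relu_bwd(cache$r1, dd1)
  nb1 <- norm_bwd(model, "norm1", cache$n1, dr1)
  if (!is.null(nb1$grads)) grads$norm1 <- nb1$grads
  b1 <- nn_linear_bwd(model$params$enc1, cache$l1, nb1$dx)
  grads$enc1 <- list(W = b1$dW, b = b1$db)
  grads
}

# Stack a list of samples into one atom matrix with sample indices.
stack_samples <- function(samples, idx = seq_along(samples)) {
  mats <- lapply(samples[idx], `[[`, "features")
  X <- do.call(rbind, mats)
  sid <- rep(seq_along(idx), vapply(mats, nrow, integer(1)))
  y <- vapply(samples[idx], `[[`, integer(1), "label")
  list(X = X, sid = sid, y = y, n = length(idx))
}

#' Classify samples (eval mode)
#'
#' @param model a trained `deepset_model`.
#' @param samples scaled sample list ([apply_scaler()] output).
#' @param idx subset of samples to classify.
#' @return list with `pred` (0/1), `probs`, `logits`, `labels`.
#' @export
deepset_predict <- function(model, samples, idx = seq_along(samples)) {
  st <- stack_samples(samples, idx)
  fw <- deepset_forward(model, st$X, st$sid, st$n, train = FALSE)
  probs <- {
    m <- apply(fw$logits, 1, max)
    e <- exp(fw$logits - m)
    e / rowSums(e)
  }
  list(pred = as.integer(max.col(fw$logits, ties.method = "first") - 1L),
       probs = probs, logits = fw$logits, labels = st$y)
}
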