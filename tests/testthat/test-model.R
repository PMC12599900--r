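test_that("config bounds are enforced", {
  expect_error(model_config(9, latent_dim = 2), "latent_dim")
  expect_error(model_config(9, dropout_rate = 0.7), "dropout")
  expect_error(model_config(9, regularization = "Weird"), "regularization")
  cfg <- model_config(9, pooling = "attention", regularization = "LayerNorm")
  expect_s3_class(cfg, "deepset_config")
})

test_that("analytic gradients match finite differences", {
  for (pool in c("mean", "sum", "max", "attention")) {
    for (reg in c("None", "LayerNorm", "BatchNorm")) {
      cfg <- model_config(input_dim = 6, latent_dim = 5, hidden_dim = 8,
                          pooling = pool, dropout_rate = 0,
                          regularization = reg, seed = 3)
      m <- deepset_init(cfg)
      b <- random_batch(3, dim = 6, seed = 7)
      loss_fn <- function(params) {
        m2 <- m
        m2$params <- params
        fw <- deepset_forward(m2, b$X, b$sid, b$n, train = TRUE)
        nn_softmax_ce(fw$logits, b$y)$loss
      }
      fw <- deepset_forward(m, b$X, b$sid, b$n, train = TRUE)
      ce <- nn_softmax_ce(fw$logits, b$y)
      gr <- deepset_backward(m, fw$cache, ce$dlogits)
      for (top in names(gr)) {
        for (leaf in names(gr[[top]])) {
          g <- gr[[top]][[leaf]]
          for (ii in seq_len(min(length(g), 3))) {
            eps <- 1e-6
            p2 <- m$params
            p2[[top]][[leaf]][ii] <- p2[[top]][[leaf]][ii] + eps
            p3 <- m$params
            p3[[top]][[leaf]][ii] <- p3[[top]][[leaf]][ii] - eps
            num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
            expect_lt(abs(num - g[ii]), 1e-6)
          }
        }
      }
    }
  }
})

test_that("logits are invariant to atom permutation (all poolings)", {
  for (pool in c("mean", "max", "attention", "sum")) {
    cfg <- model_config(input_dim = 9, latent_dim = 8, hidden_dim = 12,
                        pooling = pool, dropout_rate = 0.3,
                        regularization = "LayerNorm", seed = 2)
    m <- deepset_init(cfg)
    b <- random_batch(4, seed = 21)
    base <- deepset_forward(m, b$X, b$sid, b$n)$logits
    for (rep in 1:10) {
      perm <- with_seed(rep, unlist(lapply(split(seq_along(b$sid), b$sid),
                                           sample)))
      out <- deepset_forward(m, b$X[perm, , drop = FALSE], b$sid[perm],
                             b$n)$logits
      expect_lt(max(abs(out - base)), 1e-6)
    }
  }
})

test_that("single-atom samples pool identically under mean, sum, attention", {
  X <- matrix(stats::rnorm(9), 1, 9)
  outs <- lapply(c("mean", "sum", "attention"), function(pool) {
    cfg <- model_config(9, latent_dim = 6, hidden_dim = 8, pooling = pool,
                        seed = 5)
    m <- deepset_init(cfg)
    fw <- deepset_forward(m, X, 1L, 1L)
    pool_fwd <- pcgatoms:::pool_fwd
    groups <- pcgatoms:::group_indices(1L, 1L)
    pool_fwd(m, fw$cache$H, 1L, 1L, groups)$out
  })
  expect_equal(outs[[1]], outs[[2]], tolerance = 1e-12)
  expect_equal(outs[[1]], outs[[3]], tolerance = 1e-12)
})

test_that("duplicating atoms doubles sum pooling, preserves mean pooling", {
  b <- random_batch(1, seed = 8, min_atoms = 5, max_atoms = 5)
  X2 <- rbind(b$X, b$X)
  for (pool in c("sum", "mean")) {
    cfg <- model_config(9, latent_dim = 6, hidden_dim = 8, pooling = pool,
                        seed = 4)
    m <- deepset_init(cfg)
    f1 <- deepset_forward(m, b$X, rep(1L, nrow(b$X)), 1L)
    f2 <- deepset_forward(m, X2, rep(1L, nrow(X2)), 1L)
    p1 <- pcgatoms:::pool_fwd(m, f1$cache$H, rep(1L, nrow(b$X)), 1L,
                              pcgatoms:::group_indices(rep(1L, nrow(b$X)), 1L))$out
    p2 <- pcgatoms:::pool_fwd(m, f2$cache$H, rep(1L, nrow(X2)), 1L,
                              pcgatoms:::group_indices(rep(1L, nrow(X2)), 1L))$out
    if (pool == "sum") expect_equal(p2, 2 * p1, tolerance = 1e-9)
    else expect_equal(p2, p1, tolerance = 1e-9)
  }
})

test_that("attention pooling follows its closed form", {
  H <- matrix(stats::rnorm(5 * 4), 5, 4)
  w <- stats::rnorm(4)
  ap <- attention_pool(H, w, 0.5)
  expect_equal(sum(ap$alpha), 1, tolerance = 1e-9)
  s <- as.numeric(H %*% w) + 0.5
  al <- exp(s - max(s)) / sum(exp(s - max(s)))
  expect_equal(as.numeric(ap$pooled), as.numeric(t(al) %*% H),
               tolerance = 1e-12)
  # identical atoms pool to the common vector
  Hc <- matrix(rep(H[1, ], 4), 4, byrow = TRUE)
  expect_equal(as.numeric(attention_pool(Hc, w)$pooled), H[1, ],
               tolerance = 1e-12)
  # a dominating score concentrates all weight on one atom
  H2 <- H
  sc <- as.numeric(H2 %*% w)
  H2[3, ] <- H2[3, ] + 50 * w / sum(w^2)   # push score 3 up by 50
  ap2 <- attention_pool(H2, w)
  expect_gt(ap2$alpha[3], 1 - 1e-9)
  expect_equal(as.numeric(ap2$pooled), H2[3, ], tolerance = 1e-6)
})

test_that("forward handles atom counts from 1 to 100", {
  cfg <- model_config(9, latent_dim = 6, hidden_dim = 8,
                      pooling = "attention", seed = 6)
  m <- deepset_init(cfg)
  for (k in c(1L, 2L, 50L, 100L)) {
    X <- matrix(stats::rnorm(k * 9), k, 9)
    fw <- deepset_forward(m, X, rep(1L, k), 1L)
    expect_identical(dim(fw$logits), c(1L, 2L))
    expect_identical(dim(fw$latent), c(k, 6L))
  }
})

test_that("eval-mode forward is bit-stable across runs", {
  cfg <- model_config(9, latent_dim = 6, hidden_dim = 8,
                      dropout_rate = 0.4, regularization = "BatchNorm",
                      seed = 9)
  b <- random_batch(3, seed = 10)
  m1 <- deepset_init(cfg)
  m2 <- deepset_init(cfg)
  expect_identical(deepset_forward(m1, b$X, b$sid, b$n)$logits,
                   deepset_forward(m2, b$X, b$sid, b$n)$logits)
})

test_that("non-finite features are rejected before the forward pass", {
  cfg <- model_config(9, seed = 1)
  m <- deepset_init(cfg)
  X <- matrix(stats::rnorm(18), 2, 9)
  X[1, 3] <- NaN
  expect_error(deepset_forward(m, X, c(1L, 1L), 1L), "finite|NaN")
})
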