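# A small CART random forest (gini impurity, bootstrap sampling, mtry
# feature subsampling) for the flattened-feature baseline. No forest package
# ships with the target library, so the classic algorithm is implemented
# here; it is deliberately plain: binary classification only.

rf_build_tree <- function(X, y, mtry, max_depth, min_node) {
  p <- ncol(X)
  nodes <- list()
  # each queue entry: row indices + depth; nodes stored as lists with either
  # a split (feature, threshold, children) or a leaf prediction
  new_node <- function() length(nodes) + 1L
  grow <- function(idx, depth) {
    id <- new_node()
    nodes[[id]] <<- list()  # reserve slot
    n1 <- sum(y[idx] == 1L)
    n <- length(idx)
    if (depth >= max_depth || n < min_node || n1 == 0L || n1 == n) {
      nodes[[id]] <<- list(leaf = TRUE, pred = as.integer(n1 * 2L > n))
      return(id)
    }
    g_parent <- 1 - (n1 / n)^2 - (1 - n1 / n)^2
    feats <- sample.int(p, mtry)
    best <- list(score = g_parent - 1e-12, feat = NA, thr = NA)
    for (f in feats) {
      xf <- X[idx, f]
      ord <- order(xf)
      xs <- xf[ord]
      ys <- y[idx][ord] == 1L
      cum1 <- cumsum(ys)
      i <- seq_len(n - 1L)
      valid <- xs[i] < xs[i + 1L]
      if (!any(valid)) next
      l1 <- cum1[i]
      ln <- i
      r1 <- n1 - l1
      rn <- n - i
      gl <- 1 - (l1 / ln)^2 - (1 - l1 / ln)^2
      gr <- 1 - (r1 / rn)^2 - (1 - r1 / rn)^2
      w <- (ln * gl + rn * gr) / n
      w[!valid] <- Inf
      k <- which.min(w)
      if (w[k] < best$score) {
        best <- list(score = w[k], feat = f, thr = (xs[k] + xs[k + 1L]) / 2)
      }
    }
    if (is.na(best$feat)) {
      nodes[[id]] <<- list(leaf = TRUE, pred = as.integer(n1 * 2L > n))
      return(id)
    }
    left <- idx[X[idx, best$feat] <= best$thr]
    right <- idx[X[idx, best$feat] > best$thr]
    lid <- grow(left, depth + 1L)
    rid <- grow(right, depth + 1L)
    nodes[[id]] <<- list(leaf = FALSE, feat = best$feat, thr = best$thr,
                         left = lid, right = rid)
    id
  }
  root <- grow(seq_len(nrow(X)), 0L)
  list(nodes = nodes, root = root)
}

rf_tree_predict <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  stack <- list(list(id = tree$root, idx = seq_len(n)))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- tree$nodes[[top$id]]
    if (isTRUE(node$leaf)) {
      out[top$idx] <- node$pred
    } else {
      go_left <- X[top$idx, node$feat] <= node$thr
      if (any(go_left)) {
        stack[[length(stack) + 1L]] <- list(id = node$left,
                                            idx = top$idx[go_left])
      }
      if (any(!go_left)) {
        stack[[length(stack) + 1L]] <- list(id = node$right,
                                            idx = top$idx[!go_left])
      }
    }
  }
  out
}

#' Fit a random forest classifier (binary labels 0/1)
#'
#' @param X numeric feature matrix.
#' @param y integer labels (0/1).
#' @param n_trees forest size (default 100).
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param max_depth,min_node tree growth limits.
#' @param seed RNG seed (bootstrap + feature subsampling).
#' @return object of class `rf_model`.
#' @export
rf_fit <- function(X, y, n_trees = 100L, mtry = max(1L, floor(sqrt(ncol(X)))),
                   max_depth = 25L, min_node = 2L, seed = 1L) {
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  n <- nrow(X)
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      boot <- sample.int(n, n, replace = TRUE)
      rf_build_tree(X[boot, , drop = FALSE], y[boot], mtry, max_depth,
                    min_node)
    })
  })
  structure(list(trees = trees, n_trees = n_trees), class = "rf_model")
}

#' @rdname rf_fit
#' @param fit an `rf_model`.
#' @export
rf_predict <- function(fit, X) {
  votes <- rowSums(matrix(vapply(fit$trees,
                                 function(tr) rf_tree_predict(tr, X),
                                 integer(nrow(X))),
                          nrow = nrow(X)))
  as.integer(votes * 2L > fit$n_trees)
}
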