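# Dataset splitting, the optimization loop, random hyperparameter search
# over the documented space, and the Random Forest baseline.

#' Split specification
#'
#' @param fractions train/validation/test fractions (default 0.70/0.15/0.15).
#' @param batch_size minibatch size (default 16).
#' @param seed shuffle seed.
#' @param stratify_by `"label"` (default) or `"label+subject"`.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.70, val = 0.15, test = 0.15),
                       batch_size = 16L, seed = 1L,
                       stratify_by = c("label", "label+subject")) {
  stratify_by <- match.arg(stratify_by)
  stopifnot(abs(sum(fractions) - 1) < 1e-9, batch_size >= 1)
  structure(list(fractions = fractions, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), stratify_by = stratify_by),
            class = "split_spec")
}

#' Split samples into train/validation/test index sets
#'
#' Random shuffle under the spec's seed; sizes `round(0.7 n)`,
#' `round(0.15 n)`, remainder; disjoint and covering; stratified by label so
#' each split holds both classes when `n` permits. Note the default split is
#' sample-wise (overlapping windows from one recording can straddle splits,
#' matching the upstream protocol); use `stratify_by = "label+subject"` for
#' a coarser stratification.
#'
#' @param samples assembled sample list.
#' @param spec a [split_spec()].
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(samples, spec = split_spec()) {
  n <- length(samples)
  stopifnot(n >= 7)
  n_train <- round(spec$fractions[[1]] * n)
  n_val <- round(spec$fractions[[2]] * n)
  n_test <- n - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1) stop("a split would be empty")
  strata <- vapply(samples, function(s) {
    if (spec$stratify_by == "label") as.character(s$label)
    else paste(s$label, s$subject_id)
  }, character(1))
  with_seed(spec$seed, {
    # per-stratum shuffled queues consumed proportionally, realized by
    # ranking a uniform draw within each stratum
    u <- stats::runif(n)
    r <- stats::ave(u, strata, FUN = function(z) rank(z) / (length(z) + 1))
    ord <- order(r, u)
    list(train = sort(ord[seq_len(n_train)]),
         val = sort(ord[n_train + seq_len(n_val)]),
         test = sort(ord[n_train + n_val + seq_len(n_test)]))
  })
}

f1_score <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

.codename_adjectives <- c("lumpy", "chirpy", "fuzzy", "brassy", "mellow",
                          "spry", "dapper", "gusty", "plucky", "wobbly",
                          "zesty", "breezy", "mossy", "nimble", "quirky",
                          "rustic")
.codename_birds <- c("kagu", "heron", "siskin", "tern", "grebe", "plover",
                     "avocet", "bittern", "dunlin", "godwit", "kestrel",
                     "phalarope", "sora", "veery", "whimbrel", "osprey")

make_codename <- function(seed) {
  with_seed(derive_seed(seed, 777L), {
    paste(paste(sample(.codename_adjectives, 2), collapse = "-"),
          sample(.codename_birds, 1), sep = "-")
  })
}

eval_accuracy <- function(model, samples, idx) {
  if (!length(idx)) return(NA_real_)
  pr <- deepset_predict(model, samples, idx)
  mean(pr$pred == pr$labels)
}

#' Train one set-classifier model
#'
#' Cross-entropy loss, Adam with decoupled weight decay, minibatches of
#' `spec$batch_size`, early stopping on validation accuracy with the given
#' patience, best-validation-epoch weights restored. Test metrics are
#' computed once, after selection.
#'
#' @param samples scaled sample list.
#' @param splits from [split_dataset()].
#' @param config a [model_config()].
#' @param learning_rate,weight_decay optimizer parameters.
#' @param max_epochs,patience early-stopping budget (defaults 200 and 20).
#' @param batch_size minibatch size (default 16).
#' @param seed RNG seed for shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return object of class `trial_result`: config, per-split accuracies,
#'   per-class F1 on the test split, per-subject full-dataset accuracy
#'   table, training history, the trained model, and a generated code name.
#' @export
train_model <- function(samples, splits, config, learning_rate = 1e-3,
                        weight_decay = 0, max_epochs = 200L, patience = 20L,
                        batch_size = 16L, seed = config$seed,
                        verbose = FALSE) {
  model <- deepset_init(config)
  opt <- adam_init(model$params)
  best <- list(val_acc = -Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_acc = numeric(0))
  wait <- 0L
  diverged <- FALSE
  with_seed(derive_seed(seed, 13L), {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(splits$train)
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1, length(ord), by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
        st <- stack_samples(samples, idx)
        fw <- deepset_forward(model, st$X, st$sid, st$n, train = TRUE)
        model <- fw$model
        ce <- nn_softmax_ce(fw$logits, st$y)
        if (!is.finite(ce$loss)) { diverged <- TRUE; break }
        grads <- deepset_backward(model, fw$cache, ce$dlogits)
        upd <- adam_step(model$params, grads, opt, learning_rate,
                         weight_decay)
        model$params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + ce$loss
        nb <- nb + 1L
      }
      if (diverged) break
      val_acc <- eval_accuracy(model, samples, splits$val)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss / nb,
                                           val_acc = val_acc))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val acc %.3f", epoch,
                        ep_loss / nb, val_acc))
      }
      if (val_acc > best$val_acc) {
        best <- list(val_acc = val_acc, params = model$params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  if (diverged && !is.finite(best$val_acc)) {
    return(structure(list(failed = TRUE, config = config,
                          code_name = make_codename(seed)),
                     class = "trial_result"))
  }
  model$params <- best$params
  test_pr <- deepset_predict(model, samples, splits$test)
  subjects <- vapply(samples, `[[`, character(1), "subject_id")
  full_pr <- deepset_predict(model, samples)
  per_subject <- stats::aggregate(
    correct ~ subject_id,
    data = data.frame(subject_id = subjects,
                      correct = full_pr$pred == full_pr$labels),
    FUN = mean)
  names(per_subject)[2] <- "accuracy"
  structure(list(
    failed = FALSE,
    config = config,
    learning_rate = learning_rate,
    weight_decay = weight_decay,
    train_acc = eval_accuracy(model, samples, splits$train),
    val_acc = best$val_acc,
    test_acc = mean(test_pr$pred == test_pr$labels),
    f1_pre = f1_score(test_pr$pred, test_pr$labels, 0L),
    f1_post = f1_score(test_pr$pred, test_pr$labels, 1L),
    full_acc = mean(full_pr$pred == full_pr$labels),
    per_subject = per_subject,
    best_epoch = best$epoch,
    history = history,
    model = model,
    code_name = make_codename(seed)), class = "trial_result")
}

#' @exportS3Method base::print
print.trial_result <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat(sprintf("trial %s: FAILED (diverged)\n", x$code_name))
    return(invisible(x))
  }
  cat(sprintf("trial %s: val %.3f, test %.3f (F1 pre %.2f / post %.2f), full %.3f\n",
              x$code_name, x$val_acc, x$test_acc, x$f1_pre, x$f1_post,
              x$full_acc))
  invisible(x)
}

#' The hyperparameter search space
#'
#' Integer latent and hidden dimensions in `[4, 512]`; pooling in
#' mean/max/attention/sum; dropout in `[0, 0.5]`; regularization in
#' None/LayerNorm/BatchNorm; learning rate log-uniform in `[1e-4, 1e-2]`;
#' weight decay log-uniform with lower bound `1e-6` (the upper bound is set
#' to `1e-2`: a log-scale interval cannot reach an upper endpoint of 0).
#'
#' @return list of bounds, used by [hyperparameter_search()].
#' @export
search_space <- function() {
  list(latent_dim = c(4L, 512L),
       hidden_dim = c(4L, 512L),
       pooling = c("mean", "max", "attention", "sum"),
       dropout_rate = c(0, 0.5),
       regularization = c("None", "LayerNorm", "BatchNorm"),
       learning_rate = c(1e-4, 1e-2),
       weight_decay = c(1e-6, 1e-2))
}

sample_trial_params <- function(space, seed, input_dim) {
  with_seed(seed, {
    list(config = model_config(
           input_dim = input_dim,
           latent_dim = sample(space$latent_dim[1]:space$latent_dim[2], 1),
           hidden_dim = sample(space$hidden_dim[1]:space$hidden_dim[2], 1),
           pooling = sample(space$pooling, 1),
           dropout_rate = stats::runif(1, space$dropout_rate[1],
                                       space$dropout_rate[2]),
           regularization = sample(space$regularization, 1),
           seed = seed),
         learning_rate = 10^stats::runif(1, log10(space$learning_rate[1]),
                                         log10(space$learning_rate[2])),
         weight_decay = 10^stats::runif(1, log10(space$weight_decay[1]),
                                        log10(space$weight_decay[2])))
  })
}

#' Random hyperparameter search maximizing validation accuracy
#'
#' Draws `n_trials` seeded configurations from [search_space()] (trial `t`
#' uses a sub-seed derived from `seed` and `t`, so the sampled schedule is
#' nested: the first `k` trials of a larger budget equal a budget of `k`),
#' trains each, and ranks by validation accuracy. Failed (diverged) trials
#' are recorded but never fatal unless all fail.
#'
#' @param samples scaled sample list.
#' @param splits from [split_dataset()].
#' @param n_trials number of trials (default 25).
#' @param seed search seed.
#' @param space bounds (default [search_space()]).
#' @param max_epochs,patience per-trial training budget.
#' @param batch_size minibatch size.
#' @return object of class `search_result`: `leaderboard` (data frame ranked
#'   by validation accuracy), `results` (all trial results), `best`.
#' @export
hyperparameter_search <- function(samples, splits, n_trials = 25L, seed = 1L,
                                  space = search_space(), max_epochs = 200L,
                                  patience = 20L, batch_size = 16L) {
  stopifnot(n_trials >= 1)
  input_dim <- ncol(samples[[1]]$features)
  results <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    par <- sample_trial_params(space, derive_seed(seed, 1000L + t), input_dim)
    results[[t]] <- train_model(samples, splits, par$config,
                                learning_rate = par$learning_rate,
                                weight_decay = par$weight_decay,
                                max_epochs = max_epochs, patience = patience,
                                batch_size = batch_size,
                                seed = par$config$seed)
    results[[t]]$trial <- t
  }
  ok <- !vapply(results, function(r) isTRUE(r$failed), logical(1))
  if (!any(ok)) stop("all hyperparameter-search trials failed")
  lb <- do.call(rbind, lapply(results[ok], function(r) {
    data.frame(trial = r$trial, code_name = r$code_name,
               latent_dim = r$config$latent_dim,
               hidden_dim = r$config$hidden_dim,
               pooling = r$config$pooling,
               dropout_rate = r$config$dropout_rate,
               regularization = r$config$regularization,
               learning_rate = r$learning_rate,
               weight_decay = r$weight_decay,
               train_acc = r$train_acc, val_acc = r$val_acc,
               test_acc = r$test_acc, stringsAsFactors = FALSE)
  }))
  lb <- lb[order(-lb$val_acc, lb$trial), ]
  rownames(lb) <- NULL
  structure(list(leaderboard = lb, results = results,
                 best = results[[lb$trial[1]]]),
            class = "search_result")
}

#' @exportS3Method base::print
print.search_result <- function(x, ...) {
  cat("hyperparameter search: top of leaderboard\n")
  print(utils::head(x$leaderboard[, c("code_name", "pooling", "latent_dim",
                                      "hidden_dim", "val_acc", "test_acc")],
                    5))
  invisible(x)
}

#' Random Forest baseline on flattened set features
#'
#' Set-valued samples are flattened to fixed-length vectors (per-feature
#' mean, standard deviation, minimum and maximum over the sample's atoms),
#' split 80%:20% train:test, and classified with a 100-tree random forest.
#'
#' @param samples scaled sample list.
#' @param seed split and forest seed.
#' @param train_frac training fraction (default 0.8).
#' @param n_trees forest size (default 100).
#' @return list with `accuracy`, `f1_pre`, `f1_post`, `pred`, `truth`.
#' @export
random_forest_baseline <- function(samples, seed = 1L, train_frac = 0.8,
                                   n_trees = 100L) {
  X <- do.call(rbind, lapply(samples, function(s) {
    f <- s$features
    c(colMeans(f), apply(f, 2, stats::sd), apply(f, 2, min),
      apply(f, 2, max))
  }))
  X[!is.finite(X)] <- 0  # sd of a single-atom sample
  y <- vapply(samples, `[[`, integer(1), "label")
  n <- length(y)
  with_seed(derive_seed(seed, 21L), {
    ord <- sample(n)
    n_train <- round(train_frac * n)
    tr <- ord[seq_len(n_train)]
    te <- ord[(n_train + 1L):n]
    fit <- rf_fit(X[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                  seed = derive_seed(seed, 22L))
    pred <- rf_predict(fit, X[te, , drop = FALSE])
    list(accuracy = mean(pred == y[te]),
         f1_pre = f1_score(pred, y[te], 0L),
         f1_post = f1_score(pred, y[te], 1L),
         pred = pred, truth = y[te])
  })
}
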