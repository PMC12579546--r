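# Bilinear zero-shot compatibility model.
#
# F(x, y) = [theta(x), 1] W [phi(y), 1]^T with W of shape (d+1) x (m+1).
# The bias augmentation makes F the sum of a bilinear term, a linear prior in
# theta(x), a linear prior in phi(y), and a trainable scalar. Training
# minimizes cross-entropy of the softmax of F over the training (light)
# kinases, with decoupled weight decay; prediction applies the softmax over
# the held-out (dark) kinases.

#' Training configuration for the bilinear model
#'
#' @param learning_rate initial learning rate, in `[1e-6, 0.1]`.
#' @param optimizer `"adam"`, `"sgd"` or `"rmsprop"`.
#' @param schedule learning-rate schedule: `"exponential"`, `"step"` or
#'   `"cosine"` (cosine annealing).
#' @param momentum momentum / smoothing constant in `[0.95, 0.9999]`
#'   (SGD momentum; RMSprop squared-gradient decay; unused by Adam, which
#'   runs with the conventional 0.9 / 0.999 moments).
#' @param weight_decay decoupled weight-decay coefficient, in
#'   `[1e-5, 0.01]`; applied to the whole of `W`, bias row/column included.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param restarts default number of restarts for [bzsm_restarts()].
#' @param seed master seed (controls init and shuffling).
#' @param schedule_gamma exponential decay factor per epoch.
#' @param step_size,step_gamma step-schedule period and factor.
#' @param eval_every validation evaluation period (epochs).
#' @return a `bzsm_config` list.
#' @export
bzsm_config <- function(learning_rate = 0.01,
                        optimizer = c("adam", "sgd", "rmsprop"),
                        schedule = c("exponential", "step", "cosine"),
                        momentum = 0.99, weight_decay = 1e-4,
                        epochs = 200L, batch_size = 64L, restarts = 3L,
                        seed = 1L, schedule_gamma = 0.99, step_size = 50L,
                        step_gamma = 0.5, eval_every = 1L) {
  optimizer <- match.arg(optimizer)
  schedule <- match.arg(schedule)
  if (learning_rate < 1e-6 || learning_rate > 0.1) {
    abort("`learning_rate` must be in [1e-6, 0.1].")
  }
  if (weight_decay < 1e-5 || weight_decay > 0.01) {
    abort("`weight_decay` must be in [1e-5, 0.01].")
  }
  if (optimizer != "adam" && (momentum < 0.95 || momentum > 0.9999)) {
    abort("`momentum` must be in [0.95, 0.9999].")
  }
  structure(list(learning_rate = learning_rate, optimizer = optimizer,
                 schedule = schedule, momentum = momentum,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 schedule_gamma = schedule_gamma,
                 step_size = as.integer(step_size), step_gamma = step_gamma,
                 eval_every = as.integer(eval_every)),
            class = "bzsm_config")
}

augment1 <- function(m) cbind(m, 1)

#' Bilinear compatibility score
#'
#' `F(x, y) = [theta, 1] W [phi, 1]^T`: the sum of the bilinear interaction
#' `theta^T W[1:d, 1:m] phi`, a linear prior in `theta`, a linear prior in
#' `phi`, and the trainable corner scalar.
#'
#' @param theta phosphosite embedding vector (length `d`).
#' @param phi kinase embedding vector (length `m`).
#' @param W compatibility matrix of shape `(d + 1) x (m + 1)`.
#' @return scalar compatibility.
#' @export
compatibility <- function(theta, phi, W) {
  d <- length(theta); m <- length(phi)
  if (!all(dim(W) == c(d + 1L, m + 1L))) {
    abort(sprintf("W must be (%d+1) x (%d+1); got %d x %d.",
                  d, m, nrow(W), ncol(W)))
  }
  as.numeric(c(theta, 1) %*% W %*% c(phi, 1))
}

# F for many sites x many kinases: Theta (n x d), Phi (K x m) -> n x K
compatibility_matrix <- function(Theta, Phi, W) {
  augment1(Theta) %*% W %*% t(augment1(Phi))
}

softmax_rows <- function(F_mat) {
  mx <- apply(F_mat, 1, max)         # max-subtraction for stability
  e <- exp(F_mat - mx)
  e / rowSums(e)
}

#' Class probabilities for one phosphosite
#'
#' Softmax of the compatibility scores over the given kinase set (the light
#' kinases during training, the dark/test kinases at prediction time),
#' computed with max-subtraction for numerical stability.
#'
#' @param theta phosphosite embedding vector.
#' @param kinase_ids kinases to score.
#' @param kinase_store [embedding_store()] resolving `kinase_ids`.
#' @param W compatibility matrix.
#' @return named probability vector summing to 1.
#' @export
class_probs <- function(theta, kinase_ids, kinase_store, W) {
  if (!length(kinase_ids)) abort("`kinase_ids` must be non-empty.")
  Phi <- store_vectors(kinase_store, kinase_ids)
  F_row <- compatibility_matrix(matrix(theta, nrow = 1), Phi, W)
  setNames(as.numeric(softmax_rows(F_row)), kinase_ids)
}

# mean cross-entropy of softmax(F) rows at target classes y (indices)
bzsm_loss <- function(W, A, y, B) {
  F_mat <- A %*% W %*% t(B)
  mx <- apply(F_mat, 1, max)
  lse <- mx + log(rowSums(exp(F_mat - mx)))
  mean(lse - F_mat[cbind(seq_along(y), y)])
}

# gradient of bzsm_loss wrt W
bzsm_grad <- function(W, A, y, B) {
  F_mat <- A %*% W %*% t(B)
  P <- softmax_rows(F_mat)
  P[cbind(seq_along(y), y)] <- P[cbind(seq_along(y), y)] - 1
  t(A) %*% P %*% B / nrow(A)
}

make_optimizer <- function(config, dimW) {
  state <- list(m = matrix(0, dimW[1], dimW[2]),
                v = matrix(0, dimW[1], dimW[2]), t = 0L)
  switch(config$optimizer,
    sgd = function(W, g, lr) {
      state$m <<- config$momentum * state$m + g
      W - lr * state$m
    },
    rmsprop = function(W, g, lr) {
      state$v <<- config$momentum * state$v + (1 - config$momentum) * g^2
      W - lr * g / (sqrt(state$v) + 1e-8)
    },
    adam = function(W, g, lr) {
      state$t <<- state$t + 1L
      state$m <<- 0.9 * state$m + 0.1 * g
      state$v <<- 0.999 * state$v + 0.001 * g^2
      mhat <- state$m / (1 - 0.9^state$t)
      vhat <- state$v / (1 - 0.999^state$t)
      W - lr * mhat / (sqrt(vhat) + 1e-8)
    })
}

lr_at <- function(config, epoch) {
  base <- config$learning_rate
  switch(config$schedule,
    exponential = base * config$schedule_gamma^(epoch - 1L),
    step = base * config$step_gamma^((epoch - 1L) %/% config$step_size),
    cosine = base / 2 * (1 + cos(pi * (epoch - 1L) / max(config$epochs - 1L, 1L))))
}

#' Train the bilinear zero-shot model
#'
#' Minimizes the minibatch cross-entropy of the softmax of `F` over the
#' training (light) kinases, with decoupled weight decay applied to the full
#' augmented matrix `W`. When validation data are supplied, validation macro
#' AP is tracked and the checkpoint with the best validation macro AP is
#' returned; otherwise the final weights are.
#'
#' @param train_pairs training association pairs (`site_id`, `kinase_id`).
#' @param site_store,kinase_store embedding stores resolving every site and
#'   kinase involved.
#' @param config a [bzsm_config()].
#' @param val_pairs,val_kinases optional validation pairs and validation
#'   kinase set (disjoint from the training kinases) for checkpoint
#'   selection.
#' @return a fitted `bzsm` object with elements `W`, `d`, `m`,
#'   `train_kinases`, `log` (per-epoch tibble), `best_epoch`, `best_val_ap`,
#'   `config`.
#' @export
bzsm_train <- function(train_pairs, site_store, kinase_store,
                       config = bzsm_config(), val_pairs = NULL,
                       val_kinases = NULL) {
  if (inherits(train_pairs, "phospho_dataset")) train_pairs <- train_pairs$pairs
  if (!nrow(train_pairs)) abort("empty training set.")
  train_kin <- unique(train_pairs$kinase_id)
  if (!is.null(val_kinases)) {
    ov <- intersect(val_kinases, train_kin)
    if (length(ov)) {
      abort(sprintf("validation kinases overlap training kinases: %s",
                    paste(head(ov, 5), collapse = ", ")))
    }
  }
  Theta <- store_vectors(site_store, train_pairs$site_id)
  Phi <- store_vectors(kinase_store, train_kin)
  d <- ncol(Theta); m <- ncol(Phi)
  A <- augment1(Theta)
  B <- augment1(Phi)
  y <- match(train_pairs$kinase_id, train_kin)
  n <- nrow(A)

  has_val <- !is.null(val_pairs) && !is.null(val_kinases)
  if (has_val) {
    if (inherits(val_pairs, "phospho_dataset")) val_pairs <- val_pairs$pairs
    val_sites <- unique(val_pairs$site_id)
    ThetaV <- store_vectors(site_store, val_sites)
    PhiV <- store_vectors(kinase_store, val_kinases)
  }

  local_seed(config$seed, {
    W <- matrix(rnorm((d + 1) * (m + 1), sd = 1 / sqrt(d + 1)), d + 1, m + 1)
    step <- make_optimizer(config, dim(W))
    best_W <- W
    best_ap <- -Inf
    best_epoch <- NA_integer_
    log_rows <- vector("list", config$epochs)

    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at(config, epoch)
      idx <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        b <- idx[s:min(s + config$batch_size - 1L, n)]
        g <- bzsm_grad(W, A[b, , drop = FALSE], y[b], B)
        W <- step(W, g, lr)
        W <- W - lr * config$weight_decay * W   # decoupled weight decay
        ep_loss <- ep_loss + bzsm_loss(W, A[b, , drop = FALSE], y[b], B) * length(b)
      }
      ep_loss <- ep_loss / n
      if (!is.finite(ep_loss)) {
        abort(sprintf(
          "NaN/Inf loss at epoch %d (lr %.3g, optimizer %s); reduce the learning rate.",
          epoch, lr, config$optimizer))
      }
      val_ap <- NA_real_
      if (has_val && (epoch %% config$eval_every == 0L || epoch == config$epochs)) {
        S <- softmax_rows(compatibility_matrix(ThetaV, PhiV, W))
        dimnames(S) <- list(val_sites, val_kinases)
        val_ap <- suppressWarnings(macro_ap(S, val_pairs)$macro_ap)
        if (!is.na(val_ap) && val_ap > best_ap) {
          best_ap <- val_ap; best_W <- W; best_epoch <- epoch
        }
      }
      log_rows[[epoch]] <- tibble(epoch = epoch, loss = ep_loss, lr = lr,
                                  val_macro_ap = val_ap)
    }
    if (!has_val) { best_W <- W; best_ap <- NA_real_; best_epoch <- config$epochs }
    structure(list(W = best_W, d = d, m = m, train_kinases = train_kin,
                   log = bind_rows(log_rows), best_epoch = best_epoch,
                   best_val_ap = best_ap, config = config),
              class = "bzsm")
  })
}

#' @export
print.bzsm <- function(x, ...) {
  cat(sprintf("<bzsm> W: %d x %d (d = %d, m = %d), %d training kinases\n",
              nrow(x$W), ncol(x$W), x$d, x$m, length(x$train_kinases)))
  if (!is.na(x$best_val_ap)) {
    cat(sprintf("  best validation macro AP %.4f at epoch %s\n",
                x$best_val_ap, x$best_epoch))
  }
  invisible(x)
}

#' Predict dark-kinase scores with a fitted bilinear model
#'
#' @param object a fitted `bzsm`.
#' @param site_ids test phosphosite identifiers.
#' @param kinase_ids kinases to score (the dark/test kinases).
#' @param site_store,kinase_store embedding stores.
#' @param type `"prob"` (softmax of `F` over `kinase_ids`, the paper-time
#'   prediction rule) or `"score"` (raw `F`). Rankings per site coincide; the
#'   per-kinase ranking of sites can differ.
#' @param ... unused.
#' @return numeric matrix, sites x kinases, with dimnames.
#' @export
predict.bzsm <- function(object, site_ids, kinase_ids, site_store,
                         kinase_store, type = c("prob", "score"), ...) {
  type <- match.arg(type)
  Theta <- store_vectors(site_store, site_ids)
  Phi <- store_vectors(kinase_store, kinase_ids)
  if (ncol(Theta) != object$d || ncol(Phi) != object$m) {
    abort("embedding dimensions do not match the fitted model.")
  }
  S <- compatibility_matrix(Theta, Phi, object$W)
  if (type == "prob") S <- softmax_rows(S)
  dimnames(S) <- list(site_ids, kinase_ids)
  S
}

#' @describeIn bzsm_train per-epoch training log.
#' @param x a fitted `bzsm`.
#' @param ... unused.
#' @method tidy bzsm
#' @export
tidy.bzsm <- function(x, ...) x$log

#' @describeIn bzsm_train one-row fit summary.
#' @method glance bzsm
#' @export
glance.bzsm <- function(x, ...) {
  tibble(d = x$d, m = x$m, n_train_kinases = length(x$train_kinases),
         epochs = x$config$epochs, best_epoch = x$best_epoch,
         best_val_ap = x$best_val_ap,
         final_loss = x$log$loss[nrow(x$log)])
}

#' @describeIn bzsm_train loss and validation-AP curves.
#' @param object a fitted `bzsm`.
#' @method autoplot bzsm
#' @export
autoplot.bzsm <- function(object, ...) {
  d <- object$log |>
    tidyr::pivot_longer(c("loss", "val_macro_ap"), names_to = "metric",
                        values_to = "value") |>
    filter(!is.na(.data$value))
  ggplot(d, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "epoch", y = NULL) +
    theme_minimal()
}

#' Random hyperparameter search for the bilinear model
#'
#' Samples `n_trials` configurations (learning rate and weight decay
#' log-uniform over their admissible ranges, optimizer and schedule uniform,
#' momentum uniform over `[0.95, 0.9999]`), trains each, and returns the
#' configuration with the best validation macro AP together with the full
#' trial table.
#'
#' @param n_trials number of sampled configurations (>= 1).
#' @param seed seed for the sampler (training seeds are derived from it).
#' @inheritParams bzsm_train
#' @param epochs,batch_size fixed fit-budget settings shared by all trials.
#' @return list with `best_config` (a [bzsm_config()]) and `trials` (tibble
#'   of sampled settings and validation macro APs).
#' @export
bzsm_random_search <- function(n_trials, seed, train_pairs, site_store,
                               kinase_store, val_pairs, val_kinases,
                               epochs = 50L, batch_size = 64L) {
  if (n_trials < 1L) abort("`n_trials` must be >= 1.")
  draws <- local_seed(seed, {
    tibble(
      trial = seq_len(n_trials),
      learning_rate = 10^runif(n_trials, log10(1e-6), log10(0.1)),
      optimizer = sample(c("adam", "sgd", "rmsprop"), n_trials, replace = TRUE),
      schedule = sample(c("exponential", "step", "cosine"), n_trials, replace = TRUE),
      momentum = runif(n_trials, 0.95, 0.9999),
      weight_decay = 10^runif(n_trials, log10(1e-5), log10(0.01)))
  })
  fits <- purrr::pmap(draws, function(trial, learning_rate, optimizer,
                                      schedule, momentum, weight_decay) {
    cfg <- bzsm_config(learning_rate = learning_rate, optimizer = optimizer,
                       schedule = schedule, momentum = momentum,
                       weight_decay = weight_decay, epochs = epochs,
                       batch_size = batch_size, seed = seed + trial)
    fit <- bzsm_train(train_pairs, site_store, kinase_store, cfg,
                      val_pairs = val_pairs, val_kinases = val_kinases)
    list(cfg = cfg, val_ap = fit$best_val_ap)
  })
  trials <- draws
  trials$val_macro_ap <- vapply(fits, function(f) f$val_ap, numeric(1))
  best <- which.max(trials$val_macro_ap)
  list(best_config = fits[[best]]$cfg, trials = trials)
}

#' Train with several restarts and summarize test performance
#'
#' Trains the model `n` times, identical except for the restart seed
#' (derived from `config$seed`), evaluates each on the test data, and
#' reports the mean and sample standard deviation of the test macro AP, in
#' the conventional `mean ± sd` form.
#'
#' @inheritParams bzsm_train
#' @param test_pairs,test_kinases test association pairs and the dark/test
#'   kinase set.
#' @param n number of restarts (>= 2 for a standard deviation).
#' @return list with `mean_ap`, `sd_ap`, `aps` (per-restart vector),
#'   `models`, and `label` (the formatted `mean ± sd` string).
#' @export
bzsm_restarts <- function(config, train_pairs, site_store, kinase_store,
                          val_pairs, val_kinases, test_pairs, test_kinases,
                          n = config$restarts) {
  if (inherits(test_pairs, "phospho_dataset")) test_pairs <- test_pairs$pairs
  aps <- numeric(n)
  models <- vector("list", n)
  test_sites <- unique(test_pairs$site_id)
  for (r in seq_len(n)) {
    cfg <- config
    cfg$seed <- config$seed + (r - 1L) * 1000L
    fit <- bzsm_train(train_pairs, site_store, kinase_store, cfg,
                      val_pairs = val_pairs, val_kinases = val_kinases)
    S <- predict(fit, test_sites, test_kinases, site_store, kinase_store)
    aps[r] <- suppressWarnings(macro_ap(S, test_pairs)$macro_ap)
    models[[r]] <- fit
  }
  list(mean_ap = mean(aps),
       sd_ap = if (n >= 2L) sd(aps) else NA_real_,
       aps = aps, models = models,
       label = sprintf("%.4f ±%.4f", mean(aps),
                       if (n >= 2L) sd(aps) else 0))
}
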