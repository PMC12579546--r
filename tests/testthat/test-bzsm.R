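# small helper: a linearly separable zero-shot instance with one-hot classes
onehot_instance <- function(n_per_class = 6, classes = 4, noise = 0, seed = 1) {
  set.seed(seed)
  kin_ids <- paste0("K", seq_len(classes))
  kin_m <- diag(classes)
  rownames(kin_m) <- kin_ids
  site_ids <- paste0("s", seq_len(n_per_class * classes))
  y <- rep(seq_len(classes), each = n_per_class)
  site_m <- kin_m[y, , drop = FALSE] +
    matrix(rnorm(length(y) * classes, sd = noise), length(y))
  rownames(site_m) <- site_ids
  list(pairs = tibble::tibble(site_id = site_ids, kinase_id = kin_ids[y]),
       site_store = embedding_store(site_m),
       kinase_store = embedding_store(kin_m))
}

test_that("compatibility equals the bias-augmented bilinear product", {
  # W = 0 -> F = 0; corner-only W -> constant F (the trainable scalar term)
  expect_equal(compatibility(c(1, 2), c(3), matrix(0, 3, 2)), 0)
  Wc <- matrix(0, 3, 2); Wc[3, 2] <- 5.5
  expect_equal(compatibility(c(1, 2), c(3), Wc), 5.5)
  expect_equal(compatibility(2, 3, matrix(c(1, 0, 0, 0), 2, 2)), 6)
  expect_error(compatibility(c(1, 2), c(3), matrix(0, 2, 2)), "must be")
})

test_that("compatibility equals its four-term expansion on random matrices", {
  set.seed(51)
  for (rep in 1:25) {
    d <- sample(1:6, 1); m <- sample(1:6, 1)
    theta <- rnorm(d); phi <- rnorm(m)
    W <- matrix(rnorm((d + 1) * (m + 1)), d + 1, m + 1)
    four_terms <- as.numeric(t(theta) %*% W[1:d, 1:m, drop = FALSE] %*% phi) +
      sum(theta * W[1:d, m + 1]) +
      sum(W[d + 1, 1:m] * phi) +
      W[d + 1, m + 1]
    expect_equal(compatibility(theta, phi, W), four_terms, tolerance = 1e-12)
  }
})

test_that("class probabilities are a stable softmax over the kinase set", {
  kin <- embedding_store(matrix(c(1, 0, 0, 1), 2, 2,
                                dimnames = list(c("a", "b"), NULL)))
  W0 <- matrix(0, 3, 3)
  p <- class_probs(c(1, 1), c("a", "b"), kin, W0)
  expect_equal(unname(p), c(0.5, 0.5))                 # equal F -> uniform
  # F = (ln 2, 0) -> (2/3, 1/3): W picks out the first kinase coordinate
  W <- matrix(0, 3, 3); W[1, 1] <- log(2)
  p2 <- class_probs(c(1, 0), c("a", "b"), kin, W)
  expect_equal(unname(p2), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # normalization and invariance to adding a constant to all F values
  set.seed(52)
  Wr <- matrix(rnorm(9), 3, 3)
  Wshift <- Wr; Wshift[3, 3] <- Wshift[3, 3] + 100     # shifts every F by 100
  pr <- class_probs(rnorm(2), c("a", "b"), kin, Wr)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_equal(class_probs(c(0.3, -1), c("a", "b"), kin, Wr),
               class_probs(c(0.3, -1), c("a", "b"), kin, Wshift),
               tolerance = 1e-9)
  # huge logits do not overflow
  Wbig <- matrix(0, 3, 3); Wbig[1, 1] <- 5000
  pbig <- class_probs(c(1, 0), c("a", "b"), kin, Wbig)
  expect_equal(unname(pbig), c(1, 0))
})

test_that("the analytic gradient matches finite differences on a toy problem", {
  set.seed(53)
  d <- 3; m <- 2; n <- 5; K <- 3
  A <- cbind(matrix(rnorm(n * d), n), 1)
  B <- cbind(matrix(rnorm(K * m), K), 1)
  y <- sample(K, n, replace = TRUE)
  W <- matrix(rnorm((d + 1) * (m + 1)), d + 1, m + 1)
  g <- darkzsl:::bzsm_grad(W, A, y, B)
  eps <- 1e-6
  for (idx in sample(length(W), 8)) {
    Wp <- W; Wp[idx] <- Wp[idx] + eps
    Wm <- W; Wm[idx] <- Wm[idx] - eps
    fd <- (darkzsl:::bzsm_loss(Wp, A, y, B) -
             darkzsl:::bzsm_loss(Wm, A, y, B)) / (2 * eps)
    expect_equal(g[idx], fd, tolerance = 1e-4)
  }
})

test_that("training is bitwise deterministic given the seed", {
  inst <- onehot_instance(noise = 0.1)
  cfg <- bzsm_config(epochs = 5, seed = 99)
  f1 <- bzsm_train(inst$pairs, inst$site_store, inst$kinase_store, cfg)
  f2 <- bzsm_train(inst$pairs, inst$site_store, inst$kinase_store, cfg)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$log, f2$log)
})

test_that("noise-free one-hot classes are fit to perfect training accuracy", {
  inst <- onehot_instance(noise = 0)
  cfg <- bzsm_config(learning_rate = 0.05, epochs = 80, seed = 1)
  fit <- bzsm_train(inst$pairs, inst$site_store, inst$kinase_store, cfg)
  P <- predict(fit, inst$pairs$site_id, rownames(inst$kinase_store$vectors),
               inst$site_store, inst$kinase_store)
  top1 <- colnames(P)[max.col(P)]
  expect_identical(top1, inst$pairs$kinase_id)
})

test_that("extreme weight decay shrinks W toward 0 and probabilities toward uniform", {
  inst <- onehot_instance(noise = 0)
  cfg <- bzsm_config(learning_rate = 0.01, epochs = 40, seed = 1)
  fit <- bzsm_train(inst$pairs, inst$site_store, inst$kinase_store, cfg)
  cfg_big <- cfg
  cfg_big$weight_decay <- 50     # beyond the tuning range, to probe the limit
                                 # (kept below 1/lr so the decay map contracts)
  fit_big <- bzsm_train(inst$pairs, inst$site_store, inst$kinase_store, cfg_big)
  # the decayed fixed point has norm ~ |optimizer step| / weight_decay
  expect_lt(norm(fit_big$W, "F"), 0.1)
  expect_lt(norm(fit_big$W, "F"), norm(fit$W, "F") / 10)
  p <- class_probs(inst$site_store$vectors[1, ],
                   rownames(inst$kinase_store$vectors),
                   inst$kinase_store, fit_big$W)
  expect_equal(unname(p), rep(0.25, 4), tolerance = 0.02)
})

test_that("validation checkpointing returns the best-AP epoch and logs progress", {
  bench <- generate_benchmark(synthetic_spec(seed = 5, sigma_site = 0.2))
  sc <- zero_shot_scenario(bench, seed = 5)
  cfg <- bzsm_config(learning_rate = 0.02, epochs = 25, seed = 5)
  fit <- bzsm_train(sc$train_pairs, bench$site_store, bench$kinase_store, cfg,
                    val_pairs = sc$val_pairs, val_kinases = sc$val_ids)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(nrow(tidy(fit)), 25L)
  expect_equal(fit$best_val_ap, max(fit$log$val_macro_ap, na.rm = TRUE))
  expect_false(is.na(fit$best_epoch))
  expect_true(all(is.finite(fit$log$loss)))
  # validation kinases must be disjoint from training kinases
  expect_error(
    bzsm_train(sc$train_pairs, bench$site_store, bench$kinase_store, cfg,
               val_pairs = sc$val_pairs,
               val_kinases = unique(sc$train_pairs$kinase_id)[1]),
    "overlap")
})

test_that("random search samples within bounds and returns the argmax config", {
  inst <- onehot_instance(noise = 0.3, n_per_class = 4)
  val <- onehot_instance(noise = 0.3, seed = 2)
  # hold out kinases by renaming: validation uses distinct kinase ids
  val_pairs <- dplyr::mutate(val$pairs, kinase_id = paste0("V", kinase_id))
  vk <- unique(val_pairs$kinase_id)
  vkin <- val$kinase_store$vectors
  rownames(vkin) <- paste0("V", rownames(vkin))
  site_all <- embedding_store(rbind(inst$site_store$vectors,
                                    `rownames<-`(val$site_store$vectors,
                                                 paste0("v", rownames(val$site_store$vectors)))))
  val_pairs$site_id <- paste0("v", val_pairs$site_id)
  kin_all <- embedding_store(rbind(inst$kinase_store$vectors, vkin))
  res <- bzsm_random_search(4, seed = 7, inst$pairs, site_all, kin_all,
                            val_pairs, vk, epochs = 6)
  expect_identical(nrow(res$trials), 4L)
  expect_true(all(res$trials$learning_rate >= 1e-6 &
                    res$trials$learning_rate <= 0.1))
  expect_true(all(res$trials$weight_decay >= 1e-5 &
                    res$trials$weight_decay <= 0.01))
  expect_true(all(res$trials$momentum >= 0.95 & res$trials$momentum <= 0.9999))
  best <- res$trials[which.max(res$trials$val_macro_ap), ]
  expect_equal(res$best_config$learning_rate, best$learning_rate)
  # same seed -> identical trial sequence
  res2 <- bzsm_random_search(4, seed = 7, inst$pairs, site_all, kin_all,
                             val_pairs, vk, epochs = 6)
  expect_identical(res$trials, res2$trials)
})

test_that("restarts report mean and sample sd in the mean ± sd convention", {
  bench <- generate_benchmark(synthetic_spec(seed = 6, sigma_site = 0.3))
  sc <- zero_shot_scenario(bench, seed = 6)
  cfg <- bzsm_config(learning_rate = 0.02, epochs = 15, seed = 11)
  rs <- bzsm_restarts(cfg, sc$train_pairs, bench$site_store,
                      bench$kinase_store, sc$val_pairs, sc$val_ids,
                      sc$test_pairs, sc$dark_ids, n = 3)
  expect_length(rs$aps, 3)
  expect_equal(rs$mean_ap, mean(rs$aps), tolerance = 1e-12)
  expect_equal(rs$sd_ap, sd(rs$aps), tolerance = 1e-12)
  expect_match(rs$label, "^0\\.\\d{4} ±0\\.\\d{4}$")
})

test_that("optimizers and schedules all make progress on separable data", {
  inst <- onehot_instance(noise = 0.05)
  for (opt in c("adam", "sgd", "rmsprop")) {
    for (sch in c("exponential", "step", "cosine")) {
      cfg <- bzsm_config(learning_rate = 0.02, optimizer = opt, schedule = sch,
                         epochs = 15, seed = 3)
      fit <- bzsm_train(inst$pairs, inst$site_store, inst$kinase_store, cfg)
      expect_lt(fit$log$loss[15], fit$log$loss[1])
    }
  }
})
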