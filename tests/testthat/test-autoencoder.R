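# Shared tiny fixtures: a small synthetic dataset and an untrained model.
tiny_cfg <- function(att = "dot", epochs = 3L, seed = 11L) {
  ae_config(embedding_dim = 8L, gru_hidden = 16L, attention = att,
            epochs = epochs, batch_size = 32L, seed = seed)
}

test_that("analytic gradients match finite differences for both attention forms", {
  set.seed(99)
  for (att in c("dot", "additive")) {
    cfg <- ae_config(embedding_dim = 2, gru_hidden = 4, attention = att, seed = 3)
    B <- 2; TT <- 3; P <- 3
    model <- ae_init(cfg, input_dim = P, n_frames = TT)
    X <- array(rnorm(B * TT * P), dim = c(B, TT, P))
    fw <- ieegsift:::ae_forward_batch(model, X, teacher_forcing = TRUE, keep = TRUE)
    g <- ieegsift:::ae_backward_batch(model, X, fw)
    eps <- 1e-6
    loss_at <- function(m) {
      ieegsift:::ae_loss_batch(
        X, ieegsift:::ae_forward_batch(m, X, teacher_forcing = TRUE)$reconstruction)
    }
    for (nm in names(model$params)) {
      probe <- seq_len(min(length(model$params[[nm]]), 4L))
      for (i in probe) {
        m2 <- model
        m2$params[[nm]][i] <- model$params[[nm]][i] + eps
        lp <- loss_at(m2)
        m2$params[[nm]][i] <- model$params[[nm]][i] - eps
        lm <- loss_at(m2)
        num <- (lp - lm) / (2 * eps)
        expect_equal(g[[nm]][i], num, tolerance = 1e-3,
                     label = sprintf("%s grad %s[%d]", att, nm, i))
      }
    }
  }
})

test_that("encode emits embedding_dim values, deterministically, order-sensitively", {
  segs <- make_small_dataset(per_class = 3, seed = 31)
  X <- tensor_stack(segs)
  model <- ae_init(tiny_cfg(), input_dim = dim(X)[3], n_frames = dim(X)[2])

  e1 <- encode(model, X[1, , ])
  expect_length(as.numeric(e1), 8)
  expect_identical(e1, encode(model, X[1, , ]))
  expect_true(all(is.finite(e1)))

  # default configuration emits 128-dimensional codes
  m128 <- ae_init(ae_config(), input_dim = dim(X)[3], n_frames = dim(X)[2])
  expect_length(as.numeric(encode(m128, X[1, , ])), 128)

  rev_frames <- X[2, rev(seq_len(dim(X)[2])), ]
  expect_false(isTRUE(all.equal(as.numeric(encode(model, X[2, , ])),
                                as.numeric(encode(model, rev_frames)))))

  expect_error(encode(model, X[1, , 1:10]), class = "ieegsift_shape_mismatch")
})

test_that("forward pass reconstructs the input shape with probability-vector attention", {
  segs <- make_small_dataset(per_class = 2, seed = 32)
  tn <- build_tensor(segs[[1]])
  model <- ae_init(tiny_cfg(), input_dim = 2 * dim(tn$values)[2],
                   n_frames = dim(tn$values)[3])
  out <- ae_forward(model, tn)
  expect_equal(dim(out$reconstruction), dim(tn$values))
  expect_true(all(out$attention >= 0))
  expect_equal(rowSums(out$attention), rep(1, dim(tn$values)[3]), tolerance = 1e-6)
  mse <- mean((out$reconstruction - tn$values)^2)
  expect_true(is.finite(mse) && mse > 0)
})

test_that("training reduces MSE, is seed-reproducible, and selects the best epoch", {
  segs <- make_small_dataset(per_class = 50, seed = 41)  # 200 segments
  X <- tensor_stack(segs)
  val <- X[seq(1, 200, by = 10), , , drop = FALSE]
  cfg <- ae_config(embedding_dim = 16, gru_hidden = 32, epochs = 5,
                   batch_size = 32, seed = 13)
  fit <- train_autoencoder(X, val, cfg)
  h <- fit$history
  expect_length(h$train_mse, 5)
  expect_lt(h$train_mse[5], h$train_mse[1])
  expect_true(all(h$val_cosine >= -1 & h$val_cosine <= 1))
  expect_equal(h$best_epoch, which.max(h$val_cosine))
  expect_gte(h$val_cosine[h$best_epoch], h$val_cosine[1])

  fit2 <- train_autoencoder(X, val, cfg)
  expect_identical(fit$history$train_mse, fit2$history$train_mse)
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("epochs = 0 returns the initialized model with empty history", {
  segs <- make_small_dataset(per_class = 2, seed = 30)
  X <- tensor_stack(segs)
  fit <- train_autoencoder(X, X, tiny_cfg(epochs = 0L))
  expect_length(fit$history$train_mse, 0)
  ref <- ae_init(tiny_cfg(epochs = 0L), dim(X)[3], dim(X)[2])
  expect_identical(fit$model$params, ref$params)
  expect_error(train_autoencoder(X[integer(0), , , drop = FALSE], X, tiny_cfg()),
               class = "ieegsift_empty_input")
})

test_that("cosine similarity follows the closed form", {
  segs <- make_small_dataset(per_class = 2, seed = 33)
  X <- tensor_stack(segs)
  model <- ae_init(tiny_cfg(), dim(X)[3], dim(X)[2])
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
  vc <- validate_reconstruction(model, X[1:4, , , drop = FALSE])
  expect_true(is.finite(vc) && vc >= -1 && vc <= 1)
})

test_that("trained embeddings separate classes better than raw tensors", {
  segs <- make_small_dataset(per_class = 100, seed = 47)  # 400 segments
  labs <- vapply(segs, `[[`, integer(1), "label")
  X <- tensor_stack(segs)
  val_idx <- seq(1, 400, by = 8)
  cfg <- ae_config(embedding_dim = 16, gru_hidden = 32, epochs = 5,
                   batch_size = 64, seed = 17)
  fit <- train_autoencoder(X, X[val_idx, , , drop = FALSE], cfg)
  emb <- encode(fit$model, X)
  raw <- matrix(X, nrow = dim(X)[1])
  sil_emb <- mean_silhouette(emb, labs)
  sil_raw <- mean_silhouette(raw, labs)
  expect_gt(sil_emb, sil_raw)
})
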