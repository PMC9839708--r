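# Temporal autoencoder: GRU encoder -> embedding -> GRU decoder with
# attention over encoder states, trained by Adam to minimize reconstruction
# MSE. The encoder consumes a spectrogram as a sequence of T frames (each the
# 2F-long concatenation of both normalization channels at one time step); the
# final hidden state is mapped affinely to the embedding. The decoder is
# initialized from the embedding and emits one frame per step, receiving the
# previous target frame (teacher forcing during training, its own previous
# output at inference) plus an attention context over encoder states.
#
# All gradients are derived by hand and checked against finite differences in
# the test suite.

#' Autoencoder configuration
#'
#' @param embedding_dim dimension of the latent code (default 128).
#' @param gru_hidden hidden-state size of both recurrent units.
#' @param gru_layers number of recurrent layers (only 1 is supported).
#' @param attention `"dot"` (Luong multiplicative) or `"additive"` (Bahdanau).
#' @param embedding_pool how encoder states feed the embedding head:
#'   `"final"` uses the last hidden state, `"mean"` the time-average of all
#'   encoder states, `"max"` their elementwise maximum over time (a
#'   detector-style readout that retains brief transients which would
#'   otherwise fade from the recurrent state).
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param beta1,beta2,adam_eps Adam moment coefficients and epsilon.
#' @param clip_norm global gradient-norm ceiling per mini-batch (the standard
#'   stabilizer for recurrent training); `Inf` disables clipping.
#' @param seed integer seed governing initialization and batch shuffling.
#' @return an `ae_config` list.
#' @export
ae_config <- function(embedding_dim = 128L, gru_hidden = 128L, gru_layers = 1L,
                      attention = c("dot", "additive"), epochs = 10L,
                      learning_rate = 1e-3, batch_size = 128L,
                      beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                      clip_norm = 5,
                      embedding_pool = c("final", "mean", "max"), seed = 42L) {
  attention <- match.arg(attention)
  embedding_pool <- match.arg(embedding_pool)
  if (embedding_dim < 1 || epochs < 0 || gru_hidden < 1) {
    ieeg_error("embedding_dim/gru_hidden must be >= 1 and epochs >= 0",
               "ieegsift_bad_params")
  }
  if (gru_layers != 1L) {
    ieeg_error("only single-layer recurrent units are supported", "ieegsift_bad_params")
  }
  structure(list(embedding_dim = as.integer(embedding_dim),
                 gru_hidden = as.integer(gru_hidden), gru_layers = 1L,
                 attention = attention, epochs = as.integer(epochs),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 clip_norm = clip_norm,
                 embedding_pool = embedding_pool, seed = as.integer(seed)),
            class = "ae_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

unif_mat <- function(nr, nc, scale) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

#' Initialize an untrained autoencoder
#'
#' Weights are drawn uniformly from `[-1/sqrt(H), 1/sqrt(H)]` under the
#' config's seed.
#'
#' @param config an [ae_config()].
#' @param input_dim frame length `P = 2F`.
#' @param n_frames sequence length `T`.
#' @return an `ae_model` list holding config, dimensions and parameters.
#' @export
ae_init <- function(config, input_dim, n_frames) {
  H <- config$gru_hidden; D <- config$embedding_dim; P <- as.integer(input_dim)
  s <- 1 / sqrt(H)
  params <- withr::with_seed(config$seed, {
    p <- list(
      # encoder GRU
      Wz = unif_mat(P, H, s), Wr = unif_mat(P, H, s), Wn = unif_mat(P, H, s),
      Uz = unif_mat(H, H, s), Ur = unif_mat(H, H, s), Un = unif_mat(H, H, s),
      bz = numeric(H), br = numeric(H), bn = numeric(H),
      # embedding head and decoder init
      We = unif_mat(H, D, s), be = numeric(D),
      Wd = unif_mat(D, H, s), bd = numeric(H),
      # decoder GRU (input = previous frame)
      Vz = unif_mat(P, H, s), Vr = unif_mat(P, H, s), Vn = unif_mat(P, H, s),
      Sz = unif_mat(H, H, s), Sr = unif_mat(H, H, s), Sn = unif_mat(H, H, s),
      cz = numeric(H), cr = numeric(H), cn = numeric(H),
      # output head on [decoder state; attention context]
      Wo = unif_mat(2L * H, P, s), bo = numeric(P)
    )
    if (config$attention == "additive") {
      p$Wa <- unif_mat(H, H, s); p$Ua <- unif_mat(H, H, s)
      p$ba <- numeric(H); p$va <- stats::runif(H, -s, s)
    }
    p
  })
  structure(list(config = config, input_dim = P, n_frames = as.integer(n_frames),
                 params = params),
            class = "ae_model")
}

# one GRU step for a batch; W/U/b are the 3-gate parameter triples
gru_forward <- function(x, h, Wz, Wr, Wn, Uz, Ur, Un, bz, br, bn) {
  z <- sigmoid(x %*% Wz + h %*% Uz + rep(bz, each = nrow(x)))
  r <- sigmoid(x %*% Wr + h %*% Ur + rep(br, each = nrow(x)))
  k <- h %*% Un
  n <- tanh(x %*% Wn + r * k + rep(bn, each = nrow(x)))
  list(z = z, r = r, n = n, k = k, h_prev = h, h = (1 - z) * n + z * h)
}

# backward through one GRU step; returns dx, dh_prev and parameter grads
gru_backward <- function(cache, x, dh, Wz, Wr, Wn, Uz, Ur, Un) {
  z <- cache$z; r <- cache$r; n <- cache$n; k <- cache$k; hp <- cache$h_prev
  dz <- dh * (hp - n)
  dn <- dh * (1 - z)
  dhp <- dh * z
  dn_pre <- dn * (1 - n * n)
  dr <- dn_pre * k
  dk <- dn_pre * r
  dhp <- dhp + dk %*% t(Un)
  dz_pre <- dz * z * (1 - z)
  dr_pre <- dr * r * (1 - r)
  dhp <- dhp + dz_pre %*% t(Uz) + dr_pre %*% t(Ur)
  dx <- dz_pre %*% t(Wz) + dr_pre %*% t(Wr) + dn_pre %*% t(Wn)
  list(dx = dx, dh_prev = dhp,
       dWz = crossprod(x, dz_pre), dWr = crossprod(x, dr_pre),
       dWn = crossprod(x, dn_pre),
       dUz = crossprod(hp, dz_pre), dUr = crossprod(hp, dr_pre),
       dUn = crossprod(hp, dk),
       dbz = colSums(dz_pre), dbr = colSums(dr_pre), dbn = colSums(dn_pre))
}

row_softmax <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

# full forward pass over a batch X [B, T, P]; returns caches when `keep` is
# TRUE (training) and free-runs the decoder when teacher_forcing is FALSE
ae_forward_batch <- function(model, X, teacher_forcing = TRUE, keep = FALSE) {
  p <- model$params; cfg <- model$config
  B <- dim(X)[1]; TT <- dim(X)[2]; P <- dim(X)[3]; H <- cfg$gru_hidden
  if (P != model$input_dim) {
    ieeg_error(sprintf("frame length %d does not match the model's input dim %d",
                       P, model$input_dim), "ieegsift_shape_mismatch")
  }
  h <- matrix(0, B, H)
  hsum <- matrix(0, B, H)
  hmax <- matrix(-Inf, B, H)
  amax <- matrix(1L, B, H)
  enc_cache <- if (keep) vector("list", TT)
  Henc <- array(0, dim = c(B, TT, H))
  for (t in seq_len(TT)) {
    st <- gru_forward(matrix(X[, t, ], B, P), h,
                      p$Wz, p$Wr, p$Wn, p$Uz, p$Ur, p$Un, p$bz, p$br, p$bn)
    h <- st$h
    hsum <- hsum + h
    upd <- h > hmax
    hmax[upd] <- h[upd]
    amax[upd] <- t
    Henc[, t, ] <- h
    if (keep) enc_cache[[t]] <- st
  }
  pooled <- switch(cfg$embedding_pool,
                   mean = hsum / TT, max = hmax, final = h)
  emb <- pooled %*% p$We + rep(p$be, each = B)
  h0 <- tanh(emb %*% p$Wd + rep(p$bd, each = B))

  s <- h0
  Y <- array(0, dim = c(B, TT, P))
  A <- array(0, dim = c(B, TT, TT))          # decode step x encode step
  dec_cache <- if (keep) vector("list", TT)
  att_cache <- if (keep) vector("list", TT)
  u_prev <- matrix(0, B, P)
  for (t in seq_len(TT)) {
    u <- if (t == 1L) matrix(0, B, P)
         else if (teacher_forcing) matrix(X[, t - 1L, ], B, P)
         else u_prev
    st <- gru_forward(u, s, p$Vz, p$Vr, p$Vn, p$Sz, p$Sr, p$Sn, p$cz, p$cr, p$cn)
    s <- st$h
    if (cfg$attention == "dot") {
      scores <- matrix(0, B, TT)
      for (j in seq_len(TT)) scores[, j] <- rowSums(matrix(Henc[, j, ], B, H) * s)
      att_a <- NULL
    } else {
      sUa <- s %*% p$Ua
      scores <- matrix(0, B, TT)
      att_a <- vector("list", TT)
      for (j in seq_len(TT)) {
        a <- tanh(matrix(Henc[, j, ], B, H) %*% p$Wa + sUa + rep(p$ba, each = B))
        att_a[[j]] <- a
        scores[, j] <- a %*% p$va
      }
    }
    alpha <- row_softmax(scores)
    ctx <- matrix(0, B, H)
    for (j in seq_len(TT)) ctx <- ctx + alpha[, j] * matrix(Henc[, j, ], B, H)
    sc <- cbind(s, ctx)
    y <- sc %*% p$Wo + rep(p$bo, each = B)
    Y[, t, ] <- y
    A[, t, ] <- alpha
    u_prev <- y
    if (keep) {
      dec_cache[[t]] <- c(st, list(u = u))
      att_cache[[t]] <- list(alpha = alpha, ctx = ctx, s = s, a = att_a)
    }
  }
  list(embedding = emb, reconstruction = Y, attention = A, Henc = Henc,
       enc_cache = enc_cache, dec_cache = dec_cache, att_cache = att_cache,
       emb_raw = emb, h0 = h0, pooled = pooled, amax = amax)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# backward pass for the teacher-forced training objective
# loss = mean((Y - X)^2) over all B*T*P entries
ae_backward_batch <- function(model, X, fw) {
  p <- model$params; cfg <- model$config
  B <- dim(X)[1]; TT <- dim(X)[2]; P <- dim(X)[3]; H <- cfg$gru_hidden
  g <- zero_like(p)
  Henc <- fw$Henc
  dHenc <- array(0, dim = dim(Henc))
  scale <- 2 / (B * TT * P)

  ds_next <- matrix(0, B, H)
  for (t in rev(seq_len(TT))) {
    dy <- scale * (matrix(fw$reconstruction[, t, ], B, P) - matrix(X[, t, ], B, P))
    at <- fw$att_cache[[t]]
    sc <- cbind(at$s, at$ctx)
    g$Wo <- g$Wo + crossprod(sc, dy)
    g$bo <- g$bo + colSums(dy)
    dsc <- dy %*% t(p$Wo)
    ds <- dsc[, 1:H, drop = FALSE] + ds_next
    dctx <- dsc[, (H + 1):(2 * H), drop = FALSE]

    alpha <- at$alpha
    dalpha <- matrix(0, B, TT)
    for (j in seq_len(TT)) {
      dalpha[, j] <- rowSums(dctx * matrix(Henc[, j, ], B, H))
      dHenc[, j, ] <- dHenc[, j, ] + alpha[, j] * dctx
    }
    dscore <- alpha * (dalpha - rowSums(alpha * dalpha))
    if (cfg$attention == "dot") {
      for (j in seq_len(TT)) {
        ds <- ds + dscore[, j] * matrix(Henc[, j, ], B, H)
        dHenc[, j, ] <- dHenc[, j, ] + dscore[, j] * at$s
      }
    } else {
      for (j in seq_len(TT)) {
        a <- at$a[[j]]
        g$va <- g$va + colSums(a * dscore[, j])
        dpre <- (dscore[, j] %o% p$va) * (1 - a * a)
        g$Wa <- g$Wa + crossprod(matrix(Henc[, j, ], B, H), dpre)
        g$Ua <- g$Ua + crossprod(at$s, dpre)
        g$ba <- g$ba + colSums(dpre)
        dHenc[, j, ] <- dHenc[, j, ] + dpre %*% t(p$Wa)
        ds <- ds + dpre %*% t(p$Ua)
      }
    }

    dc <- fw$dec_cache[[t]]
    bk <- gru_backward(dc, dc$u, ds, p$Vz, p$Vr, p$Vn, p$Sz, p$Sr, p$Sn)
    g$Vz <- g$Vz + bk$dWz; g$Vr <- g$Vr + bk$dWr; g$Vn <- g$Vn + bk$dWn
    g$Sz <- g$Sz + bk$dUz; g$Sr <- g$Sr + bk$dUr; g$Sn <- g$Sn + bk$dUn
    g$cz <- g$cz + bk$dbz; g$cr <- g$cr + bk$dbr; g$cn <- g$cn + bk$dbn
    ds_next <- bk$dh_prev
  }

  # decoder initial state -> embedding head
  dh0 <- ds_next
  dpre0 <- dh0 * (1 - fw$h0 * fw$h0)
  g$Wd <- g$Wd + crossprod(fw$emb_raw, dpre0)
  g$bd <- g$bd + colSums(dpre0)
  demb <- dpre0 %*% t(p$Wd)
  g$We <- g$We + crossprod(fw$pooled, demb)
  g$be <- g$be + colSums(demb)
  dpool <- demb %*% t(p$We)
  if (cfg$embedding_pool == "mean") {
    for (t in seq_len(TT)) dHenc[, t, ] <- dHenc[, t, ] + dpool / TT
  } else if (cfg$embedding_pool == "max") {
    for (t in seq_len(TT)) {
      dHenc[, t, ] <- dHenc[, t, ] + dpool * (fw$amax == t)
    }
  } else {
    dHenc[, TT, ] <- dHenc[, TT, ] + dpool
  }

  # encoder BPTT
  dh <- matrix(0, B, H)
  for (t in rev(seq_len(TT))) {
    dh <- dh + matrix(dHenc[, t, ], B, H)
    ec <- fw$enc_cache[[t]]
    bk <- gru_backward(ec, matrix(X[, t, ], B, dim(X)[3]), dh,
                       p$Wz, p$Wr, p$Wn, p$Uz, p$Ur, p$Un)
    g$Wz <- g$Wz + bk$dWz; g$Wr <- g$Wr + bk$dWr; g$Wn <- g$Wn + bk$dWn
    g$Uz <- g$Uz + bk$dUz; g$Ur <- g$Ur + bk$dUr; g$Un <- g$Un + bk$dUn
    g$bz <- g$bz + bk$dbz; g$br <- g$br + bk$dbr; g$bn <- g$bn + bk$dbn
    dh <- bk$dh_prev
  }
  g
}

ae_loss_batch <- function(X, Y) mean((Y - X)^2)

as_frame_array <- function(x) {
  if (inherits(x, "spectrogram_tensor")) {
    fr <- tensor_frames(x)
    return(array(fr, dim = c(1L, nrow(fr), ncol(fr))))
  }
  if (is.matrix(x)) return(array(x, dim = c(1L, nrow(x), ncol(x))))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.list(x)) {
    mats <- lapply(x, function(e) if (inherits(e, "spectrogram_tensor")) tensor_frames(e) else e)
    out <- array(0, dim = c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
    for (i in seq_along(mats)) out[i, , ] <- mats[[i]]
    ids <- if (inherits(x[[1]], "spectrogram_tensor"))
      vapply(x, function(e) e$segment_id, character(1))
    dimnames(out) <- list(ids, NULL, NULL)
    return(out)
  }
  ieeg_error("unsupported input: expected tensor(s) or a frame array",
             "ieegsift_shape_mismatch")
}

#' Encode spectrogram tensors to embeddings
#'
#' Deterministic inference pass through the encoder; the final hidden state is
#' mapped affinely to the `embedding_dim`-length code.
#'
#' @param model a trained (or freshly initialized) `ae_model`.
#' @param x a `spectrogram_tensor`, a list of them, a `[T, P]` frame matrix,
#'   or a `[n, T, P]` array from [tensor_stack()].
#' @return an `n x embedding_dim` matrix (one row per input; rownames are
#'   segment ids when available).
#' @export
encode <- function(model, x) {
  X <- as_frame_array(x)
  p <- model$params
  B <- dim(X)[1]; TT <- dim(X)[2]; P <- dim(X)[3]
  if (P != model$input_dim) {
    ieeg_error(sprintf("frame length %d does not match the model's input dim %d",
                       P, model$input_dim), "ieegsift_shape_mismatch")
  }
  h <- matrix(0, B, model$config$gru_hidden)
  hsum <- matrix(0, B, model$config$gru_hidden)
  hmax <- matrix(-Inf, B, model$config$gru_hidden)
  for (t in seq_len(TT)) {
    h <- gru_forward(matrix(X[, t, ], B, P), h,
                     p$Wz, p$Wr, p$Wn, p$Uz, p$Ur, p$Un, p$bz, p$br, p$bn)$h
    hsum <- hsum + h
    hmax <- pmax(hmax, h)
  }
  pooled <- switch(model$config$embedding_pool,
                   mean = hsum / TT, max = hmax, final = h)
  emb <- pooled %*% p$We + rep(p$be, each = B)
  rownames(emb) <- dimnames(X)[[1]]
  emb
}

#' Run the full encoder-decoder on one tensor
#'
#' At inference the decoder free-runs (each step receives the model's own
#' previous output frame) plus the attention context over encoder states.
#'
#' @param model an `ae_model`.
#' @param tensor a `spectrogram_tensor` or `[T, P]` frame matrix.
#' @param teacher_forcing feed true previous frames instead of free-running.
#' @return list with `embedding` (length-D vector), `reconstruction` (`[2, F,
#'   T]` array when the input was a tensor, else `[T, P]`), and `attention`
#'   (`[T, T]` matrix of decode-step weights over encode steps).
#' @export
ae_forward <- function(model, tensor, teacher_forcing = FALSE) {
  X <- as_frame_array(tensor)
  fw <- ae_forward_batch(model, X, teacher_forcing = teacher_forcing)
  TT <- dim(X)[2]; P <- dim(X)[3]
  recon_frames <- matrix(fw$reconstruction[1, , ], TT, P)
  recon <- recon_frames
  if (inherits(tensor, "spectrogram_tensor")) {
    Fdim <- dim(tensor$values)[2]
    vals <- array(0, dim = dim(tensor$values))
    vals[1, , ] <- t(recon_frames[, 1:Fdim, drop = FALSE])
    vals[2, , ] <- t(recon_frames[, (Fdim + 1):(2 * Fdim), drop = FALSE])
    recon <- vals
  }
  list(embedding = as.numeric(fw$embedding[1, ]), reconstruction = recon,
       attention = matrix(fw$attention[1, , ], TT, TT))
}

#' Mean cosine similarity between tensors and their reconstructions
#'
#' `cos(x, xhat) = <x, xhat> / (|x| |xhat|)` on flattened frames, averaged
#' over the set; zero-norm inputs contribute 0 by convention. Reconstruction
#' uses the free-running decoder (inference mode).
#'
#' @param model an `ae_model`.
#' @param x tensors as accepted by [encode()].
#' @return scalar in `[-1, 1]`.
#' @export
validate_reconstruction <- function(model, x) {
  X <- as_frame_array(x)
  if (dim(X)[1] == 0) ieeg_error("empty validation set", "ieegsift_empty_input")
  fw <- ae_forward_batch(model, X, teacher_forcing = FALSE)
  mean(vapply(seq_len(dim(X)[1]), function(i) {
    cosine_similarity(as.numeric(X[i, , ]), as.numeric(fw$reconstruction[i, , ]))
  }, numeric(1)))
}

#' Cosine similarity of two vectors (zero-norm convention: 0)
#' @param a,b numeric vectors of equal length.
#' @return scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  c1 <- 1 - cfg$beta1^state$t
  c2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - cfg$learning_rate *
      (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

#' Train the autoencoder on unlabeled tensors
#'
#' Mini-batch Adam on the teacher-forced reconstruction MSE. After each epoch
#' the mean free-running cosine similarity on the validation tensors is
#' recorded; the returned model carries the weights of the epoch with the
#' highest validation cosine (`best_epoch`). The interface accepts tensors
#' only — labels cannot reach this stage.
#'
#' @param train_x,val_x tensors as accepted by [encode()]; `train_x` must be
#'   nonempty.
#' @param config an [ae_config()].
#' @return list `(model, history)`; `history` is a `train_history` with
#'   per-epoch `train_mse`, `val_cosine` and `best_epoch`.
#' @export
train_autoencoder <- function(train_x, val_x, config = ae_config()) {
  X <- as_frame_array(train_x)
  if (dim(X)[1] == 0) ieeg_error("empty training set", "ieegsift_empty_input")
  XV <- as_frame_array(val_x)
  model <- ae_init(config, input_dim = dim(X)[3], n_frames = dim(X)[2])
  history <- structure(list(train_mse = numeric(0), val_cosine = numeric(0),
                            best_epoch = NA_integer_),
                       class = "train_history")
  if (config$epochs == 0L) return(list(model = model, history = history))

  n <- dim(X)[1]
  best <- -Inf; best_params <- model$params
  withr::with_seed(config$seed + 1L, {
    opt <- adam_init(model$params)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        Xb <- X[idx, , , drop = FALSE]
        fw <- ae_forward_batch(model, Xb, teacher_forcing = TRUE, keep = TRUE)
        loss <- ae_loss_batch(Xb, fw$reconstruction)
        if (!is.finite(loss)) {
          ieeg_error(sprintf("non-finite training loss in epoch %d", epoch),
                     "ieegsift_diverged")
        }
        losses[bi] <- loss
        g <- ae_backward_batch(model, Xb, fw)
        if (is.finite(config$clip_norm)) {
          gnorm <- sqrt(sum(vapply(g, function(x) sum(x * x), numeric(1))))
          if (gnorm > config$clip_norm) {
            g <- lapply(g, `*`, config$clip_norm / gnorm)
          }
        }
        upd <- adam_step(model$params, g, opt, config)
        model$params <- upd$params
        opt <- upd$state
      }
      history$train_mse <- c(history$train_mse, mean(losses))
      vc <- validate_reconstruction(model, XV)
      history$val_cosine <- c(history$val_cosine, vc)
      if (vc > best) {
        best <- vc
        best_params <- model$params
        history$best_epoch <- epoch
      }
    }
  })
  model$params <- best_params
  list(model = model, history = history)
}
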