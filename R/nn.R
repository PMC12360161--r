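# Minimal neural-network engine for the three window classifiers.
#
# Everything is plain base-R matrix algebra: the networks are tiny
# (15-position windows, <=23 input features, a few hundred training
# peptides), so explicit forward/backward passes with Adam updates are
# fast and keep the package free of heavyweight framework dependencies.
# Parameters are nested lists of numeric arrays; gradients mirror the
# parameter tree exactly.
#
# Conventions: samples in rows; `X` is either an n x 15 integer id matrix
# (embedding_ids encoding; the learnable embedding lives in params$E) or
# an n x 15 x D numeric array (all other encodings). The output layer is
# a single logit; probabilities are sigmoid(logit).

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# ---- parameter trees -------------------------------------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1L]])) {
    out <- lapply(seq_along(trees[[1L]]), function(i)
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i))))
    names(out) <- names(trees[[1L]])
    out
  } else {
    do.call(f, trees)
  }
}

adam_init <- function(params) {
  zeros <- tree_map(function(p) p * 0, params)
  list(m = zeros, v = tree_map(function(p) p * 0, params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  params <- tree_map(function(p, m, v) p - lr * (m * c1) / (sqrt(v * c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

# ---- dense stack (shared head) --------------------------------------------

dense_init <- function(in_dim, hidden, out_dim = 1L) {
  sizes <- c(in_dim, hidden, out_dim)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- glorot(sizes[l], sizes[l + 1L])
    b[[l]] <- matrix(0, 1L, sizes[l + 1L])
  }
  list(W = W, b = b)
}

dense_forward <- function(dp, X, dropout = 0, training = FALSE) {
  L <- length(dp$W)
  A <- X
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- A %*% dp$W[[l]] + matrix(dp$b[[l]], nrow(A), ncol(dp$W[[l]]), byrow = TRUE)
    if (l < L) {
      H <- relu(Z)
      mask <- NULL
      if (training && dropout > 0) {
        mask <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H)) / (1 - dropout)
        H <- H * mask
      }
      caches[[l]] <- list(A_in = A, Z = Z, mask = mask)
      A <- H
    } else {
      caches[[l]] <- list(A_in = A)
    }
  }
  list(logit = Z, caches = caches)
}

dense_backward <- function(dp, caches, dlogit) {
  L <- length(dp$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  dZ <- dlogit
  for (l in L:1) {
    dW[[l]] <- crossprod(caches[[l]]$A_in, dZ)
    db[[l]] <- matrix(colSums(dZ), 1L)
    dA <- dZ %*% t(dp$W[[l]])
    if (l > 1L) {
      if (!is.null(caches[[l - 1L]]$mask)) dA <- dA * caches[[l - 1L]]$mask
      dZ <- dA * (caches[[l - 1L]]$Z > 0)
    }
  }
  list(grads = list(W = dW, b = db), dX = dA)
}

# ---- embedding front-end ---------------------------------------------------

embed_lookup <- function(E, ids) {
  n <- nrow(ids); L <- ncol(ids); d <- ncol(E)
  array(E[as.vector(ids), ], dim = c(n, L, d))
}

embed_backward <- function(E, ids, dX3) {
  dE <- E * 0
  flat <- matrix(dX3, nrow(ids) * ncol(ids), ncol(E))
  idx <- as.vector(ids)
  for (v in unique(idx)) {
    rows <- idx == v
    dE[v, ] <- colSums(flat[rows, , drop = FALSE])
  }
  dE
}

# ---- GRU layer -------------------------------------------------------------
# Gates: z = sig(xWz + hUz + bz), r = sig(xWr + hUr + br),
# g = tanh(xWg + (r*h)Ug + bg), h' = (1-z)*h + z*g; h0 = 0.
# Orthogonal recurrent weights and a negative update-gate bias (slow state
# turnover) stabilize learning of dependencies far from the C-terminal
# read-out.

gru_layer_init <- function(D, H) {
  ortho <- function(H) qr.Q(qr(matrix(stats::rnorm(H * H), H, H)))
  list(Wz = glorot(D, H), Uz = ortho(H), bz = matrix(-1, 1L, H),
       Wr = glorot(D, H), Ur = ortho(H), br = matrix(0, 1L, H),
       Wg = glorot(D, H), Ug = ortho(H), bg = matrix(0, 1L, H))
}

# X3: n x T x D input; returns the full hidden sequence H3 (n x T x H)
# plus per-step intermediates for backprop.
gru_layer_forward <- function(g, X3) {
  n <- dim(X3)[1L]; Tn <- dim(X3)[2L]; H <- ncol(g$Wz)
  h <- matrix(0, n, H)
  H3 <- array(0, dim = c(n, Tn, H))
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- slice_t(X3, t)
    z <- sigmoid(x %*% g$Wz + h %*% g$Uz + matrix(g$bz, n, H, byrow = TRUE))
    r <- sigmoid(x %*% g$Wr + h %*% g$Ur + matrix(g$br, n, H, byrow = TRUE))
    gg <- tanh(x %*% g$Wg + (r * h) %*% g$Ug + matrix(g$bg, n, H, byrow = TRUE))
    h_new <- (1 - z) * h + z * gg
    steps[[t]] <- list(x = x, h_prev = h, z = z, r = r, g = gg)
    H3[, t, ] <- h_new
    h <- h_new
  }
  list(H3 = H3, steps = steps)
}

# dH3: gradient w.r.t. every hidden output (n x T x H). Returns parameter
# gradients and the gradient w.r.t. the layer input.
gru_layer_backward <- function(g, steps, dH3, in_dim) {
  n <- dim(dH3)[1L]; Tn <- dim(dH3)[2L]; H <- ncol(g$Wz)
  gr <- list(Wz = g$Wz * 0, Uz = g$Uz * 0, bz = g$bz * 0,
             Wr = g$Wr * 0, Ur = g$Ur * 0, br = g$br * 0,
             Wg = g$Wg * 0, Ug = g$Ug * 0, bg = g$bg * 0)
  dX3 <- array(0, dim = c(n, Tn, in_dim))
  dh <- matrix(0, n, H)
  for (t in Tn:1) {
    st <- steps[[t]]
    dh <- dh + slice_t(dH3, t)
    dz <- dh * (st$g - st$h_prev)
    dg <- dh * st$z
    dh_prev <- dh * (1 - st$z)
    dg_pre <- dg * (1 - st$g^2)
    gr$Wg <- gr$Wg + crossprod(st$x, dg_pre)
    gr$Ug <- gr$Ug + crossprod(st$r * st$h_prev, dg_pre)
    gr$bg <- gr$bg + matrix(colSums(dg_pre), 1L)
    drh <- dg_pre %*% t(g$Ug)
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r
    dz_pre <- dz * st$z * (1 - st$z)
    dr_pre <- dr * st$r * (1 - st$r)
    gr$Wz <- gr$Wz + crossprod(st$x, dz_pre)
    gr$Uz <- gr$Uz + crossprod(st$h_prev, dz_pre)
    gr$bz <- gr$bz + matrix(colSums(dz_pre), 1L)
    gr$Wr <- gr$Wr + crossprod(st$x, dr_pre)
    gr$Ur <- gr$Ur + crossprod(st$h_prev, dr_pre)
    gr$br <- gr$br + matrix(colSums(dr_pre), 1L)
    dh_prev <- dh_prev + dz_pre %*% t(g$Uz) + dr_pre %*% t(g$Ur)
    dX3[, t, ] <- dz_pre %*% t(g$Wz) + dr_pre %*% t(g$Wr) + dg_pre %*% t(g$Wg)
    dh <- dh_prev
  }
  list(grads = gr, dX3 = dX3)
}

# ---- architectures ---------------------------------------------------------

nn_input_dim <- function(config) {
  switch(config$encoding,
    onehot        = 23L,
    embedding_ids = as.integer(config$embedding_dim),
    blosum62_flag = 22L,
    descriptors   = 20L,
    stop("unknown encoding: ", config$encoding))
}

nn_init <- function(config) {
  D <- nn_input_dim(config)
  params <- list()
  if (config$encoding == "embedding_ids")
    params$E <- glorot(length(TOKENS), as.integer(config$embedding_dim))
  arch <- config$architecture
  if (arch == "mlp") {
    params$dense <- dense_init(WINDOW_LENGTH * D, config$hidden)
  } else if (arch == "cnn") {
    k <- as.integer(config$kernel)
    if (k < 1L || k > WINDOW_LENGTH)
      stop("CNN kernel size must be in 1..", WINDOW_LENGTH)
    params$conv <- list(W = glorot(k * D, as.integer(config$filters)),
                        b = matrix(0, 1L, as.integer(config$filters)))
    params$dense <- dense_init(as.integer(config$filters), config$hidden)
  } else if (arch == "gru") {
    H <- as.integer(config$gru_hidden)
    params$gru <- lapply(seq_len(as.integer(config$gru_layers)), function(l)
      gru_layer_init(if (l == 1L) D else H, H))
    params$dense <- dense_init(H, config$hidden)
  } else {
    stop("unknown architecture: ", arch)
  }
  params
}

# X3 slice helper that never drops the sample dimension.
slice_t <- function(X3, t) matrix(X3[, t, ], dim(X3)[1L], dim(X3)[3L])

nn_forward <- function(params, X, config, training = FALSE) {
  if (config$encoding == "embedding_ids") {
    ids <- X
    X3 <- embed_lookup(params$E, ids)
  } else {
    ids <- NULL
    X3 <- X
  }
  n <- dim(X3)[1L]; D <- dim(X3)[3L]
  arch <- config$architecture
  if (arch == "mlp") {
    Xflat <- matrix(X3, n, WINDOW_LENGTH * D)
    df <- dense_forward(params$dense, Xflat, config$dropout, training)
    cache <- list(ids = ids, X3dim = dim(X3), dense = df$caches)
  } else if (arch == "cnn") {
    k <- as.integer(config$kernel); Lp <- WINDOW_LENGTH - k + 1L
    Fc <- as.integer(config$filters)
    M <- matrix(0, n * Lp, k * D)
    for (j in seq_len(k))
      for (t0 in seq_len(Lp))
        M[(t0 - 1L) * n + seq_len(n), ((j - 1L) * D + 1L):(j * D)] <-
          slice_t(X3, t0 + j - 1L)
    Z <- M %*% params$conv$W +
      matrix(params$conv$b, n * Lp, Fc, byrow = TRUE)
    A <- relu(Z)
    # pool: max over the Lp positions per (sample, filter)
    A3 <- array(A, dim = c(n, Lp, Fc))  # rows were position-major blocks of n
    P <- matrix(0, n, Fc); amax <- matrix(0L, n, Fc)
    for (f in seq_len(Fc)) {
      Af <- matrix(A3[, , f], n, Lp)
      amax[, f] <- max.col(Af, ties.method = "first")
      P[, f] <- Af[cbind(seq_len(n), amax[, f])]
    }
    df <- dense_forward(params$dense, P, config$dropout, training)
    cache <- list(ids = ids, X3dim = dim(X3), M = M, Z = Z, amax = amax,
                  Lp = Lp, dense = df$caches)
  } else if (arch == "gru") {
    layers <- vector("list", length(params$gru))
    inp <- X3
    for (l in seq_along(params$gru)) {
      layers[[l]] <- gru_layer_forward(params$gru[[l]], inp)
      inp <- layers[[l]]$H3
    }
    h_final <- slice_t(inp, WINDOW_LENGTH)
    df <- dense_forward(params$dense, h_final, config$dropout, training)
    cache <- list(ids = ids, X3dim = dim(X3), layers = layers,
                  dense = df$caches)
  }
  list(prob = as.vector(sigmoid(df$logit)), logit = as.vector(df$logit),
       cache = cache)
}

nn_backward <- function(params, cache, dlogit, config) {
  n <- cache$X3dim[1L]; D <- cache$X3dim[3L]
  dlogit <- matrix(dlogit, n, 1L)
  arch <- config$architecture
  grads <- list()
  db <- dense_backward(params$dense, cache$dense, dlogit)
  grads$dense <- db$grads
  if (arch == "mlp") {
    dX3 <- array(db$dX, dim = cache$X3dim)
  } else if (arch == "cnn") {
    k <- as.integer(config$kernel); Lp <- cache$Lp
    Fc <- as.integer(config$filters)
    dP <- db$dX                      # n x F
    dA <- matrix(0, n * Lp, Fc)
    for (f in seq_len(Fc))
      dA[(cache$amax[, f] - 1L) * n + seq_len(n), f] <- dP[, f]
    dZ <- dA * (cache$Z > 0)
    grads$conv <- list(W = crossprod(cache$M, dZ),
                       b = matrix(colSums(dZ), 1L))
    dM <- dZ %*% t(params$conv$W)
    dX3 <- array(0, dim = cache$X3dim)
    for (j in seq_len(k))
      for (t0 in seq_len(Lp))
        dX3[, t0 + j - 1L, ] <- dX3[, t0 + j - 1L, ] +
          dM[(t0 - 1L) * n + seq_len(n), ((j - 1L) * D + 1L):(j * D)]
  } else if (arch == "gru") {
    n_layers <- length(params$gru)
    H <- ncol(params$gru[[1L]]$Wz)
    # gradient enters only at the final hidden state of the top layer
    dH3 <- array(0, dim = c(n, WINDOW_LENGTH, H))
    dH3[, WINDOW_LENGTH, ] <- db$dX
    grads$gru <- vector("list", n_layers)
    for (l in n_layers:1) {
      in_dim <- if (l == 1L) D else H
      bw <- gru_layer_backward(params$gru[[l]], cache$layers[[l]]$steps,
                               dH3, in_dim)
      grads$gru[[l]] <- bw$grads
      dH3 <- bw$dX3
    }
    dX3 <- dH3
  }
  if (config$encoding == "embedding_ids") {
    out <- list(E = embed_backward(params$E, cache$ids, dX3))
    out[names(grads)] <- grads
    # keep tree order identical to params
    grads <- out[names(params)]
  } else {
    grads <- grads[names(params)]
  }
  grads
}

# Binary cross-entropy; probabilities clipped for stability.
bce_loss <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# F1 at a strict probability threshold; returns NA when undefined.
f1_at_threshold <- function(y_true, y_score, threshold = 0.5) {
  pred <- y_score > threshold
  tp <- sum(pred & y_true == 1)
  fp <- sum(pred & y_true == 0)
  fn <- sum(!pred & y_true == 1)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Trace the early-stopping rule over a validation-F1 history
#'
#' Training monitors validation F1 after every epoch; from the fifth epoch
#' on, it halts once `patience` consecutive epochs have passed without an
#' improvement over the running best, and the best epoch's parameters are
#' kept. This helper applies the same rule to a recorded F1 trace.
#'
#' @param f1 Numeric vector of per-epoch validation F1 values.
#' @param min_epoch Earliest epoch at which stopping may trigger.
#' @param patience Number of non-improving epochs tolerated.
#' @return List with `best_epoch` (first epoch attaining the maximum) and
#'   `stop_epoch` (epoch after which training halts; `NA` if the trace
#'   ends without triggering).
#' @examples
#' trace_early_stop(c(.2, .3, .4, .5, .6, .6, .6, .6, .6, .6))
#' @export
trace_early_stop <- function(f1, min_epoch = 5L, patience = 5L) {
  best_epoch <- NA_integer_
  best <- -Inf
  for (e in seq_along(f1)) {
    if (!is.na(f1[e]) && f1[e] > best + 1e-12) {
      best <- f1[e]
      best_epoch <- e
    }
    if (e >= min_epoch && !is.na(best_epoch) && e - best_epoch >= patience)
      return(list(best_epoch = best_epoch, stop_epoch = e))
  }
  list(best_epoch = best_epoch, stop_epoch = NA_integer_)
}

# Mini-batch training with Adam and early stopping on validation F1.
# The caller is responsible for seeding the RNG.
train_nn <- function(config, X, y, Xval, yval) {
  params <- nn_init(config)
  state <- adam_init(params)
  n <- if (is.matrix(X)) nrow(X) else dim(X)[1L]
  take <- function(Z, i) {
    if (is.matrix(Z)) Z[i, , drop = FALSE] else Z[i, , , drop = FALSE]
  }
  history <- numeric(0)
  best <- list(f1 = -Inf, epoch = NA_integer_, params = params)
  bs <- min(as.integer(config$batch_size), n)
  for (epoch in seq_len(as.integer(config$max_epochs))) {
    idx <- sample.int(n)
    for (start in seq(1L, n, by = bs)) {
      b <- idx[start:min(start + bs - 1L, n)]
      fw <- nn_forward(params, take(X, b), config, training = TRUE)
      dlogit <- (fw$prob - y[b]) / length(b)
      gr <- nn_backward(params, fw$cache, dlogit, config)
      upd <- adam_step(params, gr, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    f1 <- f1_at_threshold(yval, nn_forward(params, Xval, config)$prob)
    if (is.na(f1)) f1 <- 0
    history <- c(history, f1)
    if (f1 > best$f1 + 1e-12)
      best <- list(f1 = f1, epoch = epoch, params = params)
    es <- trace_early_stop(history, config$min_epochs, config$patience)
    if (!is.na(es$stop_epoch)) break
  }
  list(params = best$params, best_epoch = best$epoch,
       history = data.frame(epoch = seq_along(history), val_f1 = history))
}
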