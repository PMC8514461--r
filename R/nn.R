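# Internal neural-network engine: batched bidirectional LSTM layers, fully
# connected layers, embedding, softmax cross-entropy, and Adam, implemented
# on base-R matrix algebra. Sequences are represented timestep-major as a
# list of T matrices (batch x features). Backpropagation is validated against
# a finite-difference oracle in the test suite.

sigm <- function(x) 1 / (1 + exp(-x))

addb <- function(Z, b) Z + rep(b, each = nrow(Z))

zeros_like <- function(x) {
  if (is.list(x)) return(lapply(x, zeros_like))
  x * 0
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a = a, b = b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

tree_add <- function(a, b) tree_map2(`+`, a, b)

init_mat <- function(nr, nc, r) matrix(stats::runif(nr * nc, -r, r), nr, nc)

init_lstm_dir <- function(d_in, h) {
  r <- 1 / sqrt(h)
  b <- rep(0, 4L * h)
  b[(h + 1L):(2L * h)] <- 1  # forget-gate bias starts open
  list(W = init_mat(d_in, 4L * h, r), U = init_mat(h, 4L * h, r), b = b)
}

init_bilstm <- function(d_in, h) {
  list(fwd = init_lstm_dir(d_in, h), bwd = init_lstm_dir(d_in, h))
}

init_fc <- function(d_in, d_out) {
  r <- 1 / sqrt(d_in)
  list(W = init_mat(d_in, d_out, r), b = rep(0, d_out))
}

# ---- unidirectional LSTM ----

lstm_dir_forward <- function(X, p) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  H <- length(p$b) %/% 4L
  hprev <- matrix(0, B, H)
  cprev <- matrix(0, B, H)
  Hs <- vector("list", Tn)
  cache <- vector("list", Tn)
  i1 <- 1:H; i2 <- (H + 1L):(2L * H); i3 <- (2L * H + 1L):(3L * H); i4 <- (3L * H + 1L):(4L * H)
  for (t in seq_len(Tn)) {
    Z <- addb(X[[t]] %*% p$W + hprev %*% p$U, p$b)
    gi <- sigm(Z[, i1, drop = FALSE])
    gf <- sigm(Z[, i2, drop = FALSE])
    gg <- tanh(Z[, i3, drop = FALSE])
    go <- sigm(Z[, i4, drop = FALSE])
    cc <- gf * cprev + gi * gg
    tc <- tanh(cc)
    h <- go * tc
    cache[[t]] <- list(x = X[[t]], i = gi, f = gf, g = gg, o = go,
                       tc = tc, cprev = cprev, hprev = hprev)
    hprev <- h; cprev <- cc
    Hs[[t]] <- h
  }
  list(H = Hs, cache = cache)
}

lstm_dir_backward <- function(dH, cache, p) {
  Tn <- length(cache)
  B <- nrow(cache[[1]]$x)
  H <- length(p$b) %/% 4L
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  dX <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- dh_next
    if (!is.null(dH[[t]])) dh <- dh + dH[[t]]
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$cprev
    dg <- dc * cc$i
    dc_next <- dc * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$x, dZ)
    dU <- dU + crossprod(cc$hprev, dZ)
    db <- db + colSums(dZ)
    dX[[t]] <- tcrossprod(dZ, p$W)
    dh_next <- tcrossprod(dZ, p$U)
  }
  list(dX = dX, grads = list(W = dW, U = dU, b = db))
}

# ---- bidirectional LSTM ----

bilstm_forward <- function(X, p) {
  Tn <- length(X)
  fw <- lstm_dir_forward(X, p$fwd)
  bw <- lstm_dir_forward(rev(X), p$bwd)
  out <- vector("list", Tn)
  for (t in seq_len(Tn)) out[[t]] <- cbind(fw$H[[t]], bw$H[[Tn - t + 1L]])
  # final state of each direction (forward after t=T, backward after t=1)
  final <- cbind(fw$H[[Tn]], bw$H[[Tn]])
  list(out = out, final = final, fw = fw, bw = bw)
}

bilstm_backward <- function(dOut, dFinal, fwres, p) {
  Tn <- length(fwres$fw$cache)
  H <- length(p$fwd$b) %/% 4L
  dHf <- vector("list", Tn)
  dHb <- vector("list", Tn)  # backward-time order
  for (t in seq_len(Tn)) {
    if (!is.null(dOut) && !is.null(dOut[[t]])) {
      dHf[[t]] <- dOut[[t]][, 1:H, drop = FALSE]
      dHb[[Tn - t + 1L]] <- dOut[[t]][, (H + 1L):(2L * H), drop = FALSE]
    }
  }
  if (!is.null(dFinal)) {
    add <- function(a, b) if (is.null(a)) b else a + b
    dHf[[Tn]] <- add(dHf[[Tn]], dFinal[, 1:H, drop = FALSE])
    dHb[[Tn]] <- add(dHb[[Tn]], dFinal[, (H + 1L):(2L * H), drop = FALSE])
  }
  fb <- lstm_dir_backward(dHf, fwres$fw$cache, p$fwd)
  bb <- lstm_dir_backward(dHb, fwres$bw$cache, p$bwd)
  dX <- vector("list", Tn)
  for (t in seq_len(Tn)) dX[[t]] <- fb$dX[[t]] + bb$dX[[Tn - t + 1L]]
  list(dX = dX, grads = list(fwd = fb$grads, bwd = bb$grads))
}

# ---- per-timestep fully connected layer (ReLU) ----

fc_seq_forward <- function(X, p, relu = TRUE) {
  Y <- vector("list", length(X))
  pre <- vector("list", length(X))
  for (t in seq_along(X)) {
    z <- addb(X[[t]] %*% p$W, p$b)
    pre[[t]] <- z
    Y[[t]] <- if (relu) pmax(z, 0) else z
  }
  list(Y = Y, pre = pre, X = X)
}

fc_seq_backward <- function(dY, fwres, p, relu = TRUE) {
  dW <- p$W * 0; db <- p$b * 0
  dX <- vector("list", length(dY))
  for (t in seq_along(dY)) {
    dz <- dY[[t]]
    if (relu) dz <- dz * (fwres$pre[[t]] > 0)
    dW <- dW + crossprod(fwres$X[[t]], dz)
    db <- db + colSums(dz)
    dX[[t]] <- tcrossprod(dz, p$W)
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

fc_forward <- function(X, p, relu = FALSE) {
  z <- addb(X %*% p$W, p$b)
  list(Y = if (relu) pmax(z, 0) else z, pre = z, X = X)
}

fc_backward <- function(dY, fwres, p, relu = FALSE) {
  dz <- dY
  if (relu) dz <- dz * (fwres$pre > 0)
  list(dX = tcrossprod(dz, p$W),
       grads = list(W = crossprod(fwres$X, dz), b = colSums(dz)))
}

# ---- dropout (inverted scaling; identity when not training) ----

dropout_seq_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, masks = NULL))
  masks <- lapply(X, function(x) {
    matrix((stats::runif(length(x)) >= rate) / (1 - rate), nrow(x), ncol(x))
  })
  list(Y = mapply(`*`, X, masks, SIMPLIFY = FALSE), masks = masks)
}

dropout_seq_backward <- function(dY, masks) {
  if (is.null(masks)) return(dY)
  mapply(`*`, dY, masks, SIMPLIFY = FALSE)
}

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= rate) / (1 - rate), nrow(X), ncol(X))
  list(Y = X * mask, mask = mask)
}

# ---- softmax cross-entropy ----

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- Adam ----

adam_init <- function(params) list(m = zeros_like(params), v = zeros_like(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  upd <- tree_map2(function(m, v) lr * (m * c1) / (sqrt(v * c2) + eps), state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}
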