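# The two-branch bidirectional LSTM classifier.
#
# Architecture: sequence features (embedded base + mean/sd/signal-count per
# k-mer position) and signal features (m subsampled currents per position)
# are each fed through a bidirectional LSTM followed by a per-position fully
# connected layer; the two per-position outputs are concatenated and fed
# through a stack of bidirectional LSTM layers; the final hidden states of
# both directions pass through two fully connected layers and a softmax that
# yields (P_unmethylated, P_methylated) with P_m + P_um = 1. Dropout is
# applied to LSTM outputs and the penultimate fully connected layer during
# training only.

#' Model configuration
#'
#' Defaults follow the published architecture (three merged bidirectional
#' LSTM layers of 256 hidden units, initial learning rate 0.001). The branch
#' hidden width, dropout rate, base-embedding dimension and batch size are
#' exposed here as configuration. Desk-scale analyses use much smaller
#' widths; see the package vignette.
#'
#' @param k,m Feature window length and signals per base (see
#'   [feature_config()]).
#' @param mode `"full"` (both branches), `"signal_only"` or `"sequence_only"`.
#' @param embed_dim Base-embedding dimension.
#' @param branch_hidden Hidden units in each branch bidirectional LSTM.
#' @param branch_out Output width of each branch's fully connected layer
#'   (defaults to `branch_hidden`).
#' @param merged_layers Number of bidirectional LSTM layers in the merged
#'   stack (default 3).
#' @param merged_hidden Hidden units per merged layer (default 256).
#' @param dropout_rate Dropout probability in `[0, 1)` (default 0.5).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 512).
#' @param max_epochs Maximum training epochs.
#' @param early_stopping Stop when validation accuracy of the current epoch
#'   drops below the best seen so far.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return Object of class `model_config`.
#' @export
model_config <- function(k = 13L, m = 16L,
                         mode = c("full", "signal_only", "sequence_only"),
                         embed_dim = 4L, branch_hidden = 256L, branch_out = NULL,
                         merged_layers = 3L, merged_hidden = 256L,
                         dropout_rate = 0.5, learning_rate = 0.001,
                         batch_size = 512L, max_epochs = 10L,
                         early_stopping = TRUE, seed = 42L) {
  mode <- match.arg(mode)
  branch_out <- as.integer(branch_out %||% branch_hidden)
  cfg <- list(k = as.integer(k), m = as.integer(m), mode = mode,
              embed_dim = as.integer(embed_dim),
              branch_hidden = as.integer(branch_hidden), branch_out = branch_out,
              merged_layers = as.integer(merged_layers),
              merged_hidden = as.integer(merged_hidden),
              dropout_rate = dropout_rate, learning_rate = learning_rate,
              batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
              early_stopping = isTRUE(early_stopping), seed = as.integer(seed))
  if (cfg$k < 3L || cfg$k %% 2L == 0L) stopf("k must be odd and >= 3")
  if (cfg$m < 1L) stopf("m must be >= 1")
  if (cfg$merged_layers < 1L) stopf("merged_layers must be >= 1")
  if (cfg$learning_rate <= 0) stopf("learning_rate must be positive")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  if (cfg$batch_size < 1L || cfg$max_epochs < 1L) stopf("batch_size and max_epochs must be >= 1")
  structure(cfg, class = "model_config")
}

#' Build an untrained methylation classifier
#'
#' @param cfg A [model_config()].
#' @return Object of class `methyl_model`.
#' @export
build_model <- function(cfg) {
  if (!inherits(cfg, "model_config")) stopf("cfg must be a model_config")
  set.seed(cfg$seed)
  p <- list()
  if (cfg$mode != "signal_only") {
    p$embed <- init_mat(4L, cfg$embed_dim, 0.5)
    p$seq_lstm <- init_bilstm(cfg$embed_dim + 3L, cfg$branch_hidden)
    p$seq_fc <- init_fc(2L * cfg$branch_hidden, cfg$branch_out)
  }
  if (cfg$mode != "sequence_only") {
    p$sig_lstm <- init_bilstm(cfg$m, cfg$branch_hidden)
    p$sig_fc <- init_fc(2L * cfg$branch_hidden, cfg$branch_out)
  }
  d0 <- cfg$branch_out * (if (cfg$mode == "full") 2L else 1L)
  p$merged <- vector("list", cfg$merged_layers)
  for (l in seq_len(cfg$merged_layers)) {
    p$merged[[l]] <- init_bilstm(if (l == 1L) d0 else 2L * cfg$merged_hidden,
                                 cfg$merged_hidden)
  }
  p$fc1 <- init_fc(2L * cfg$merged_hidden, cfg$merged_hidden)
  p$fc2 <- init_fc(cfg$merged_hidden, 2L)
  structure(list(cfg = cfg, params = p, history = NULL), class = "methyl_model")
}

#' Number of trainable parameters of a model
#' @param model A `methyl_model`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(model) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  as.integer(cnt(model$params))
}

#' @export
print.methyl_model <- function(x, ...) {
  cat(sprintf("<methyl_model: mode=%s, k=%d, m=%d, %d parameters%s>\n",
              x$cfg$mode, x$cfg$k, x$cfg$m, parameter_count(x),
              if (is.null(x$history)) ", untrained" else ", trained"))
  invisible(x)
}

# Assemble the timestep-major inputs of a batch from a site_samples subset.
make_batch <- function(ss, idx, cfg) {
  list(code = ss$seq_code[idx, , drop = FALSE],
       mean = ss$seq_mean[idx, , drop = FALSE],
       sd = ss$seq_sd[idx, , drop = FALSE],
       count = log1p(ss$seq_count[idx, , drop = FALSE]),
       signal = ss$signal[idx, , , drop = FALSE],
       label = ss$info$label[idx])
}

model_forward <- function(model, batch, training = FALSE) {
  cfg <- model$cfg; p <- model$params
  k <- cfg$k
  cache <- list()
  branch_out <- NULL

  if (cfg$mode != "signal_only") {
    Xs <- vector("list", k)
    for (t in seq_len(k)) {
      Xs[[t]] <- cbind(p$embed[batch$code[, t] + 1L, , drop = FALSE],
                       batch$mean[, t], batch$sd[, t], batch$count[, t])
    }
    seq_bl <- bilstm_forward(Xs, p$seq_lstm)
    seq_dp <- dropout_seq_forward(seq_bl$out, cfg$dropout_rate, training)
    seq_fc <- fc_seq_forward(seq_dp$Y, p$seq_fc, relu = TRUE)
    cache$seq <- list(bl = seq_bl, dp = seq_dp, fc = seq_fc)
    branch_out <- seq_fc$Y
  }
  if (cfg$mode != "sequence_only") {
    Xg <- vector("list", k)
    for (t in seq_len(k)) Xg[[t]] <- batch$signal[, t, , drop = TRUE]
    if (!is.matrix(Xg[[1]])) Xg <- lapply(Xg, function(x) matrix(x, nrow = 1))
    sig_bl <- bilstm_forward(Xg, p$sig_lstm)
    sig_dp <- dropout_seq_forward(sig_bl$out, cfg$dropout_rate, training)
    sig_fc <- fc_seq_forward(sig_dp$Y, p$sig_fc, relu = TRUE)
    cache$sig <- list(bl = sig_bl, dp = sig_dp, fc = sig_fc)
    branch_out <- if (is.null(branch_out)) sig_fc$Y else {
      mapply(cbind, branch_out, sig_fc$Y, SIMPLIFY = FALSE)
    }
  }

  merged_in <- branch_out
  cache$merged <- vector("list", cfg$merged_layers)
  for (l in seq_len(cfg$merged_layers)) {
    bl <- bilstm_forward(merged_in, p$merged[[l]])
    if (l < cfg$merged_layers) {
      dp <- dropout_seq_forward(bl$out, cfg$dropout_rate, training)
      cache$merged[[l]] <- list(bl = bl, dp = dp)
      merged_in <- dp$Y
    } else {
      cache$merged[[l]] <- list(bl = bl)
    }
  }
  final <- cache$merged[[cfg$merged_layers]]$bl$final
  dp_f <- dropout_forward(final, cfg$dropout_rate, training)
  fc1 <- fc_forward(dp_f$Y, p$fc1, relu = TRUE)
  dp1 <- dropout_forward(fc1$Y, cfg$dropout_rate, training)
  fc2 <- fc_forward(dp1$Y, p$fc2, relu = FALSE)
  cache$head <- list(dp_f = dp_f, fc1 = fc1, dp1 = dp1, fc2 = fc2)
  list(logits = fc2$Y, probs = softmax(fc2$Y), cache = cache)
}

model_backward <- function(model, batch, fw, dlogits) {
  cfg <- model$cfg; p <- model$params
  k <- cfg$k
  g <- list()
  hd <- fw$cache$head
  b2 <- fc_backward(dlogits, hd$fc2, p$fc2, relu = FALSE)
  g$fc2 <- b2$grads
  d1 <- b2$dX
  if (!is.null(hd$dp1$mask)) d1 <- d1 * hd$dp1$mask
  b1 <- fc_backward(d1, hd$fc1, p$fc1, relu = TRUE)
  g$fc1 <- b1$grads
  dfinal <- b1$dX
  if (!is.null(hd$dp_f$mask)) dfinal <- dfinal * hd$dp_f$mask

  g$merged <- vector("list", cfg$merged_layers)
  dOut <- NULL
  for (l in rev(seq_len(cfg$merged_layers))) {
    mc <- fw$cache$merged[[l]]
    if (l == cfg$merged_layers) {
      bb <- bilstm_backward(NULL, dfinal, mc$bl, p$merged[[l]])
    } else {
      dOut <- dropout_seq_backward(dOut, mc$dp$masks)
      bb <- bilstm_backward(dOut, NULL, mc$bl, p$merged[[l]])
    }
    g$merged[[l]] <- bb$grads
    dOut <- bb$dX
  }

  # dOut now carries gradients w.r.t. the concatenated branch outputs
  if (cfg$mode == "full") {
    fb <- cfg$branch_out
    d_seq <- lapply(dOut, function(x) x[, 1:fb, drop = FALSE])
    d_sig <- lapply(dOut, function(x) x[, (fb + 1L):(2L * fb), drop = FALSE])
  } else if (cfg$mode == "sequence_only") {
    d_seq <- dOut; d_sig <- NULL
  } else {
    d_seq <- NULL; d_sig <- dOut
  }

  if (!is.null(d_seq)) {
    sc <- fw$cache$seq
    bfc <- fc_seq_backward(d_seq, sc$fc, p$seq_fc, relu = TRUE)
    g$seq_fc <- bfc$grads
    dbl <- dropout_seq_backward(bfc$dX, sc$dp$masks)
    bbl <- bilstm_backward(dbl, NULL, sc$bl, p$seq_lstm)
    g$seq_lstm <- bbl$grads
    dE <- p$embed * 0
    e <- cfg$embed_dim
    for (t in seq_len(k)) {
      dxe <- bbl$dX[[t]][, 1:e, drop = FALSE]
      code_t <- batch$code[, t]
      for (cval in 0:3) {
        rows <- code_t == cval
        if (any(rows)) dE[cval + 1L, ] <- dE[cval + 1L, ] + colSums(dxe[rows, , drop = FALSE])
      }
    }
    g$embed <- dE
  }
  if (!is.null(d_sig)) {
    sc <- fw$cache$sig
    bfc <- fc_seq_backward(d_sig, sc$fc, p$sig_fc, relu = TRUE)
    g$sig_fc <- bfc$grads
    dbl <- dropout_seq_backward(bfc$dX, sc$dp$masks)
    bbl <- bilstm_backward(dbl, NULL, sc$bl, p$sig_lstm)
    g$sig_lstm <- bbl$grads
  }
  g[names(model$params)]
}

# Cross-entropy loss and gradients for one labelled batch.
model_loss_grads <- function(model, batch, training = TRUE) {
  fw <- model_forward(model, batch, training = training)
  B <- nrow(fw$probs)
  y1 <- batch$label + 1L  # column index: 1 = unmethylated, 2 = methylated
  eps <- 1e-12
  loss <- -mean(log(fw$probs[cbind(seq_len(B), y1)] + eps))
  Y <- matrix(0, B, 2L)
  Y[cbind(seq_len(B), y1)] <- 1
  dlogits <- (fw$probs - Y) / B
  list(loss = loss, grads = model_backward(model, batch, fw, dlogits))
}

#' Train a methylation classifier
#'
#' Minimizes softmax cross-entropy with the Adam optimizer. When a validation
#' set is given, validation accuracy is computed each epoch, the best-scoring
#' parameters are retained, and (if `early_stopping` is enabled in the
#' configuration) training stops as soon as the accuracy of the current epoch
#' falls below the best seen so far. All randomness (shuffling, dropout)
#' derives from the configuration seed, so training is reproducible.
#'
#' @param model An untrained (or trained) `methyl_model` from [build_model()].
#' @param train_samples Labelled `site_samples`.
#' @param valid_samples Optional labelled `site_samples` for validation.
#' @param epochs Optional override of `cfg$max_epochs`.
#' @return The trained model; `model$history` holds a data.frame with
#'   per-epoch training loss and validation accuracy.
#' @export
train_model <- function(model, train_samples, valid_samples = NULL, epochs = NULL) {
  cfg <- model$cfg
  n <- n_samples(train_samples)
  if (n == 0L) stopf("empty training set")
  if (anyNA(train_samples$info$label)) stopf("training samples must be labelled")
  epochs <- as.integer(epochs %||% cfg$max_epochs)
  set.seed(cfg$seed)
  state <- adam_init(model$params)
  best_acc <- -Inf
  best_params <- model$params
  hist <- data.frame(epoch = integer(), train_loss = numeric(), valid_acc = numeric())
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    tot_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      if (length(idx) < 2L) next  # drop degenerate 1-sample tail batches
      batch <- make_batch(train_samples, idx, cfg)
      lg <- model_loss_grads(model, batch, training = TRUE)
      st <- adam_step(model$params, lg$grads, state, cfg$learning_rate)
      model$params <- st$params
      state <- st$state
      tot_loss <- tot_loss + lg$loss * length(idx)
      nb <- nb + length(idx)
    }
    acc <- NA_real_
    if (!is.null(valid_samples) && n_samples(valid_samples) > 0L) {
      pv <- predict(model, valid_samples)
      acc <- mean((pv$p_methylated > 0.5) == (valid_samples$info$label == 1L))
      if (cfg$early_stopping && acc < best_acc) {
        hist <- rbind(hist, data.frame(epoch = ep, train_loss = tot_loss / nb, valid_acc = acc))
        break
      }
      if (acc >= best_acc) {
        best_acc <- acc
        best_params <- model$params
      }
    } else {
      best_params <- model$params
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tot_loss / nb, valid_acc = acc))
  }
  model$params <- best_params
  model$history <- hist
  model
}

#' Predict methylation probabilities for samples
#'
#' @param object A trained `methyl_model`.
#' @param samples A `site_samples` object.
#' @param ... Unused.
#' @return data.frame with columns `p_methylated`, `p_unmethylated`
#'   (softmax-normalized, summing to 1), one row per sample in input order.
#' @export
predict.methyl_model <- function(object, samples, ...) {
  cfg <- object$cfg
  n <- n_samples(samples)
  out <- matrix(NA_real_, n, 2L)
  if (n > 0L) {
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- start:min(start + cfg$batch_size - 1L, n)
      batch <- make_batch(samples, idx, cfg)
      fw <- model_forward(object, batch, training = FALSE)
      out[idx, ] <- fw$probs
    }
  }
  data.frame(p_methylated = out[, 2L], p_unmethylated = out[, 1L])
}

#' Split samples into training and validation sets
#'
#' @param samples A `site_samples` object.
#' @param ratio Fraction assigned to training (default 0.99, a 99:1 split).
#' @param seed Integer seed.
#' @return List with elements `train` and `valid`; the two parts are
#'   disjoint and exhaustive.
#' @export
split_train_valid <- function(samples, ratio = 0.99, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stopf("ratio must be in (0,1)")
  n <- n_samples(samples)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- floor(n * ratio)
  list(train = subset_samples(samples, perm[seq_len(n_train)]),
       valid = subset_samples(samples, perm[setdiff(seq_len(n), seq_len(n_train))]))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: it stores the configuration and all
#' weights.
#'
#' @param model A `methyl_model`.
#' @param path Checkpoint path.
#' @return `path` invisibly (`save_model`); the restored model (`load_model`).
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  structure(x, class = "methyl_model")
}
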